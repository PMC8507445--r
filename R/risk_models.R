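#' Validate a baseline cancer-rate table
#'
#' Baseline (unexposed-population) cancer rates per 100,000 person-years,
#' by site, sex, age and kind (incidence or mortality). Rates between
#' tabulated ages are linearly interpolated; beyond the last tabulated age
#' the last value is held.
#'
#' @param df data.frame with columns `site`, `sex`, `age`, `rate_per_100k`,
#'   `kind`.
#' @return the validated data.frame with class `baseline_rates`.
#' @export
baseline_rates <- function(df) {
  need <- c("site", "sex", "age", "rate_per_100k", "kind")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop2("baseline-rate table is missing column(s): ", paste(miss, collapse = ", "))
  reg <- site_registry()$site
  unknown <- setdiff(unique(df$site), reg)
  if (length(unknown))
    stop2("unknown cancer site(s): ", paste(unknown, collapse = ", "))
  if (!all(df$sex %in% c("male", "female")))
    stop2("`sex` must be 'male' or 'female'")
  if (!all(df$kind %in% c("incidence", "mortality")))
    stop2("`kind` must be 'incidence' or 'mortality'")
  if (any(df$rate_per_100k < 0)) stop2("baseline rates must be >= 0")
  if (any(df$age < 0)) stop2("ages must be >= 0")
  class(df) <- c("baseline_rates", "data.frame")
  df
}

#' Baseline rate at given ages
#'
#' Looks up one site/sex/kind series and evaluates it at `ages` by linear
#' interpolation, holding the boundary values outside the tabulated range.
#'
#' @param baseline a [baseline_rates()] table.
#' @param site,sex,kind series selectors.
#' @param ages ages in years (vectorized).
#' @return rate per 100,000 person-years at each age.
#' @export
baseline_rate_at <- function(baseline, site, sex, kind, ages) {
  sub <- baseline[baseline$site == site & baseline$sex == sex &
                    baseline$kind == kind, , drop = FALSE]
  if (!nrow(sub))
    stop2(sprintf("no baseline %s rates for site '%s', sex '%s'", kind, site, sex))
  if (nrow(sub) == 1L) return(rep(sub$rate_per_100k, length(ages)))
  stats::approx(sub$age, sub$rate_per_100k, xout = ages,
                method = "linear", rule = 2)$y
}

#' Excess-risk model parameters for one cancer site
#'
#' The parametric family of the BEIR VII / EPA risk models: excess relative
#' risk (ERR) and excess absolute risk (EAR) both of the form
#' \deqn{\beta \exp(\gamma e^*) (a/60)^\eta,\qquad
#'       e^* = (\min(e, 30) - 30)/10,}
#' mixed additively on the excess-rate scale with transport weight `w`,
#' scaled by the dose response `f(D)` (`D` linear; `D(1+\theta D)`
#' linear-quadratic) and divided by the DDREF.
#'
#' @param site site label from [site_registry()].
#' @param sex `"male"` or `"female"`.
#' @param beta_err ERR per Gy at the reference ages (`e = 30`, `a = 60`).
#' @param beta_ear EAR per 10,000 person-years per Gy at the reference ages.
#' @param gamma per-decade log-linear coefficient in age at exposure
#'   (age-at-exposure effect is capped at `e = 30`).
#' @param eta power of attained age (pivot `a = 60`).
#' @param transport_weight ERR-vs-EAR mixing weight `w` in `[0, 1]`
#'   (1 = pure relative-risk transport, 0 = pure absolute).
#' @param ddref dose and dose-rate effectiveness factor, `>= 1`.
#' @param latency years after exposure with no attributed excess risk
#'   (default 5; 2 for leukaemia).
#' @param dose_response `"linear"` or `"linear_quadratic"`.
#' @param theta curvature per Gy (linear-quadratic only).
#' @param target_organ dosimetry organ whose absorbed dose drives this site.
#' @return an object of class `risk_model_params`.
#' @export
risk_model_params <- function(site, sex, beta_err, beta_ear,
                              gamma = 0, eta = 0,
                              transport_weight = 0.7, ddref = 1.5,
                              latency = 5, dose_response = "linear",
                              theta = 0, target_organ = NULL) {
  sex <- check_sex(sex)
  reg <- site_registry()
  if (!site %in% reg$site) stop2("unknown cancer site: ", site)
  dose_response <- match.arg(dose_response, c("linear", "linear_quadratic"))
  if (beta_err < 0 || beta_ear < 0) stop2("beta coefficients must be >= 0")
  if (transport_weight < 0 || transport_weight > 1)
    stop2("`transport_weight` must lie in [0, 1]")
  if (ddref < 1) stop2("`ddref` must be >= 1")
  if (latency < 0) stop2("`latency` must be >= 0")
  target_organ <- target_organ %||% reg$target_organ[match(site, reg$site)]
  structure(list(site = site, sex = sex, beta_err = beta_err,
                 beta_ear = beta_ear, gamma = gamma, eta = eta,
                 transport_weight = transport_weight, ddref = ddref,
                 latency = latency, dose_response = dose_response,
                 theta = theta, target_organ = target_organ),
            class = "risk_model_params")
}

#' @export
print.risk_model_params <- function(x, ...) {
  cat(sprintf(
    "<risk_model_params> %s (%s): ERR %.3g, EAR %.3g, gamma %.3g, eta %.3g, w %.2f, DDREF %.2f, L %d y, %s\n",
    x$site, x$sex, x$beta_err, x$beta_ear, x$gamma, x$eta,
    x$transport_weight, x$ddref, as.integer(x$latency), x$dose_response))
  invisible(x)
}

estar <- function(e) (pmin(e, 30) - 30) / 10

age_modifiers <- function(params, e, a) {
  if (any(a < e + params$latency))
    stop2(sprintf("attained age inside the %g-year latency period after exposure at age %g",
                  params$latency, e))
  exp(params$gamma * estar(e)) * (a / 60)^params$eta
}

#' Excess relative risk per Gy
#'
#' `beta_err * exp(gamma * e*) * (a/60)^eta` with
#' `e* = (min(e, 30) - 30)/10`.
#'
#' @param params a [risk_model_params()].
#' @param e age at exposure, years.
#' @param a attained age, years (`>= e + latency`); vectorized.
#' @return dimensionless ERR per Gy.
#' @export
err <- function(params, e, a) {
  stopifnot(inherits(params, "risk_model_params"))
  params$beta_err * age_modifiers(params, e, a)
}

#' Excess absolute risk per Gy
#'
#' Same age structure as [err()], on the scale of excess cases per
#' 10,000 person-years per Gy.
#'
#' @inheritParams err
#' @return EAR per 10,000 person-years per Gy.
#' @export
ear <- function(params, e, a) {
  stopifnot(inherits(params, "risk_model_params"))
  params$beta_ear * age_modifiers(params, e, a)
}

#' Age-specific excess cancer rate M(D, e, a)
#'
#' The excess rate of cancer diagnosis (or death, with mortality baselines)
#' at attained age `a` for an organ absorbed dose `D` received at age `e`:
#' \deqn{M = \frac{f(D)}{\mathrm{DDREF}}\left[w\,\mathrm{ERR}(e,a)\,\lambda(a)
#'   + (1-w)\,\frac{\mathrm{EAR}(e,a)}{10{,}000}\right]}
#' where `lambda(a)` is the baseline rate per person-year and `f(D)` the
#' dose response.
#'
#' @inheritParams err
#' @param baseline a [baseline_rates()] table covering the site and sex.
#' @param D absorbed dose to the target organ, Gy.
#' @param kind `"incidence"` or `"mortality"` baseline series.
#' @return excess events per person-year at each `a`.
#' @export
excess_rate <- function(params, baseline, D, e, a, kind = "incidence") {
  stopifnot(inherits(params, "risk_model_params"))
  if (D < 0) stop2("absorbed dose must be >= 0")
  kind <- match.arg(kind, c("incidence", "mortality"))
  lambda <- baseline_rate_at(baseline, params$site, params$sex, kind, a) / 1e5
  fD <- if (params$dose_response == "linear_quadratic")
    D * (1 + params$theta * D) else D
  mods <- age_modifiers(params, e, a)
  w <- params$transport_weight
  fD / params$ddref *
    (w * params$beta_err * mods * lambda +
       (1 - w) * params$beta_ear * mods / 1e4)
}
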