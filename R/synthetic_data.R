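#' Configuration for the synthetic-data generator
#'
#' The generator emulates the statistical structure of the national inputs
#' the LAR pipeline consumes — life-table survivorship, baseline cancer
#' rates, organ dose coefficients and risk-model parameter sets — with
#' known, recorded ground truth. Mortality follows a Gompertz-Makeham
#' hazard; cancer incidence follows site-specific power laws in age,
#' calibrated so the sex-specific lifetime baseline cancer risk matches
#' the nominal population values (39.3% men, 37.7% women); dose
#' coefficients decrease from age 1 to adult as internal dosimetry tables
#' do.
#'
#' @param seed integer seed; everything downstream is deterministic in it.
#' @param gompertz list `alpha` (baseline hazard /yr), `beta` (log-slope
#'   /yr), `makeham` (age-independent hazard /yr).
#' @param female_hazard_factor multiplier on `alpha` for the female table
#'   (women outlive men).
#' @param lifetime_risk named targets for the calibrated lifetime baseline
#'   cancer incidence risk per sex.
#' @param power_range,onset_range ranges for the per-site incidence
#'   power-law exponent and onset age.
#' @param lethality_range range of the per-site mortality/incidence ratio.
#' @param adult_coeff_range adult dose-coefficient range, mGy/MBq.
#' @param age_ratio_range range of the age-1 / adult coefficient ratio.
#' @param beta_err_range,beta_ear_range,gamma_range,eta_range,w_range
#'   draw ranges for the risk-model parameters.
#' @param theta_range curvature range (per Gy) for the leukaemia
#'   linear-quadratic response.
#' @param ddref_solid DDREF applied to solid sites (leukaemia uses 1).
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             gompertz = list(alpha = 5e-5, beta = 0.09,
                                             makeham = 5e-4),
                             female_hazard_factor = 0.8,
                             lifetime_risk = c(male = 0.393, female = 0.377),
                             power_range = c(1.5, 2.5),
                             onset_range = c(0, 45),
                             lethality_range = c(0.2, 0.9),
                             adult_coeff_range = c(0.001, 0.01),
                             age_ratio_range = c(2, 10),
                             beta_err_range = c(0.1, 1),
                             beta_ear_range = c(0.5, 5),
                             gamma_range = c(-0.5, -0.1),
                             eta_range = c(-2, 1.5),
                             w_range = c(0.3, 0.7),
                             theta_range = c(0.5, 1.5),
                             ddref_solid = 1.5) {
  stopifnot(gompertz$alpha >= 0, gompertz$makeham >= 0,
            gompertz$alpha + gompertz$makeham >= 0)
  structure(list(seed = as.integer(seed), gompertz = gompertz,
                 female_hazard_factor = female_hazard_factor,
                 lifetime_risk = lifetime_risk,
                 power_range = power_range, onset_range = onset_range,
                 lethality_range = lethality_range,
                 adult_coeff_range = adult_coeff_range,
                 age_ratio_range = age_ratio_range,
                 beta_err_range = beta_err_range,
                 beta_ear_range = beta_ear_range,
                 gamma_range = gamma_range, eta_range = eta_range,
                 w_range = w_range, theta_range = theta_range,
                 ddref_solid = ddref_solid),
            class = "synthetic_config")
}

#' Synthetic Gompertz-Makeham life table
#'
#' `l(a) = exp(-sum_{u<a} (c + alpha exp(beta u)))` on ages 0..110;
#' deterministic given the configuration (no random draws). With the
#' default parameters life expectancy falls around 80 years.
#'
#' @param config a [synthetic_config()].
#' @param sex `"male"` or `"female"`; the female table scales `alpha` by
#'   `female_hazard_factor`.
#' @return a [life_table()].
#' @export
make_lifetable <- function(config, sex = "male") {
  stopifnot(inherits(config, "synthetic_config"))
  sex <- check_sex(sex)
  g <- config$gompertz
  alpha <- g$alpha * if (sex == "female") config$female_hazard_factor else 1
  u <- 0:109
  hazard <- g$makeham + alpha * exp(g$beta * u)
  lx <- c(1, exp(-cumsum(hazard)))
  lt <- life_table(sex, 0:110, lx)
  e0 <- life_expectancy(lt)
  if (lx[111] > 0.05)
    warning(sprintf("implausible population: l(110) = %.3g > 0.05", lx[111]))
  if (e0 < 40 || e0 > 100)
    warning(sprintf("implausible population: life expectancy %.1f y outside [40, 100]", e0))
  lt
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

#' Synthetic baseline cancer-rate tables
#'
#' Per-site incidence rates `lambda_s(a) = base_s max(0, a - onset_s)^{p_s}`
#' per 100,000 person-years, for both sexes and for incidence and
#' mortality (mortality = incidence x a per-site lethality in (0, 1]).
#' The per-site scales `base_s` are calibrated so that the survival-
#' weighted lifetime incidence risk per sex equals the configured targets.
#' Ground truth (base, power, onset, lethality, share) is attached as the
#' `"ground_truth"` attribute.
#'
#' @param config a [synthetic_config()].
#' @return a [baseline_rates()] data.frame covering all registry sites,
#'   both sexes, ages 0..110, both kinds.
#' @export
make_baseline_rates <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  ages <- 0:110
  out <- list()
  truth <- list()
  for (sex in c("male", "female")) {
    lt <- make_lifetable(config, sex)
    g <- trapezoid_grid(0, 110, 1)
    S <- survival_at(lt, g$a)
    sites <- sites_for_sex(sex)$site
    draws <- with_seed(config$seed + if (sex == "male") 11L else 12L, {
      data.frame(site = sites,
                 power = stats::runif(length(sites), config$power_range[1],
                                      config$power_range[2]),
                 onset = stats::runif(length(sites), config$onset_range[1],
                                      config$onset_range[2]),
                 lethality = stats::runif(length(sites),
                                          config$lethality_range[1],
                                          config$lethality_range[2]),
                 share_raw = stats::runif(length(sites), 0.2, 1))
    })
    draws$share <- draws$share_raw / sum(draws$share_raw)
    draws$base <- NA_real_
    total_target <- unname(config$lifetime_risk[[sex]])
    for (i in seq_along(sites)) {
      shape <- pmax(0, ages - draws$onset[i])^draws$power[i]
      # calibrate base so this site's survival-weighted lifetime risk
      # equals its share of the sex total
      integral <- sum(g$w * pmax(0, g$a - draws$onset[i])^draws$power[i] * S) / 1e5
      base <- if (integral > 0) draws$share[i] * total_target / integral else 0
      draws$base[i] <- base
      rate <- base * shape
      out[[length(out) + 1L]] <- data.frame(
        site = sites[i], sex = sex, age = ages,
        rate_per_100k = rate, kind = "incidence",
        stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        site = sites[i], sex = sex, age = ages,
        rate_per_100k = rate * draws$lethality[i], kind = "mortality",
        stringsAsFactors = FALSE)
    }
    draws$sex <- sex
    truth[[sex]] <- draws
  }
  res <- baseline_rates(do.call(rbind, out))
  attr(res, "ground_truth") <- do.call(rbind, truth)
  res
}

#' Synthetic dose-coefficient table
#'
#' Per-organ coefficients strictly decreasing from the age-1 phantom to
#' the adult phantom (children receive more dose per MBq), with the
#' age-1/adult ratio drawn from the configured range; labelled as a
#' bone-seeking 99mTc agent so the adult interpolation anchor sits at
#' 25 years.
#'
#' @param config a [synthetic_config()].
#' @param organs organ labels; default the registry's target organs.
#' @param bone_seeker logical, default `TRUE`.
#' @return a [dose_coefficient_table()].
#' @export
make_dose_coefficients <- function(config,
                                   organs = unique(site_registry()$target_organ),
                                   bone_seeker = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  df <- with_seed(config$seed + 21L, {
    rows <- lapply(organs, function(o) {
      adult <- runif1(config$adult_coeff_range)
      ratio <- runif1(config$age_ratio_range)
      frac <- c(1, 0.75, 0.5, 0.25, 0) # log-linear decay across age groups
      data.frame(radiopharmaceutical = "99mTc-phosphonate-synthetic",
                 organ = o, age_group = AGE_GROUPS,
                 mGy_per_MBq = adult * ratio^frac,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  dose_coefficient_table(df, bone_seeker = bone_seeker)
}

#' Synthetic risk-model parameter set
#'
#' Draws per-site ERR/EAR coefficients and age modifiers from the
#' configured ranges for every site applicable to `sex`. Leukaemia gets
#' the linear-quadratic dose response, latency 2 and DDREF 1; solid sites
#' are linear with the solid DDREF and latency 5. The drawn values are
#' attached as the `"ground_truth"` attribute for parameter-recovery
#' checks.
#'
#' @param config a [synthetic_config()].
#' @param sex `"male"` or `"female"`.
#' @return named list of [risk_model_params()], one per site.
#' @export
make_risk_params <- function(config, sex = "male") {
  stopifnot(inherits(config, "synthetic_config"))
  sex <- check_sex(sex)
  reg <- sites_for_sex(sex)
  models <- with_seed(config$seed + 31L + if (sex == "male") 0L else 100L, {
    lapply(seq_len(nrow(reg)), function(i) {
      lq <- reg$dose_response[i] == "linear_quadratic"
      risk_model_params(
        site = reg$site[i], sex = sex,
        beta_err = runif1(config$beta_err_range),
        beta_ear = runif1(config$beta_ear_range),
        gamma = runif1(config$gamma_range),
        eta = runif1(config$eta_range),
        transport_weight = runif1(config$w_range),
        ddref = if (lq) 1 else config$ddref_solid,
        latency = reg$latency[i],
        dose_response = reg$dose_response[i],
        theta = if (lq) runif1(config$theta_range) else 0,
        target_organ = reg$target_organ[i])
    })
  })
  names(models) <- reg$site
  truth <- data.frame(
    site = reg$site, sex = sex,
    beta_err = vapply(models, `[[`, numeric(1), "beta_err"),
    beta_ear = vapply(models, `[[`, numeric(1), "beta_ear"),
    gamma = vapply(models, `[[`, numeric(1), "gamma"),
    eta = vapply(models, `[[`, numeric(1), "eta"),
    transport_weight = vapply(models, `[[`, numeric(1), "transport_weight"),
    theta = vapply(models, `[[`, numeric(1), "theta"),
    row.names = NULL)
  attr(models, "ground_truth") <- truth
  models
}

#' The study's three patient cohorts
#'
#' Paget's disease (5-year survival 93%) and prostate cancer with bone
#' metastases (2-year survival 68% with one lesion, 22% with more than
#' one), as [cohort_spec()] objects.
#'
#' @return named list of [cohort_spec()].
#' @export
default_cohorts <- function() {
  list(pagets = cohort_spec("pagets", 0.93, 5),
       one_lesion = cohort_spec("one_lesion", 0.68, 2),
       multiple_lesions = cohort_spec("multiple_lesions", 0.22, 2))
}

#' Assemble a fully synthetic model stack
#'
#' Convenience constructor: life tables, baseline rates, risk models and
#' dose coefficients for both sexes, all generated from one seeded
#' configuration.
#'
#' @param config a [synthetic_config()].
#' @param kind default rate series for the stack.
#' @return a [lar_stack()].
#' @export
#' @examples
#' stack <- synthetic_stack(synthetic_config(seed = 1))
#' stack_lar(stack, "male", 40, 500)
synthetic_stack <- function(config = synthetic_config(), kind = "incidence") {
  lar_stack(
    life_tables = list(male = make_lifetable(config, "male"),
                       female = make_lifetable(config, "female")),
    baselines = make_baseline_rates(config),
    models = list(male = make_risk_params(config, "male"),
                  female = make_risk_params(config, "female")),
    dose_coefficients = make_dose_coefficients(config),
    kind = kind)
}
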