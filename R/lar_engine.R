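#' Define an exposure scenario
#'
#' @param sex `"male"` or `"female"`.
#' @param age_at_exposure years (0 to the life-table maximum).
#' @param activity administered activity, MBq (`> 0`).
#' @param cohort optional [cohort_spec()] for a patient group with reduced
#'   life expectancy; `NULL` for the general population.
#' @return an object of class `exposure_scenario`.
#' @export
exposure_scenario <- function(sex, age_at_exposure, activity = 500,
                              cohort = NULL) {
  sex <- check_sex(sex)
  if (age_at_exposure < 0) stop2("`age_at_exposure` must be >= 0")
  if (activity <= 0) stop2("`activity` must be > 0 MBq")
  if (!is.null(cohort)) stopifnot(inherits(cohort, "cohort_spec"))
  structure(list(sex = sex, age_at_exposure = age_at_exposure,
                 activity = activity, cohort = cohort),
            class = "exposure_scenario")
}

# trapezoidal quadrature nodes/weights on [lo, hi] at the given step
trapezoid_grid <- function(lo, hi, step) {
  a <- seq(lo, hi, by = step)
  if (a[length(a)] < hi) a <- c(a, hi)
  w <- c(diff(a), 0) / 2 + c(0, diff(a)) / 2
  list(a = a, w = w)
}

#' Lifetime attributable risk for one cancer site
#'
#' Integrates the survival-adjusted excess rate over attained age,
#' \deqn{\mathrm{LAR}(D,e) = \int_{e+L}^{110} M(D,e,a)\,
#'   \frac{S(a)}{S(e+L)}\,\mathrm{d}a,}
#' by the trapezoidal rule on an annual grid (the native resolution of
#' life tables and cancer-rate statistics). When a cohort is set, the
#' survivorship `S(a)` in the numerator is the cohort-modified curve while
#' the normalizing `S(e+L)` is the general population's, so the cohort's
#' excess mortality after exposure lowers the projected risk.
#'
#' @param params a [risk_model_params()] for the site.
#' @param baseline a [baseline_rates()] table.
#' @param table the population [life_table()].
#' @param D absorbed dose to the site's target organ, Gy.
#' @param e age at exposure, years.
#' @param kind `"incidence"` or `"mortality"`.
#' @param cohort optional [cohort_spec()].
#' @param step integration step in years (default 1; smaller steps are for
#'   convergence checks only).
#' @param upper upper integration limit (default 110 years).
#' @param cohort_table pre-modified life table, to avoid recomputing the
#'   cohort modification per site (internal use).
#' @return LAR, a dimensionless probability.
#' @export
lar_site <- function(params, baseline, table, D, e, kind = "incidence",
                     cohort = NULL, step = 1, upper = 110,
                     cohort_table = NULL) {
  stopifnot(inherits(params, "risk_model_params"),
            inherits(table, "life_table"))
  L <- params$latency
  upper <- min(upper, max_age(table))
  if (e + L >= upper) {
    warning(sprintf("exposure age %g + latency %g reaches the upper age limit %g; LAR = 0",
                    e, L, upper))
    return(0)
  }
  s_ref <- survival_at(table, e + L)
  if (s_ref <= 0)
    stop2("cohort extinct before latency end: population survivorship is 0 at age ",
          format(e + L))
  tab <- cohort_table %||%
    (if (is.null(cohort)) table else apply_cohort_modification(table, cohort, e))
  g <- trapezoid_grid(e + L, upper, step)
  M <- excess_rate(params, baseline, D, e, g$a, kind = kind)
  sum(g$w * M * survival_at(tab, g$a)) / s_ref
}

check_model_set <- function(models) {
  if (!length(models)) stop2("empty risk-model set")
  ok <- vapply(models, inherits, logical(1), "risk_model_params")
  if (!all(ok)) stop2("`models` must be a list of risk_model_params")
  names(models) <- vapply(models, `[[`, character(1), "site")
  models
}

#' Total LAR across the cancer-site registry
#'
#' Evaluates [lar_site()] for every site in the model set with the dose to
#' that site's target organ, and sums. The per-site values and the total
#' are returned with a provenance digest of every input.
#'
#' @param scenario an [exposure_scenario()].
#' @param models named list of [risk_model_params()], one per site, for the
#'   scenario's sex.
#' @param baselines a [baseline_rates()] table.
#' @param table the population [life_table()] for the scenario's sex.
#' @param doses named numeric vector of organ absorbed doses in Gy (see
#'   [organ_doses()]).
#' @param kind `"incidence"` or `"mortality"`.
#' @param step integration step, years.
#' @return an object of class `lar_result` with `per_site`, `total`,
#'   `scenario`, `kind` and `inputs_digest`.
#' @export
lar_total <- function(scenario, models, baselines, table, doses,
                      kind = "incidence", step = 1) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  models <- check_model_set(models)
  organs <- vapply(models, `[[`, character(1), "target_organ")
  gaps <- setdiff(organs, names(doses))
  if (length(gaps))
    stop2("no organ dose supplied for: ", paste(sort(unique(gaps)), collapse = ", "))
  e <- scenario$age_at_exposure
  ctab <- if (!is.null(scenario$cohort))
    apply_cohort_modification(table, scenario$cohort, e)
  per_site <- vapply(models, function(p) {
    lar_site(p, baselines, table, D = unname(doses[[p$target_organ]]),
             e = e, kind = kind, step = step, cohort_table = ctab)
  }, numeric(1))
  structure(list(
    scenario = scenario, kind = kind,
    per_site = per_site, total = sum(per_site),
    inputs_digest = list(models = fingerprint(models),
                         baselines = fingerprint(unclass(baselines)),
                         life_table = fingerprint(table),
                         doses = fingerprint(doses))),
    class = "lar_result")
}

#' LAR of radiation-induced cancer mortality
#'
#' Identical machinery to [lar_total()] with the mortality baseline series.
#'
#' @inheritParams lar_total
#' @return a `lar_result` with `kind = "mortality"`.
#' @export
lar_mortality <- function(scenario, models, baselines, table, doses,
                          step = 1) {
  lar_total(scenario, models, baselines, table, doses,
            kind = "mortality", step = step)
}

#' @export
print.lar_result <- function(x, ...) {
  cat(sprintf("<lar_result> %s LAR, %s age %g, %g MBq%s\n",
              x$kind, x$scenario$sex, x$scenario$age_at_exposure,
              x$scenario$activity,
              if (is.null(x$scenario$cohort)) "" else
                paste0(", cohort ", x$scenario$cohort$name)))
  ord <- order(x$per_site, decreasing = TRUE)
  top <- utils::head(ord, 5)
  for (i in top)
    cat(sprintf("  %-12s %.3e\n", names(x$per_site)[i], x$per_site[i]))
  if (length(ord) > 5) cat(sprintf("  ... %d more sites\n", length(ord) - 5))
  cat(sprintf("  total        %.3e  (%s)\n", x$total, format_one_in(x$total)))
  invisible(x)
}

#' Lifetime baseline cancer risk of an unexposed population
#'
#' Survival-weighted integral of the baseline rate over remaining lifetime,
#' \eqn{\sum_a \lambda(a) S(a)/S(e_0)}, summed over the requested sites.
#' This is the unexposed risk against which LAR values are put in context
#' (e.g. a general baseline cancer risk of roughly 0.4).
#'
#' @param baselines a [baseline_rates()] table.
#' @param table a [life_table()].
#' @param sex `"male"` or `"female"`.
#' @param kind `"incidence"` or `"mortality"`.
#' @param e0 conditioning age (default 0, i.e. risk from birth).
#' @param sites site labels to sum over; default all sites applicable to
#'   `sex` present in `baselines`.
#' @param upper upper age limit (default 110).
#' @return probability.
#' @export
lifetime_baseline_risk <- function(baselines, table, sex,
                                   kind = "incidence", e0 = 0,
                                   sites = NULL, upper = 110) {
  sex <- check_sex(sex)
  kind <- match.arg(kind, c("incidence", "mortality"))
  upper <- min(upper, max_age(table))
  sites <- sites %||% intersect(sites_for_sex(sex)$site,
                                unique(baselines$site[baselines$sex == sex]))
  s0 <- survival_at(table, e0)
  if (s0 <= 0) stop2("population extinct at age ", format(e0))
  g <- trapezoid_grid(e0, upper, 1)
  S <- survival_at(table, g$a) / s0
  total <- 0
  for (s in sites) {
    lam <- baseline_rate_at(baselines, s, sex, kind, g$a) / 1e5
    total <- total + sum(g$w * lam * S)
  }
  total
}

#' Nominal effective-dose risk
#'
#' The ICRP nominal stochastic risk attached to an effective dose:
#' 5.5% per Sv for the whole population, 4.1% per Sv for radiation
#' workers. Provided for side-by-side reporting against LAR; effective
#' dose carries no age or sex dependence.
#'
#' @param E effective dose, Sv (`>= 0`).
#' @param population `"whole"` or `"worker"`.
#' @return probability.
#' @export
#' @examples
#' effective_dose_risk(0.003, "whole") # 1.65e-4
effective_dose_risk <- function(E, population = c("whole", "worker")) {
  population <- match.arg(population)
  if (any(E < 0)) stop2("effective dose must be >= 0")
  E * switch(population, whole = 0.055, worker = 0.041)
}
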