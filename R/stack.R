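#' Bundle all model inputs into a stack
#'
#' A `lar_stack` holds everything needed to evaluate LAR at any (sex, age,
#' activity): per-sex life tables and risk-model sets, the baseline-rate
#' table and the dose-coefficient table. It is the unit the protocol
#' optimizer and the run drivers operate on.
#'
#' @param life_tables named list `list(male = , female = )` of
#'   [life_table()] objects (either sex may be omitted if never queried).
#' @param baselines a [baseline_rates()] table.
#' @param models named list `list(male = , female = )`, each a named list
#'   of [risk_model_params()] per site.
#' @param dose_coefficients a [dose_coefficient_table()].
#' @param kind default rate series, `"incidence"` or `"mortality"`.
#' @return an object of class `lar_stack`.
#' @export
lar_stack <- function(life_tables, baselines, models, dose_coefficients,
                      kind = "incidence") {
  kind <- match.arg(kind, c("incidence", "mortality"))
  stopifnot(is.list(life_tables), is.list(models),
            inherits(dose_coefficients, "dose_coefficient_table"))
  for (s in names(life_tables)) stopifnot(inherits(life_tables[[s]], "life_table"))
  models <- lapply(models, check_model_set)
  structure(list(life_tables = life_tables, baselines = baselines,
                 models = models, dose_coefficients = dose_coefficients,
                 kind = kind),
            class = "lar_stack")
}

#' @export
print.lar_stack <- function(x, ...) {
  cat(sprintf("<lar_stack> sexes: %s; sites: %s; kind: %s\n",
              paste(names(x$models), collapse = ", "),
              paste(vapply(x$models, length, integer(1)), collapse = "/"),
              x$kind))
  invisible(x)
}

#' Total LAR from a stack
#'
#' Fast scalar evaluation used by the protocol optimizer and the drivers:
#' organ doses from the administered activity at the exposure age, then the
#' summed per-site LAR.
#'
#' @param stack a [lar_stack()].
#' @param sex `"male"` or `"female"`.
#' @param age age at exposure, years.
#' @param activity administered activity, MBq.
#' @param cohort optional [cohort_spec()].
#' @param kind rate series; defaults to the stack's.
#' @param step integration step, years.
#' @return total LAR (probability).
#' @export
stack_lar <- function(stack, sex, age, activity, cohort = NULL,
                      kind = stack$kind, step = 1) {
  stopifnot(inherits(stack, "lar_stack"))
  sex <- check_sex(sex)
  table <- stack$life_tables[[sex]]
  if (is.null(table)) stop2("stack has no life table for sex ", sex)
  models <- stack$models[[sex]]
  if (is.null(models)) stop2("stack has no risk models for sex ", sex)
  doses <- organ_doses(stack$dose_coefficients, activity, age)
  ctab <- if (!is.null(cohort)) apply_cohort_modification(table, cohort, age)
  total <- 0
  for (p in models) {
    total <- total + lar_site(p, stack$baselines, table,
                              D = unname(doses[[p$target_organ]]),
                              e = age, kind = kind, step = step,
                              cohort_table = ctab)
  }
  total
}

#' Full LAR result from a stack
#'
#' Convenience wrapper building the [lar_total()] result (per-site values,
#' provenance digest) for one scenario out of a stack.
#'
#' @param stack a [lar_stack()].
#' @param scenario an [exposure_scenario()].
#' @param kind rate series; defaults to the stack's.
#' @return a `lar_result`.
#' @export
stack_lar_result <- function(stack, scenario, kind = stack$kind) {
  sex <- scenario$sex
  doses <- organ_doses(stack$dose_coefficients, scenario$activity,
                       scenario$age_at_exposure)
  lar_total(scenario, stack$models[[sex]], stack$baselines,
            stack$life_tables[[sex]], doses, kind = kind)
}
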