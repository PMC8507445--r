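read_csv_checked <- function(path, need) {
  if (!file.exists(path)) stop2("file not found: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop2("cannot parse '", path, "': ",
                                           conditionMessage(e)),
                 warning = function(w) stop2("malformed CSV '", path, "': ",
                                             conditionMessage(w)))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop2("'", path, "' is missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Read life tables from CSV
#'
#' Expects columns `sex,age,lx`; `lx` may be survivorship in `[0,1]` or raw
#' counts (normalized by the age-0 value). One file may hold both sexes.
#'
#' @param path CSV file path.
#' @return named list of [life_table()] objects, one per sex present.
#' @export
read_life_tables <- function(path) {
  df <- read_csv_checked(path, c("sex", "age", "lx"))
  out <- list()
  for (sx in unique(df$sex)) {
    sub <- df[df$sex == sx, , drop = FALSE]
    sub <- sub[order(sub$age), , drop = FALSE]
    out[[sx]] <- tryCatch(life_table(sx, sub$age, sub$lx),
                          error = function(e) stop2("in '", path, "' (sex ",
                                                    sx, "): ",
                                                    conditionMessage(e)))
  }
  out
}

#' Write life tables to CSV
#'
#' @param tables named list of [life_table()] (or a single one).
#' @param path output CSV path.
#' @export
write_life_tables <- function(tables, path) {
  if (inherits(tables, "life_table")) tables <- list(tables)
  df <- do.call(rbind, lapply(tables, function(t)
    data.frame(sex = t$sex, age = t$ages, lx = t$lx)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read baseline cancer rates from CSV
#'
#' Expects columns `site,sex,age,rate_per_100k,kind`.
#'
#' @param path CSV file path.
#' @return a [baseline_rates()] table.
#' @export
read_baseline_rates <- function(path) {
  df <- read_csv_checked(path, c("site", "sex", "age", "rate_per_100k", "kind"))
  tryCatch(baseline_rates(df),
           error = function(e) stop2("in '", path, "': ", conditionMessage(e)))
}

#' Write baseline cancer rates to CSV
#' @param baselines a [baseline_rates()] table.
#' @param path output CSV path.
#' @export
write_baseline_rates <- function(baselines, path) {
  utils::write.csv(as.data.frame(baselines), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read dose coefficients from CSV
#'
#' Expects columns `radiopharmaceutical,organ,age_group,mGy_per_MBq` with
#' `age_group` in 1, 5, 10, 15, adult.
#'
#' @param path CSV file path.
#' @param bone_seeker logical flag for the agent (CSV carries no flag).
#' @return a [dose_coefficient_table()].
#' @export
read_dose_coefficients <- function(path, bone_seeker = TRUE) {
  df <- read_csv_checked(path, c("radiopharmaceutical", "organ", "age_group",
                                 "mGy_per_MBq"))
  tryCatch(dose_coefficient_table(df, bone_seeker = bone_seeker),
           error = function(e) stop2("in '", path, "': ", conditionMessage(e)))
}

#' Write dose coefficients to CSV
#' @param table a [dose_coefficient_table()].
#' @param path output CSV path.
#' @export
write_dose_coefficients <- function(table, path) {
  df <- data.frame(
    radiopharmaceutical = table$radiopharmaceutical,
    organ = rep(rownames(table$coefficients), each = ncol(table$coefficients)),
    age_group = rep(colnames(table$coefficients),
                    times = nrow(table$coefficients)),
    mGy_per_MBq = as.vector(t(table$coefficients)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write risk-model parameter sets to JSON
#'
#' @param models named list by sex, each a named list of
#'   [risk_model_params()].
#' @param path output JSON path.
#' @export
write_risk_params <- function(models, path) {
  blocks <- list()
  for (sx in names(models))
    for (m in models[[sx]]) blocks[[length(blocks) + 1L]] <- unclass(m)
  jsonlite::write_json(blocks, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read risk-model parameter sets from JSON
#'
#' @param path JSON path written by [write_risk_params()] (or hand-written
#'   blocks with the [risk_model_params()] fields).
#' @return named list by sex of named lists of [risk_model_params()].
#' @export
read_risk_params <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  blocks <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- list()
  for (b in blocks) {
    p <- risk_model_params(
      site = b$site, sex = b$sex, beta_err = b$beta_err,
      beta_ear = b$beta_ear, gamma = b$gamma %||% 0, eta = b$eta %||% 0,
      transport_weight = b$transport_weight %||% 0.7,
      ddref = b$ddref %||% 1.5, latency = b$latency %||% 5,
      dose_response = b$dose_response %||% "linear",
      theta = b$theta %||% 0, target_organ = b$target_organ)
    out[[p$sex]][[p$site]] <- p
  }
  out
}

#' Read and validate a run configuration
#'
#' YAML with paths to the input CSV/JSON files, a `scenario` block
#' (`sexes`, `ages`, `activity`, optional `cohort` name), optional
#' `cohorts` definitions (`name`, `k_year_survival`, `k_years`, optional
#' `window_years`), `kind`, an optional `protocol` block (`A_ref`,
#' `t_ref`, `window`, `target_scope`) and `output_dir`.
#'
#' @param path YAML file path.
#' @return the validated config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (key in c("life_tables", "baseline_rates", "dose_coefficients",
                "risk_params")) {
    if (is.null(cfg[[key]])) stop2("run config is missing '", key, "'")
    if (!file.exists(cfg[[key]]))
      stop2("run config '", key, "' points to a missing file: ", cfg[[key]])
  }
  cfg$kind <- match.arg(cfg$kind %||% "incidence", c("incidence", "mortality"))
  cfg$scenario <- cfg$scenario %||% list()
  cfg$scenario$sexes <- unlist(cfg$scenario$sexes %||% c("male", "female"))
  cfg$scenario$ages <- unlist(cfg$scenario$ages %||% 0:90)
  cfg$scenario$activity <- cfg$scenario$activity %||% 500
  cfg$output_dir <- cfg$output_dir %||% "."
  cfg
}

config_cohorts <- function(config) {
  defs <- default_cohorts()
  for (c in config$cohorts %||% list()) {
    defs[[c$name]] <- cohort_spec(c$name, c$k_year_survival, c$k_years,
                                  window = c$window_years %||%
                                    max(c$k_years, 5))
  }
  defs
}

build_stack_from_config <- function(config) {
  lar_stack(
    life_tables = read_life_tables(config$life_tables),
    baselines = read_baseline_rates(config$baseline_rates),
    models = read_risk_params(config$risk_params),
    dose_coefficients = read_dose_coefficients(
      config$dose_coefficients, bone_seeker = config$bone_seeker %||% TRUE),
    kind = config$kind)
}

#' Run the LAR-versus-age-at-exposure analysis
#'
#' Computes per-site and total LAR for every (sex, age at exposure) on the
#' configured grid, for the general population or a named cohort, and
#' writes `lar_curve.csv` (columns `site,sex,age_at_exposure,kind,lar`,
#' with `site = "total"` rows) plus a JSON report embedding the input
#' provenance digest and "1 in N" renderings of the totals.
#'
#' @param config a config list (see [read_run_config()]) or a YAML path.
#' @return invisibly, the curve data.frame (output paths in attributes).
#' @export
run_lar_curve <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stack <- build_stack_from_config(config)
  cohort <- NULL
  if (!is.null(config$scenario$cohort)) {
    defs <- config_cohorts(config)
    cohort <- defs[[config$scenario$cohort]]
    if (is.null(cohort))
      stop2("unknown cohort '", config$scenario$cohort, "'")
  }
  rows <- list()
  digests <- NULL
  for (sx in config$scenario$sexes) {
    for (a in config$scenario$ages) {
      sc <- exposure_scenario(sx, a, config$scenario$activity, cohort = cohort)
      res <- stack_lar_result(stack, sc, kind = config$kind)
      digests <- digests %||% res$inputs_digest
      rows[[length(rows) + 1L]] <- data.frame(
        site = c(names(res$per_site), "total"), sex = sx,
        age_at_exposure = a, kind = config$kind,
        lar = c(unname(res$per_site), res$total),
        stringsAsFactors = FALSE)
    }
  }
  curve <- do.call(rbind, rows)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(config$output_dir, "lar_curve.csv")
  utils::write.csv(curve, csv_path, row.names = FALSE, quote = FALSE)
  totals <- curve[curve$site == "total", , drop = FALSE]
  report <- list(
    kind = config$kind,
    cohort = config$scenario$cohort %||% "none",
    activity_MBq = config$scenario$activity,
    inputs_digest = digests,
    totals = data.frame(sex = totals$sex,
                        age_at_exposure = totals$age_at_exposure,
                        lar = totals$lar,
                        one_in = format_one_in(totals$lar)))
  json_path <- file.path(config$output_dir, "lar_report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  attr(curve, "csv") <- csv_path
  attr(curve, "json") <- json_path
  invisible(curve)
}

#' Run the equal-risk protocol analysis
#'
#' Builds the stack from the configured files and writes the
#' [protocol_table()] as `protocol.csv`.
#'
#' @param config a config list (see [read_run_config()]) or a YAML path.
#' @return invisibly, the protocol data.frame (output path in an
#'   attribute).
#' @export
run_protocol <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stack <- build_stack_from_config(config)
  p <- config$protocol %||% list()
  tab <- protocol_table(
    stack,
    sexes = config$scenario$sexes,
    ages = config$scenario$ages,
    A_ref = p$A_ref %||% 500, t_ref = p$t_ref %||% 4,
    window = unlist(p$window %||% c(3, 5)),
    target_scope = p$target_scope %||% "per_sex",
    kind = config$kind)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(config$output_dir, "protocol.csv")
  utils::write.csv(tab, csv_path, row.names = FALSE, quote = FALSE)
  attr(tab, "csv") <- csv_path
  invisible(tab)
}
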