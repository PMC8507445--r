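AGE_GROUPS <- c("1", "5", "10", "15", "adult")

#' Build a dose-coefficient table
#'
#' Organ absorbed dose per unit administered activity (mGy/MBq) tabulated
#' at the five reference phantom ages 1, 5, 10, 15 and adult. The adult
#' phantom represents a 20-year-old except for bone composition, so for
#' bone-seeking radiopharmaceuticals the age interpolation extends to 25
#' years; otherwise it stops at 20.
#'
#' @param df data.frame with columns `radiopharmaceutical`, `organ`,
#'   `age_group` (one of `"1"`, `"5"`, `"10"`, `"15"`, `"adult"`) and
#'   `mGy_per_MBq` (`> 0`).
#' @param bone_seeker logical; `TRUE` for bone-seeking agents such as
#'   99mTc-phosphonates.
#' @return an object of class `dose_coefficient_table`.
#' @export
dose_coefficient_table <- function(df, bone_seeker = TRUE) {
  need <- c("radiopharmaceutical", "organ", "age_group", "mGy_per_MBq")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop2("dose-coefficient table is missing column(s): ",
          paste(miss, collapse = ", "))
  df$age_group <- as.character(df$age_group)
  if (!all(df$age_group %in% AGE_GROUPS))
    stop2("`age_group` must be one of ", paste(AGE_GROUPS, collapse = ", "))
  if (any(df$mGy_per_MBq <= 0)) stop2("dose coefficients must be > 0")
  organs <- unique(df$organ)
  coef <- matrix(NA_real_, nrow = length(organs), ncol = length(AGE_GROUPS),
                 dimnames = list(organs, AGE_GROUPS))
  for (i in seq_len(nrow(df)))
    coef[df$organ[i], df$age_group[i]] <- df$mGy_per_MBq[i]
  if (anyNA(coef)) {
    bad <- which(is.na(coef), arr.ind = TRUE)
    stop2(sprintf("missing coefficient for organ '%s', age group '%s'",
                  organs[bad[1, 1]], AGE_GROUPS[bad[1, 2]]))
  }
  structure(list(radiopharmaceutical = unique(df$radiopharmaceutical)[1],
                 organs = organs, coefficients = coef,
                 bone_seeker = isTRUE(bone_seeker)),
            class = "dose_coefficient_table")
}

#' @export
print.dose_coefficient_table <- function(x, ...) {
  cat(sprintf("<dose_coefficient_table> %s, %d organs, bone_seeker=%s\n",
              x$radiopharmaceutical, length(x$organs), x$bone_seeker))
  invisible(x)
}

adult_anchor_age <- function(table) if (table$bone_seeker) 25 else 20

#' Dose coefficient at an arbitrary age
#'
#' Piecewise-linear interpolation between the anchor ages 1, 5, 10, 15 and
#' the adult anchor (25 years for bone seekers, 20 otherwise). Ages below 1
#' use the age-1 value; ages at or above the adult anchor use the adult
#' value.
#'
#' @param table a [dose_coefficient_table()].
#' @param organ organ label present in the table.
#' @param age age in years (`>= 0`); vectorized.
#' @return mGy/MBq.
#' @export
coefficient_at_age <- function(table, organ, age) {
  stopifnot(inherits(table, "dose_coefficient_table"))
  if (!organ %in% table$organs) stop2("unknown organ: ", organ)
  if (any(age < 0)) stop2("age must be >= 0")
  anchors <- c(1, 5, 10, 15, adult_anchor_age(table))
  stats::approx(anchors, table$coefficients[organ, ], xout = age,
                method = "linear", rule = 2)$y
}

#' Organ absorbed doses for an administration
#'
#' `dose(organ) = activity x coefficient_at_age(organ, age) x 1e-3`
#' (mGy to Gy). The organ absorbed dose is the dose quantity entering the
#' excess-rate models.
#'
#' @param table a [dose_coefficient_table()].
#' @param activity administered activity, MBq (`> 0`).
#' @param age patient age in years.
#' @return named numeric vector of absorbed doses in Gy, one per organ.
#' @export
#' @examples
#' tab <- dose_coefficient_table(data.frame(
#'   radiopharmaceutical = "99mTc-phosphonate", organ = "red_marrow",
#'   age_group = c("1", "5", "10", "15", "adult"),
#'   mGy_per_MBq = c(0.02, 0.012, 0.009, 0.0075, 0.0063)))
#' organ_doses(tab, 500, 40) # 0.0063 mGy/MBq -> 3.15e-3 Gy
organ_doses <- function(table, activity, age) {
  stopifnot(inherits(table, "dose_coefficient_table"))
  if (activity <= 0) stop2("`activity` must be > 0 MBq")
  doses <- vapply(table$organs,
                  function(o) activity * coefficient_at_age(table, o, age) * 1e-3,
                  numeric(1))
  names(doses) <- table$organs
  doses
}
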