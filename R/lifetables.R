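#' Build a life table from survivorship or counts
#'
#' A life table holds the survivorship function `l(a)`: the probability of
#' being alive at integer age `a`, i.e. the number alive at age `a` divided
#' by the number alive at age 0. Inputs given as raw counts `N(a)` are
#' normalized by `N(0)` so that `l(0) = 1`.
#'
#' @param sex `"male"` or `"female"`.
#' @param ages contiguous integer ages starting at 0 (the grid should reach
#'   at least 110 for LAR work, but any contiguous grid is accepted).
#' @param survivorship survivorship probabilities in `[0, 1]` (or raw counts,
#'   auto-normalized), non-increasing in age, same length as `ages`.
#' @return an object of class `life_table` with elements `sex`, `ages`, `lx`.
#' @export
#' @examples
#' lt <- life_table("male", 0:2, c(1000, 990, 970))
#' lt$lx # 1.00 0.99 0.97
life_table <- function(sex, ages, survivorship) {
  sex <- check_sex(sex)
  ages <- as.integer(ages)
  if (length(ages) != length(survivorship))
    stop2("`ages` and `survivorship` must have the same length")
  if (length(ages) < 2L)
    stop2("a life table needs at least two ages")
  if (ages[1] != 0L || any(diff(ages) != 1L))
    stop2("`ages` must be contiguous integers starting at 0; missing ages detected")
  lx <- as.numeric(survivorship)
  if (anyNA(lx)) stop2("survivorship contains missing values")
  if (lx[1] <= 0) stop2("survivorship (or count) at age 0 must be positive")
  if (lx[1] != 1) lx <- lx / lx[1] # counts: normalize by N(0)
  bad <- which(diff(lx) > 0)
  if (length(bad))
    stop2(sprintf("survivorship must be non-increasing; it increases at age %d",
                  ages[bad[1] + 1L]))
  if (any(lx < 0) || any(lx > 1))
    stop2("survivorship must lie in [0, 1] after normalization")
  structure(list(sex = sex, ages = ages, lx = lx), class = "life_table")
}

#' @export
print.life_table <- function(x, ...) {
  e0 <- life_expectancy(x)
  cat(sprintf("<life_table> sex=%s, ages 0-%d, l(%d)=%.4g, life expectancy %.1f y\n",
              x$sex, max(x$ages), max(x$ages), x$lx[length(x$lx)], e0))
  invisible(x)
}

max_age <- function(table) max(table$ages)

#' Life expectancy at birth implied by a life table
#'
#' Trapezoidal integral of the survivorship curve over the age grid.
#'
#' @param table a [life_table()].
#' @return years.
#' @export
life_expectancy <- function(table) {
  lx <- table$lx
  sum((lx[-1] + lx[-length(lx)]) / 2)
}

#' Survivorship at an age, interpolating fractional ages
#'
#' Returns `l(a)`; fractional ages are linearly interpolated between the
#' integer grid points of the annual life table.
#'
#' @param table a [life_table()].
#' @param a age in years, possibly fractional; vectorized.
#' @return survival probability (same length as `a`).
#' @export
survival_at <- function(table, a) {
  stopifnot(inherits(table, "life_table"))
  if (any(a < 0 | a > max_age(table)))
    stop2(sprintf("age outside the life-table grid [0, %d]", max_age(table)))
  stats::approx(table$ages, table$lx, xout = a, method = "linear")$y
}

#' Conditional survival from one age to a later age
#'
#' `S(a)/S(e0)`: the probability of being alive at age `a` given alive at
#' age `e0`.
#'
#' @param table a [life_table()].
#' @param a attained age, `a >= e0`; vectorized.
#' @param e0 conditioning age.
#' @return probability.
#' @export
conditional_survival <- function(table, a, e0) {
  if (any(a < e0)) stop2("`a` must be >= `e0`")
  s0 <- survival_at(table, e0)
  if (s0 <= 0) stop2(sprintf("cohort extinct at normalization age %s", format(e0)))
  survival_at(table, a) / s0
}

#' Define a patient cohort by its k-year survival
#'
#' Patient groups with reduced life expectancy (e.g. Paget's disease,
#' prostate cancer with bone metastases) are characterized by a published
#' k-year survival fraction. The implied constant annual survival
#' probability (ASP) is the k-th root of that fraction; it is applied to
#' the population life table over a modification window after exposure.
#'
#' @param name cohort label.
#' @param k_year_fraction k-year survival fraction in `(0, 1]`.
#' @param k horizon of the published fraction, integer years `>= 1`.
#' @param window years after exposure over which the ASP is applied;
#'   defaults to `max(k, 5)` so the modification reaches the start of the
#'   solid-cancer risk integration.
#' @return an object of class `cohort_spec`.
#' @export
#' @examples
#' cohort_spec("pagets", 0.93, 5)           # 5-year survival 93%
#' cohort_spec("one_lesion", 0.68, 2)       # 2-year survival 68%
#' cohort_spec("multiple_lesions", 0.22, 2) # 2-year survival 22%
cohort_spec <- function(name, k_year_fraction, k, window = max(k, 5L)) {
  stopifnot(is.character(name), length(name) == 1L)
  k <- as.integer(k)
  window <- as.integer(window)
  if (!(k >= 1L)) stop2("`k` must be an integer >= 1")
  if (!(window >= 1L)) stop2("`window` must be an integer >= 1")
  if (!(k_year_fraction > 0 && k_year_fraction <= 1))
    stop2("`k_year_fraction` must lie in (0, 1]")
  structure(list(name = name, k_year_fraction = k_year_fraction,
                 k = k, window = window),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %s: %g%% survival at %d y (ASP %.5f), window %d y\n",
              x$name, 100 * x$k_year_fraction, x$k,
              annual_survival_probability(x), x$window))
  invisible(x)
}

#' Annual survival probability of a cohort
#'
#' The constant annual survival probability that compounds to the cohort's
#' published k-year survival fraction: `ASP = fraction^(1/k)`.
#'
#' @param spec a [cohort_spec()].
#' @return probability in `(0, 1]`.
#' @export
#' @examples
#' annual_survival_probability(cohort_spec("pagets", 0.93, 5)) # 0.93^(1/5)
annual_survival_probability <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  spec$k_year_fraction^(1 / spec$k)
}

#' Apply a cohort's survival modification to a population life table
#'
#' For ages in `(e, e + window]` the cohort's conditional annual survival is
#' the minimum of the population's annual survival and the cohort ASP (the
#' cohort is never healthier than the general population); beyond the window
#' the cohort resumes the population's conditional survival:
#' \deqn{l^*(a) = l^*(a-1)\,\min\{l(a)/l(a-1),\ \mathrm{ASP}\}}
#' for `a` in the window, with `l^*(a) = l(a)` up to the exposure age and
#' `l^*(a) = l^*(e+w)\, l(a)/l(e+w)` afterwards.
#'
#' @param table a [life_table()].
#' @param spec a [cohort_spec()].
#' @param e age at exposure (integer year within the grid, `l(e) > 0`).
#' @return a new `life_table`, pointwise `<=` the input.
#' @export
apply_cohort_modification <- function(table, spec, e) {
  stopifnot(inherits(table, "life_table"), inherits(spec, "cohort_spec"))
  e <- as.integer(e)
  amax <- max_age(table)
  if (e < 0L || e > amax) stop2("exposure age outside the life-table grid")
  idx <- function(a) a + 1L # ages start at 0
  lx <- table$lx
  if (lx[idx(e)] <= 0) stop2(sprintf("population extinct at exposure age %d", e))
  asp <- annual_survival_probability(spec)
  end <- min(e + spec$window, amax)
  out <- lx
  if (end > e) {
    for (a in seq(e + 1L, end)) {
      r <- if (lx[idx(a - 1L)] > 0) lx[idx(a)] / lx[idx(a - 1L)] else 0
      out[idx(a)] <- out[idx(a - 1L)] * min(r, asp)
    }
    if (end < amax) {
      later <- seq(end + 1L, amax)
      out[idx(later)] <- if (lx[idx(end)] > 0)
        out[idx(end)] * lx[idx(later)] / lx[idx(end)] else 0
    }
  }
  res <- life_table(table$sex, table$ages, out)
  attr(res, "cohort") <- spec$name
  res
}
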