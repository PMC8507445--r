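#' Mean reference-administration risk over an age grid
#'
#' Evaluates LAR at the reference administered activity for every (sex,
#' age) on the grid and returns the unweighted arithmetic mean — the common
#' risk level the equal-risk protocol then targets.
#'
#' @param stack a [lar_stack()].
#' @param sexes character vector of sexes.
#' @param ages integer age grid (default 0:90).
#' @param A_ref reference administered activity, MBq (default 500).
#' @param kind rate series; defaults to the stack's.
#' @return probability (the target risk).
#' @export
target_risk <- function(stack, sexes, ages = 0:90, A_ref = 500,
                        kind = stack$kind) {
  if (!length(sexes) || !length(ages)) stop2("empty (sex, age) grid")
  vals <- unlist(lapply(sexes, function(sx)
    vapply(ages, function(a) stack_lar(stack, sx, a, A_ref, kind = kind),
           numeric(1))))
  mean(vals)
}

#' Administered activity achieving a target risk
#'
#' Since risk is proportional to administration for linear dose responses,
#' the equal-risk activity is `A_ref * target / LAR(A_ref)`; a secant
#' refinement then drives the achieved LAR to the target within 1e-9
#' relative, which also covers linear-quadratic (leukaemia) components
#' where strict proportionality does not hold.
#'
#' @param stack a [lar_stack()].
#' @param target target LAR (probability, `> 0`).
#' @param sex,age patient sex and age at exposure.
#' @param A_ref reference administered activity, MBq.
#' @param kind rate series; defaults to the stack's.
#' @param tol relative tolerance on the achieved LAR.
#' @return activity in MBq whose LAR equals `target`.
#' @export
equal_risk_activity <- function(stack, target, sex, age, A_ref = 500,
                                kind = stack$kind, tol = 1e-12) {
  stopifnot(target > 0)
  lar_ref <- stack_lar(stack, sex, age, A_ref, kind = kind)
  if (lar_ref <= 0)
    stop2("risk saturated at zero at this age; no finite equal-risk activity")
  A1 <- A_ref * target / lar_ref # exact for all-linear configurations
  f1 <- stack_lar(stack, sex, age, A1, kind = kind) - target
  A0 <- A_ref; f0 <- lar_ref - target
  for (i in seq_len(50)) {
    if (abs(f1) <= tol * target) break
    if (f1 == f0) break
    A2 <- A1 - f1 * (A1 - A0) / (f1 - f0)
    if (!is.finite(A2) || A2 <= 0) A2 <- A1 / 2
    A0 <- A1; f0 <- f1
    A1 <- A2; f1 <- stack_lar(stack, sex, age, A1, kind = kind) - target
  }
  A1
}

#' Acquisition time for an administered activity
#'
#' Counts (image quality) are held fixed at the reference pair, so the
#' acquisition time is inversely proportional to the administration:
#' `t = t_ref * A_ref / A`. Times outside the guideline window (default
#' 3-5 min) are clamped to the boundary and the activity is recomputed
#' from the clamped time to preserve the count budget.
#'
#' @param A administered activity, MBq (`> 0`).
#' @param A_ref,t_ref reference administration (500 MBq) and acquisition
#'   time (4 min).
#' @param window allowed acquisition-time range in minutes, `c(min, max)`.
#' @return a list with `time` (min, clamped into the window),
#'   `time_unclamped`, `activity` (MBq, recomputed when clamped) and
#'   `clamped` (logical).
#' @export
#' @examples
#' acquisition_time(500)  # 4 min, unclamped
#' acquisition_time(1000) # 2 min -> clamped to 3 min, activity 666.67 MBq
acquisition_time <- function(A, A_ref = 500, t_ref = 4, window = c(3, 5)) {
  if (A <= 0) stop2("`A` must be > 0 MBq")
  stopifnot(length(window) == 2L, window[1] > 0, window[1] <= window[2])
  t <- t_ref * A_ref / A
  clamped <- t < window[1] || t > window[2]
  t_cl <- min(max(t, window[1]), window[2])
  list(time = t_cl,
       time_unclamped = t,
       activity = if (clamped) t_ref * A_ref / t_cl else A,
       clamped = clamped)
}

#' Equal-risk protocol table
#'
#' For every (sex, age) on the grid: the administered activity whose LAR
#' equals the grid-mean reference risk, the matching acquisition time under
#' the fixed count budget `A x t = A_ref x t_ref`, and the achieved LAR.
#' Ages whose equal-risk time falls outside the guideline window are
#' clamped (flagged), with the activity recomputed from the clamped time.
#'
#' @param stack a [lar_stack()].
#' @param sexes sexes to tabulate.
#' @param ages integer age grid.
#' @param A_ref,t_ref reference administration (MBq) and acquisition time
#'   (min).
#' @param window acquisition-time window, minutes.
#' @param target_scope `"per_sex"` (each sex targets its own grid mean) or
#'   `"combined"` (one mean over both sexes).
#' @param kind rate series; defaults to the stack's.
#' @return data.frame with columns `sex`, `age`, `activity_MBq`,
#'   `acq_time_min`, `acq_time_unclamped_min`, `achieved_lar`, `clamped`.
#' @export
protocol_table <- function(stack, sexes = c("male", "female"), ages = 0:90,
                           A_ref = 500, t_ref = 4, window = c(3, 5),
                           target_scope = c("per_sex", "combined"),
                           kind = stack$kind) {
  target_scope <- match.arg(target_scope)
  combined_target <- if (target_scope == "combined")
    target_risk(stack, sexes, ages, A_ref, kind = kind)
  rows <- list()
  for (sx in sexes) {
    tgt <- combined_target %||% target_risk(stack, sx, ages, A_ref, kind = kind)
    for (a in ages) {
      A <- equal_risk_activity(stack, tgt, sx, a, A_ref, kind = kind)
      at <- acquisition_time(A, A_ref, t_ref, window)
      achieved <- stack_lar(stack, sx, a, at$activity, kind = kind)
      rows[[length(rows) + 1L]] <- data.frame(
        sex = sx, age = a, activity_MBq = at$activity,
        acq_time_min = at$time, acq_time_unclamped_min = at$time_unclamped,
        achieved_lar = achieved, clamped = at$clamped,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
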