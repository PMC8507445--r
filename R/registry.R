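#' Cancer-site registry
#'
#' The fixed registry of 15 cancer sites used throughout the package:
#' 14 specific sites plus the aggregate "residual" category for sites whose
#' radiogenic risk cannot be individually quantified from the epidemiology.
#' Each site carries its dosimetry target organ, the sexes it applies to,
#' the default latency (2 years for leukaemia, 5 for solid cancers) and the
#' default dose-response family (linear-quadratic for leukaemia, linear
#' with DDREF for solid sites).
#'
#' @return a data.frame with columns `site`, `target_organ`, `sex`
#'   (`"both"`, `"male"` or `"female"`), `latency` (years) and
#'   `dose_response`.
#' @export
#' @examples
#' site_registry()
site_registry <- function() {
  site <- c("stomach", "colon", "liver", "lung", "breast", "prostate",
            "uterus", "ovary", "bladder", "thyroid", "kidney", "bone",
            "skin", "leukaemia", "residual")
  data.frame(
    site = site,
    target_organ = c("stomach", "colon", "liver", "lungs", "breast",
                     "prostate", "uterus", "ovaries", "urinary_bladder",
                     "thyroid", "kidneys", "bone_surfaces", "skin",
                     "red_marrow", "remainder"),
    sex = c("both", "both", "both", "both", "female", "male", "female",
            "female", "both", "both", "both", "both", "both", "both",
            "both"),
    latency = ifelse(site == "leukaemia", 2L, 5L),
    dose_response = ifelse(site == "leukaemia", "linear_quadratic", "linear"),
    stringsAsFactors = FALSE
  )
}

#' Sites applicable to one sex
#'
#' @param sex `"male"` or `"female"`.
#' @return subset of [site_registry()].
#' @export
sites_for_sex <- function(sex) {
  sex <- match.arg(sex, c("male", "female"))
  reg <- site_registry()
  reg[reg$sex %in% c("both", sex), , drop = FALSE]
}

check_sex <- function(sex) match.arg(sex, c("male", "female"))
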