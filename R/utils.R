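#' @keywords internal
"_PACKAGE"

# null-default operator
`%||%` <- function(a, b) if (is.null(a)) b else a

# stable fingerprint of an R object for provenance reporting
fingerprint <- function(x) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Render a probability as a "1 in N" string
#'
#' N is `1/p` rounded to two significant figures, the convention used in
#' patient-facing risk communication ("1 in 3400").
#'
#' @param p probability (or vector of probabilities) in (0, 1].
#' @return character vector.
#' @export
#' @examples
#' format_one_in(3e-4)
format_one_in <- function(p) {
  stopifnot(is.numeric(p))
  out <- rep(NA_character_, length(p))
  ok <- is.finite(p) & p > 0
  n <- signif(1 / p[ok], 2)
  out[ok] <- paste("1 in", format(n, big.mark = " ", scientific = FALSE, trim = TRUE))
  out[is.finite(p) & p == 0] <- "no excess risk"
  out
}

stop2 <- function(...) stop(..., call. = FALSE)
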