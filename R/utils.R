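#' Round half away from zero
#'
#' Printed summary tables round percentages half-up (2.345 -> 2.35), unlike
#' [base::round()], which rounds half to even. A small epsilon guards against
#' binary-representation artefacts such as `3.155 * 100 == 315.49999...`.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percent of modified sites
#'
#' The percentage column of the region/context summary tables:
#' `100 * modified / analyzed`, rounded half-up to 2 decimals, with an `NA`
#' sentinel when nothing was analyzed.
#'
#' @param modified count of modified sites.
#' @param analyzed count of analyzed sites.
#' @param digits decimal places (default 2, the table convention).
#' @return numeric vector with `NA` where `analyzed == 0`.
#' @export
pct_modified <- function(modified, analyzed, digits = 2) {
  out <- rep(NA_real_, length(analyzed))
  ok <- analyzed > 0
  out[ok] <- round_half_up(100 * modified[ok] / analyzed[ok], digits)
  out
}

#' Reverse complement of a nucleotide string
#'
#' @param x character vector of A/C/G/T/N strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  out <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(x)))
  unname(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
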