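#' Round half away from zero
#'
#' Rounds to the printed precision the way performance tables are usually
#' rounded (0.5 always rounds up), unlike [base::round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.675), 0)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Shannon entropy (bits) of an empirical probability vector.
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

# Per-stage seed derivation: small fixed offsets from a master seed keep every
# stage independently reproducible while staying well inside 32-bit range.
stage_seed <- function(seed, stage) {
  offsets <- c(cohort = 0L, split = 1L, cv = 2L, permute = 3L, stream = 4L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage, call. = FALSE)
  as.integer(seed %% 2e9) + offsets[[stage]]
}
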