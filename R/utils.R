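# Shared helpers.

#' @useDynLib usdenoise, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd pt coef predict
#' @importFrom utils modifyList write.csv read.csv
NULL

# Clamp to the valid intensity range and round to integer levels.
quantize <- function(x, bit_depth = 8L) {
  L <- 2^bit_depth - 1
  pmin(pmax(round(x), 0), L)
}

# Deterministic child seeds (kept below 2^31) derived from a master seed.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min)
    stop(sprintf("'%s' must be a finite number >= %s", name, min), call. = FALSE)
  invisible(x)
}

check_same_shape <- function(x, y) {
  if (!identical(dim(x), dim(y)))
    stop("images must have identical dimensions", call. = FALSE)
  invisible(TRUE)
}
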