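# Non-local means comparator. Each output pixel is the patch-similarity
# weighted average of the pixels in its search window: weights
# exp(-||patch_i - patch_j||^2 / h^2) (summed squared difference over the
# patch), normalized to sum to 1. Patches near the border read from a
# mirror-padded image; search windows are clipped at the border.

#' Non-local means parameters
#'
#' @param patch_size odd patch side >= 3.
#' @param search_window odd search-window side >= `patch_size`.
#' @param h filtering strength (> 0), on the scale of the summed squared
#'   patch difference; larger h averages more aggressively. A practical
#'   choice for noise of pixel-unit standard deviation `s` is
#'   `h = sqrt(2) * patch_size * s`.
#' @return object of class `nlmeans_params`.
#' @export
nlmeans_params <- function(patch_size = 5L, search_window = 11L, h = 180) {
  patch_size <- as.integer(patch_size)
  search_window <- as.integer(search_window)
  if (patch_size < 3L || patch_size %% 2L == 0L)
    stop("patch_size must be an odd integer >= 3", call. = FALSE)
  if (search_window %% 2L == 0L || search_window < patch_size)
    stop("search_window must be odd and >= patch_size", call. = FALSE)
  stopifnot_scalar_number(h, "h", min = .Machine$double.eps)
  structure(list(patch_size = patch_size, search_window = search_window, h = h),
            class = "nlmeans_params")
}

#' Denoise with non-local means
#'
#' Deterministic, shape-preserving, range-valid. If the image is smaller than
#' the search window the window is clipped to the whole image, with a
#' warning.
#'
#' @param a noisy image (numeric matrix).
#' @param params an [nlmeans_params()].
#' @param bit_depth bits per pixel (for the output clamp).
#' @param quantize round the result to integer levels (default TRUE); set
#'   FALSE to obtain the raw weighted averages.
#' @return denoised image of the same shape.
#' @export
nl_means <- function(a, params = nlmeans_params(), bit_depth = 8L,
                     quantize = TRUE) {
  if (!is.matrix(a)) stop("'a' must be a numeric matrix", call. = FALSE)
  sw <- params$search_window
  if (nrow(a) < sw || ncol(a) < sw) {
    warning("image smaller than the search window; using the whole image",
            call. = FALSE)
    sw <- 2L * max(nrow(a), ncol(a)) + 1L
  }
  out <- nlm_filter(a, params$patch_size, sw, params$h)
  if (quantize) out <- pmin(pmax(round(out), 0), 2^bit_depth - 1)
  out
}
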