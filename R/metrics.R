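# Image quality metrics: MSE, PSNR (dB) and SSIM. Statistics use the
# population convention (divide by N) throughout; SSIM offers a global
# whole-image mode (the default) and an 8x8 non-overlapping windowed mode.

#' Mean squared error between two images
#'
#' @param x,y numeric matrices of identical shape.
#' @return non-negative scalar, symmetric in its arguments.
#' @export
img_mse <- function(x, y) {
  check_same_shape(x, y)
  mean((x - y)^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 * log10((2^n - 1)^2 / MSE)`; identical images (MSE = 0) return `Inf`.
#' Strictly decreasing in MSE for fixed bit depth.
#'
#' @param x,y numeric matrices of identical shape.
#' @param bit_depth bits per pixel n; the peak intensity is `2^n - 1`.
#' @return PSNR in dB, or `Inf` when the images are identical.
#' @export
img_psnr <- function(x, y, bit_depth = 8L) {
  m <- img_mse(x, y)
  if (m == 0) return(Inf)
  L <- 2^bit_depth - 1
  10 * log10(L^2 / m)
}

#' Structural similarity index
#'
#' `SSIM = (2 u_x u_y + C1)(2 s_xy + C2) / ((u_x^2 + u_y^2 + C1)(s_x^2 + s_y^2 + C2))`
#' with means u, population variances s^2 and covariance s_xy. The stabilising
#' constants default to the field-standard `C1 = (0.01 L)^2`,
#' `C2 = (0.03 L)^2` with `L = 2^n - 1`. Global mode evaluates the statistic
#' once over the whole image; windowed mode averages it over 8x8
#' non-overlapping windows (falling back to global when the image is smaller
#' than one window). Values lie in [-1, 1], with 1 iff the images are equal.
#'
#' @param x,y numeric matrices of identical shape.
#' @param C1,C2 positive stabilising constants.
#' @param bit_depth bits per pixel (sets the default constants).
#' @param mode `"global"` or `"windowed"`.
#' @param window window side for windowed mode.
#' @return SSIM in [-1, 1].
#' @export
img_ssim <- function(x, y, C1 = NULL, C2 = NULL, bit_depth = 8L,
                     mode = c("global", "windowed"), window = 8L) {
  check_same_shape(x, y)
  mode <- match.arg(mode)
  L <- 2^bit_depth - 1
  if (is.null(C1)) C1 <- (0.01 * L)^2
  if (is.null(C2)) C2 <- (0.03 * L)^2
  if (C1 <= 0 || C2 <= 0)
    stop("SSIM constants C1 and C2 must be positive", call. = FALSE)
  if (mode == "global" || nrow(x) < window || ncol(x) < window)
    return(ssim_stat(x, y, C1, C2))
  nr <- nrow(x) %/% window
  nc <- ncol(x) %/% window
  vals <- numeric(nr * nc)
  k <- 1L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      ri <- (i - 1L) * window + seq_len(window)
      ci <- (j - 1L) * window + seq_len(window)
      vals[k] <- ssim_stat(x[ri, ci], y[ri, ci], C1, C2)
      k <- k + 1L
    }
  }
  mean(vals)
}

ssim_stat <- function(x, y, C1, C2) {
  ux <- mean(x)
  uy <- mean(y)
  vx <- mean(x^2) - ux^2
  vy <- mean(y^2) - uy^2
  cxy <- mean(x * y) - ux * uy
  ((2 * ux * uy + C1) * (2 * cxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
}

#' Full quality report for an image pair
#'
#' @param x,y numeric matrices of identical shape (test and reference).
#' @param bit_depth bits per pixel.
#' @param ... passed to [img_ssim()].
#' @return object of class `metric_report`: list with `mse`, `psnr_db`,
#'   `ssim`, and `bit_depth`.
#' @export
metric_report <- function(x, y, bit_depth = 8L, ...) {
  structure(list(mse = img_mse(x, y),
                 psnr_db = img_psnr(x, y, bit_depth),
                 ssim = img_ssim(x, y, bit_depth = bit_depth, ...),
                 bit_depth = bit_depth),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("MSE %.4f | PSNR %s dB | SSIM %.4f (%d-bit)\n",
              x$mse, ifelse(is.infinite(x$psnr_db), "inf",
                            sprintf("%.4f", x$psnr_db)),
              x$ssim, x$bit_depth))
  invisible(x)
}
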