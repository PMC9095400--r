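# Synthetic ultrasound-like phantoms: a hypoechoic (dark) elliptical cyst with
# a few bright floaters, embedded in brighter tissue-echo texture modelled as
# smoothed white noise. Phantoms provide known-clean references so the
# denoisers and metrics can be exercised without any external data.

#' Describe a synthetic ultrasound phantom
#'
#' A phantom is a quantized 8-bit grayscale image of an elliptical fluid-filled
#' (hypoechoic) cyst over brighter surrounding tissue. The background carries
#' tissue-echo texture (Gaussian-smoothed white noise of a given correlation
#' length) and the cyst may contain small bright floating spots.
#'
#' @param size integer c(height, width), both > 0.
#' @param cyst list with `center` c(row, col), `semi_axes` c(a, b) in pixels,
#'   and `mean` intensity (must be darker than the background mean).
#' @param background list with `mean` intensity, texture standard deviation
#'   `sd`, and texture correlation length `corr_length` (pixels, the sd of the
#'   Gaussian smoothing kernel).
#' @param spots list with `count`, `intensity`, and blob `radius` (pixels) of
#'   the bright floaters placed inside the cyst.
#' @param bit_depth bits per pixel; intensities live in [0, 2^bit_depth - 1].
#' @param seed integer seed making the phantom fully reproducible.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(64L, 64L),
                         cyst = list(center = NULL, semi_axes = NULL, mean = 40),
                         background = list(mean = 160, sd = 12, corr_length = 2),
                         spots = list(count = 3L, intensity = 230, radius = 1.2),
                         bit_depth = 8L,
                         seed = 1L) {
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 1L))
    stop("'size' must be two positive integers", call. = FALSE)
  if (is.null(cyst$center)) cyst$center <- (size + 1) / 2
  if (is.null(cyst$semi_axes)) cyst$semi_axes <- size / 4
  if (cyst$mean >= background$mean)
    stop("cyst mean intensity must be below the background mean (hypoechoic)",
         call. = FALSE)
  lo <- cyst$center - cyst$semi_axes
  hi <- cyst$center + cyst$semi_axes
  if (any(lo < 1) || any(hi > size))
    stop("cyst ellipse must lie fully inside the image", call. = FALSE)
  structure(list(size = size, cyst = cyst, background = background,
                 spots = spots, bit_depth = as.integer(bit_depth),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Boolean mask of the cyst ellipse.
ellipse_mask <- function(spec) {
  h <- spec$size[1]; w <- spec$size[2]
  r <- matrix(seq_len(h), h, w)
  c <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((r - spec$cyst$center[1]) / spec$cyst$semi_axes[1])^2 +
    ((c - spec$cyst$center[2]) / spec$cyst$semi_axes[2])^2 <= 1
}

# Separable Gaussian blur with zero padding; used only to correlate texture
# noise, so edge attenuation is irrelevant (the noise is zero mean).
gauss_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  km <- matrix(outer(k, k), ncol = 1)
  w <- matrix(km, nrow = length(k)^2, ncol = 1)
  xa <- array(x, dim = c(dim(x), 1L))
  out <- conv2d_fw(xa, w, 0, length(k), length(k), 1L, r)
  matrix(out, nrow(x), ncol(x))
}

#' Generate a synthetic phantom image
#'
#' Deterministic for a fixed spec (the spec carries its own seed). The
#' generated image is quantized to the spec's bit depth, and the mean
#' intensity inside the cyst ellipse is below the mean outside it.
#'
#' @param spec a [phantom_spec()].
#' @return numeric matrix (height x width) of quantized intensities.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  h <- spec$size[1]; w <- spec$size[2]
  withr::with_seed(spec$seed, {
    mask <- ellipse_mask(spec)
    base <- matrix(spec$background$mean, h, w)
    base[mask] <- spec$cyst$mean
    tex <- matrix(rnorm(h * w), h, w)
    tex <- gauss_blur(tex, spec$background$corr_length)
    s <- sd(as.numeric(tex))
    if (s > 0) tex <- tex / s * spec$background$sd
    img <- base + tex
    n_spots <- as.integer(spec$spots$count)
    if (n_spots > 0) {
      inside <- which(mask, arr.ind = TRUE)
      pick <- inside[sample.int(nrow(inside), n_spots, replace = TRUE), ,
                     drop = FALSE]
      rr <- matrix(seq_len(h), h, w)
      cc <- matrix(seq_len(w), h, w, byrow = TRUE)
      for (k in seq_len(n_spots)) {
        d2 <- (rr - pick[k, 1])^2 + (cc - pick[k, 2])^2
        blob <- exp(-d2 / (2 * spec$spots$radius^2))
        img <- img + (spec$spots$intensity - spec$cyst$mean) * blob * mask
      }
    }
    quantize(img, spec$bit_depth)
  })
}

#' Random phantom family
#'
#' Returns a sampler `function(seed)` producing [phantom_spec()]s whose cyst
#' position, size, intensities and spot count are jittered within the given
#' ranges. Used by [make_dataset()] to emit a varied corpus.
#'
#' @param size image size, c(height, width).
#' @param cyst_mean,background_mean ranges c(lo, hi) for the two mean
#'   intensities (cyst darker than background by construction).
#' @param spot_count range of bright-floater counts (inclusive).
#' @return function mapping an integer seed to a `phantom_spec`.
#' @export
phantom_sampler <- function(size = c(64L, 64L),
                            cyst_mean = c(30, 55),
                            background_mean = c(140, 180),
                            spot_count = c(0L, 4L)) {
  force(size)
  function(seed) {
    withr::with_seed(as.integer(seed), {
      ax <- runif(2, 0.15, 0.3) * size
      ctr <- c(runif(1, 1 + ax[1], size[1] - ax[1]),
               runif(1, 1 + ax[2], size[2] - ax[2]))
      phantom_spec(
        size = size,
        cyst = list(center = ctr, semi_axes = ax,
                    mean = runif(1, cyst_mean[1], cyst_mean[2])),
        background = list(mean = runif(1, background_mean[1], background_mean[2]),
                          sd = runif(1, 8, 16),
                          corr_length = runif(1, 1.2, 2.5)),
        spots = list(count = sample(spot_count[1]:spot_count[2], 1),
                     intensity = runif(1, 200, 245),
                     radius = runif(1, 0.8, 1.6)),
        seed = sample.int(.Machine$integer.max, 1)
      )
    })
  }
}
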