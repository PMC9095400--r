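# Noise decomposition. The package follows the convention
#   a + e = b,
# where a is the stored noisy image, b the clean reference, and e the
# correction that restores the clean image. Noise is drawn, the noisy image is
# clipped/quantized to the valid range, and e is then *recomputed* as b - a so
# the identity holds exactly no matter what clipping did.

# Dimensionless benchmark noise level -> pixel units for 8-bit additive noise.
SIGMA_PIXEL_SCALE <- 25.5

#' Describe a noise model
#'
#' @param model `"multiplicative_speckle"` (default; granular interference
#'   noise proportional to local intensity, `a = b + b*eta`,
#'   `eta ~ N(0, sigma^2)`) or `"additive_gaussian"`
#'   (`a = b - e0`, `e0 ~ N(0, sigma_px^2)` with
#'   `sigma_px = sigma * sigma_scale`).
#' @param sigma dimensionless noise level >= 0 (the benchmark axis; 0 means no
#'   noise).
#' @param sigma_scale pixels per unit sigma for the additive model on 8-bit
#'   images.
#' @param seed integer seed.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(model = c("multiplicative_speckle", "additive_gaussian"),
                       sigma = 1.0, sigma_scale = SIGMA_PIXEL_SCALE,
                       seed = 1L) {
  model <- match.arg(model)
  stopifnot_scalar_number(sigma, "sigma", min = 0)
  structure(list(model = model, sigma = sigma, sigma_scale = sigma_scale,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Corrupt a clean image with speckle or Gaussian noise
#'
#' Returns the (noisy, clean, noise) triple satisfying `a + e = b` exactly:
#' the noisy image is clipped to the valid intensity range (it keeps
#' fractional values so the noise distribution is not discretized), after
#' which `e` is recomputed as `b - a` so the decomposition survives
#' clipping.
#'
#' @param b clean quantized image (numeric matrix).
#' @param noise a [noise_spec()].
#' @param bit_depth bits per pixel of `b`.
#' @return object of class `noisy_sample`: list with elements `a` (noisy),
#'   `b` (clean), `e` (noise, `b - a`), and `noise_spec`.
#' @export
add_noise <- function(b, noise = noise_spec(), bit_depth = 8L) {
  if (!is.matrix(b)) stop("'b' must be a numeric matrix", call. = FALSE)
  if (!inherits(noise, "noise_spec")) stop("'noise' must be a noise_spec",
                                           call. = FALSE)
  a <- withr::with_seed(noise$seed, {
    if (noise$sigma == 0) {
      b
    } else if (noise$model == "additive_gaussian") {
      sigma_px <- noise$sigma * noise$sigma_scale
      b - matrix(rnorm(length(b), 0, sigma_px), nrow(b))
    } else {
      eta <- matrix(rnorm(length(b), 0, noise$sigma), nrow(b))
      b + b * eta
    }
  })
  a <- pmin(pmax(a, 0), 2^bit_depth - 1)
  structure(list(a = a, b = b, e = b - a, noise_spec = noise),
            class = "noisy_sample")
}

#' Simulate a corpus of noisy/clean phantom pairs
#'
#' Per-sample phantom and noise seeds are derived deterministically from the
#' master seed, and a disjoint train/validation split is emitted alongside.
#'
#' @param n_images number of samples (>= 1).
#' @param sampler phantom family from [phantom_sampler()] (a function mapping
#'   a seed to a [phantom_spec()]).
#' @param noise a [noise_spec()]; its seed field is ignored in favour of
#'   per-sample derived seeds.
#' @param seed master seed.
#' @param train_frac fraction of samples assigned to the training split.
#' @return object of class `denoise_dataset`: list with `samples` (list of
#'   [add_noise()] triples), `train_idx`, `val_idx`, `seed`.
#' @export
make_dataset <- function(n_images, sampler = phantom_sampler(),
                         noise = noise_spec(), seed = 1L, train_frac = 0.8) {
  n_images <- as.integer(n_images)
  if (is.na(n_images) || n_images < 1L)
    stop("'n_images' must be a positive integer", call. = FALSE)
  seeds <- derive_seeds(seed, 2L * n_images)
  samples <- lapply(seq_len(n_images), function(i) {
    spec <- sampler(seeds[2L * i - 1L])
    b <- generate_phantom(spec)
    ns <- noise
    ns$seed <- seeds[2L * i]
    add_noise(b, ns)
  })
  n_train <- floor(train_frac * n_images)
  perm <- withr::with_seed(as.integer(seed), sample.int(n_images))
  structure(list(samples = samples,
                 train_idx = sort(perm[seq_len(n_train)]),
                 val_idx = sort(perm[setdiff(seq_len(n_images),
                                             seq_len(n_train))]),
                 seed = as.integer(seed)),
            class = "denoise_dataset")
}

#' @export
print.denoise_dataset <- function(x, ...) {
  d <- dim(x$samples[[1]]$b)
  cat(sprintf(
    "denoise_dataset: %d samples (%dx%d), %d train / %d validation\n",
    length(x$samples), d[1], d[2], length(x$train_idx), length(x$val_idx)))
  ns <- x$samples[[1]]$noise_spec
  cat(sprintf("noise: %s, sigma = %g\n", ns$model, ns$sigma))
  invisible(x)
}
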