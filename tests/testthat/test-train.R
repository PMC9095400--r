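small_ds <- function(n = 8, sigma = 1, seed = 50, size = 32L) {
  make_dataset(n, sampler = phantom_sampler(size = c(size, size)),
               noise = noise_spec(sigma = sigma), seed = seed)
}

test_that("loss history has one finite entry per epoch", {
  ds <- small_ds()
  fit <- suppressWarnings(
    train_denoiser(plain_cnn(depth = 3, channels = 4, init_seed = 1), ds,
                   train_config(epochs = 3, seed = 2, patch_size = 32L)))
  expect_length(fit$loss_history, 3)
  expect_true(all(is.finite(fit$loss_history)))
  expect_length(fit$val_psnr_history, 3)
  expect_true(fit$model$trained)
})

test_that("zero learning rate leaves every parameter bitwise unchanged", {
  ds <- small_ds()
  m <- improved_unet(depth = 1, base_channels = 4, init_seed = 7)
  fit <- suppressWarnings(
    train_denoiser(m, ds, train_config(epochs = 2, learning_rate = 0,
                                       seed = 3, patch_size = 32L)))
  expect_identical(fit$model$params, m$params)
})

test_that("identical config and seed reproduce the identical loss history", {
  ds <- small_ds()
  run <- function() suppressWarnings(
    train_denoiser(improved_unet(depth = 1, base_channels = 4, init_seed = 5),
                   ds, train_config(epochs = 3, seed = 11, patch_size = 32L)))
  f1 <- run()
  f2 <- run()
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("training overfits a single repeated batch monotonically", {
  ds <- small_ds(n = 3, seed = 51)
  ds$train_idx <- c(1L, 2L)
  ds$val_idx <- 3L
  fit <- suppressWarnings(
    train_denoiser(improved_unet(depth = 1, base_channels = 4, init_seed = 2),
                   ds, train_config(epochs = 15, batch_size = 2, seed = 4,
                                    patch_size = 32L)))
  tail_losses <- fit$loss_history[5:15]
  expect_true(all(diff(tail_losses) <= 1e-6))
  expect_lt(fit$loss_history[15], fit$loss_history[1])
})

test_that("a constant-residual model recovers a known constant noise offset", {
  # corpus whose residual e is a constant shift of -20 intensity levels
  b <- generate_phantom(phantom_spec(size = c(16L, 16L), seed = 6))
  mk <- function(b) {
    a <- pmin(pmax(b + 20, 0), 255)
    structure(list(a = a, b = b, e = b - a, noise_spec = noise_spec(sigma = 0)),
              class = "noisy_sample")
  }
  ds <- structure(list(samples = list(mk(b), mk(b + 1), mk(b + 2)),
                       train_idx = 1:2, val_idx = 3L, seed = 1L),
                  class = "denoise_dataset")
  fit <- suppressWarnings(
    train_denoiser(constant_residual_model(), ds,
                   train_config(epochs = 300, learning_rate = 0.01, seed = 1,
                                patch_size = 16L)))
  expect_lt(abs(fit$model$params$c - (-20 / 255)), 0.005)
})

test_that("loss kind must match the model's learning mode", {
  ds <- small_ds()
  expect_error(train_denoiser(improved_unet(), ds,
                              train_config(loss = "mse_on_image")),
               "incompatible")
  expect_error(train_denoiser(plain_cnn(), ds,
                              train_config(loss = "mse_on_residual")),
               "incompatible")
  expect_error(train_denoiser(improved_unet(), list()), "denoise_dataset")
})
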