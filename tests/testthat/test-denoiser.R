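test_that("PReLU follows its two branches and degenerates to ReLU at slope 0", {
  expect_equal(prelu(2.0, 0.25), 2.0)
  expect_equal(prelu(-2.0, 0.25), -0.5)
  expect_equal(prelu(-3.0, 0), 0)
  x <- array(c(-1, 1), dim = c(1, 2, 2))
  expect_equal(prelu(x, c(0.1, 0.5)),
               array(c(-0.1, 1, -0.5, 1), dim = c(1, 2, 2)))
})

test_that("residual block is the identity under zero weights and counts its parameters", {
  C <- 4L
  zeros <- list(conv1 = list(W = matrix(0, 9 * C, C), b = numeric(C)),
                conv2 = list(W = matrix(0, 9 * C, C), b = numeric(C)),
                slope = rep(0.25, C))
  x <- array(rnorm(5 * 7 * C), dim = c(5, 7, C))
  expect_identical(residual_block(x, zeros), x)

  # two 3x3 conv layers + biases + per-channel PReLU slopes
  n_par <- 2 * (3 * 3 * C * C + C) + C
  expect_equal(length(zeros$conv1$W) + length(zeros$conv1$b) +
                 length(zeros$conv2$W) + length(zeros$conv2$b) +
                 length(zeros$slope), n_par)
  expect_error(residual_block(array(0, c(5, 5, 2)), zeros), "channel")
})

test_that("each downsampling level halves the spatial size and doubles channels", {
  m <- improved_unet(depth = 2, base_channels = 8)
  sh <- model_shapes(m, c(64, 64))
  expect_equal(sh$encoder, list(c(64L, 64L, 8L), c(32L, 32L, 16L),
                                c(16L, 16L, 32L)))
  expect_equal(sh$downsample, rep("stride_conv", 2))

  p <- plain_unet(depth = 2, base_channels = 8)
  shp <- model_shapes(p, c(64, 64))
  expect_equal(shp$encoder, list(c(64L, 64L, 8L), c(32L, 32L, 16L),
                                 c(16L, 16L, 32L)))
  expect_equal(shp$downsample, rep("max_pool", 2))
})

test_that("the plain-UNet preset is the classic codec, the improved preset is not", {
  p <- plain_unet()
  expect_equal(p$arch$downsample, "max_pool")
  expect_false(p$arch$use_residual_blocks || p$arch$use_rdub ||
                 p$arch$use_recon || p$arch$residual)
  expect_false(any(grepl("rdub|recon", names(p$params))))

  m <- improved_unet()
  expect_equal(m$arch$downsample, "stride_conv")
  expect_true(m$arch$use_residual_blocks && m$arch$use_rdub &&
                m$arch$use_recon && m$arch$residual)
  expect_true(any(grepl("rdub", names(m$params))))
  expect_true(any(grepl("recon", names(m$params))))
  expect_false(n_parameters(m) == n_parameters(p))
})

test_that("forward pass preserves the input shape, padding odd sizes", {
  s <- tiny_sample(sigma = 1, size = 64L)
  for (m in list(improved_unet(), plain_unet(), plain_cnn())) {
    out <- predict(m, s$a)
    expect_equal(dim(out), dim(s$a))
    expect_true(all(out >= 0 & out <= 255))
  }
  odd <- s$a[1:50, 1:45]
  out <- predict(improved_unet(), odd)
  expect_equal(dim(out), c(50L, 45L))
})

test_that("a zeroed Recon head makes the improved UNet an exact identity", {
  m <- improved_unet()
  m$params[["recon.conv2.W"]][] <- 0
  m$params[["recon.conv2.b"]][] <- 0
  s <- tiny_sample(sigma = 1, size = 64L)
  out <- predict(m, s$a, quantize = FALSE)
  expect_equal(out, s$a, tolerance = 1e-12)
})

test_that("a zeroed final layer makes the plain CNN output zero (no skip)", {
  m <- plain_cnn()
  m$params[["layer5.W"]][] <- 0
  m$params[["layer5.b"]][] <- 0
  s <- tiny_sample(sigma = 1, size = 32L)
  expect_true(all(predict(m, s$a) == 0))
})

test_that("parameter initialization is a pure function of the seed", {
  expect_identical(improved_unet(init_seed = 33)$params,
                   improved_unet(init_seed = 33)$params)
  expect_false(identical(improved_unet(init_seed = 33)$params,
                         improved_unet(init_seed = 34)$params))
})

test_that("autodiff gradients match central differences on all architectures", {
  expect_lt(max_grad_error(improved_unet(depth = 1, base_channels = 2,
                                         init_seed = 9),
                           "mse_on_residual", seed = 1), 1e-5)
  expect_lt(max_grad_error(plain_unet(depth = 1, base_channels = 2,
                                      init_seed = 9),
                           "mse_on_image", seed = 2), 1e-5)
  expect_lt(max_grad_error(plain_cnn(depth = 3, channels = 3, init_seed = 9),
                           "mse_on_image", seed = 3), 1e-5)
})

test_that("checkpoints round-trip through JSON", {
  m <- improved_unet(depth = 1, base_channels = 4, init_seed = 12)
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_equal(m2$params, m$params)
  expect_equal(m2$arch$kind, "improved_unet")
  s <- tiny_sample(sigma = 1, size = 32L)
  expect_identical(predict(m, s$a), predict(m2, s$a))
})
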