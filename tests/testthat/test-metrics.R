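test_that("MSE matches hand evaluation and is symmetric", {
  x <- matrix(c(0, 4, 2, 6), 2, 2)  # rows (0,2),(4,6)
  y <- matrix(1, 2, 2)
  expect_equal(img_mse(x, y), 9)
  expect_equal(img_mse(y, x), 9)
  expect_equal(img_mse(x, x), 0)
  expect_equal(img_mse(matrix(0, 3, 3), matrix(1, 3, 3)), 1)
  expect_error(img_mse(matrix(0, 2, 2), matrix(0, 3, 3)), "dimensions")
})

test_that("PSNR follows its definition, with an infinity sentinel at MSE 0", {
  x <- matrix(0, 4, 4)
  expect_equal(img_psnr(x, x + 255), 0)              # MSE = 255^2
  expect_identical(img_psnr(x, x), Inf)
  expect_equal(img_psnr(x, x + 1), 48.1308, tolerance = 1e-3 / 48)
})

test_that("PSNR decreases strictly as MSE grows", {
  withr::with_seed(8, {
    x <- matrix(runif(64, 0, 255), 8, 8)
    mses <- psnrs <- numeric(20)
    for (i in seq_len(20)) {
      y <- x + rnorm(64, sd = i)
      mses[i] <- img_mse(x, y)
      psnrs[i] <- img_psnr(x, y)
    }
    o <- order(mses)
    expect_true(all(diff(psnrs[o]) < 0))
  })
})

test_that("SSIM matches a brute-force evaluation of its definition", {
  x <- matrix(c(0, 0, 255, 255), 2, 2)
  y <- matrix(c(255, 255, 0, 0), 2, 2)
  expect_equal(img_ssim(x, y, C1 = 6.5025, C2 = 58.5225),
               ssim_oracle(x, y, 6.5025, 58.5225), tolerance = 1e-9)
  withr::with_seed(21, {
    for (i in 1:20) {
      a <- matrix(runif(9, 0, 255), 3, 3)
      b <- matrix(runif(9, 0, 255), 3, 3)
      expect_equal(img_ssim(a, b), ssim_oracle(a, b, 6.5025, 58.5225),
                   tolerance = 1e-9)
    }
  })
})

test_that("SSIM identity, symmetry and range hold over random pairs", {
  withr::with_seed(31, {
    for (i in 1:25) {
      a <- matrix(runif(64, 0, 255), 8, 8)
      b <- matrix(runif(64, 0, 255), 8, 8)
      s <- img_ssim(a, b)
      expect_gte(s, -1)
      expect_lte(s, 1)
      expect_equal(s, img_ssim(b, a))
    }
    a <- matrix(runif(64, 0, 255), 8, 8)
    expect_equal(img_ssim(a, a), 1)
    expect_lt(img_ssim(a, 255 - a), 1)
  })
})

test_that("windowed SSIM degenerates to global on a single window", {
  withr::with_seed(41, {
    a <- matrix(runif(64, 0, 255), 8, 8)
    b <- matrix(runif(64, 0, 255), 8, 8)
    expect_equal(img_ssim(a, b, mode = "windowed", window = 8L),
                 img_ssim(a, b, mode = "global"))
  })
})

test_that("SSIM rejects non-positive constants and shape mismatches", {
  a <- matrix(0, 4, 4)
  expect_error(img_ssim(a, a, C1 = 0, C2 = 1), "positive")
  expect_error(img_ssim(a, matrix(0, 5, 5)), "dimensions")
})

test_that("metric_report collects the three measures coherently", {
  s <- tiny_sample(sigma = 0.5)
  r <- metric_report(s$a, s$b)
  expect_equal(r$mse, img_mse(s$a, s$b))
  expect_equal(r$psnr_db, img_psnr(s$a, s$b))
  expect_equal(r$ssim, img_ssim(s$a, s$b))
  r0 <- metric_report(s$b, s$b)
  expect_identical(r0$psnr_db, Inf)
  expect_equal(r0$ssim, 1)
})
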