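test_that("the benchmark grid is complete and cached consistently", {
  bench <- run_benchmark(
    methods = list(identity = "identity",
                   blur = function(a) nl_means(a, nlmeans_params(h = 1000))),
    sigmas = c(0.5, 1.5), n_images = 4,
    sampler = phantom_sampler(size = c(32L, 32L)), seed = 9)
  expect_equal(dim(bench$psnr$table), c(2L, 2L))
  expect_equal(dim(bench$ssim$table), c(2L, 2L))
  expect_false(anyNA(bench$psnr$table))
  expect_false(anyNA(bench$ssim$table))
  expect_true(all(bench$ssim$table >= -1 & bench$ssim$table <= 1))
  # grid means equal the mean of the per-image dump (same cached outputs)
  pi <- bench$per_image
  expect_equal(bench$psnr$table["identity", "0.5"],
               mean(pi$psnr[pi$method == "identity" & pi$sigma == 0.5]))
  expect_equal(bench$ssim$table["blur", "1.5"],
               mean(pi$ssim[pi$method == "blur" & pi$sigma == 1.5]))
})

test_that("benchmark runs are deterministic in the seed", {
  run <- function() run_benchmark(
    methods = list(identity = "identity"), sigmas = 1, n_images = 3,
    sampler = phantom_sampler(size = c(32L, 32L)), seed = 4)
  expect_identical(run()$psnr$table, run()$psnr$table)
})

test_that("missing per-sigma checkpoints are reported by cell", {
  fits <- list("0.5" = plain_cnn(init_seed = 1))
  expect_error(
    run_benchmark(methods = list(cnn = fits), sigmas = c(0.5, 1), n_images = 2,
                  sampler = phantom_sampler(size = c(32L, 32L)), seed = 2),
    "cnn.*sigma = 1")
})

test_that("benchmark tables round-trip through CSV, including infinities", {
  tab <- benchmark_table(
    "PSNR",
    matrix(c(30.123456, Inf, 28.5, 31.25), 2, 2,
           dimnames = list(c("identity", "m"), c("0.5", "1"))),
    n_images = 4L, seed = 3L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_benchmark_table(tab, path)
  txt <- readLines(path)
  expect_equal(length(txt), 3L)             # header + 2 method rows
  expect_equal(length(strsplit(txt[1], ",")[[1]]), 3L)  # label + 2 sigmas
  expect_true(any(grepl("inf", txt)))
  back <- read_benchmark_table(path)
  expect_equal(back$table, tab$table)
  expect_equal(back$metric, "PSNR")
  expect_equal(back$n_images, 4L)
})

test_that("paired bootstrap comparison reports one interval per sigma", {
  bench <- run_benchmark(
    methods = list(identity = "identity",
                   blur = function(a) nl_means(a, nlmeans_params(h = 1000))),
    sigmas = c(1, 2), n_images = 5,
    sampler = phantom_sampler(size = c(32L, 32L)), seed = 8)
  cmp <- compare_methods(bench, "blur", "identity", n_boot = 200)
  expect_equal(nrow(cmp), 2)
  expect_true(all(cmp$lo <= cmp$mean_diff & cmp$mean_diff <= cmp$hi))
})
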