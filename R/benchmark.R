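# Benchmark harness: PSNR and SSIM grids of {NL-means, plain CNN, plain UNet,
# improved UNet} x noise levels on a freshly simulated evaluation corpus,
# plus an "identity" (no denoising) pseudo-method as the floor. Both metric
# tables are computed from the same cached denoised outputs.

#' Run the denoising benchmark grid
#'
#' For every (method, sigma) cell: simulate an evaluation corpus at that
#' noise level, denoise every image, and average PSNR and SSIM against the
#' clean references. Learned methods may be given either as one shared
#' checkpoint used at every noise level or as a list of per-sigma
#' checkpoints named by sigma.
#'
#' @param methods named list; each element is one of a `denoiser_model` /
#'   `trained_denoiser` (shared checkpoint), a list of those named by sigma
#'   (e.g. `list("0.5" = fit1, "1" = fit2)`), the string `"identity"` or
#'   `"nlmeans"`, or a `function(noisy_matrix) -> matrix`.
#' @param sigmas noise levels (the table columns).
#' @param n_images evaluation corpus size per sigma.
#' @param sampler phantom family from [phantom_sampler()].
#' @param noise_model `"multiplicative_speckle"` or `"additive_gaussian"`.
#' @param seed corpus seed; the evaluation corpus is derived from it and is
#'   disjoint (by seed stream) from any training corpus built with a
#'   different seed.
#' @param nlmeans_h optional function(sigma) giving the NL-means filtering
#'   strength per noise level; the default is
#'   `sqrt(2) * patch_size * sigma_px`, where `sigma_px` is the noise level
#'   mapped to pixel units (`sigma * 25.5` for additive noise; for
#'   multiplicative speckle `sigma * 128`, the mid-range intensity, since
#'   the noise spread is proportional to the signal).
#' @param ssim_mode SSIM mode, `"global"` or `"windowed"`.
#' @return object of class `benchmark_result`: list with `psnr` and `ssim`
#'   (`benchmark_table`s), `per_image` (long data frame), `n_images`, `seed`.
#' @export
run_benchmark <- function(methods, sigmas = c(0.5, 1, 1.5, 2, 2.5),
                          n_images = 50L, sampler = phantom_sampler(),
                          noise_model = "multiplicative_speckle", seed = 1L,
                          nlmeans_h = NULL, ssim_mode = "global") {
  if (is.null(names(methods)) || any(names(methods) == ""))
    stop("'methods' must be a fully named list", call. = FALSE)
  if (is.null(nlmeans_h)) {
    px <- if (noise_model == "additive_gaussian") SIGMA_PIXEL_SCALE else 128
    nlmeans_h <- function(sigma) {
      p <- nlmeans_params()
      sqrt(2) * p$patch_size * max(sigma, 0.1) * px
    }
  }
  sig_seeds <- derive_seeds(seed, length(sigmas))
  psnr_tab <- matrix(NA_real_, length(methods), length(sigmas),
                     dimnames = list(names(methods), as.character(sigmas)))
  ssim_tab <- psnr_tab
  per_image <- list()
  for (si in seq_along(sigmas)) {
    sg <- sigmas[si]
    corpus <- make_dataset(n_images, sampler = sampler,
                           noise = noise_spec(noise_model, sigma = sg),
                           seed = sig_seeds[si], train_frac = 0)
    for (mi in seq_along(methods)) {
      fn <- resolve_method(methods[[mi]], names(methods)[mi], sg, nlmeans_h)
      res <- vapply(corpus$samples, function(s) {
        den <- fn(s$a)
        c(img_psnr(den, s$b), img_ssim(den, s$b, mode = ssim_mode))
      }, numeric(2))
      psnr_tab[mi, si] <- mean(res[1, ])
      ssim_tab[mi, si] <- mean(res[2, ])
      per_image[[length(per_image) + 1L]] <- data.frame(
        method = names(methods)[mi], sigma = sg,
        image = seq_len(n_images), psnr = res[1, ], ssim = res[2, ])
    }
  }
  structure(list(
    psnr = benchmark_table("PSNR", psnr_tab, n_images, seed),
    ssim = benchmark_table("SSIM", ssim_tab, n_images, seed),
    per_image = do.call(rbind, per_image),
    n_images = as.integer(n_images), seed = as.integer(seed)),
    class = "benchmark_result")
}

resolve_method <- function(m, name, sigma, nlmeans_h) {
  if (is.list(m) && !inherits(m, c("denoiser_model", "trained_denoiser"))) {
    key <- as.character(sigma)
    if (is.null(m[[key]]))
      stop(sprintf("no checkpoint for method '%s' at sigma = %s", name, key),
           call. = FALSE)
    m <- m[[key]]
  }
  if (inherits(m, c("denoiser_model", "trained_denoiser")))
    return(function(a) predict(m, a))
  if (is.function(m)) return(m)
  if (identical(m, "identity")) return(function(a) a)
  if (identical(m, "nlmeans")) {
    p <- nlmeans_params(h = nlmeans_h(sigma))
    return(function(a) nl_means(a, p))
  }
  stop(sprintf("cannot interpret method '%s'", name), call. = FALSE)
}

#' One metric grid of the benchmark
#'
#' @param metric `"PSNR"` or `"SSIM"`.
#' @param table numeric matrix, methods x sigma levels (dimnames set).
#' @param n_images evaluation corpus size per cell.
#' @param seed corpus seed.
#' @return object of class `benchmark_table`.
#' @export
benchmark_table <- function(metric, table, n_images, seed) {
  if (anyNA(table)) stop("benchmark table has missing cells", call. = FALSE)
  structure(list(metric = metric, table = table,
                 n_images = as.integer(n_images), seed = as.integer(seed)),
            class = "benchmark_table")
}

#' @export
print.benchmark_table <- function(x, ...) {
  cat(sprintf("%s over %d images (seed %d):\n", x$metric, x$n_images, x$seed))
  print(round(x$table, 4))
  invisible(x)
}

#' @export
print.benchmark_result <- function(x, ...) {
  print(x$psnr)
  cat("\n")
  print(x$ssim)
  invisible(x)
}

#' Write a benchmark table to CSV (with a JSON provenance sidecar)
#'
#' The CSV has one row per method and one column per sigma, an infinite PSNR
#' rendered as `"inf"`; `<path>.json` records metric, corpus size and seed.
#' [read_benchmark_table()] restores an equal object.
#'
#' @param table a `benchmark_table`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_benchmark_table <- function(table, path) {
  df <- as.data.frame(table$table)
  df[] <- lapply(df, function(v) ifelse(is.infinite(v), "inf",
                                        formatC(v, digits = 15, format = "g")))
  df <- cbind(method = rownames(table$table), df)
  tryCatch(write.csv(df, path, row.names = FALSE),
           error = function(e) stop("cannot write benchmark table to '", path,
                                    "': ", conditionMessage(e), call. = FALSE))
  jsonlite::write_json(
    list(metric = table$metric, n_images = table$n_images, seed = table$seed,
         sigmas = colnames(table$table)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a benchmark table written by [write_benchmark_table()]
#' @param path CSV path (expects the `.json` sidecar next to it).
#' @return a `benchmark_table`.
#' @export
read_benchmark_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(df[, -1, drop = FALSE])
  tab <- matrix(ifelse(m == "inf", Inf, suppressWarnings(as.numeric(m))),
                nrow(m), ncol(m),
                dimnames = list(df$method, colnames(m)))
  benchmark_table(meta$metric, tab, meta$n_images, meta$seed)
}

#' Paired bootstrap comparison of two benchmarked methods
#'
#' For each sigma, the mean per-image PSNR difference (method `a` minus
#' method `b`) with a paired bootstrap percentile interval. The comparison is
#' reported, not asserted: which learned method wins is training-dependent.
#'
#' @param bench a `benchmark_result`.
#' @param a,b method names present in the benchmark.
#' @param metric `"psnr"` or `"ssim"`.
#' @param n_boot bootstrap replicates.
#' @param level interval coverage.
#' @param seed bootstrap seed.
#' @return data frame with sigma, mean difference and interval bounds.
#' @export
compare_methods <- function(bench, a = "improved_unet", b = "unet",
                            metric = c("psnr", "ssim"), n_boot = 2000L,
                            level = 0.95, seed = 1L) {
  metric <- match.arg(metric)
  pi <- bench$per_image
  sigmas <- sort(unique(pi$sigma))
  withr::with_seed(as.integer(seed), {
    rows <- lapply(sigmas, function(sg) {
      va <- pi[pi$method == a & pi$sigma == sg, metric]
      vb <- pi[pi$method == b & pi$sigma == sg, metric]
      d <- va - vb
      boots <- replicate(n_boot, mean(d[sample.int(length(d), replace = TRUE)]))
      qs <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2))
      data.frame(sigma = sg, mean_diff = mean(d), lo = qs[1], hi = qs[2])
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pinned desk-scale end-to-end experiment
#'
#' Simulates a training corpus at sigma = 1, trains the three learned
#' denoisers (improved UNet, plain UNet, plain CNN), then runs the full
#' 4-methods-plus-identity benchmark grid across the five standard noise
#' levels with the shared checkpoints. This is the package's reference
#' experiment; with the defaults it takes a few minutes on one CPU.
#'
#' @param seed master seed (training corpus, initialization, benchmark
#'   corpus are all derived from it).
#' @param n_train training corpus size.
#' @param epochs training epochs for each model.
#' @param n_eval evaluation corpus size per noise level.
#' @param sigmas benchmark noise levels.
#' @param verbose print training progress.
#' @return list with the three `trained_denoiser` fits and the
#'   `benchmark_result`.
#' @export
run_pinned_experiment <- function(seed = 42L, n_train = 200L, epochs = 30L,
                                  n_eval = 50L,
                                  sigmas = c(0.5, 1, 1.5, 2, 2.5),
                                  verbose = FALSE) {
  sd <- derive_seeds(seed, 6)
  train_set <- make_dataset(n_train, noise = noise_spec(sigma = 1.0),
                            seed = sd[1])
  cfg <- function(s) train_config(epochs = epochs, seed = s)
  fits <- list(
    improved_unet = train_denoiser(improved_unet(init_seed = sd[2]), train_set,
                                   cfg(sd[3]), verbose = verbose),
    unet = train_denoiser(plain_unet(init_seed = sd[2]), train_set,
                          cfg(sd[4]), verbose = verbose),
    cnn = train_denoiser(plain_cnn(init_seed = sd[2]), train_set,
                         cfg(sd[5]), verbose = verbose))
  bench <- run_benchmark(
    methods = list(nlmeans = "nlmeans", cnn = fits$cnn, unet = fits$unet,
                   improved_unet = fits$improved_unet, identity = "identity"),
    sigmas = sigmas, n_images = n_eval, seed = sd[6])
  list(fits = fits, benchmark = bench)
}
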