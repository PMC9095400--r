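# Supervised desk-scale training. The improved UNet is trained on the
# residual MSE (predicted noise map vs true e, both on the [0, 1] scale);
# the direct-prediction baselines on image MSE. Optimization is
# adaptive-moment gradient descent (Adam) over mini-batches, fully
# reproducible from the config seed.

#' Training configuration
#'
#' @param epochs number of passes over the training split (>= 1).
#' @param batch_size mini-batch size.
#' @param learning_rate Adam step size.
#' @param loss `"auto"` picks `"mse_on_residual"` for residual-learning
#'   models and `"mse_on_image"` for direct-prediction models; setting it
#'   explicitly must agree with the model's kind.
#' @param seed seed controlling shuffling (and any crops).
#' @param patch_size side of random square training crops; images at or below
#'   this size are used whole.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 30L, batch_size = 8L, learning_rate = 1e-3,
                         loss = c("auto", "mse_on_residual", "mse_on_image"),
                         seed = 1L, patch_size = 64L) {
  loss <- match.arg(loss)
  if (epochs < 1L || batch_size < 1L) stop("epochs and batch_size must be >= 1",
                                           call. = FALSE)
  stopifnot_scalar_number(learning_rate, "learning_rate", min = 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, loss = loss,
                 seed = as.integer(seed), patch_size = as.integer(patch_size)),
            class = "train_config")
}

resolve_loss <- function(model, config) {
  want <- if (model$arch$residual) "mse_on_residual" else "mse_on_image"
  if (config$loss == "auto") return(want)
  if (config$loss != want)
    stop(sprintf("loss '%s' is incompatible with a %s model (use '%s')",
                 config$loss, model$arch$kind, want), call. = FALSE)
  config$loss
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = st)
}

# Loss and parameter gradients for one sample. Returns list(loss, grads).
sample_grads <- function(model, a, b, loss_kind, crop = NULL, bit_depth = 8L) {
  L <- 2^bit_depth - 1
  if (!is.null(crop)) {
    a <- a[crop$r, crop$c, drop = FALSE]
    b <- b[crop$r, crop$c, drop = FALSE]
  }
  xn <- array(a / L, dim = c(nrow(a), ncol(a), 1L))
  target <- if (loss_kind == "mse_on_residual") (b - a) / L else b / L
  tarr <- array(target, dim = dim(xn))
  tp <- ad_tape()
  pn <- lapply(model$params, function(v) ad_leaf(tp, v))
  x <- ad_leaf(tp, xn)
  out <- forward_model(tp, pn, x, model$arch)$out
  diff <- out$value - tarr
  loss <- mean(diff^2)
  grads <- ad_grad(tp, out, 2 * diff / length(diff))
  by_name <- lapply(pn, function(nd) grads[[nd$id]])
  list(loss = loss, grads = by_name)
}

#' Train a denoiser on a simulated corpus
#'
#' Mini-batch Adam on the configured MSE loss; gradients are averaged over
#' the batch. Two runs with identical model, dataset and config produce
#' identical loss histories. After each epoch the mean validation PSNR of the
#' denoised validation images is recorded; if the final value does not beat
#' the noisy-input PSNR a warning (not an error) is emitted.
#'
#' @param model an untrained `denoiser_model`.
#' @param dataset a `denoise_dataset` from [make_dataset()] (must contain a
#'   non-empty validation split).
#' @param config a [train_config()].
#' @param verbose print per-epoch progress.
#' @return object of class `trained_denoiser`: list with `model` (trained),
#'   `loss_history`, `val_psnr_history`, `noisy_psnr` (validation baseline),
#'   and `config`.
#' @export
train_denoiser <- function(model, dataset, config = train_config(),
                           verbose = FALSE) {
  if (!inherits(model, "denoiser_model")) stop("'model' must be a denoiser_model",
                                               call. = FALSE)
  if (!inherits(dataset, "denoise_dataset") || length(dataset$samples) == 0L)
    stop("'dataset' must be a non-empty denoise_dataset", call. = FALSE)
  loss_kind <- resolve_loss(model, config)
  train_ids <- dataset$train_idx
  val_ids <- dataset$val_idx
  if (length(train_ids) == 0L) stop("empty training split", call. = FALSE)
  params <- model$params
  st <- adam_state(params)
  loss_history <- numeric(config$epochs)
  val_psnr_history <- numeric(config$epochs)
  m <- spatial_multiple(model$arch)

  withr::with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample(train_ids)
      ep_loss <- 0
      n_seen <- 0L
      for (start in seq(1L, length(ord), by = config$batch_size)) {
        ids <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        acc <- NULL
        bl <- 0
        for (id in ids) {
          s <- dataset$samples[[id]]
          crop <- make_crop(dim(s$a), config$patch_size, m)
          model$params <- params
          sg <- sample_grads(model, s$a, s$b, loss_kind, crop)
          bl <- bl + sg$loss
          acc <- if (is.null(acc)) sg$grads else
            mapply(function(u, v) {
              if (is.null(u)) v else if (is.null(v)) u else u + v
            }, acc, sg$grads, SIMPLIFY = FALSE)
        }
        acc <- lapply(acc, function(g) if (is.null(g)) NULL else g / length(ids))
        upd <- adam_step(params, acc, st, config$learning_rate)
        params <- upd$params
        st <- upd$state
        ep_loss <- ep_loss + bl
        n_seen <- n_seen + length(ids)
      }
      loss_history[ep] <- ep_loss / n_seen
      if (!is.finite(loss_history[ep]))
        stop(sprintf("non-finite training loss at epoch %d (lr too high?)", ep),
             call. = FALSE)
      model$params <- params
      val_psnr_history[ep] <- if (length(val_ids) > 0)
        mean(vapply(dataset$samples[val_ids], function(s)
          img_psnr(predict(model, s$a, quantize = FALSE), s$b), numeric(1)))
      else NA_real_
      if (verbose)
        message(sprintf("epoch %3d  loss %.6f  val PSNR %.3f dB",
                        ep, loss_history[ep], val_psnr_history[ep]))
    }
  })

  model$params <- params
  model$trained <- TRUE
  noisy_psnr <- if (length(val_ids) > 0)
    mean(vapply(dataset$samples[val_ids], function(s) img_psnr(s$a, s$b),
                numeric(1)))
  else NA_real_
  if (length(val_ids) > 0 && is.finite(noisy_psnr) &&
      val_psnr_history[config$epochs] <= noisy_psnr)
    warning(sprintf(
      "final validation PSNR (%.2f dB) does not beat the noisy input (%.2f dB)",
      val_psnr_history[config$epochs], noisy_psnr), call. = FALSE)
  structure(list(model = model, loss_history = loss_history,
                 val_psnr_history = val_psnr_history,
                 noisy_psnr = noisy_psnr, config = config),
            class = "trained_denoiser")
}

make_crop <- function(d, patch, multiple) {
  if (d[1] <= patch && d[2] <= patch) return(NULL)
  ph <- min(patch, d[1])
  pw <- min(patch, d[2])
  ph <- ph - ph %% multiple
  pw <- pw - pw %% multiple
  r0 <- sample.int(d[1] - ph + 1L, 1)
  c0 <- sample.int(d[2] - pw + 1L, 1)
  list(r = r0:(r0 + ph - 1L), c = c0:(c0 + pw - 1L))
}

#' @export
predict.trained_denoiser <- function(object, image, ...) {
  predict(object$model, image, ...)
}

#' @export
print.trained_denoiser <- function(x, ...) {
  cat(sprintf("trained %s: %d epochs, final loss %.6g\n", x$model$arch$kind,
              length(x$loss_history), x$loss_history[length(x$loss_history)]))
  if (is.finite(x$noisy_psnr))
    cat(sprintf("validation PSNR %.2f dB (noisy input: %.2f dB)\n",
                x$val_psnr_history[length(x$val_psnr_history)], x$noisy_psnr))
  invisible(x)
}

#' @export
summary.trained_denoiser <- function(object, ...) {
  print(object)
  cat("loss history:\n")
  print(summary(object$loss_history))
  invisible(object)
}

#' Plot training curves
#'
#' Loss (log scale) and mean validation PSNR per epoch.
#'
#' @param x a `trained_denoiser`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.trained_denoiser <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$loss_history, type = "l", log = "y", xlab = "epoch",
                 ylab = "training loss", ...)
  graphics::plot(x$val_psnr_history, type = "l", xlab = "epoch",
                 ylab = "validation PSNR (dB)", ...)
  if (is.finite(x$noisy_psnr))
    graphics::abline(h = x$noisy_psnr, lty = 2)
  invisible(x)
}
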