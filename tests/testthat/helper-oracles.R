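# Independent brute-force oracles used to validate the fast implementations.

# SSIM by direct evaluation of the definition with population statistics.
ssim_oracle <- function(x, y, C1, C2) {
  n <- length(x)
  ux <- sum(x) / n
  uy <- sum(y) / n
  vx <- sum((x - ux)^2) / n
  vy <- sum((y - uy)^2) / n
  cxy <- sum((x - ux) * (y - uy)) / n
  ((2 * ux * uy + C1) * (2 * cxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
}

# Non-local means by an explicit double loop over pixels and window
# neighbours; mirrors the production conventions (mirror-padded patches,
# border-clipped search window, weights exp(-sum sq diff / h^2)). Also
# asserts that the weights at every pixel normalize to 1.
nlm_oracle <- function(img, patch, window, h) {
  H <- nrow(img)
  W <- ncol(img)
  pr <- patch %/% 2
  wr <- window %/% 2
  mirror_idx <- function(i, n) {
    i <- ifelse(i < 1, 1 - i, i)
    ifelse(i > n, 2 * n - i + 1, i)
  }
  pad <- img[mirror_idx(seq(1 - pr, H + pr), H),
             mirror_idx(seq(1 - pr, W + pr), W)]
  patch_at <- function(i, j) pad[(i):(i + 2 * pr), (j):(j + 2 * pr)]
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      pi <- patch_at(i, j)
      ks <- max(1, i - wr):min(H, i + wr)
      ls <- max(1, j - wr):min(W, j + wr)
      wts <- matrix(0, length(ks), length(ls))
      for (a in seq_along(ks)) {
        for (b in seq_along(ls)) {
          pj <- patch_at(ks[a], ls[b])
          wts[a, b] <- exp(-sum((pi - pj)^2) / h^2)
        }
      }
      wn <- wts / sum(wts)
      stopifnot(abs(sum(wn) - 1) < 1e-12)
      out[i, j] <- sum(wn * img[ks, ls])
    }
  }
  out
}

# Small deterministic phantom pair for quick tests.
tiny_sample <- function(sigma = 1, seed = 101, size = 32L, spots = 2L) {
  spec <- phantom_spec(size = c(size, size),
                       spots = list(count = spots, intensity = 230,
                                    radius = 1.2),
                       seed = seed)
  b <- generate_phantom(spec)
  add_noise(b, noise_spec(sigma = sigma, seed = seed + 1L))
}

# Central-difference gradient check of a few entries of every parameter.
# Parameters are jittered away from their init first: zero biases put
# ReLU/PReLU pre-activations exactly at the kink, where a central difference
# straddles the two branches and disagrees with the (one-sided) analytic
# derivative for reasons that have nothing to do with correctness.
max_grad_error <- function(model, loss_kind, seed = 1, n_entries = 2,
                           eps = 1e-5) {
  withr::with_seed(seed, {
    model$params <- lapply(model$params,
                           function(p) p + runif(length(p), 0.005, 0.02))
    a <- matrix(runif(64, 0, 255), 8, 8)
    b <- matrix(runif(64, 0, 255), 8, 8)
    sg <- usdenoise:::sample_grads(model, a, b, loss_kind)
    lossfn <- function(params) {
      m2 <- model
      m2$params <- params
      usdenoise:::sample_grads(m2, a, b, loss_kind)$loss
    }
    num_at <- function(nm, i, eps) {
      pp <- model$params
      pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- model$params
      pm[[nm]][i] <- pm[[nm]][i] - eps
      (lossfn(pp) - lossfn(pm)) / (2 * eps)
    }
    worst <- 0
    for (nm in names(model$params)) {
      p <- model$params[[nm]]
      for (i in sample(seq_along(p), min(n_entries, length(p)))) {
        num1 <- num_at(nm, i, eps)
        num2 <- num_at(nm, i, eps / 4)
        # inconsistent finite differences mean the probe straddles an
        # activation kink; such points say nothing about the analytic
        # gradient, so skip them
        if (abs(num1 - num2) / max(1e-8, abs(num1), abs(num2)) > 1e-4) next
        ana <- sg$grads[[nm]][i]
        worst <- max(worst, abs(num2 - ana) / max(1e-8, abs(num2), abs(ana)))
      }
    }
    worst
  })
}
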