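# Denoiser architectures.
#
# improved UNet (residual noise learning): strided-convolution downsampling,
# residual blocks with PReLU, decoder feature recovery by RDUB (a residual
# block plus 1x1 projection of each encoder map, superimposed elementwise on
# the matching decoder level, in addition to the concatenating skip), and a
# Recon head (two 3x3 convolutions) emitting the predicted noise map e-hat,
# so the clean estimate is a + e-hat.
#
# plain UNet: the classic codec — 2x2 max pooling, double 3x3 conv + ReLU
# blocks, concatenating same-level skips — trained to predict the clean image
# directly.
#
# plain CNN: a flat stack of 3x3 convolutions with PReLU, no down/upsampling,
# predicting the clean image directly.
#
# Every downsampling level halves the spatial dimensions and doubles the
# channel count.

#' Architecture description for a denoiser
#'
#' @param kind one of `"improved_unet"`, `"plain_unet"`, `"plain_cnn"`,
#'   `"constant_residual"`.
#' @param depth number of downsampling levels (UNets) or of convolution
#'   layers (plain CNN).
#' @param base_channels channels at the top level (UNets) or throughout the
#'   stack (plain CNN).
#' @param downsample `"stride_conv"` or `"max_pool"`.
#' @param use_residual_blocks,use_rdub,use_recon feature switches; the
#'   improved preset has all on, the plain preset all off.
#' @param residual TRUE when the network predicts the noise map e (so the
#'   output is a + e-hat), FALSE when it predicts the clean image directly.
#' @param prelu_shared one PReLU slope per layer (TRUE) or per channel.
#' @param init_seed seed for deterministic parameter initialization.
#' @return object of class `architecture_spec`.
#' @export
architecture_spec <- function(kind, depth, base_channels,
                              downsample = c("stride_conv", "max_pool"),
                              use_residual_blocks = FALSE, use_rdub = FALSE,
                              use_recon = FALSE, residual = FALSE,
                              prelu_shared = FALSE, init_seed = 1L) {
  downsample <- match.arg(downsample)
  depth <- as.integer(depth)
  base_channels <- as.integer(base_channels)
  if (kind != "constant_residual" && (depth < 1L || base_channels < 1L))
    stop("depth and base_channels must be >= 1", call. = FALSE)
  structure(list(kind = kind, depth = depth, base_channels = base_channels,
                 downsample = downsample,
                 use_residual_blocks = use_residual_blocks,
                 use_rdub = use_rdub, use_recon = use_recon,
                 residual = residual, prelu_shared = prelu_shared,
                 init_seed = as.integer(init_seed)),
            class = "architecture_spec")
}

# He fan-in initialization for a conv layer, as a (kh*kw*cin) x cout matrix.
# The final output layer of each network instead gets a near-zero scale so
# optimization starts from the zero-residual (identity) / zero-image map, the
# standard stabilization for residual denoisers.
he_conv <- function(kh, kw, cin, cout, scale = NULL) {
  fan_in <- kh * kw * cin
  if (is.null(scale)) scale <- sqrt(2 / fan_in)
  list(W = matrix(rnorm(fan_in * cout, sd = scale), fan_in, cout),
       b = numeric(cout))
}

slope_init <- function(channels, shared) rep(0.25, if (shared) 1L else channels)

init_params <- function(spec) {
  ps <- list()
  add_conv <- function(name, kh, cin, cout, scale = NULL) {
    l <- he_conv(kh, kh, cin, cout, scale)
    ps[[paste0(name, ".W")]] <<- l$W
    ps[[paste0(name, ".b")]] <<- l$b
  }
  add_slope <- function(name, ch) {
    ps[[paste0(name)]] <<- slope_init(ch, spec$prelu_shared)
  }
  D <- spec$depth
  C0 <- spec$base_channels
  ch <- function(k) C0 * 2L^k
  withr::with_seed(spec$init_seed, switch(
    spec$kind,
    improved_unet = {
      add_conv("stem", 3, 1, C0); add_slope("stem.s", C0)
      for (k in 0:(D - 1)) {
        add_conv(sprintf("enc%d.conv1", k), 3, ch(k), ch(k))
        add_slope(sprintf("enc%d.s", k), ch(k))
        add_conv(sprintf("enc%d.conv2", k), 3, ch(k), ch(k))
        add_conv(sprintf("down%d", k), 3, ch(k), ch(k + 1))
        add_slope(sprintf("down%d.s", k), ch(k + 1))
      }
      add_conv("bott.conv1", 3, ch(D), ch(D)); add_slope("bott.s", ch(D))
      add_conv("bott.conv2", 3, ch(D), ch(D))
      for (k in (D - 1):0) {
        add_conv(sprintf("up%d", k), 3, ch(k + 1), ch(k))
        add_slope(sprintf("up%d.s", k), ch(k))
        add_conv(sprintf("dec%d", k), 3, 2 * ch(k), ch(k))
        add_slope(sprintf("dec%d.s", k), ch(k))
        add_conv(sprintf("rdub%d.conv1", k), 3, ch(k), ch(k))
        add_slope(sprintf("rdub%d.s", k), ch(k))
        add_conv(sprintf("rdub%d.conv2", k), 3, ch(k), ch(k))
        add_conv(sprintf("rdub%d.proj", k), 1, ch(k), ch(k))
      }
      cr <- max(1L, C0 %/% 2L)
      add_conv("recon.conv1", 3, C0, cr); add_slope("recon.s", cr)
      add_conv("recon.conv2", 3, cr, 1, scale = 1e-3)
    },
    plain_unet = {
      add_conv("lvl0.c1", 3, 1, C0)
      add_conv("lvl0.c2", 3, C0, C0)
      for (k in seq_len(D)) {
        add_conv(sprintf("lvl%d.c1", k), 3, ch(k - 1), ch(k))
        add_conv(sprintf("lvl%d.c2", k), 3, ch(k), ch(k))
      }
      for (k in (D - 1):0) {
        add_conv(sprintf("up%d", k), 3, ch(k + 1), ch(k))
        add_conv(sprintf("dec%d.c1", k), 3, 2 * ch(k), ch(k))
        add_conv(sprintf("dec%d.c2", k), 3, ch(k), ch(k))
      }
      add_conv("final", 3, C0, 1, scale = 1e-3)
    },
    plain_cnn = {
      add_conv("layer1", 3, 1, C0); add_slope("layer1.s", C0)
      if (D >= 3) for (k in 2:(D - 1)) {
        add_conv(sprintf("layer%d", k), 3, C0, C0)
        add_slope(sprintf("layer%d.s", k), C0)
      }
      add_conv(sprintf("layer%d", D), 3, C0, 1, scale = 1e-3)
    },
    constant_residual = {
      ps[["c"]] <- 0
    },
    stop("unknown architecture kind: ", spec$kind)
  ))
  ps
}

#' Build a denoiser model from an architecture description
#'
#' Parameter initialization is He-style fan-in scaling with PReLU slopes at
#' 0.25, fully determined by `init_seed`.
#'
#' @param spec an [architecture_spec()].
#' @return object of class `denoiser_model` (subclassed by kind).
#' @export
build_model <- function(spec) {
  structure(list(arch = spec, params = init_params(spec), trained = FALSE),
            class = c(spec$kind, "denoiser_model"))
}

#' Improved UNet denoiser (residual noise learning preset)
#'
#' Strided-convolution downsampling, residual blocks, RDUB feature recovery,
#' Recon reconstruction head; predicts the noise map so the clean estimate is
#' input + prediction.
#'
#' @param depth downsampling levels.
#' @param base_channels channels at the top level (doubled at each level).
#' @param prelu_shared share one PReLU slope across channels per layer.
#' @param init_seed initialization seed.
#' @return a `denoiser_model`.
#' @export
improved_unet <- function(depth = 2L, base_channels = 8L,
                          prelu_shared = FALSE, init_seed = 1L) {
  build_model(architecture_spec("improved_unet", depth, base_channels,
                                "stride_conv", use_residual_blocks = TRUE,
                                use_rdub = TRUE, use_recon = TRUE,
                                residual = TRUE, prelu_shared = prelu_shared,
                                init_seed = init_seed))
}

#' Classic max-pool UNet baseline
#'
#' The traditional codec: 2x2 max pooling, plain double-conv + ReLU blocks,
#' concatenating same-level skip connections; predicts the clean image
#' directly (no residual learning).
#'
#' @inheritParams improved_unet
#' @return a `denoiser_model`.
#' @export
plain_unet <- function(depth = 2L, base_channels = 8L, init_seed = 1L) {
  build_model(architecture_spec("plain_unet", depth, base_channels,
                                "max_pool", init_seed = init_seed))
}

#' Flat convolutional denoiser baseline
#'
#' A stack of `depth` 3x3 convolutions (PReLU between) with no down- or
#' upsampling, predicting the clean image directly.
#'
#' @param depth number of convolution layers (>= 2).
#' @param channels channels in the hidden layers.
#' @param init_seed initialization seed.
#' @return a `denoiser_model`.
#' @export
plain_cnn <- function(depth = 5L, channels = 16L, init_seed = 1L) {
  if (depth < 2L) stop("plain_cnn needs depth >= 2", call. = FALSE)
  build_model(architecture_spec("plain_cnn", depth, channels,
                                init_seed = init_seed))
}

#' Degenerate constant-residual model
#'
#' Predicts one constant value everywhere as the noise map. Its optimum under
#' the residual MSE loss is the corpus-mean residual, which makes it a
#' closed-form diagnostic for the training loop.
#'
#' @return a `denoiser_model`.
#' @export
constant_residual_model <- function() {
  build_model(architecture_spec("constant_residual", 0L, 1L, residual = TRUE))
}

# --- forward passes (tape-based) --------------------------------------------

conv_pn <- function(tp, x, pn, name, stride = 1L, kh = 3L) {
  op_conv(tp, x, pn[[paste0(name, ".W")]], pn[[paste0(name, ".b")]],
          stride = stride, kh = kh, kw = kh)
}

rb_pn <- function(tp, x, pn, name) {
  h <- conv_pn(tp, x, pn, paste0(name, ".conv1"))
  h <- op_prelu(tp, h, pn[[paste0(name, ".s")]])
  h <- conv_pn(tp, h, pn, paste0(name, ".conv2"))
  op_add(tp, x, h)
}

forward_model <- function(tp, pn, x, spec, trace = FALSE) {
  tr <- list(encoder = list(), downsample = character(0))
  D <- spec$depth
  out <- switch(
    spec$kind,
    improved_unet = {
      h <- op_prelu(tp, conv_pn(tp, x, pn, "stem"), pn[["stem.s"]])
      enc <- vector("list", D)
      for (k in 0:(D - 1)) {
        h <- rb_pn(tp, h, pn, sprintf("enc%d", k))
        enc[[k + 1]] <- h
        if (trace) {
          tr$encoder[[k + 1]] <- dim(h$value)
          tr$downsample <- c(tr$downsample, "stride_conv")
        }
        h <- op_prelu(tp, conv_pn(tp, h, pn, sprintf("down%d", k), stride = 2L),
                      pn[[sprintf("down%d.s", k)]])
      }
      if (trace) tr$encoder[[D + 1]] <- dim(h$value)
      h <- rb_pn(tp, h, pn, "bott")
      for (k in (D - 1):0) {
        h <- op_prelu(tp, conv_pn(tp, op_upsample2(tp, h), pn, sprintf("up%d", k)),
                      pn[[sprintf("up%d.s", k)]])
        h <- op_concat(tp, enc[[k + 1]], h)
        h <- op_prelu(tp, conv_pn(tp, h, pn, sprintf("dec%d", k)),
                      pn[[sprintf("dec%d.s", k)]])
        r <- rb_pn(tp, enc[[k + 1]], pn, sprintf("rdub%d", k))
        r <- conv_pn(tp, r, pn, sprintf("rdub%d.proj", k), kh = 1L)
        h <- op_add(tp, h, r)
      }
      h <- op_prelu(tp, conv_pn(tp, h, pn, "recon.conv1"), pn[["recon.s"]])
      conv_pn(tp, h, pn, "recon.conv2")
    },
    plain_unet = {
      dconv <- function(h, name) {
        h <- op_relu(tp, conv_pn(tp, h, pn, paste0(name, ".c1")))
        op_relu(tp, conv_pn(tp, h, pn, paste0(name, ".c2")))
      }
      h <- dconv(x, "lvl0")
      enc <- vector("list", D)
      enc[[1]] <- h
      if (trace) tr$encoder[[1]] <- dim(h$value)
      for (k in seq_len(D)) {
        if (trace) tr$downsample <- c(tr$downsample, "max_pool")
        h <- dconv(op_maxpool2(tp, h), sprintf("lvl%d", k))
        if (k < D) enc[[k + 1]] <- h
        if (trace) tr$encoder[[k + 1]] <- dim(h$value)
      }
      for (k in (D - 1):0) {
        h <- op_relu(tp, conv_pn(tp, op_upsample2(tp, h), pn, sprintf("up%d", k)))
        h <- op_concat(tp, enc[[k + 1]], h)
        h <- dconv(h, sprintf("dec%d", k))
      }
      conv_pn(tp, h, pn, "final")
    },
    plain_cnn = {
      h <- op_prelu(tp, conv_pn(tp, x, pn, "layer1"), pn[["layer1.s"]])
      if (D >= 3) for (k in 2:(D - 1)) {
        h <- op_prelu(tp, conv_pn(tp, h, pn, sprintf("layer%d", k)),
                      pn[[sprintf("layer%d.s", k)]])
      }
      conv_pn(tp, h, pn, sprintf("layer%d", D))
    },
    constant_residual = {
      d <- dim(x$value)
      cnode <- pn[["c"]]
      ad_node(tp, array(cnode$value, dim = d), list(cnode),
              function(g) list(sum(g)))
    },
    stop("unknown architecture kind: ", spec$kind)
  )
  list(out = out, trace = tr)
}

# Run the network on a normalized H x W x 1 array; returns the raw network
# output (residual map or direct image estimate, [0, 1] scale) plus trace.
model_forward_array <- function(model, xarr, trace = FALSE) {
  tp <- ad_tape()
  pn <- lapply(model$params, function(v) ad_leaf(tp, v))
  xn <- ad_leaf(tp, xarr)
  forward_model(tp, pn, xn, model$arch, trace = trace)
}

# Multiple of 2^depth the inputs must be padded to.
spatial_multiple <- function(spec) {
  if (spec$kind %in% c("improved_unet", "plain_unet")) 2L^spec$depth else 1L
}

pad_reflect <- function(x, m) {
  h <- nrow(x); w <- ncol(x)
  ph <- (m - h %% m) %% m
  pw <- (m - w %% m) %% m
  if (ph > 0) x <- rbind(x, x[h:(h - ph + 1L), , drop = FALSE])
  if (pw > 0) x <- cbind(x, x[, w:(w - pw + 1L), drop = FALSE])
  x
}

#' Denoise an image with a model
#'
#' The image is scaled to [0, 1], reflect-padded to a multiple of the model's
#' downsampling factor if needed, run through the network, and (for residual
#' models) added back to the input; the result is cropped, rescaled, clipped
#' to the valid range and quantized.
#'
#' @param object a `denoiser_model` or a `trained_denoiser` fit.
#' @param image noisy image, numeric matrix in [0, 2^bit_depth - 1].
#' @param bit_depth bits per pixel.
#' @param quantize round the result to integer levels (default TRUE).
#' @param ... unused.
#' @return denoised image, numeric matrix of the input's shape.
#' @export
predict.denoiser_model <- function(object, image, bit_depth = 8L,
                                   quantize = TRUE, ...) {
  if (!is.matrix(image)) stop("'image' must be a numeric matrix", call. = FALSE)
  L <- 2^bit_depth - 1
  h <- nrow(image); w <- ncol(image)
  xp <- pad_reflect(image / L, spatial_multiple(object$arch))
  xarr <- array(xp, dim = c(nrow(xp), ncol(xp), 1L))
  out <- model_forward_array(object, xarr)$out$value
  est <- if (object$arch$residual) xarr + out else out
  est <- matrix(est[, , 1], nrow(xp), ncol(xp))[seq_len(h), seq_len(w)] * L
  est <- pmin(pmax(est, 0), L)
  if (quantize) est <- round(est)
  est
}

#' Total number of learnable parameters
#' @param model a `denoiser_model`.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) sum(vapply(model$params, length, integer(1)))

#' Apply a residual block to a feature map
#'
#' `output = input + conv3x3(PReLU(conv3x3(input)))` with same-padding; the
#' input/output skip makes the block an exact identity when all weights and
#' biases are zero.
#'
#' @param features H x W x C numeric array.
#' @param params list with `conv1`, `conv2` (each `list(W, b)` with W a
#'   `(9*C) x C` matrix) and `slope` (PReLU slope, length 1 or C).
#' @return array of the same shape.
#' @export
residual_block <- function(features, params) {
  C <- dim(features)[3]
  if (nrow(params$conv1$W) != 9 * C)
    stop("residual block channel mismatch", call. = FALSE)
  h <- conv2d_fw(features, params$conv1$W, params$conv1$b, 3L, 3L, 1L, 1L)
  h <- prelu(h, params$slope)
  features + conv2d_fw(h, params$conv2$W, params$conv2$b, 3L, 3L, 1L, 1L)
}

# Internal feature-map shapes of the encoder path (and downsampling mode per
# level), obtained by running a traced forward pass on a zero input.
#' Inspect internal encoder geometry of a model
#'
#' @param model a `denoiser_model`.
#' @param input_size c(height, width) of the probe input.
#' @return list with `encoder` (one c(H, W, C) per level, top to bottom) and
#'   `downsample` (the mechanism used at each level).
#' @export
model_shapes <- function(model, input_size = c(64L, 64L)) {
  xarr <- array(0, dim = c(input_size[1], input_size[2], 1L))
  model_forward_array(model, xarr, trace = TRUE)$trace
}

#' @export
print.denoiser_model <- function(x, ...) {
  a <- x$arch
  cat(sprintf("%s denoiser (%s)\n", a$kind,
              if (x$trained) "trained" else "untrained"))
  if (a$kind %in% c("improved_unet", "plain_unet")) {
    cat(sprintf("  depth %d, base channels %d, downsampling: %s\n",
                a$depth, a$base_channels, a$downsample))
    cat(sprintf("  residual blocks: %s, RDUB: %s, Recon: %s, residual learning: %s\n",
                a$use_residual_blocks, a$use_rdub, a$use_recon, a$residual))
  } else if (a$kind == "plain_cnn") {
    cat(sprintf("  %d conv layers, %d channels\n", a$depth, a$base_channels))
  }
  cat(sprintf("  parameters: %d\n", n_parameters(x)))
  invisible(x)
}

#' @export
summary.denoiser_model <- function(object, ...) print(object, ...)
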