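# Minimal reverse-mode tape over H x W x C feature arrays.
#
# A tape records one node per operation; each node keeps the ids of its inputs
# and a closure mapping the gradient at its output to gradients at its inputs.
# Backprop walks the tape in reverse, accumulating gradients by node id. The
# engine is deliberately small: only the operations the denoiser architectures
# need are implemented (convolution, PReLU/ReLU, 2x2 max pool, nearest
# upsampling, channel concatenation, elementwise add).

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp
}

ad_leaf <- function(tp, value) {
  id <- length(tp$nodes) + 1L
  tp$nodes[[id]] <- list(inputs = integer(0), back = NULL)
  list(id = id, value = value)
}

ad_node <- function(tp, value, inputs, back) {
  id <- length(tp$nodes) + 1L
  tp$nodes[[id]] <- list(
    inputs = vapply(inputs, function(n) n$id, integer(1)),
    back = back
  )
  list(id = id, value = value)
}

# Gradients of every node reachable from `out`, as a list indexed by node id.
ad_grad <- function(tp, out, gout) {
  grads <- vector("list", length(tp$nodes))
  grads[[out$id]] <- gout
  for (id in rev(seq_along(tp$nodes))) {
    g <- grads[[id]]
    nd <- tp$nodes[[id]]
    if (is.null(g) || is.null(nd$back)) next
    gi <- nd$back(g)
    for (k in seq_along(nd$inputs)) {
      if (is.null(gi[[k]])) next
      j <- nd$inputs[k]
      grads[[j]] <- if (is.null(grads[[j]])) gi[[k]] else grads[[j]] + gi[[k]]
    }
  }
  grads
}

# Convolution with same-padding by default; weight node w holds a
# (kh*kw*Cin) x Cout matrix, bias node b a length-Cout vector.
op_conv <- function(tp, x, w, b, stride = 1L, kh = 3L, kw = 3L,
                    pad = (kh - 1L) %/% 2L) {
  xv <- x$value
  wv <- w$value
  d <- dim(xv)
  fw <- conv2d_fw_cache(xv, wv, as.numeric(b$value), kh, kw, stride, pad)
  ad_node(tp, fw$out, list(x, w, b), function(g) {
    r <- conv2d_bw_cache(fw$P, wv, g, d[1], d[2], d[3], kh, kw, stride, pad)
    list(r$gx, r$gw, as.numeric(r$gb))
  })
}

#' Parametric rectified linear unit
#'
#' Elementwise activation that is the identity for positive inputs and a
#' learnable linear slope for non-positive inputs; with slope 0 it degenerates
#' to the ordinary ReLU. The slope may be shared across channels (length 1) or
#' per channel (length C).
#'
#' @param x numeric vector, matrix or array.
#' @param slope slope applied where `x <= 0`; length 1 or, for an H x W x C
#'   array, length C (one slope per channel).
#' @return object of the same shape as `x`.
#' @examples
#' prelu(c(2, -2), 0.25)   # 2, -0.5
#' prelu(-3, 0)            # 0 (ReLU)
#' @export
prelu <- function(x, slope) {
  sl <- prelu_slope_array(x, slope)
  neg <- x <= 0
  x * (!neg) + x * sl * neg
}

prelu_slope_array <- function(x, slope) {
  d <- dim(x)
  if (length(slope) == 1L) {
    if (is.null(d)) return(rep(slope, length(x)))
    return(array(slope, dim = d))
  }
  if (is.null(d) || length(d) != 3L)
    stop("per-channel PReLU slope requires an H x W x C array", call. = FALSE)
  if (length(slope) != d[3])
    stop("PReLU slope length must be 1 or the number of channels", call. = FALSE)
  array(rep(slope, each = d[1] * d[2]), dim = d)
}

op_prelu <- function(tp, x, s) {
  xv <- x$value
  sv <- as.numeric(s$value)
  if (length(sv) != 1L && length(sv) != dim(xv)[3])
    stop("PReLU slope length must be 1 or the number of channels", call. = FALSE)
  out <- prelu_fw(xv, sv)
  ad_node(tp, out, list(x, s), function(g) {
    r <- prelu_bw(xv, sv, g)
    list(r$gx, as.numeric(r$gs))
  })
}

op_relu <- function(tp, x) {
  xv <- x$value
  pos <- xv > 0
  ad_node(tp, xv * pos, list(x), function(g) list(g * pos))
}

op_add <- function(tp, a, b) {
  ad_node(tp, a$value + b$value, list(a, b), function(g) list(g, g))
}

op_concat <- function(tp, a, b) {
  da <- dim(a$value)
  db <- dim(b$value)
  out <- array(c(a$value, b$value), dim = c(da[1], da[2], da[3] + db[3]))
  ad_node(tp, out, list(a, b), function(g) {
    list(g[, , seq_len(da[3]), drop = FALSE],
         g[, , da[3] + seq_len(db[3]), drop = FALSE])
  })
}

op_maxpool2 <- function(tp, x) {
  xv <- x$value
  r <- maxpool2_fw(xv)
  H <- dim(xv)[1]
  W <- dim(xv)[2]
  ad_node(tp, r$out, list(x), function(g) list(maxpool2_bw(g, r$idx, H, W)))
}

upsample2_nearest <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}

op_upsample2 <- function(tp, x) {
  ad_node(tp, upsample2_nearest(x$value), list(x), function(g) {
    d <- dim(g)
    o <- seq.int(1L, d[1], 2L)
    p <- seq.int(1L, d[2], 2L)
    list(g[o, p, , drop = FALSE] + g[o + 1L, p, , drop = FALSE] +
         g[o, p + 1L, , drop = FALSE] + g[o + 1L, p + 1L, , drop = FALSE])
  })
}
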