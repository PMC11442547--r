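# Minimal define-by-hand neural network layers for volumetric regression.
#
# Every tensor is an R array with dim = c(C, D, H, W): channels first and
# fastest-varying, so a pointwise convolution is one BLAS gemm on the
# (C, D*H*W) matrix view. Layers are environments holding `params`, `grads`
# and closures `forward(x, training)` / `backward(g)`; composite blocks hold
# sublayers in `layers`. Backward passes consume the caches written by the
# matching training-mode forward.

new_layer <- function(type) {
  self <- new.env(parent = emptyenv())
  self$type <- type
  self$params <- list()
  self$grads <- list()
  self$buffers <- list()
  self$layers <- list()
  self$cache <- NULL
  class(self) <- c(type, "cm_layer")
  self
}

## weight initializers (He fan-in scaling for conv/linear paths)
init_kaiming <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

# cap on im2col buffer entries before chunking over output slices (~240 MB)
.cm_col_budget <- 3e7

conv_out_len <- function(n, k, s, p) (n + 2L * p - k) %/% s + 1L

#' @noRd
layer_conv3d <- function(cin, cout, k, stride = c(1L, 1L, 1L), pad = c(0L, 0L, 0L)) {
  self <- new_layer("cm_conv3d")
  k <- as.integer(k); stride <- as.integer(stride); pad <- as.integer(pad)
  k3 <- prod(k)
  self$params <- list(W = init_kaiming(cout, cin * k3, cin * k3), b = numeric(cout))
  self$grads <- lapply(self$params, function(p) p * 0)
  self$meta <- list(cin = cin, cout = cout, k = k, stride = stride, pad = pad)

  out_dim <- function(d) {
    c(cout,
      conv_out_len(d[2], k[1], stride[1], pad[1]),
      conv_out_len(d[3], k[2], stride[2], pad[2]),
      conv_out_len(d[4], k[3], stride[3], pad[3]))
  }
  self$out_dim <- out_dim
  self$flops <- function(d) {
    od <- out_dim(d)
    2 * k3 * cin * cout * prod(od[2:4])
  }
  # small-channel convs bypass im2col: a fused C++ kernel is faster and
  # avoids materializing the patch matrix
  direct <- (cin * cout <= 1536)
  self$forward <- function(x, training = FALSE) {
    d <- dim(x)
    od <- out_dim(d)
    if (training) self$cache <- list(x = x, d = d, od = od)
    W <- self$params$W; b <- self$params$b
    if (direct) {
      return(cm_conv3d_direct_fwd(x, d, W, b, cout, k[1], k[2], k[3],
                                  stride[1], stride[2], stride[3],
                                  pad[1], pad[2], pad[3]))
    }
    y <- array(0, od)
    nrow_col <- cin * k3
    chunk <- max(1L, as.integer(.cm_col_budget %/% (nrow_col * od[3] * od[4])))
    z0 <- 0L
    while (z0 < od[2]) {
      z1 <- min(z0 + chunk, od[2]) - 1L
      col <- cm_im2col3d(x, d, k[1], k[2], k[3],
                         stride[1], stride[2], stride[3],
                         pad[1], pad[2], pad[3], od[3], od[4], z0, z1)
      y[, (z0 + 1):(z1 + 1), , ] <- (W %*% col) + b
      z0 <- z1 + 1L
    }
    y
  }
  self$backward <- function(g) {
    cc <- self$cache
    d <- cc$d; od <- cc$od
    W <- self$params$W
    if (direct) {
      r <- cm_conv3d_direct_bwd(cc$x, d, W, g, cout, k[1], k[2], k[3],
                                stride[1], stride[2], stride[3],
                                pad[1], pad[2], pad[3])
      self$grads$W <- self$grads$W + r$gw
      self$grads$b <- self$grads$b + r$gb
      return(r$gx)
    }
    gW <- self$grads$W * 0
    gx <- array(0, d)
    dim(g) <- od
    nrow_col <- cin * k3
    chunk <- max(1L, as.integer(.cm_col_budget %/% (nrow_col * od[3] * od[4])))
    z0 <- 0L
    while (z0 < od[2]) {
      z1 <- min(z0 + chunk, od[2]) - 1L
      col <- cm_im2col3d(cc$x, d, k[1], k[2], k[3],
                         stride[1], stride[2], stride[3],
                         pad[1], pad[2], pad[3], od[3], od[4], z0, z1)
      gch <- g[, (z0 + 1):(z1 + 1), , , drop = FALSE]
      dim(gch) <- c(cout, length(gch) %/% cout)
      gW <- gW + tcrossprod(gch, col)
      cm_col2im3d(crossprod(W, gch), gx, d, k[1], k[2], k[3],
                  stride[1], stride[2], stride[3],
                  pad[1], pad[2], pad[3], od[3], od[4], z0, z1)
      z0 <- z1 + 1L
    }
    self$grads$W <- self$grads$W + gW
    dim(g) <- c(cout, length(g) %/% cout)
    self$grads$b <- self$grads$b + rowSums(g)
    gx
  }
  self
}

# pointwise (1x1x1) convolution: plain gemm over the voxel axis
#' @noRd
layer_pwconv <- function(cin, cout) {
  self <- new_layer("cm_pwconv")
  self$params <- list(W = init_kaiming(cout, cin, cin), b = numeric(cout))
  self$grads <- lapply(self$params, function(p) p * 0)
  self$meta <- list(cin = cin, cout = cout)
  self$out_dim <- function(d) c(cout, d[2], d[3], d[4])
  self$flops <- function(d) 2 * cin * cout * prod(d[2:4])
  self$forward <- function(x, training = FALSE) {
    d <- dim(x)
    dim(x) <- c(d[1], prod(d[2:4]))
    if (training) self$cache <- list(x = x, d = d)
    y <- self$params$W %*% x + self$params$b
    dim(y) <- c(cout, d[2], d[3], d[4])
    y
  }
  self$backward <- function(g) {
    cc <- self$cache
    dim(g) <- c(cout, prod(cc$d[2:4]))
    self$grads$W <- self$grads$W + tcrossprod(g, cc$x)
    self$grads$b <- self$grads$b + rowSums(g)
    gx <- crossprod(self$params$W, g)
    dim(gx) <- cc$d
    gx
  }
  self
}

#' @noRd
layer_dwconv3d <- function(C, k = c(3L, 3L, 3L), stride = c(1L, 1L, 1L), pad = c(1L, 1L, 1L)) {
  self <- new_layer("cm_dwconv3d")
  k <- as.integer(k); stride <- as.integer(stride); pad <- as.integer(pad)
  k3 <- prod(k)
  self$params <- list(W = init_kaiming(C, k3, k3), b = numeric(C))
  self$grads <- lapply(self$params, function(p) p * 0)
  self$meta <- list(cin = C, cout = C, k = k, stride = stride, pad = pad)
  out_dim <- function(d) {
    c(C,
      conv_out_len(d[2], k[1], stride[1], pad[1]),
      conv_out_len(d[3], k[2], stride[2], pad[2]),
      conv_out_len(d[4], k[3], stride[3], pad[3]))
  }
  self$out_dim <- out_dim
  self$flops <- function(d) 2 * k3 * C * prod(out_dim(d)[2:4])
  self$forward <- function(x, training = FALSE) {
    if (training) self$cache <- list(x = x, d = dim(x))
    cm_dwconv3d_fwd(x, dim(x), self$params$W, self$params$b,
                    k[1], k[2], k[3], stride[1], stride[2], stride[3],
                    pad[1], pad[2], pad[3])
  }
  self$backward <- function(g) {
    cc <- self$cache
    r <- cm_dwconv3d_bwd(cc$x, cc$d, self$params$W, g,
                         k[1], k[2], k[3], stride[1], stride[2], stride[3],
                         pad[1], pad[2], pad[3])
    self$grads$W <- self$grads$W + r$gw
    self$grads$b <- self$grads$b + r$gb
    r$gx
  }
  self
}

# transposed 3D convolution (depth stride 1, spatial stride 2 in the decoder);
# implemented as the adjoint gather/scatter of the matching forward conv
#' @noRd
layer_convT3d <- function(cin, cout, k = c(3L, 3L, 3L), stride = c(1L, 2L, 2L),
                          pad = c(1L, 1L, 1L), outpad = c(0L, 1L, 1L)) {
  self <- new_layer("cm_convT3d")
  k <- as.integer(k); stride <- as.integer(stride)
  pad <- as.integer(pad); outpad <- as.integer(outpad)
  k3 <- prod(k)
  # weight as (cout*k3, cin): col = W %*% x_mat, then scatter-add
  self$params <- list(W = init_kaiming(cout * k3, cin, cin * k3), b = numeric(cout))
  self$grads <- lapply(self$params, function(p) p * 0)
  self$meta <- list(cin = cin, cout = cout, k = k, stride = stride,
                    pad = pad, outpad = outpad)
  out_dim <- function(d) {
    c(cout,
      (d[2] - 1L) * stride[1] - 2L * pad[1] + k[1] + outpad[1],
      (d[3] - 1L) * stride[2] - 2L * pad[2] + k[2] + outpad[2],
      (d[4] - 1L) * stride[3] - 2L * pad[3] + k[3] + outpad[3])
  }
  self$out_dim <- out_dim
  self$flops <- function(d) 2 * k3 * cin * cout * prod(d[2:4])
  self$forward <- function(x, training = FALSE) {
    d <- dim(x)
    od <- out_dim(d)
    if (training) self$cache <- list(x = x, d = d, od = od)
    y <- array(rep(self$params$b, prod(od[2:4])), od)
    W <- self$params$W
    chunk <- max(1L, as.integer(.cm_col_budget %/% ((cout * k3) * d[3] * d[4])))
    z0 <- 0L
    while (z0 < d[2]) {
      z1 <- min(z0 + chunk, d[2]) - 1L
      xc <- x[, (z0 + 1):(z1 + 1), , , drop = FALSE]
      dim(xc) <- c(cin, length(xc) %/% cin)
      cm_col2im3d(W %*% xc, y, od, k[1], k[2], k[3],
                  stride[1], stride[2], stride[3],
                  pad[1], pad[2], pad[3], d[3], d[4], z0, z1)
      z0 <- z1 + 1L
    }
    y
  }
  self$backward <- function(g) {
    cc <- self$cache
    d <- cc$d; od <- cc$od
    dim(g) <- od
    W <- self$params$W
    gW <- self$grads$W * 0
    gx <- array(0, d)
    chunk <- max(1L, as.integer(.cm_col_budget %/% ((cout * k3) * d[3] * d[4])))
    z0 <- 0L
    while (z0 < d[2]) {
      z1 <- min(z0 + chunk, d[2]) - 1L
      gcol <- cm_im2col3d(g, od, k[1], k[2], k[3],
                          stride[1], stride[2], stride[3],
                          pad[1], pad[2], pad[3], d[3], d[4], z0, z1)
      xc <- cc$x[, (z0 + 1):(z1 + 1), , , drop = FALSE]
      dim(xc) <- c(cin, length(xc) %/% cin)
      gW <- gW + tcrossprod(gcol, xc)
      gxc <- crossprod(W, gcol)
      dim(gxc) <- c(cin, z1 - z0 + 1L, d[3], d[4])
      gx[, (z0 + 1):(z1 + 1), , ] <- gxc
      z0 <- z1 + 1L
    }
    self$grads$W <- self$grads$W + gW
    dim(g) <- c(cout, prod(od[2:4]))
    self$grads$b <- self$grads$b + rowSums(g)
    gx
  }
  self
}

# batch normalization with per-sample statistics over (D,H,W) during
# training and running moments at inference
#' @noRd
layer_bn <- function(C, eps = 1e-5, momentum = 0.1) {
  self <- new_layer("cm_bn")
  self$params <- list(gamma = rep(1, C), beta = numeric(C))
  self$grads <- list(gamma = numeric(C), beta = numeric(C))
  self$buffers <- list(rmean = numeric(C), rvar = rep(1, C))
  self$meta <- list(cin = C, cout = C)
  self$out_dim <- function(d) d
  self$flops <- function(d) 0
  self$forward <- function(x, training = FALSE) {
    d <- dim(x)
    M <- prod(d[2:4])
    if (training) {
      r <- cm_bn_fwd(x, d[1], M, self$params$gamma, self$params$beta, eps)
      self$buffers$rmean <- (1 - momentum) * self$buffers$rmean + momentum * r$mu
      self$buffers$rvar <- (1 - momentum) * self$buffers$rvar + momentum * r$var
      self$cache <- list(xhat = r$xhat, istd = r$istd, d = d)
      y <- r$y
    } else {
      dim(x) <- c(d[1], M)
      istd <- 1 / sqrt(self$buffers$rvar + eps)
      y <- self$params$gamma * istd * (x - self$buffers$rmean) + self$params$beta
    }
    dim(y) <- d
    y
  }
  self$backward <- function(g) {
    cc <- self$cache
    r <- cm_bn_bwd(g, cc$xhat, cc$d[1], prod(cc$d[2:4]),
                   self$params$gamma, cc$istd)
    self$grads$gamma <- self$grads$gamma + r$ggamma
    self$grads$beta <- self$grads$beta + r$gbeta
    gx <- r$gx
    dim(gx) <- cc$d
    gx
  }
  self
}

#' @noRd
layer_silu <- function() {
  self <- new_layer("cm_silu")
  self$out_dim <- function(d) d
  self$flops <- function(d) 0
  self$forward <- function(x, training = FALSE) {
    r <- cm_silu_fwd(x, training)
    y <- r$y
    if (!is.null(dim(x))) dim(y) <- dim(x)
    if (training) self$cache <- list(x = x, s = r$s)
    y
  }
  self$backward <- function(g) {
    cc <- self$cache
    gx <- cm_silu_bwd(g, cc$x, cc$s)
    if (!is.null(dim(g))) dim(gx) <- dim(g)
    gx
  }
  self
}

#' @noRd
layer_tanh <- function() {
  self <- new_layer("cm_tanh")
  self$out_dim <- function(d) d
  self$flops <- function(d) 0
  self$forward <- function(x, training = FALSE) {
    y <- tanh(x)
    if (training) self$cache <- list(y = y)
    y
  }
  self$backward <- function(g) g * (1 - self$cache$y^2)
  self
}

# linear map on a (C_in, M) matrix (token features in columns)
#' @noRd
layer_linear <- function(cin, cout) {
  self <- new_layer("cm_linear")
  self$params <- list(W = init_kaiming(cout, cin, cin), b = numeric(cout))
  self$grads <- lapply(self$params, function(p) p * 0)
  self$meta <- list(cin = cin, cout = cout)
  self$forward <- function(x, training = FALSE) {
    if (training) self$cache <- list(x = x)
    self$params$W %*% x + self$params$b
  }
  self$backward <- function(g) {
    self$grads$W <- self$grads$W + tcrossprod(g, self$cache$x)
    self$grads$b <- self$grads$b + rowSums(g)
    crossprod(self$params$W, g)
  }
  self
}

# layer normalization over the channel/feature axis of a (C, M) matrix
#' @noRd
layer_layernorm <- function(C, eps = 1e-5) {
  self <- new_layer("cm_layernorm")
  self$params <- list(gamma = rep(1, C), beta = numeric(C))
  self$grads <- list(gamma = numeric(C), beta = numeric(C))
  self$meta <- list(cin = C, cout = C)
  self$forward <- function(x, training = FALSE) {
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    v <- colMeans(xc * xc)
    istd <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2, istd, `*`)
    if (training) self$cache <- list(xhat = xhat, istd = istd)
    self$params$gamma * xhat + self$params$beta
  }
  self$backward <- function(g) {
    cc <- self$cache
    xhat <- cc$xhat
    self$grads$gamma <- self$grads$gamma + rowSums(g * xhat)
    self$grads$beta <- self$grads$beta + rowSums(g)
    gh <- self$params$gamma * g
    gx <- sweep(gh, 2, colMeans(gh)) - sweep(xhat, 2, colMeans(gh * xhat), `*`)
    sweep(gx, 2, cc$istd, `*`)
  }
  self
}

## ---- parameter walking -----------------------------------------------------

# returns list of list(env=, name=) references into layer environments
collect_param_refs <- function(layer) {
  out <- list()
  if (length(layer$params)) {
    for (nm in names(layer$params)) out[[length(out) + 1]] <- list(env = layer, name = nm)
  }
  for (sub in layer$layers) out <- c(out, collect_param_refs(sub))
  out
}

zero_grads <- function(layer) {
  if (length(layer$grads)) {
    for (nm in names(layer$grads)) layer$grads[[nm]] <- layer$grads[[nm]] * 0
  }
  for (sub in layer$layers) zero_grads(sub)
  invisible(NULL)
}

set_training_mode <- function(layer, clear_cache = TRUE) {
  if (clear_cache) layer$cache <- NULL
  for (sub in layer$layers) set_training_mode(sub, clear_cache)
  invisible(NULL)
}
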