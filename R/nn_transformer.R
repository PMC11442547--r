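# Transformer components operating on unfolded token tensors of shape
# (C, N, P): feature dimension C, N tokens, P independent positions.
# Attention runs across the N axis independently at each of the P positions
# (MobileViT layout), with multi-head softmax attention.

#' Unfold a volumetric feature tensor into tokens
#'
#' Partitions a `(C, D, H, W)` array either into non-overlapping
#' `p x p x p` volumes (`mode = "volume_p3"`, giving `N = D*H*W/p^3` tokens of
#' `P = p^3` positions) or slice-wise (`mode = "slice_wise"`, giving `N = D`
#' slice tokens of `P = H*W` positions). The inverse is [fold_volumes()];
#' both are exact permutations of the input entries.
#'
#' @param x numeric 4D array with dim `(C, D, H, W)`.
#' @param p integer edge length of the cubic patch (ignored for slice mode).
#' @param mode `"volume_p3"` or `"slice_wise"`.
#' @return numeric 3D array with dim `(C, N, P)`.
#' @export
unfold_volumes <- function(x, p = 2L, mode = c("volume_p3", "slice_wise")) {
  mode <- match.arg(mode)
  d <- dim(x)
  if (length(d) != 4) stop("expected a (C, D, H, W) array")
  if (mode == "slice_wise") {
    dim(x) <- c(d[1], d[2], d[3] * d[4])
    return(x)
  }
  p <- as.integer(p)
  if (any(d[2:4] %% p != 0))
    stop("D, H and W must all be divisible by p = ", p)
  dim(x) <- c(d[1], p, d[2] %/% p, p, d[3] %/% p, p, d[4] %/% p)
  xu <- aperm(x, c(1, 3, 5, 7, 2, 4, 6))
  dim(xu) <- c(d[1], prod(d[2:4]) %/% p^3, p^3)
  xu
}

#' Fold a token tensor back into a volumetric feature tensor
#'
#' Exact inverse of [unfold_volumes()] for the same `p`, `mode` and original
#' spatial dimensions.
#'
#' @param xu numeric 3D array with dim `(C, N, P)`.
#' @param dims integer vector `(D, H, W)` of the original volume.
#' @inheritParams unfold_volumes
#' @return numeric 4D array with dim `(C, D, H, W)`.
#' @export
fold_volumes <- function(xu, dims, p = 2L, mode = c("volume_p3", "slice_wise")) {
  mode <- match.arg(mode)
  d <- dim(xu)
  if (length(d) != 3) stop("expected a (C, N, P) array")
  C <- d[1]
  if (mode == "slice_wise") {
    dim(xu) <- c(C, dims[1], dims[2], dims[3])
    return(xu)
  }
  p <- as.integer(p)
  dim(xu) <- c(C, dims[1] %/% p, dims[2] %/% p, dims[3] %/% p, p, p, p)
  x <- aperm(xu, c(1, 5, 2, 6, 3, 7, 4))
  dim(x) <- c(C, dims[1], dims[2], dims[3])
  x
}

row_softmax <- function(S) {
  m <- apply(S, 1, max)
  E <- exp(S - m)
  E / rowSums(E)
}

#' @noRd
layer_mhsa <- function(dim_c, heads) {
  stopifnot(dim_c %% heads == 0)
  self <- new_layer("cm_mhsa")
  dh <- dim_c %/% heads
  mk <- function() init_kaiming(dim_c, dim_c, dim_c)
  self$params <- list(Wq = mk(), Wk = mk(), Wv = mk(), Wo = mk(),
                      bq = numeric(dim_c), bk = numeric(dim_c),
                      bv = numeric(dim_c), bo = numeric(dim_c))
  self$grads <- lapply(self$params, function(p) p * 0)
  self$meta <- list(cin = dim_c, cout = dim_c, heads = heads)
  self$flops <- function(d) {
    # d = (C, N, P); qkv + output projections plus the two attention gemms
    N <- d[2]; P <- d[3]
    8 * dim_c^2 * N * P + 4 * N^2 * dim_c * P
  }
  self$forward <- function(x, training = FALSE) {
    d <- dim(x)
    N <- d[2]; P <- d[3]
    xm <- x; dim(xm) <- c(dim_c, N * P)
    pr <- self$params
    Q <- pr$Wq %*% xm + pr$bq
    K <- pr$Wk %*% xm + pr$bk
    V <- pr$Wv %*% xm + pr$bv
    dim(Q) <- dim(K) <- dim(V) <- c(dh, heads, N, P)
    O <- array(0, c(dh, heads, N, P))
    attn <- if (training) vector("list", heads * P) else NULL
    sc <- 1 / sqrt(dh)
    for (p in seq_len(P)) {
      for (h in seq_len(heads)) {
        Qi <- Q[, h, , p, drop = TRUE]; dim(Qi) <- c(dh, N)
        Ki <- K[, h, , p, drop = TRUE]; dim(Ki) <- c(dh, N)
        Vi <- V[, h, , p, drop = TRUE]; dim(Vi) <- c(dh, N)
        A <- row_softmax(crossprod(Qi, Ki) * sc)
        O[, h, , p] <- tcrossprod(Vi, A)
        if (training) attn[[(p - 1) * heads + h]] <- A
      }
    }
    Om <- O; dim(Om) <- c(dim_c, N * P)
    y <- pr$Wo %*% Om + pr$bo
    dim(y) <- d
    if (training) self$cache <- list(xm = xm, Q = Q, K = K, V = V,
                                     attn = attn, Om = Om, d = d)
    y
  }
  self$backward <- function(g) {
    cc <- self$cache
    d <- cc$d; N <- d[2]; P <- d[3]
    pr <- self$params
    dim(g) <- c(dim_c, N * P)
    self$grads$Wo <- self$grads$Wo + tcrossprod(g, cc$Om)
    self$grads$bo <- self$grads$bo + rowSums(g)
    gO <- crossprod(pr$Wo, g)
    dim(gO) <- c(dh, heads, N, P)
    gQ <- array(0, c(dh, heads, N, P))
    gK <- gQ; gV <- gQ
    sc <- 1 / sqrt(dh)
    for (p in seq_len(P)) {
      for (h in seq_len(heads)) {
        A <- cc$attn[[(p - 1) * heads + h]]
        Qi <- cc$Q[, h, , p, drop = TRUE]; dim(Qi) <- c(dh, N)
        Ki <- cc$K[, h, , p, drop = TRUE]; dim(Ki) <- c(dh, N)
        Vi <- cc$V[, h, , p, drop = TRUE]; dim(Vi) <- c(dh, N)
        gOi <- gO[, h, , p, drop = TRUE]; dim(gOi) <- c(dh, N)
        gV[, h, , p] <- gOi %*% A
        gA <- crossprod(gOi, Vi)        # gA[i, j] = sum_d gO[d, i] V[d, j]
        gS <- A * (gA - rowSums(gA * A)) * sc
        gQ[, h, , p] <- tcrossprod(Ki, gS)
        gK[, h, , p] <- Qi %*% gS
      }
    }
    dim(gQ) <- dim(gK) <- dim(gV) <- c(dim_c, N * P)
    self$grads$Wq <- self$grads$Wq + tcrossprod(gQ, cc$xm)
    self$grads$Wk <- self$grads$Wk + tcrossprod(gK, cc$xm)
    self$grads$Wv <- self$grads$Wv + tcrossprod(gV, cc$xm)
    self$grads$bq <- self$grads$bq + rowSums(gQ)
    self$grads$bk <- self$grads$bk + rowSums(gK)
    self$grads$bv <- self$grads$bv + rowSums(gV)
    gx <- crossprod(pr$Wq, gQ) + crossprod(pr$Wk, gK) + crossprod(pr$Wv, gV)
    dim(gx) <- d
    gx
  }
  self
}

# pre-norm Transformer layer: LN -> MHSA -> +res, LN -> MLP(SiLU) -> +res
#' @noRd
layer_transformer <- function(dim_c, heads, mlp_ratio = 2) {
  self <- new_layer("cm_transformer")
  hid <- as.integer(round(mlp_ratio * dim_c))
  self$layers <- list(ln1 = layer_layernorm(dim_c),
                      attn = layer_mhsa(dim_c, heads),
                      ln2 = layer_layernorm(dim_c),
                      fc1 = layer_linear(dim_c, hid),
                      act = layer_silu(),
                      fc2 = layer_linear(hid, dim_c))
  self$meta <- list(cin = dim_c, cout = dim_c)
  self$flops <- function(d) {
    NP <- d[2] * d[3]
    self$layers$attn$flops(d) + 2 * dim_c * hid * NP * 2
  }
  self$forward <- function(x, training = FALSE) {
    d <- dim(x)
    L <- self$layers
    xm <- x; dim(xm) <- c(d[1], d[2] * d[3])
    h <- L$ln1$forward(xm, training)
    dim(h) <- d
    a <- L$attn$forward(h, training)
    y1 <- x + a
    y1m <- y1; dim(y1m) <- c(d[1], d[2] * d[3])
    h2 <- L$ln2$forward(y1m, training)
    f <- L$fc2$forward(L$act$forward(L$fc1$forward(h2, training), training), training)
    y <- y1m + f
    dim(y) <- d
    y
  }
  self$backward <- function(g) {
    d <- dim(g)
    L <- self$layers
    gm <- g; dim(gm) <- c(d[1], d[2] * d[3])
    gf <- L$fc1$backward(L$act$backward(L$fc2$backward(gm)))
    gy1 <- gm + L$ln2$backward(gf)
    dim(gy1) <- d
    ga <- L$attn$backward(gy1)
    dim(ga) <- c(d[1], d[2] * d[3])
    gx <- L$ln1$backward(ga)
    dim(gx) <- d
    gy1_arr <- gy1
    dim(gy1_arr) <- d
    gx + gy1_arr
  }
  self
}

# learned positional embedding over the token axis, shared across positions
#' @noRd
layer_posembed <- function(dim_c, n_tokens) {
  self <- new_layer("cm_posembed")
  self$params <- list(E = matrix(stats::rnorm(dim_c * n_tokens, sd = 0.02),
                                 dim_c, n_tokens))
  self$grads <- list(E = self$params$E * 0)
  self$meta <- list(cin = dim_c, cout = dim_c)
  self$flops <- function(d) 0
  self$forward <- function(x, training = FALSE) {
    if (dim(x)[2] != ncol(self$params$E))
      stop("position embedding built for ", ncol(self$params$E),
           " tokens, got ", dim(x)[2])
    x + as.vector(self$params$E)
  }
  self$backward <- function(g) {
    d <- dim(g)
    gm <- g; dim(gm) <- c(d[1] * d[2], d[3])
    gE <- rowSums(gm)
    dim(gE) <- c(d[1], d[2])
    self$grads$E <- self$grads$E + gE
    g
  }
  self
}
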