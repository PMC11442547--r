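# Composite blocks of the encoder-decoder: inverted-residual (MV2) blocks,
# hybrid conv/Transformer (MViT) blocks, the slice-wise ViT block, and the
# deconvolution + residual decoder stages.

# plain sequential container
#' @noRd
block_seq <- function(...) {
  self <- new_layer("cm_seq")
  self$layers <- list(...)
  self$out_dim <- function(d) {
    for (l in self$layers) d <- l$out_dim(d)
    d
  }
  self$flops <- function(d) {
    f <- 0
    for (l in self$layers) {
      f <- f + l$flops(d)
      d <- l$out_dim(d)
    }
    f
  }
  self$forward <- function(x, training = FALSE) {
    for (l in self$layers) x <- l$forward(x, training)
    x
  }
  self$backward <- function(g) {
    for (l in rev(self$layers)) g <- l$backward(g)
    g
  }
  self
}

# MobileNetV2-style 3D inverted residual: pointwise expansion, depthwise
# 3x3x3 (spatial stride s, depth stride 1), pointwise projection; identity
# shortcut when stride 1 and channel counts match.
#' @noRd
block_mv2 <- function(cin, cout, stride = 1L, expansion = 4L,
                      dw_pad = c(1L, 1L, 1L)) {
  self <- new_layer("cm_mv2")
  e <- cin * expansion
  self$layers <- list(
    pw1 = layer_pwconv(cin, e), bn1 = layer_bn(e), a1 = layer_silu(),
    dw = layer_dwconv3d(e, k = c(3L, 3L, 3L), stride = c(1L, stride, stride),
                        pad = dw_pad),
    bn2 = layer_bn(e), a2 = layer_silu(),
    pw2 = layer_pwconv(e, cout), bn3 = layer_bn(cout))
  self$meta <- list(cin = cin, cout = cout, stride = stride)
  self$residual <- (stride == 1L && cin == cout)
  # start residual branches at zero so the block is the identity at
  # initialization (faster early optimization of deep stacks)
  if (self$residual) self$layers$bn3$params$gamma[] <- 0
  chain <- function(d, acc = FALSE) {
    f <- 0
    for (l in self$layers) {
      f <- f + l$flops(d)
      d <- l$out_dim(d)
    }
    if (acc) f else d
  }
  self$out_dim <- function(d) chain(d)
  self$flops <- function(d) chain(d, acc = TRUE)
  self$forward <- function(x, training = FALSE) {
    y <- x
    for (l in self$layers) y <- l$forward(y, training)
    if (self$residual) y + x else y
  }
  self$backward <- function(g) {
    gx <- g
    for (l in rev(self$layers)) gx <- l$backward(gx)
    if (self$residual) gx + g else gx
  }
  self
}

# MobileViT-style 3D block. Local path: depthwise conv + pointwise to the
# attention width d; global path: unfold into p^3 volumes, L Transformer
# layers with a residual around the whole stack, fold back; then pointwise
# back to C, channel-concat with the block input, pointwise fusion.
#' @noRd
block_mvit <- function(C, d_attn, L, heads = 4L, p = 2L, mlp_ratio = 2) {
  self <- new_layer("cm_mvit")
  tls <- lapply(seq_len(L), function(i) layer_transformer(d_attn, heads, mlp_ratio))
  names(tls) <- paste0("tf", seq_len(L))
  self$layers <- c(list(
    dw = layer_dwconv3d(C), bn1 = layer_bn(C), a1 = layer_silu(),
    pw_in = layer_pwconv(C, d_attn)),
    tls,
    list(pw_out = layer_pwconv(d_attn, C), bn2 = layer_bn(C), a2 = layer_silu(),
         fuse = layer_pwconv(2L * C, C), bn3 = layer_bn(C), a3 = layer_silu()))
  self$meta <- list(cin = C, cout = C, d_attn = d_attn, L = L, p = p)
  self$out_dim <- function(d) d
  self$flops <- function(d) {
    L_ <- self$layers
    vox <- prod(d[2:4])
    td <- c(d_attn, vox %/% p^3, p^3)
    f <- L_$dw$flops(d) + L_$pw_in$flops(d)
    for (i in seq_len(L)) f <- f + L_[[paste0("tf", i)]]$flops(td)
    f + L_$pw_out$flops(d) + L_$fuse$flops(c(2L * C, d[2:4]))
  }
  self$forward <- function(x, training = FALSE) {
    d <- dim(x)
    if (any(d[2:4] %% p != 0))
      stop("MViT block needs D, H, W divisible by p = ", p,
           " (got ", paste(d[2:4], collapse = "x"), ")")
    L_ <- self$layers
    t_ <- L_$a1$forward(L_$bn1$forward(L_$dw$forward(x, training), training), training)
    t_ <- L_$pw_in$forward(t_, training)
    u <- unfold_volumes(t_, p)
    u0 <- u
    for (i in seq_len(L)) u <- L_[[paste0("tf", i)]]$forward(u, training)
    u <- u + u0                     # residual around the Transformer stack
    v <- fold_volumes(u, d[2:4], p)
    v <- L_$a2$forward(L_$bn2$forward(L_$pw_out$forward(v, training), training), training)
    cat_ <- array(0, c(2L * C, d[2:4]))
    cat_[seq_len(C), , , ] <- x
    cat_[C + seq_len(C), , , ] <- v
    if (training) self$cache <- list(d = d)
    L_$a3$forward(L_$bn3$forward(L_$fuse$forward(cat_, training), training), training)
  }
  self$backward <- function(g) {
    d <- self$cache$d
    L_ <- self$layers
    gcat <- L_$fuse$backward(L_$bn3$backward(L_$a3$backward(g)))
    gx_direct <- gcat[seq_len(C), , , , drop = FALSE]
    dim(gx_direct) <- d
    gv <- gcat[C + seq_len(C), , , , drop = FALSE]
    dim(gv) <- d
    gv <- L_$pw_out$backward(L_$bn2$backward(L_$a2$backward(gv)))
    gu <- unfold_volumes(gv, p)     # adjoint of fold is unfold
    gu0 <- gu
    for (i in rev(seq_len(L))) gu <- L_[[paste0("tf", i)]]$backward(gu)
    gu <- gu + gu0
    gt <- fold_volumes(gu, d[2:4], p)
    gt <- L_$pw_in$backward(gt)
    gx <- L_$dw$backward(L_$bn1$backward(L_$a1$backward(gt)))
    gx + gx_direct
  }
  self
}

# slice-wise ViT block: one token per depth slice, learned positional
# embedding, L_V Transformer layers.
#' @noRd
block_vit <- function(C, L_V, depth_tokens, heads = 4L, mlp_ratio = 2) {
  self <- new_layer("cm_vit")
  tls <- lapply(seq_len(L_V), function(i) layer_transformer(C, heads, mlp_ratio))
  names(tls) <- paste0("tf", seq_len(L_V))
  self$layers <- c(list(pos = layer_posembed(C, depth_tokens)), tls)
  self$meta <- list(cin = C, cout = C, L_V = L_V)
  self$out_dim <- function(d) d
  self$flops <- function(d) {
    td <- c(C, d[2], d[3] * d[4])
    f <- 0
    for (i in seq_len(L_V)) f <- f + self$layers[[paste0("tf", i)]]$flops(td)
    f
  }
  self$forward <- function(x, training = FALSE) {
    d <- dim(x)
    if (training) self$cache <- list(d = d)
    u <- unfold_volumes(x, mode = "slice_wise")
    u <- self$layers$pos$forward(u, training)
    for (i in seq_len(L_V)) u <- self$layers[[paste0("tf", i)]]$forward(u, training)
    fold_volumes(u, d[2:4], mode = "slice_wise")
  }
  self$backward <- function(g) {
    d <- self$cache$d
    gu <- unfold_volumes(g, mode = "slice_wise")
    for (i in rev(seq_len(self$meta$L_V))) gu <- self$layers[[paste0("tf", i)]]$backward(gu)
    gu <- self$layers$pos$backward(gu)
    fold_volumes(gu, d[2:4], mode = "slice_wise")
  }
  self
}

# residual refinement block of the decoder: 3x1x1 -> 3x3x3 -> 3x1x1 conv
# sequence with a (projected) shortcut from input to output
#' @noRd
block_residual <- function(cin, cout) {
  self <- new_layer("cm_resblock")
  self$layers <- list(
    c1 = layer_conv3d(cin, cout, k = c(3L, 1L, 1L), pad = c(1L, 0L, 0L)),
    b1 = layer_bn(cout), a1 = layer_silu(),
    c2 = layer_conv3d(cout, cout, k = c(3L, 3L, 3L), pad = c(1L, 1L, 1L)),
    b2 = layer_bn(cout), a2 = layer_silu(),
    c3 = layer_conv3d(cout, cout, k = c(3L, 1L, 1L), pad = c(1L, 0L, 0L)),
    b3 = layer_bn(cout),
    aout = layer_silu())
  # main path starts at zero: the block begins as SiLU(shortcut)
  self$layers$b3$params$gamma[] <- 0
  if (cin != cout) self$layers$proj <- layer_pwconv(cin, cout)
  self$meta <- list(cin = cin, cout = cout)
  self$out_dim <- function(d) c(cout, d[2:4])
  self$flops <- function(d) {
    L_ <- self$layers
    f <- L_$c1$flops(d) + L_$c2$flops(c(cout, d[2:4])) + L_$c3$flops(c(cout, d[2:4]))
    if (!is.null(L_$proj)) f <- f + L_$proj$flops(d)
    f
  }
  self$forward <- function(x, training = FALSE) {
    L_ <- self$layers
    h <- L_$a1$forward(L_$b1$forward(L_$c1$forward(x, training), training), training)
    h <- L_$a2$forward(L_$b2$forward(L_$c2$forward(h, training), training), training)
    h <- L_$b3$forward(L_$c3$forward(h, training), training)
    s <- if (is.null(L_$proj)) x else L_$proj$forward(x, training)
    L_$aout$forward(h + s, training)
  }
  self$backward <- function(g) {
    L_ <- self$layers
    gy <- L_$aout$backward(g)
    gs <- if (is.null(L_$proj)) gy else L_$proj$backward(gy)
    gh <- L_$c3$backward(L_$b3$backward(gy))
    gh <- L_$c2$backward(L_$b2$backward(L_$a2$backward(gh)))
    gh <- L_$c1$backward(L_$b1$backward(L_$a1$backward(gh)))
    gh + gs
  }
  self
}

# one decoder stage: transposed conv upsampling, optional skip concat,
# residual refinement
#' @noRd
block_decoder_stage <- function(cin, cskip, cout, pad, outpad) {
  self <- new_layer("cm_decstage")
  self$layers <- list(
    up = layer_convT3d(cin, cout, pad = c(1L, pad, pad),
                       outpad = c(0L, outpad, outpad)),
    bn = layer_bn(cout), act = layer_silu(),
    res = block_residual(cout + cskip, cout))
  self$meta <- list(cin = cin, cskip = cskip, cout = cout)
  self$out_dim <- function(d) {
    du <- self$layers$up$out_dim(d)
    c(cout, du[2:4])
  }
  self$flops <- function(d) {
    du <- self$layers$up$out_dim(d)
    self$layers$up$flops(d) + self$layers$res$flops(c(cout + cskip, du[2:4]))
  }
  self$forward <- function(x, skip = NULL, training = FALSE) {
    L_ <- self$layers
    t_ <- L_$act$forward(L_$bn$forward(L_$up$forward(x, training), training), training)
    if (cskip > 0) {
      d <- dim(t_)
      if (!all(dim(skip)[2:4] == d[2:4]))
        stop("skip connection shape mismatch: upsampled ",
             paste(d[2:4], collapse = "x"), " vs skip ",
             paste(dim(skip)[2:4], collapse = "x"))
      cat_ <- array(0, c(cout + cskip, d[2:4]))
      cat_[seq_len(cout), , , ] <- t_
      cat_[cout + seq_len(cskip), , , ] <- skip
      t_ <- cat_
    }
    if (training) self$cache <- list(d = dim(t_))
    L_$res$forward(t_, training)
  }
  self$backward <- function(g) {
    L_ <- self$layers
    gt <- L_$res$backward(g)
    gskip <- NULL
    if (cskip > 0) {
      d <- dim(gt)
      gskip <- gt[cout + seq_len(cskip), , , , drop = FALSE]
      dim(gskip) <- c(cskip, d[2:4])
      gt <- gt[seq_len(cout), , , , drop = FALSE]
      dim(gt) <- c(cout, d[2:4])
    }
    gx <- L_$up$backward(L_$bn$backward(L_$act$backward(gt)))
    list(gx = gx, gskip = gskip)
  }
  self
}
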