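# Network configuration, assembly, forward/backward orchestration and
# static profiling (parameter and FLOP counts).

#' Model configuration for the collateral-map regression network
#'
#' Collects every architectural hyperparameter of the encoder-decoder:
#' a conv stem (1x3x3, spatial stride 2), two groups of 3D inverted-residual
#' (MV2) blocks, two hybrid conv/Transformer (MViT) blocks with `L_M = c(2, 4)`
#' Transformer layers, a slice-wise ViT bottleneck block, and a five-stage
#' deconvolution + residual decoder with skip connections, ending in a
#' five-channel 1x1x1 head with Tanh.
#'
#' The default widths are the package's frozen *reference configuration*,
#' calibrated so that [count_parameters()] and [count_flops()] at the native
#' input size (40 x 20 x 224 x 224) reproduce the published complexity budget
#' of the architecture (26.736 M trainable parameters, 7.140e11 FLOPs under
#' the 2-FLOPs-per-multiply-accumulate convention). All striding is
#' spatial-only, so the slice axis keeps its full depth (canonically 20)
#' through the whole network; the encoder resolution ladder for 224 input is
#' 112, 56, 28, 14, 6 with a 512-channel 6x6 bottleneck.
#'
#' @param in_channels number of input channels (time points), canonical 40.
#' @param out_phases number of regressed phase maps, fixed 5.
#' @param depth slice count (tokens of the ViT block), canonical 20.
#' @param input_size in-plane input size the padding schedule targets.
#' @param stem_width,g2_widths,g3_widths channel widths after the stem and
#'   after each of the four downsampling stages (resolutions 112; 56, 28;
#'   14, 6 for 224 input).
#' @param vit_width channel width inside the slice-wise ViT block.
#' @param bottleneck_channels encoder output width, canonical 512.
#' @param mvit_dims attention widths of the two MViT blocks.
#' @param decoder_widths channel widths of the five decoder stages
#'   (low to high resolution).
#' @param L_M Transformer depths of the two MViT blocks.
#' @param L_V Transformer depth of the ViT block.
#' @param heads attention heads (all attention layers).
#' @param patch_p cubic patch edge for MViT unfolding.
#' @param mv2_expansion expansion factor of the MV2 blocks.
#' @param mlp_ratio hidden/width ratio of the Transformer MLPs.
#' @return an object of class `cm_config` (a validated list).
#' @export
model_config <- function(in_channels = 40L, out_phases = 5L, depth = 20L,
                         input_size = 224L,
                         stem_width = 40L,
                         g2_widths = c(64L, 96L),
                         g3_widths = c(128L, 295L),
                         vit_width = 256L,
                         bottleneck_channels = 512L,
                         mvit_dims = c(192L, 256L),
                         decoder_widths = c(452L, 256L, 128L, 79L, 42L),
                         L_M = c(2L, 4L), L_V = 4L, heads = 4L,
                         patch_p = 2L, mv2_expansion = 4L, mlp_ratio = 2) {
  cfg <- list(in_channels = as.integer(in_channels),
              out_phases = as.integer(out_phases),
              depth = as.integer(depth),
              input_size = as.integer(input_size),
              stem_width = as.integer(stem_width),
              g2_widths = as.integer(g2_widths),
              g3_widths = as.integer(g3_widths),
              vit_width = as.integer(vit_width),
              bottleneck_channels = as.integer(bottleneck_channels),
              mvit_dims = as.integer(mvit_dims),
              decoder_widths = as.integer(decoder_widths),
              L_M = as.integer(L_M), L_V = as.integer(L_V),
              heads = as.integer(heads), patch_p = as.integer(patch_p),
              mv2_expansion = as.integer(mv2_expansion),
              mlp_ratio = mlp_ratio)
  stopifnot(length(cfg$g2_widths) == 2, length(cfg$g3_widths) == 2,
            length(cfg$mvit_dims) == 2, length(cfg$decoder_widths) == 5,
            length(cfg$L_M) == 2)
  if (any(c(cfg$mvit_dims, cfg$vit_width) %% cfg$heads != 0))
    stop("attention widths must be divisible by the number of heads")
  if (cfg$depth %% cfg$patch_p != 0)
    stop("slice count must be divisible by patch_p for MViT unfolding")
  sizes <- encoder_sizes(cfg$input_size)
  if (any(sizes[3:4] %% cfg$patch_p != 0))  # MViT blocks sit at these levels
    stop("encoder resolutions ", paste(sizes, collapse = ", "),
         " violate patch divisibility for p = ", cfg$patch_p)
  class(cfg) <- "cm_config"
  cfg
}

# spatial resolution ladder of the encoder: stem and three same-padded
# stride-2 stages, one final valid (unpadded) stride-2 stage
encoder_sizes <- function(n) {
  s1 <- (n - 1L) %/% 2L + 1L          # stem, k 3, s 2, p 1
  s2 <- (s1 - 1L) %/% 2L + 1L
  s3 <- (s2 - 1L) %/% 2L + 1L
  s4 <- (s3 - 1L) %/% 2L + 1L
  s5 <- (s4 - 3L) %/% 2L + 1L         # valid padding: 14 -> 6 for 224 input
  c(s1, s2, s3, s4, s5)
}

# choose transposed-conv (pad, output_pad) to map `n_in` to exactly `n_out`
# with kernel 3, stride 2
deconv_padding <- function(n_in, n_out) {
  for (p in 0:2) for (op in 0:1) {
    if ((n_in - 1L) * 2L + 3L + op - 2L * p == n_out) return(c(p, op))
  }
  stop("no (pad, output_pad) maps ", n_in, " to ", n_out)
}

#' Build the collateral-map regression network
#'
#' Assembles the encoder-decoder from a [model_config()]: encoder group 1 is
#' a 1x3x3 conv stem (spatial stride 2); group 2 holds two sets of two
#' stride-1 MV2 blocks plus one stride-2 MV2 block; group 3 holds two sets of
#' an MViT block plus a stride-2 MV2 block (the last one unpadded so 14 maps
#' to 6); group 4 is pointwise conv, slice-wise ViT, pointwise conv to the
#' bottleneck width. The decoder applies five sets of a 3x3x3 transposed
#' convolution (spatial stride 2) and a residual layer, with skip
#' concatenations from the four encoder resolutions, and a 1x1x1 five-channel
#' Tanh head.
#'
#' @param cfg a [model_config()].
#' @return an object of class `cm_model`.
#' @export
build_model <- function(cfg = model_config()) {
  stopifnot(inherits(cfg, "cm_config"))
  sizes <- encoder_sizes(cfg$input_size)
  cs <- cfg$stem_width
  w56 <- cfg$g2_widths[1]; w28 <- cfg$g2_widths[2]
  w14 <- cfg$g3_widths[1]; w6 <- cfg$g3_widths[2]
  dd <- cfg$decoder_widths
  ex <- cfg$mv2_expansion

  m <- new_layer("cm_model")
  m$cfg <- cfg
  m$layers <- list(
    stem = block_seq(layer_conv3d(cfg$in_channels, cs, k = c(1L, 3L, 3L),
                                  stride = c(1L, 2L, 2L), pad = c(0L, 1L, 1L)),
                     layer_bn(cs), layer_silu()),
    g2a1 = block_mv2(cs, cs, 1L, ex),
    g2a2 = block_mv2(cs, cs, 1L, ex),
    g2a3 = block_mv2(cs, w56, 2L, ex),
    g2b1 = block_mv2(w56, w56, 1L, ex),
    g2b2 = block_mv2(w56, w56, 1L, ex),
    g2b3 = block_mv2(w56, w28, 2L, ex),
    mvit1 = block_mvit(w28, cfg$mvit_dims[1], cfg$L_M[1], cfg$heads,
                       cfg$patch_p, cfg$mlp_ratio),
    down3 = block_mv2(w28, w14, 2L, ex),
    mvit2 = block_mvit(w14, cfg$mvit_dims[2], cfg$L_M[2], cfg$heads,
                       cfg$patch_p, cfg$mlp_ratio),
    down4 = block_mv2(w14, w6, 2L, ex, dw_pad = c(1L, 0L, 0L)),
    g4pre = block_seq(layer_pwconv(w6, cfg$vit_width),
                      layer_bn(cfg$vit_width), layer_silu()),
    vit = block_vit(cfg$vit_width, cfg$L_V, cfg$depth, cfg$heads, cfg$mlp_ratio),
    g4post = block_seq(layer_pwconv(cfg$vit_width, cfg$bottleneck_channels),
                       layer_bn(cfg$bottleneck_channels), layer_silu()),
    dec1 = NULL, dec2 = NULL, dec3 = NULL, dec4 = NULL, dec5 = NULL,
    head = block_seq(layer_pwconv(dd[5], cfg$out_phases), layer_tanh()))
  # start the regression head at the lower edge of the target interval
  # (background / no-bolus prior) so optimization refines deviations
  m$layers$head$layers[[1]]$params$b[] <- atanh(-0.9)
  # physiology-informed stem initialization: the first channels start as
  # temporal band-contrast filters (mean over a band of frames minus the
  # pre-contrast frame, center tap only), seeding bolus-passage features
  # that the phase maps are built from; remaining channels stay random
  stem_conv <- m$layers$stem$layers[[1]]
  Tn <- cfg$in_channels
  n_bands <- min(cs, 5L)
  bounds <- round(seq(1, Tn, length.out = n_bands + 1L))
  center_cols <- 4L * Tn + seq_len(Tn)   # tap (0,1,1) of the 1x3x3 kernel
  for (b in seq_len(n_bands)) {
    band <- seq(bounds[b] + 1L, bounds[b + 1L])
    w <- numeric(Tn)
    w[band] <- 1 / length(band)
    w[1L] <- w[1L] - 1
    stem_conv$params$W[b, center_cols] <- w
  }

  dec_in <- c(cfg$bottleneck_channels, dd[1:4])
  dec_skip <- c(w14, w28, w56, cs, 0L)
  dec_src <- c(sizes[5], sizes[4], sizes[3], sizes[2], sizes[1])
  dec_tgt <- c(sizes[4], sizes[3], sizes[2], sizes[1], cfg$input_size)
  for (i in 1:5) {
    pp <- deconv_padding(dec_src[i], dec_tgt[i])
    m$layers[[paste0("dec", i)]] <-
      block_decoder_stage(dec_in[i], dec_skip[i], dd[i], pp[1], pp[2])
  }

  m$forward <- function(x, training = FALSE) {
    L_ <- m$layers
    s0 <- L_$stem$forward(x, training)
    a <- L_$g2a3$forward(L_$g2a2$forward(L_$g2a1$forward(s0, training), training), training)
    b <- L_$g2b3$forward(L_$g2b2$forward(L_$g2b1$forward(a, training), training), training)
    c_ <- L_$mvit1$forward(b, training)
    d_ <- L_$down3$forward(c_, training)
    e_ <- L_$mvit2$forward(d_, training)
    f_ <- L_$down4$forward(e_, training)
    bot <- L_$g4post$forward(L_$vit$forward(L_$g4pre$forward(f_, training), training), training)
    m$bottleneck_dim <- dim(bot)
    u <- L_$dec1$forward(bot, skip = d_, training = training)
    u <- L_$dec2$forward(u, skip = b, training = training)
    u <- L_$dec3$forward(u, skip = a, training = training)
    u <- L_$dec4$forward(u, skip = s0, training = training)
    u <- L_$dec5$forward(u, training = training)
    L_$head$forward(u, training)
  }

  m$backward <- function(g) {
    L_ <- m$layers
    g <- L_$head$backward(g)
    r5 <- L_$dec5$backward(g)
    r4 <- L_$dec4$backward(r5$gx)
    r3 <- L_$dec3$backward(r4$gx)
    r2 <- L_$dec2$backward(r3$gx)
    r1 <- L_$dec1$backward(r2$gx)
    gbot <- r1$gx
    gf <- L_$g4pre$backward(L_$vit$backward(L_$g4post$backward(gbot)))
    ge <- L_$down4$backward(gf)
    gd <- L_$mvit2$backward(ge) + r1$gskip
    gc <- L_$down3$backward(gd)
    gb <- L_$mvit1$backward(gc) + r2$gskip
    ga <- L_$g2b1$backward(L_$g2b2$backward(L_$g2b3$backward(gb))) + r3$gskip
    gs0 <- L_$g2a1$backward(L_$g2a2$backward(L_$g2a3$backward(ga))) + r4$gskip
    L_$stem$backward(gs0)
  }

  m$trace <- function(in_dim) {
    L_ <- m$layers
    f <- 0
    step <- function(layer, d) {
      f <<- f + layer$flops(d)
      layer$out_dim(d)
    }
    d <- in_dim
    d <- step(L_$stem, d); s0d <- d
    for (nm in c("g2a1", "g2a2", "g2a3")) d <- step(L_[[nm]], d)
    ad <- d
    for (nm in c("g2b1", "g2b2", "g2b3")) d <- step(L_[[nm]], d)
    bd <- d
    d <- step(L_$mvit1, d)
    d <- step(L_$down3, d); dd_ <- d
    d <- step(L_$mvit2, d)
    d <- step(L_$down4, d)
    d <- step(L_$g4pre, d)
    d <- step(L_$vit, d)
    d <- step(L_$g4post, d)
    bottleneck <- d
    for (nm in paste0("dec", 1:5)) d <- step(L_[[nm]], d)
    d <- step(L_$head, d)
    list(bottleneck_dim = bottleneck, out_dim = d, flops = f,
         skip_dims = list(s0d, ad, bd, dd_))
  }
  m
}

#' Count trainable parameters of a built model
#'
#' @param model a `cm_model` from [build_model()].
#' @return integer-valued total number of trainable scalars.
#' @export
count_parameters <- function(model) {
  refs <- collect_param_refs(model)
  sum(vapply(refs, function(r) length(r$env$params[[r$name]]), numeric(1)))
}

#' Count forward-pass FLOPs of a built model at a given input shape
#'
#' Static layer-by-layer count under the 2-FLOPs-per-multiply-accumulate
#' convention: convolution, linear and attention matrix products are counted;
#' biases, normalizations and activations are excluded.
#'
#' @param model a `cm_model`.
#' @param input_shape integer vector `(T, D, H, W)`; defaults to the shape
#'   the model was configured for.
#' @return total floating-point operations (a double).
#' @export
count_flops <- function(model, input_shape = NULL) {
  cfg <- model$cfg
  if (is.null(input_shape))
    input_shape <- c(cfg$in_channels, cfg$depth, cfg$input_size, cfg$input_size)
  model$trace(as.integer(input_shape))$flops
}

#' Static shape trace of the network
#'
#' Runs shape inference (no arithmetic on voxel data) through every stage and
#' returns the bottleneck and output dimensions together with the FLOP total.
#'
#' @inheritParams count_flops
#' @return list with `bottleneck_dim`, `out_dim`, `flops`.
#' @export
model_shape_trace <- function(model, input_shape = NULL) {
  cfg <- model$cfg
  if (is.null(input_shape))
    input_shape <- c(cfg$in_channels, cfg$depth, cfg$input_size, cfg$input_size)
  model$trace(as.integer(input_shape))
}

## ---- checkpoint (de)serialization -----------------------------------------

walk_layers <- function(layer, path = "") {
  out <- list()
  if (length(layer$params) || length(layer$buffers))
    out[[length(out) + 1]] <- list(env = layer, path = path)
  nms <- names(layer$layers)
  for (i in seq_along(layer$layers)) {
    nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
    out <- c(out, walk_layers(layer$layers[[i]], paste0(path, "/", nm)))
  }
  out
}

#' Extract all weights and running statistics of a model
#' @param model a `cm_model`.
#' @return named list keyed by layer path.
#' @export
state_dict <- function(model) {
  nodes <- walk_layers(model)
  sd <- lapply(nodes, function(n) list(params = n$env$params, buffers = n$env$buffers))
  names(sd) <- vapply(nodes, function(n) n$path, character(1))
  sd
}

#' Load weights produced by [state_dict()] into a structurally identical model
#' @param model a `cm_model`.
#' @param sd a state dict.
#' @export
load_state_dict <- function(model, sd) {
  nodes <- walk_layers(model)
  paths <- vapply(nodes, function(n) n$path, character(1))
  if (!identical(sort(paths), sort(names(sd))))
    stop("state dict does not match model structure")
  for (n in nodes) {
    entry <- sd[[n$path]]
    for (nm in names(entry$params)) {
      stopifnot(length(entry$params[[nm]]) == length(n$env$params[[nm]]))
      n$env$params[[nm]] <- entry$params[[nm]]
    }
    for (nm in names(entry$buffers)) n$env$buffers[[nm]] <- entry$buffers[[nm]]
  }
  invisible(model)
}
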