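# Shared fixtures, all generated in code.

# small random series with reproducible content
rand_series <- function(Tn = 6, D = 4, H = 10, W = 10, seed = 1, dt = 1.6) {
  set.seed(seed)
  perfusion_series(array(runif(Tn * D * H * W, 50, 150), c(Tn, D, H, W)),
                   dt_seconds = dt, subject_id = "fix")
}

rand_maps <- function(D = 4, H = 10, W = 10, seed = 2,
                      value_range = "raw") {
  set.seed(seed)
  collateral_maps(array(runif(5 * D * H * W), c(5, D, H, W)),
                  value_range = value_range)
}

# tiny model configuration that still satisfies the resolution ladder
tiny_config <- function(depth = 2L) {
  model_config(input_size = 64L, depth = depth,
               stem_width = 4L, g2_widths = c(6L, 8L),
               g3_widths = c(8L, 12L), vit_width = 12L,
               bottleneck_channels = 16L, mvit_dims = c(8L, 8L),
               decoder_widths = c(12L, 8L, 8L, 6L, 4L),
               L_M = c(1L, 1L), L_V = 1L)
}

# numerical gradient of sum(layer(x) * R) wrt one parameter entry
num_grad_param <- function(layer, fwd_loss, nm, idx, eps = 1e-5) {
  p0 <- layer$params[[nm]][idx]
  layer$params[[nm]][idx] <- p0 + eps
  lp <- fwd_loss()
  layer$params[[nm]][idx] <- p0 - eps
  lm <- fwd_loss()
  layer$params[[nm]][idx] <- p0
  (lp - lm) / (2 * eps)
}

# gradient check of a single layer against central differences
expect_gradcheck <- function(make_layer, xdim, n_param = 3, n_input = 3,
                             tol = 1e-5) {
  ns <- asNamespace("collmapnet")
  layer <- make_layer()
  x <- array(rnorm(prod(xdim)), xdim)
  R <- NULL
  fwd_loss <- function() {
    y <- layer$forward(x, training = TRUE)
    if (is.null(R)) R <<- array(rnorm(length(y)), dim(y))
    sum(y * R)
  }
  fwd_loss()
  ns$zero_grads(layer)
  invisible(layer$forward(x, training = TRUE))
  gx <- layer$backward(R)
  refs <- ns$collect_param_refs(layer)
  for (r in refs) {
    p <- r$env$params[[r$name]]
    for (idx in sample(length(p), min(n_param, length(p)))) {
      ng <- num_grad_param(r$env, fwd_loss, r$name, idx)
      ag <- r$env$grads[[r$name]][idx]
      expect_lt(abs(ng - ag) / max(1, abs(ng), abs(ag)), tol)
    }
  }
  for (idx in sample(length(x), n_input)) {
    x0 <- x[idx]
    eps <- 1e-5
    x[idx] <- x0 + eps
    lp <- sum(layer$forward(x, training = TRUE) * R)
    x[idx] <- x0 - eps
    lm <- sum(layer$forward(x, training = TRUE) * R)
    x[idx] <- x0
    ng <- (lp - lm) / (2 * eps)
    expect_lt(abs(ng - gx[idx]) / max(1, abs(ng), abs(gx[idx])), tol)
  }
  invisible(TRUE)
}
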