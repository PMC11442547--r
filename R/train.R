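# Training loop (Adam, reduce-on-plateau schedule, horizontal-flip
# augmentation, min-validation-loss model selection), prediction, and
# cohort evaluation with per-group / per-center aggregation.

#' Training configuration
#'
#' Defaults follow the published protocol: Adam with initial learning rate
#' 0.001, reduced by a factor of 0.75 after 3 epochs without validation
#' improvement, mini-batches of 4, horizontal flipping as the only
#' augmentation, and selection of the minimum-validation-loss model.
#'
#' @param lr0 initial learning rate.
#' @param plateau_factor multiplicative LR decay on plateau.
#' @param plateau_patience epochs without improvement before decay.
#' @param batch_size mini-batch size.
#' @param max_epochs maximum training epochs.
#' @param flip_prob probability of a joint left-right flip per sample.
#' @param seed master seed (weights, shuffling, augmentation).
#' @param improve_tol minimal absolute decrease counting as improvement.
#' @param berhu_c BerHu threshold used as training loss.
#' @param stop_val_r2 optional early-stop threshold on mean validation
#'   R-squared (`NULL` disables).
#' @return object of class `train_config`.
#' @export
train_config <- function(lr0 = 0.001, plateau_factor = 0.75,
                         plateau_patience = 3L, batch_size = 4L,
                         max_epochs = 300L, flip_prob = 0.5, seed = 1L,
                         improve_tol = 1e-6, berhu_c = 0.2,
                         stop_val_r2 = NULL) {
  stopifnot(lr0 > 0, plateau_factor > 0, plateau_factor < 1,
            plateau_patience >= 1, batch_size >= 1, max_epochs >= 1,
            flip_prob >= 0, flip_prob <= 1)
  structure(list(lr0 = lr0, plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 flip_prob = flip_prob, seed = as.integer(seed),
                 improve_tol = improve_tol, berhu_c = berhu_c,
                 stop_val_r2 = stop_val_r2),
            class = "train_config")
}

# reduce-on-plateau learning-rate scheduler; observe() takes the epoch's
# validation loss and returns the learning rate for the next epoch
#' @noRd
plateau_scheduler <- function(lr0, factor, patience, tol = 1e-6) {
  self <- new.env(parent = emptyenv())
  self$lr <- lr0
  self$best <- Inf
  self$bad <- 0L
  self$observe <- function(val_loss) {
    if (val_loss < self$best - tol) {
      self$best <- val_loss
      self$bad <- 0L
    } else {
      self$bad <- self$bad + 1L
      if (self$bad >= patience) {
        self$lr <- self$lr * factor
        self$bad <- 0L
      }
    }
    self$lr
  }
  self
}

flip_lr_array <- function(a) {
  d <- dim(a)
  a[, , , d[4]:1, drop = FALSE]
}

#' Jointly flip a series and its target maps left-right
#'
#' With probability `flip_prob`, both the input series and the target maps
#' are flipped along the left-right (x) axis together, preserving voxel
#' correspondence; otherwise both are returned unchanged.
#'
#' @param series a [perfusion_series()].
#' @param targets a [collateral_maps()].
#' @param flip_prob flip probability (draws one uniform variate).
#' @return list with elements `series`, `targets`, `flipped`.
#' @export
augment_flip <- function(series, targets, flip_prob = 0.5) {
  stopifnot(inherits(series, "perfusion_series"), inherits(targets, "collateral_maps"))
  do_flip <- stats::runif(1) < flip_prob
  if (do_flip) {
    series$data <- flip_lr_array(series$data)
    targets$maps <- flip_lr_array(targets$maps)
  }
  list(series = series, targets = targets, flipped = do_flip)
}

# preprocess one subject record into training tensors
prepare_record <- function(rec, pre_cfg) {
  stopifnot(inherits(rec, "subject_record"))
  pp <- preprocess_subject(rec$series, rec$targets, pre_cfg)
  list(x = pp$series$data, y = if (!is.null(pp$maps)) pp$maps$maps else NULL,
       mask = pp$mask$mask, group = rec$group, center = rec$center,
       id = rec$series$subject_id)
}

adam_state <- function(refs) {
  lapply(refs, function(r) {
    p <- r$env$params[[r$name]]
    list(m = p * 0, v = p * 0)
  })
}

adam_step <- function(refs, st, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  b1t <- 1 - beta1^t
  b2t <- 1 - beta2^t
  for (i in seq_along(refs)) {
    r <- refs[[i]]
    g <- r$env$grads[[r$name]]
    st[[i]]$m <- beta1 * st[[i]]$m + (1 - beta1) * g
    st[[i]]$v <- beta2 * st[[i]]$v + (1 - beta2) * g * g
    mhat <- st[[i]]$m / b1t
    vhat <- st[[i]]$v / b2t
    r$env$params[[r$name]] <- r$env$params[[r$name]] - lr * mhat / (sqrt(vhat) + eps)
  }
  st
}

val_metrics <- function(model, prepared, berhu_c) {
  losses <- numeric(length(prepared))
  r2s <- numeric(length(prepared))
  for (i in seq_along(prepared)) {
    s <- prepared[[i]]
    yhat <- model$forward(s$x, training = FALSE)
    losses[i] <- berhu_loss(s$y, yhat, c = berhu_c)
    idx <- which(s$mask != 0)
    r2p <- vapply(1:5, function(p) {
      r_squared(s$y[p, , , ][idx], yhat[p, , , ][idx])
    }, numeric(1))
    r2s[i] <- mean(r2p)
  }
  list(loss = mean(losses), r2 = mean(r2s))
}

#' Fit the collateral-map regression network
#'
#' Trains the encoder-decoder on preprocessed phantom or patient subjects
#' with the BerHu loss and the published optimization protocol: Adam,
#' reduce-on-plateau learning-rate schedule watching the validation loss,
#' joint left-right flip augmentation, and selection of the epoch with
#' minimal validation loss. One master seed drives weight initialization,
#' shuffling and augmentation, so runs replay exactly.
#'
#' @param subjects list of [subject_record()]s with targets (training set).
#' @param val_subjects list of [subject_record()]s (validation set).
#' @param cfg a [model_config()].
#' @param tcfg a [train_config()].
#' @param pre_cfg a [preprocess_config()] applied to every subject.
#' @param verbose print per-epoch progress.
#' @return an object of class `collnet`: the fitted model (weights of the
#'   best-validation epoch), configurations, and per-epoch `history`.
#' @export
train_collnet <- function(subjects, val_subjects, cfg = model_config(),
                          tcfg = train_config(),
                          pre_cfg = preprocess_config(), verbose = FALSE) {
  if (length(subjects) == 0 || length(val_subjects) == 0)
    stop("training and validation sets must be non-empty")
  set.seed(tcfg$seed)
  train_prep <- lapply(subjects, prepare_record, pre_cfg = pre_cfg)
  val_prep <- lapply(val_subjects, prepare_record, pre_cfg = pre_cfg)
  for (s in c(train_prep, val_prep))
    if (is.null(s$y)) stop("every subject needs target maps for training")

  model <- build_model(cfg)
  # intercept initialization: start each phase's head bias at the atanh of
  # that phase's mean target over the training set (cf. initializing a GLM
  # intercept at the base rate); removes the long offset-learning transient
  phase_means <- rowMeans(vapply(train_prep, function(s) {
    apply(s$y, 1, mean)
  }, numeric(cfg$out_phases)))
  phase_means <- pmin(pmax(phase_means, -0.95), 0.95)
  model$layers$head$layers[[1]]$params$b <- atanh(phase_means)
  refs <- collect_param_refs(model)
  opt <- adam_state(refs)
  sched <- plateau_scheduler(tcfg$lr0, tcfg$plateau_factor,
                             tcfg$plateau_patience, tcfg$improve_tol)
  lr <- tcfg$lr0
  best <- list(val_loss = Inf, epoch = 0L, state = NULL)
  history <- data.frame()
  step_t <- 0L
  n <- length(train_prep)

  for (epoch in seq_len(tcfg$max_epochs)) {
    ord <- sample.int(n)
    tl <- 0
    b0 <- 1
    while (b0 <= n) {
      b1 <- min(b0 + tcfg$batch_size - 1L, n)
      zero_grads(model)
      nb <- b1 - b0 + 1L
      for (j in b0:b1) {
        s <- train_prep[[ord[j]]]
        x <- s$x; y <- s$y
        if (stats::runif(1) < tcfg$flip_prob) {
          x <- flip_lr_array(x)
          y <- flip_lr_array(y)
        }
        yhat <- model$forward(x, training = TRUE)
        l <- berhu_loss(y, yhat, c = tcfg$berhu_c)
        if (!is.finite(l)) stop("training diverged: non-finite loss at epoch ",
                                epoch)
        tl <- tl + l
        g <- berhu_grad(y, yhat, c = tcfg$berhu_c) / nb
        dim(g) <- dim(yhat)
        model$backward(g)
      }
      step_t <- step_t + 1L
      opt <- adam_step(refs, opt, lr, step_t)
      b0 <- b1 + 1L
    }
    train_loss <- tl / n
    vm <- val_metrics(model, val_prep, tcfg$berhu_c)
    if (vm$loss < best$val_loss) {
      best <- list(val_loss = vm$loss, epoch = epoch, state = state_dict(model))
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = train_loss,
                                val_loss = vm$loss, val_r2 = vm$r2, lr = lr))
    if (verbose)
      cat(sprintf("epoch %3d  train %.5f  val %.5f  val R2 %.4f  lr %.6f\n",
                  epoch, train_loss, vm$loss, vm$r2, lr))
    lr <- sched$observe(vm$loss)
    if (!is.null(tcfg$stop_val_r2) && vm$r2 >= tcfg$stop_val_r2) break
  }
  load_state_dict(model, best$state)
  structure(list(model = model, cfg = cfg, tcfg = tcfg, pre_cfg = pre_cfg,
                 history = history, best_epoch = best$epoch,
                 best_val_loss = best$val_loss),
            class = "collnet")
}

#' @export
print.collnet <- function(x, ...) {
  cat("Collateral-map regression network (3D conv/Transformer encoder-decoder)\n")
  cat(sprintf("  %d trainable parameters; input %dx%dx%dx%d -> 5 phase maps\n",
              count_parameters(x$model), x$cfg$in_channels, x$cfg$depth,
              x$cfg$input_size, x$cfg$input_size))
  cat(sprintf("  trained %d epochs; best validation BerHu loss %.5f at epoch %d\n",
              nrow(x$history), x$best_val_loss, x$best_epoch))
  invisible(x)
}

#' @export
summary.collnet <- function(object, ...) {
  print(object)
  h <- object$history
  cat(sprintf("  final val R-squared %.4f; learning rate span %.2e .. %.2e\n",
              h$val_r2[nrow(h)], max(h$lr), min(h$lr)))
  invisible(object$history)
}

#' Predict five-phase collateral maps for one subject
#'
#' @param object a fitted `collnet`.
#' @param newdata a [subject_record()], [perfusion_series()], or a
#'   preprocessed `(T, D, H, W)` array. Records/series are passed through
#'   the same preprocessing as during training.
#' @param ... unused.
#' @return a [collateral_maps()] with values in the target range semantics
#'   `[-0.9, 0.9]` (network output is in `(-1, 1)`).
#' @export
predict.collnet <- function(object, newdata, ...) {
  x <- if (is.array(newdata)) {
    newdata
  } else if (inherits(newdata, "subject_record")) {
    prepare_record(newdata, object$pre_cfg)$x
  } else if (inherits(newdata, "perfusion_series")) {
    pp <- preprocess_subject(newdata, cfg = object$pre_cfg)
    pp$series$data
  } else stop("unsupported newdata type")
  cfg <- object$cfg
  d <- dim(x)
  if (d[1] != cfg$in_channels)
    stop("input has ", d[1], " time points; model expects ", cfg$in_channels)
  yhat <- object$model$forward(x, training = FALSE)
  collateral_maps(yhat, value_range = "target")
}

#' Residual maps (prediction minus truth) for a list of subjects
#' @param object a fitted `collnet`.
#' @param subjects list of [subject_record()]s with targets.
#' @param ... unused.
#' @return list of `(5, D, H, W)` residual arrays.
#' @export
residuals.collnet <- function(object, subjects, ...) {
  lapply(subjects, function(rec) {
    s <- prepare_record(rec, object$pre_cfg)
    yhat <- object$model$forward(s$x, training = FALSE)
    yhat - s$y
  })
}

#' @export
coef.collnet <- function(object, ...) state_dict(object$model)

#' Plot training history (train/validation loss and learning rate)
#' @param x a fitted `collnet`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.collnet <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "BerHu loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  graphics::abline(v = x$best_epoch, lty = 3)
  invisible(x)
}

#' Evaluate a fitted model over a cohort
#'
#' Computes the per-subject, per-phase metrics via [evaluate_subject()] and
#' aggregates them overall, by diagnostic group and by center, reporting
#' mean and sample standard deviation (n - 1 denominator) per cell.
#'
#' @param fit a fitted `collnet`.
#' @param subjects list of [subject_record()]s with targets.
#' @return list with `per_subject` (long data frame) and `summary`
#'   (aggregated data frame with columns `stratum`, `level`, `phase`,
#'   `metric`, `mean`, `sd`, `n`).
#' @export
evaluate_cohort <- function(fit, subjects) {
  stopifnot(inherits(fit, "collnet"))
  rows <- list()
  for (i in seq_along(subjects)) {
    rec <- subjects[[i]]
    if (is.null(rec$targets)) stop("subject ", i, " has no target maps")
    s <- prepare_record(rec, fit$pre_cfg)
    yhat <- fit$model$forward(s$x, training = FALSE)
    df <- evaluate_subject(collateral_maps(yhat, "target"),
                           collateral_maps(s$y, "target"),
                           brain_mask(s$mask))
    df$subject <- s$id
    df$group <- s$group
    df$center <- s$center
    rows[[i]] <- df
  }
  per_subject <- do.call(rbind, rows)
  long <- stats::reshape(per_subject, direction = "long",
                         varying = c("r_squared", "mae", "tanimoto", "ssim"),
                         v.names = "value", timevar = "metric",
                         times = c("r_squared", "mae", "tanimoto", "ssim"))
  agg <- function(stratum, key) {
    sp <- split(long, list(long[[key]], long$phase, long$metric), drop = TRUE)
    do.call(rbind, lapply(sp, function(d) {
      data.frame(stratum = stratum, level = as.character(d[[key]][1]),
                 phase = d$phase[1], metric = d$metric[1],
                 mean = mean(d$value),
                 sd = if (nrow(d) > 1) stats::sd(d$value) else 0,
                 n = nrow(d))
    }))
  }
  long$all <- "all"
  summary_df <- rbind(agg("overall", "all"), agg("group", "group"),
                      agg("center", "center"))
  rownames(summary_df) <- NULL
  list(per_subject = per_subject, summary = summary_df)
}

## ---- checkpoints -----------------------------------------------------------

#' Save a fitted model (weights + configurations) to a file
#' @param fit a `collnet`.
#' @param path output path (RDS).
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "collnet"))
  saveRDS(list(cfg = fit$cfg, tcfg = fit$tcfg, pre_cfg = fit$pre_cfg,
               state = state_dict(fit$model), history = fit$history,
               best_epoch = fit$best_epoch, best_val_loss = fit$best_val_loss),
          path)
  invisible(path)
}

#' Load a fitted model saved by [save_checkpoint()]
#' @param path checkpoint path.
#' @return a `collnet` with rebuilt model and restored weights.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$cfg)
  load_state_dict(model, ck$state)
  structure(list(model = model, cfg = ck$cfg, tcfg = ck$tcfg,
                 pre_cfg = ck$pre_cfg, history = ck$history,
                 best_epoch = ck$best_epoch, best_val_loss = ck$best_val_loss),
            class = "collnet")
}
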