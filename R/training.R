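#' Training configuration
#'
#' Defaults follow the reference training protocol: Huber loss (delta = 2
#' UPDRS points), AdamW with initial learning rate 3e-4 and decoupled
#' weight decay 0.005, global gradient-norm clipping at 1.0, batch size 16,
#' up to 150 epochs with early-stopping patience 25, a 15% patient-level
#' validation holdout, plateau learning-rate reduction (factor 0.5,
#' patience 10, floor 1e-6) and the piecewise learning-rate schedule of
#' [lr_at_epoch()]. The ablation preset shortens training to 50 epochs
#' with patience 10.
#'
#' @param huber_delta Huber transition point (UPDRS points).
#' @param base_lr Initial learning rate.
#' @param weight_decay Decoupled AdamW weight decay.
#' @param grad_clip_norm Global gradient-norm clip.
#' @param batch_size Samples per step.
#' @param max_epochs Maximum training epochs.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping (best weights restored).
#' @param val_fraction Fraction of training patients held out for
#'   validation.
#' @param plateau_factor,plateau_patience,min_lr Plateau LR reduction.
#' @param train_windows_per_patient,val_windows_per_patient Caps on the
#'   evenly spaced windows per patient used for optimisation and for
#'   validation monitoring (`Inf` = use all). Consecutive windows overlap
#'   in all but one timestep, so spaced subsamples lose little
#'   information; a larger validation cap keeps the early-stopping signal
#'   smooth.
#' @param rng_seed Seed controlling shuffling, dropout and the validation
#'   split.
#' @return A `train_config` list.
#' @export
train_config <- function(huber_delta = 2.0, base_lr = 3e-4,
                         weight_decay = 0.005, grad_clip_norm = 1.0,
                         batch_size = 16, max_epochs = 150,
                         early_stop_patience = 25, val_fraction = 0.15,
                         plateau_factor = 0.5, plateau_patience = 10,
                         min_lr = 1e-6,
                         train_windows_per_patient = Inf,
                         val_windows_per_patient = Inf, rng_seed = 7) {
  stopifnot(huber_delta > 0, val_fraction > 0, val_fraction < 1,
            early_stop_patience >= 1, plateau_patience >= 1)
  structure(list(
    huber_delta = huber_delta, base_lr = base_lr,
    weight_decay = weight_decay, grad_clip_norm = grad_clip_norm,
    batch_size = batch_size, max_epochs = max_epochs,
    early_stop_patience = early_stop_patience, val_fraction = val_fraction,
    plateau_factor = plateau_factor, plateau_patience = plateau_patience,
    min_lr = min_lr,
    train_windows_per_patient = train_windows_per_patient,
    val_windows_per_patient = val_windows_per_patient, rng_seed = rng_seed
  ), class = "train_config")
}

#' Ablation-study training preset
#'
#' @param ... Overrides passed on to [train_config()].
#' @return A `train_config` with `max_epochs = 50` and patience 10.
#' @export
ablation_train_config <- function(...) {
  do.call(train_config, utils::modifyList(
    list(max_epochs = 50, early_stop_patience = 10), list(...)))
}

#' Huber loss
#'
#' Mean over the batch of the robust Huber penalty: `0.5 r^2` for
#' `|r| <= delta`, `delta (|r| - delta / 2)` beyond, `r = y - yhat`.
#' Quadratic near zero like MSE, linear in the tails like MAE, and C1
#' continuous at the elbow.
#'
#' @param y,yhat Observed and predicted values.
#' @param delta Transition point, > 0.
#' @return Nonnegative scalar.
#' @export
huber_loss <- function(y, yhat, delta = 2.0) {
  stopifnot(delta > 0, length(y) == length(yhat))
  r <- y - yhat
  mean(ifelse(abs(r) <= delta, 0.5 * r^2, delta * (abs(r) - 0.5 * delta)))
}

huber_grad_yhat <- function(y, yhat, delta) {
  r <- y - yhat
  -ifelse(abs(r) <= delta, r, delta * sign(r)) / length(y)
}

#' Learning rate schedule
#'
#' Constant for the first 10 epochs; 5% multiplicative decays applied at
#' epochs 10, 20 and 30; a 10%-per-30-epochs decay applied once at epoch
#' 60; 15%-per-30-epochs decays applied at epochs 90, 120, and so on.
#'
#' @param epoch Zero-based epoch index.
#' @param config A [train_config()] (supplies `base_lr`).
#' @return The learning rate for that epoch.
#' @export
lr_at_epoch <- function(epoch, config = train_config()) {
  stopifnot(epoch >= 0)
  n5 <- sum(c(10, 20, 30) <= epoch)
  n10 <- as.numeric(epoch >= 60)
  n15 <- if (epoch >= 90) floor((epoch - 90) / 30) + 1 else 0
  config$base_lr * 0.95^n5 * 0.90^n10 * 0.85^n15
}

# ---- scaling ------------------------------------------------------------

robust_fit_col <- function(x) {
  ctr <- median(x)
  iqr <- quantile(x, 0.75, names = FALSE) - quantile(x, 0.25, names = FALSE)
  if (iqr < 1e-9) iqr <- 1
  c(center = ctr, scale = iqr)
}

#' Fit robust feature scalers on training-fold data
#'
#' Voice and meta blocks (and the numeric clinical columns) get a
#' median/IQR robust scaler with post-scaling clipping to \[-5, 5\]; a
#' degenerate IQR falls back to 1. Categorical clinical codes (disease
#' stage, progression rate) pass through untouched. Text embeddings are
#' mean-centred only. Must be fitted on training-fold patients exclusively.
#'
#' @param fs A feature set from [build_feature_set()].
#' @param subject_ids Training-fold subject identifiers.
#' @return A fitted `scaler_state`.
#' @export
fit_scalers <- function(fs, subject_ids = names(fs$patients)) {
  pats <- fs$patients[subject_ids]
  stopifnot(length(pats) > 0)
  stack <- function(name) do.call(rbind, lapply(pats, `[[`, name))
  voice <- stack("voice")
  clinical <- stack("clinical")
  meta <- stack("meta")
  embs <- do.call(rbind, lapply(pats, function(p) {
    if (is.matrix(p$emb)) p$emb else matrix(p$emb, nrow = 1)
  }))
  clin_numeric <- setdiff(seq_len(ncol(clinical)), clinical_categorical_cols)
  structure(list(
    voice = t(apply(voice, 2, robust_fit_col)),
    clinical = t(apply(clinical[, clin_numeric, drop = FALSE], 2,
                       robust_fit_col)),
    clinical_numeric_cols = clin_numeric,
    meta = t(apply(meta, 2, robust_fit_col)),
    text_center = colMeans(embs),
    clip = 5, fitted = TRUE
  ), class = "scaler_state")
}

scale_block <- function(M, tab, clip) {
  Z <- sweep(sweep(M, 2, tab[, "center"]), 2, tab[, "scale"], "/")
  pmin(pmax(Z, -clip), clip)
}

#' Apply fitted scalers to a feature set
#'
#' @param fs A feature set from [build_feature_set()].
#' @param scaler A fitted [fit_scalers()] state.
#' @return The feature set with transformed blocks.
#' @export
apply_scalers <- function(fs, scaler) {
  if (!isTRUE(scaler$fitted)) {
    stop("state error: scaler has not been fitted", call. = FALSE)
  }
  fs$patients <- lapply(fs$patients, function(p) {
    p$voice <- scale_block(p$voice, scaler$voice, scaler$clip)
    cn <- scaler$clinical_numeric_cols
    p$clinical[, cn] <- scale_block(p$clinical[, cn, drop = FALSE],
                                    scaler$clinical, scaler$clip)
    p$meta <- scale_block(p$meta, scaler$meta, scaler$clip)
    if (is.matrix(p$emb)) {
      p$emb <- sweep(p$emb, 2, scaler$text_center)
    } else {
      p$emb <- p$emb - scaler$text_center
    }
    p
  })
  fs$scaled <- TRUE
  fs
}

# ---- optimizer ----------------------------------------------------------

adamw_init <- function(P) {
  list(m = lapply(P, function(x) x * 0), v = lapply(P, function(x) x * 0),
       t = 0)
}

# Returns list(params, state, grad_norm). Gradients arrive with the L2
# kernel penalty already folded in; clipping happens here.
adamw_step <- function(P, grads, state, lr, weight_decay, clip,
                       kernels, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  coef <- if (gnorm > clip) clip / (gnorm + 1e-12) else 1
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]] * coef
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    P[[nm]] <- P[[nm]] - lr * upd
    if (nm %in% kernels) P[[nm]] <- P[[nm]] - lr * weight_decay * P[[nm]]
  }
  list(P = P, state = state, grad_norm = min(gnorm, clip))
}

# ---- fit loop -----------------------------------------------------------

#' Train a model on supervised windows
#'
#' Minimises mean Huber loss plus the L2 kernel penalty with AdamW,
#' per-step global gradient clipping, the epoch learning-rate schedule,
#' plateau LR reduction on validation loss, early stopping with
#' best-weight restoration, and a patient-level validation holdout (whole
#' patients, matching the patient-wise leakage stance of the evaluation
#' protocol). Fully reproducible given `config$rng_seed`.
#'
#' @param model A `dcan_model` (or the simple recurrent baseline).
#' @param fs A scaled feature set ([apply_scalers()]).
#' @param window_rows Integer rows of `fs$windows` to train on.
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return List with the trained `model` and a per-epoch `history` data
#'   frame (train/val loss, MAE, MSE, learning rate, max clipped gradient
#'   norm).
#' @export
train_model <- function(model, fs, window_rows = seq_len(nrow(fs$windows)),
                        config = train_config(), verbose = FALSE) {
  if (length(window_rows) == 0) {
    stop("empty training set", call. = FALSE)
  }
  if (!isTRUE(fs$scaled)) {
    stop("state error: feature set has not been scaled; fit scalers on the ",
         "training fold first", call. = FALSE)
  }
  set.seed(config$rng_seed)
  win <- fs$windows[window_rows, , drop = FALSE]
  pats <- unique(win$subject_id)
  n_val_pat <- max(1, round(config$val_fraction * length(pats)))
  if (length(pats) < 2) {
    val_pats <- character(0)
  } else {
    val_pats <- sample(pats, n_val_pat)
  }
  cap_rows <- function(rows, per_patient) {
    if (!is.finite(per_patient)) return(rows)
    sub <- fs$windows$subject_id[rows]
    unlist(lapply(split(rows, sub), function(idx) {
      if (length(idx) > per_patient) {
        idx[unique(round(seq(1, length(idx), length.out = per_patient)))]
      } else idx
    }), use.names = FALSE)
  }
  val_rows <- cap_rows(window_rows[win$subject_id %in% val_pats],
                       config$val_windows_per_patient)
  trn_rows <- cap_rows(setdiff(window_rows,
                               window_rows[win$subject_id %in% val_pats]),
                       config$train_windows_per_patient)
  if (length(trn_rows) == 0) stop("empty training set", call. = FALSE)
  monitor_rows <- if (length(val_rows) > 0) val_rows else trn_rows

  # Standardise the target internally: the head then works at unit scale
  # instead of tens of UPDRS points. The Huber elbow is rescaled so the
  # robustness transition stays at exactly huber_delta UPDRS points, and
  # predictions are mapped back to raw units by predict_model().
  y_center <- mean(fs$windows$y[trn_rows])
  y_scale <- sd(fs$windows$y[trn_rows])
  if (!is.finite(y_scale) || y_scale < 1e-8) y_scale <- 1
  model$target_scaler <- c(center = y_center, scale = y_scale)
  delta_s <- config$huber_delta / y_scale
  kernels <- kernel_param_names(model$params)
  state <- adamw_init(model$params)
  lam <- model$config$l2_lambda %||% 0
  best <- list(loss = Inf, params = model$params, epoch = -1)
  plateau_best <- Inf
  plateau_wait <- 0
  plateau_mult <- 1
  stall <- 0
  hist <- list()

  eval_rows <- function(rows) {
    preds <- predict_model(model, fs, rows)
    y <- fs$windows$y[rows]
    c(loss = huber_loss(y, preds, config$huber_delta),
      mae = mean(abs(y - preds)), mse = mean((y - preds)^2))
  }
  scale_y <- function(y) (y - y_center) / y_scale

  for (epoch in seq_len(config$max_epochs) - 1) {
    lr <- max(lr_at_epoch(epoch, config) * plateau_mult, config$min_lr)
    ord <- sample(trn_rows)
    nb <- ceiling(length(ord) / config$batch_size)
    ep_loss <- 0
    max_gnorm <- 0
    for (bi in seq_len(nb)) {
      rows <- ord[((bi - 1) * config$batch_size + 1):
                    min(bi * config$batch_size, length(ord))]
      batch <- gather_batch(fs, rows)
      fwd <- model_forward(model, batch, train = TRUE)
      if (any(!is.finite(fwd$yhat))) {
        stop("non-finite loss: diverged at epoch ", epoch, ", batch ", bi,
             call. = FALSE)
      }
      ys <- scale_y(batch$y)
      dy <- huber_grad_yhat(ys, fwd$yhat, delta_s)
      grads <- model_backward(model, fwd, dy)
      if (lam > 0) {
        for (nm in intersect(kernels, names(grads))) {
          grads[[nm]] <- grads[[nm]] + 2 * lam * model$params[[nm]]
        }
      }
      stp <- adamw_step(model$params, grads, state, lr,
                        config$weight_decay, config$grad_clip_norm, kernels)
      model$params <- stp$P
      state <- stp$state
      max_gnorm <- max(max_gnorm, stp$grad_norm)
      ep_loss <- ep_loss +
        huber_loss(batch$y, y_center + y_scale * fwd$yhat,
                   config$huber_delta) * length(rows)
    }
    ep_loss <- ep_loss / length(trn_rows)
    vm <- eval_rows(monitor_rows)
    hist[[length(hist) + 1]] <- data.frame(
      epoch = epoch, lr = lr, train_loss = ep_loss,
      val_loss = vm[["loss"]], val_mae = vm[["mae"]], val_mse = vm[["mse"]],
      max_grad_norm = max_gnorm
    )
    if (verbose) {
      message(sprintf("epoch %3d lr %.2e train %.4f val %.4f",
                      epoch, lr, ep_loss, vm[["loss"]]))
    }
    if (vm[["loss"]] < best$loss - 1e-12) {
      best <- list(loss = vm[["loss"]], params = model$params,
                   epoch = epoch)
      stall <- 0
    } else {
      stall <- stall + 1
    }
    if (vm[["loss"]] < plateau_best - 1e-12) {
      plateau_best <- vm[["loss"]]
      plateau_wait <- 0
    } else {
      plateau_wait <- plateau_wait + 1
      if (plateau_wait >= config$plateau_patience) {
        plateau_mult <- plateau_mult * config$plateau_factor
        plateau_wait <- 0
      }
    }
    if (stall >= config$early_stop_patience) break
  }
  model$params <- best$params
  list(model = model, history = do.call(rbind, hist),
       best_epoch = best$epoch, val_patients = val_pats)
}

#' Predict motor-UPDRS for supervised windows
#'
#' Forward passes in inference mode (no dropout); deterministic.
#'
#' @param model A trained model.
#' @param fs A scaled feature set.
#' @param window_rows Rows of `fs$windows` to score.
#' @param batch_size Forward-pass batch size.
#' @param return_alpha Also return the per-sample modality weights.
#' @return Numeric predictions, or a list with `yhat` and `alpha` when
#'   `return_alpha = TRUE`.
#' @export
predict_model <- function(model, fs, window_rows,
                          batch_size = 128, return_alpha = FALSE) {
  out <- numeric(length(window_rows))
  alphas <- NULL
  nb <- ceiling(length(window_rows) / batch_size)
  for (bi in seq_len(nb)) {
    sel <- ((bi - 1) * batch_size + 1):min(bi * batch_size,
                                           length(window_rows))
    batch <- gather_batch(fs, window_rows[sel])
    fwd <- model_forward(model, batch, train = FALSE)
    ts <- model$target_scaler
    out[sel] <- if (is.null(ts)) fwd$yhat else
      ts[["center"]] + ts[["scale"]] * fwd$yhat
    if (return_alpha && !is.null(fwd$alpha)) {
      alphas <- rbind(alphas, fwd$alpha)
    }
  }
  if (return_alpha) list(yhat = out, alpha = alphas) else out
}

# dispatch between the full network and the simple recurrent baseline
model_forward <- function(model, batch, train = FALSE) {
  if (inherits(model, "dcan_model")) dcan_forward(model, batch, train)
  else rnn_forward(model, batch, train)
}
model_backward <- function(model, fwd, dy) {
  if (inherits(model, "dcan_model")) dcan_backward(model, fwd, dy)
  else rnn_backward(model, fwd, dy)
}
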