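#' Build the full multi-modal feature set for a cohort
#'
#' Runs the per-patient feature engineering (voice, clinical, meta blocks),
#' computes clinical narrative summaries and their embeddings, and indexes
#' every supervised window (target visits 3..n per patient). In
#' `full_history` narrative mode (the reference behaviour) one summary per
#' patient is embedded from the complete series — note that this reuses a
#' patient's later visits in the text channel, which is acceptable under
#' patient-level cross-validation but is not causally clean; `causal` mode
#' embeds one summary per target visit from the history up to that visit.
#'
#' @param cohort A `telemon_cohort`.
#' @param config A [feature_config()].
#' @param narrative_mode `"full_history"` or `"causal"`.
#' @param encoder Text encoder, e.g. [hashing_encoder()].
#' @return A `feature_set`: per-patient blocks and embeddings plus a
#'   `windows` index (`subject_id`, `target_idx`, `y`).
#' @export
build_feature_set <- function(cohort, config = feature_config(),
                              narrative_mode = c("full_history", "causal"),
                              encoder = hashing_encoder()) {
  narrative_mode <- match.arg(narrative_mode)
  sex_codes <- attr(cohort, "sex_codes") %||% c(male = 0, female = 1)
  patients <- list()
  wins <- list()
  for (s in cohort) {
    n <- nrow(s$visits)
    blocks <- list(
      voice = build_voice_features(s, config),
      clinical = build_clinical_features(s, config),
      meta = build_meta_features(s)
    )
    if (narrative_mode == "full_history") {
      stats <- compute_narrative_stats(s, sex_codes = sex_codes)
      emb <- embed_summary(render_summary(stats), encoder)$e
    } else {
      targets <- if (n >= 3) 3:n else integer(0)
      emb <- matrix(0, n, 768)
      for (i in targets) {
        stats <- compute_narrative_stats(s, upto = i, sex_codes = sex_codes)
        emb[i, ] <- embed_summary(render_summary(stats), encoder)$e
      }
    }
    patients[[s$subject_id]] <- list(
      voice = blocks$voice, clinical = blocks$clinical, meta = blocks$meta,
      emb = emb, n = n, y = s$visits$motor_updrs
    )
    if (n >= 3) {
      wins[[s$subject_id]] <- data.frame(
        subject_id = s$subject_id, target_idx = 3:n,
        y = s$visits$motor_updrs[3:n], stringsAsFactors = FALSE
      )
    }
  }
  structure(list(
    patients = patients,
    windows = do.call(rbind, c(wins, list(make.row.names = FALSE))),
    config = config, narrative_mode = narrative_mode, scaled = FALSE
  ), class = "feature_set")
}

# Assemble (B*T) x D batch matrices for the given rows of fs$windows.
# Padded timesteps are zero-filled; the mask marks valid positions.
gather_batch <- function(fs, rows) {
  Tl <- fs$config$sequence_length
  B <- length(rows)
  w <- fs$windows[rows, , drop = FALSE]
  xv <- vector("list", B); xc <- vector("list", B); xm <- vector("list", B)
  emb <- matrix(0, B, 768)
  mask <- matrix(0, B, Tl)
  for (k in seq_len(B)) {
    p <- fs$patients[[w$subject_id[k]]]
    i <- w$target_idx[k]
    lo <- max(1, i - Tl + 1)
    avail <- i - lo + 1
    pad <- Tl - avail
    slice <- function(M) {
      S <- M[lo:i, , drop = FALSE]
      if (pad > 0) S <- rbind(matrix(0, pad, ncol(S)), S)
      S
    }
    xv[[k]] <- slice(p$voice)
    xc[[k]] <- slice(p$clinical)
    xm[[k]] <- slice(p$meta)
    emb[k, ] <- if (is.matrix(p$emb)) p$emb[i, ] else p$emb
    mask[k, (pad + 1):Tl] <- 1
  }
  list(
    X_v = do.call(rbind, xv),
    X_c = do.call(rbind, xc),
    X_m = do.call(rbind, xm),
    X_t = emb,  # one embedding row per sample; tiled inside the model
    mask = mask, y = w$y
  )
}

# Flatten windows for the classical baselines: the final-timestep voice,
# clinical and meta features (optionally the text embedding).
flatten_windows <- function(fs, rows, include_text = FALSE) {
  out <- matrix(0, length(rows),
                ncol(fs$patients[[1]]$voice) +
                  ncol(fs$patients[[1]]$clinical) +
                  ncol(fs$patients[[1]]$meta) +
                  if (include_text) 768 else 0)
  w <- fs$windows[rows, , drop = FALSE]
  for (k in seq_along(rows)) {
    p <- fs$patients[[w$subject_id[k]]]
    i <- w$target_idx[k]
    v <- c(p$voice[i, ], p$clinical[i, ], p$meta[i, ])
    if (include_text) {
      v <- c(v, if (is.matrix(p$emb)) p$emb[i, ] else p$emb)
    }
    out[k, ] <- v
  }
  out
}

# ---- simple recurrent baseline -----------------------------------------

#' Single-layer recurrent baseline regressor
#'
#' A plain unidirectional LSTM over the concatenated per-timestep voice,
#' clinical and meta features, followed by a linear readout of the final
#' timestep. Trained with the same loop as the full network; serves as the
#' recurrent entry of the classical-baseline comparison.
#'
#' @param input_dim Total per-timestep feature dimension.
#' @param hidden_dim LSTM width.
#' @param seed Initialisation seed.
#' @return An `rnn_model`.
#' @export
build_simple_recurrent <- function(input_dim, hidden_dim = 64, seed = 42) {
  set.seed(seed)
  P <- list()
  lst <- init_lstm_params(input_dim, hidden_dim)
  P[["rnn.lstm.Wx"]] <- lst$Wx
  P[["rnn.lstm.Wh"]] <- lst$Wh
  P[["rnn.lstm.b"]] <- lst$b
  l <- sqrt(6 / (hidden_dim + 1))
  P[["rnn.out.W"]] <- matrix(runif(hidden_dim, -l, l), hidden_dim, 1)
  P[["rnn.out.b"]] <- 0
  structure(list(
    config = list(hidden_dim = hidden_dim, input_dim = input_dim,
                  l2_lambda = 0),
    params = P,
    n_parameters = sum(vapply(P, length, numeric(1)))
  ), class = "rnn_model")
}

rnn_forward <- function(model, batch, train = FALSE) {
  B <- nrow(batch$mask)
  Tl <- ncol(batch$mask)
  mvec <- as.numeric(t(batch$mask))
  X <- cbind(batch$X_v, batch$X_c, batch$X_m) * mvec
  f <- .lstm_forward_cpp(X, model$params[["rnn.lstm.Wx"]],
                         model$params[["rnn.lstm.Wh"]],
                         model$params[["rnn.lstm.b"]], B, Tl, FALSE)
  last <- seq_len(B) * Tl
  hT <- f$H[last, , drop = FALSE]
  yhat <- as.numeric(hT %*% model$params[["rnn.out.W"]] +
                       model$params[["rnn.out.b"]])
  list(yhat = yhat, alpha = NULL,
       cache = list(B = B, T = Tl, X = X, f = f, last = last, hT = hT))
}

rnn_backward <- function(model, fwd, dy) {
  c <- fwd$cache
  G <- new.env(); G$g <- list()
  dOut <- matrix(dy, ncol = 1)
  gacc(G, "rnn.out.W", crossprod(c$hT, dOut))
  gacc(G, "rnn.out.b", sum(dy))
  dH <- matrix(0, c$B * c$T, ncol(c$f$H))
  dH[c$last, ] <- dOut %*% t(model$params[["rnn.out.W"]])
  bk <- .lstm_backward_cpp(dH, c$X, model$params[["rnn.lstm.Wx"]],
                           model$params[["rnn.lstm.Wh"]],
                           c$f$Ht, c$f$C, c$f$G, c$B, c$T, FALSE)
  gacc(G, "rnn.lstm.Wx", bk$dWx)
  gacc(G, "rnn.lstm.Wh", bk$dWh)
  gacc(G, "rnn.lstm.b", as.numeric(bk$db))
  G$g
}
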