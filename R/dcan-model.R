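modality_keys <- c(voice = "v", clinical = "c", meta = "m", text = "t")

#' Model architecture configuration
#'
#' Defaults follow the reference configuration of the dynamic context-aware
#' network: hidden dimension 256 throughout, 4 attention heads in every
#' block (head dimension `hidden_dim / heads`), dropout 0.15 on attention
#' residuals and the prediction head, 0.2 in the dense encoders, 0.3 in the
#' temporal block, and an L2 kernel penalty of 3e-4. The ablation preset
#' used for modality-contribution studies is `model_config(hidden_dim =
#' 128, dropout_encoder = 0.2, l2_lambda = 5e-4)`.
#'
#' @param hidden_dim Width `h_d` of all encoded representations; must be
#'   divisible by the head counts.
#' @param fusion_heads,encoder_heads Attention heads in the fusion and
#'   encoder/temporal attention blocks.
#' @param dropout_attention,dropout_encoder,dropout_temporal,dropout_head
#'   Dropout probabilities, in `[0, 1)`.
#' @param l2_lambda L2 penalty on dense and recurrent kernels.
#' @param modalities Character subset of
#'   `c("voice", "clinical", "meta", "text")`; absent modalities are
#'   removed from the encoders and the fusion softmax re-normalises over
#'   the remainder.
#' @param D_v,D_c,D_m,D_t Input feature dimensions per modality.
#' @param sequence_length Supervised window length `T`.
#' @param residual_per_layer Residual connections around each temporal LSTM
#'   layer (default) or around the stacked pair.
#' @return A `model_config` list.
#' @export
model_config <- function(hidden_dim = 256, fusion_heads = 4,
                         encoder_heads = 4, dropout_attention = 0.15,
                         dropout_encoder = 0.2, dropout_temporal = 0.3,
                         dropout_head = 0.15, l2_lambda = 3e-4,
                         modalities = c("voice", "clinical", "meta", "text"),
                         D_v = 146, D_c = 9, D_m = 3, D_t = 768,
                         sequence_length = 10,
                         residual_per_layer = TRUE) {
  stopifnot(hidden_dim %% fusion_heads == 0,
            hidden_dim %% encoder_heads == 0, hidden_dim %% 2 == 0)
  drops <- c(dropout_attention, dropout_encoder, dropout_temporal,
             dropout_head)
  if (any(drops < 0) || any(drops >= 1)) {
    stop("invalid config: dropout rates must lie in [0, 1)", call. = FALSE)
  }
  if (l2_lambda < 0) stop("invalid config: l2_lambda >= 0", call. = FALSE)
  modalities <- match.arg(modalities, several.ok = TRUE)
  structure(list(
    hidden_dim = hidden_dim, fusion_heads = fusion_heads,
    encoder_heads = encoder_heads, dropout_attention = dropout_attention,
    dropout_encoder = dropout_encoder, dropout_temporal = dropout_temporal,
    dropout_head = dropout_head, l2_lambda = l2_lambda,
    modalities = modalities,
    D = c(voice = D_v, clinical = D_c, meta = D_m, text = D_t),
    sequence_length = sequence_length,
    residual_per_layer = residual_per_layer
  ), class = "model_config")
}

#' Ablation-study hyperparameter preset
#'
#' The reduced configuration used for modality-contribution studies:
#' hidden dimension 128, dropout 0.2, L2 5e-4, 4 attention heads.
#'
#' @param ... Overrides passed on to [model_config()].
#' @return A `model_config`.
#' @export
ablation_model_config <- function(...) {
  defaults <- list(hidden_dim = 128, dropout_attention = 0.2,
                   dropout_encoder = 0.2, dropout_temporal = 0.2,
                   dropout_head = 0.2, l2_lambda = 5e-4, fusion_heads = 4,
                   encoder_heads = 4)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

init_dense_params <- function(D, h) {
  gl <- function(d1, d2) {
    l <- sqrt(6 / (d1 + d2))
    matrix(runif(d1 * d2, -l, l), d1, d2)
  }
  list(W = gl(D, h), b = numeric(h))
}

#' Assemble a dynamic context-aware network
#'
#' Wires the modality encoders (a stacked bidirectional LSTM + self-attention
#' encoder for voice; position-wise GELU dense encoders for clinical, meta
#' and text), the multi-head dynamic attention fusion (per-modality
#' self-attention, temporal mean pooling, a learned softmax over modality
#' weights, and convex recombination of the attended sequences), the
#' causally masked temporal block, and the prediction head. Padded
#' timesteps are zeroed on input, excluded from attention and pooling, and
#' cannot influence the prediction.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for parameter initialisation.
#' @return A `dcan_model` list with elements `config`, `params` and
#'   `n_parameters`.
#' @export
build_model <- function(config = model_config(), seed = 42) {
  stopifnot(inherits(config, "model_config"))
  set.seed(seed)
  h <- config$hidden_dim
  h2 <- h %/% 2
  P <- list()
  put <- function(prefix, lst) {
    for (nm in names(lst)) P[[paste0(prefix, ".", nm)]] <<- lst[[nm]]
  }
  mods <- config$modalities
  if ("voice" %in% mods) {
    put("v.lstm1.f", init_lstm_params(config$D[["voice"]], h2))
    put("v.lstm1.b", init_lstm_params(config$D[["voice"]], h2))
    put("v.lstm2.f", init_lstm_params(h, h2))
    put("v.lstm2.b", init_lstm_params(h, h2))
    put("v.att", init_mha_params(h))
    put("v.ln", list(g = rep(1, h), b = numeric(h)))
  }
  for (mod in intersect(c("clinical", "meta", "text"), mods)) {
    key <- modality_keys[[mod]]
    put(paste0(key, ".d1"), init_dense_params(config$D[[mod]], h))
    put(paste0(key, ".d2"), init_dense_params(h, h))
    put(paste0(key, ".ln"), list(g = rep(1, h), b = numeric(h)))
  }
  for (mod in mods) {
    put(paste0("fus.", modality_keys[[mod]], ".att"), init_mha_params(h))
  }
  nm <- length(mods)
  gl <- function(d1, d2) {
    l <- sqrt(6 / (d1 + d2))
    matrix(runif(d1 * d2, -l, l), d1, d2)
  }
  # zero-initialised weighting layer: fusion starts at exactly uniform
  # convex modality weights and learns to depart from them
  P[["fus.Wc"]] <- matrix(0, nm, nm * h)
  P[["fus.bc"]] <- numeric(nm)
  put("tmp.lstm1.f", init_lstm_params(h, h2))
  put("tmp.lstm1.b", init_lstm_params(h, h2))
  put("tmp.lstm2.f", init_lstm_params(h, h2))
  put("tmp.lstm2.b", init_lstm_params(h, h2))
  put("tmp.att", init_mha_params(h))
  put("tmp.ln", list(g = rep(1, h), b = numeric(h)))
  put("head.d1", init_dense_params(h, h))
  put("head.d2", init_dense_params(h, h))
  put("head.d3", init_dense_params(h, h))
  put("head.ln", list(g = rep(1, h), b = numeric(h)))
  put("head.out", list(W = gl(h, 1), b = numeric(1)))
  structure(list(
    config = config, params = P,
    n_parameters = sum(vapply(P, length, numeric(1)))
  ), class = "dcan_model")
}

# parameter names subject to L2 penalty / decoupled weight decay
kernel_param_names <- function(P) {
  names(P)[grepl("\\.(W|Wx|Wh|Wq|Wk|Wv|Wo|Wc)$", names(P))]
}

dense_branch_fwd <- function(X, P, key, p_drop, train) {
  l1 <- linear_fwd(X, P[[paste0(key, ".d1.W")]], P[[paste0(key, ".d1.b")]])
  a1 <- gelu_fwd(l1$Y)
  d1 <- dropout_fwd(a1$Y, p_drop, train)
  l2 <- linear_fwd(d1$Y, P[[paste0(key, ".d2.W")]],
                   P[[paste0(key, ".d2.b")]])
  a2 <- gelu_fwd(l2$Y)
  d2 <- dropout_fwd(a2$Y, p_drop, train)
  ln <- layernorm_fwd(d2$Y, P[[paste0(key, ".ln.g")]],
                      P[[paste0(key, ".ln.b")]])
  list(H = ln$Y, l1 = l1, a1 = a1, d1 = d1, l2 = l2, a2 = a2, d2 = d2,
       ln = ln)
}

dense_branch_bwd <- function(dH, cache, P, key, G) {
  ln <- layernorm_bwd(dH, cache$ln, P[[paste0(key, ".ln.g")]])
  gacc(G, paste0(key, ".ln.g"), ln$dg)
  gacc(G, paste0(key, ".ln.b"), ln$db)
  d2 <- dropout_bwd(ln$dX, cache$d2)
  da2 <- gelu_bwd(d2, cache$l2$Y, cache$a2$Phi)
  l2 <- linear_bwd(da2, cache$l2, P[[paste0(key, ".d2.W")]])
  gacc(G, paste0(key, ".d2.W"), l2$dW)
  gacc(G, paste0(key, ".d2.b"), l2$db)
  d1 <- dropout_bwd(l2$dX, cache$d1)
  da1 <- gelu_bwd(d1, cache$l1$Y, cache$a1$Phi)
  l1 <- linear_bwd(da1, cache$l1, P[[paste0(key, ".d1.W")]])
  gacc(G, paste0(key, ".d1.W"), l1$dW)
  gacc(G, paste0(key, ".d1.b"), l1$db)
  l1$dX
}

# Full forward pass over a batch. `batch` holds (B*T) x D blocks X_v, X_c,
# X_m, X_t (only those in config$modalities are required), a B x T padding
# mask and optionally the targets y.
dcan_forward <- function(model, batch, train = FALSE) {
  cfg <- model$config
  P <- model$params
  B <- nrow(batch$mask)
  Tl <- ncol(batch$mask)
  mvec <- as.numeric(t(batch$mask))
  mods <- cfg$modalities
  cache <- list(B = B, T = Tl, mvec = mvec)

  H <- list()
  grp <- rep(seq_len(B), each = Tl)
  for (mod in mods) {
    key <- modality_keys[[mod]]
    if (mod == "voice") {
      X <- batch$X_v * mvec
      l1 <- bilstm_fwd(X, P, "v.lstm1", B, Tl)
      l2 <- bilstm_fwd(l1$H, P, "v.lstm2", B, Tl)
      att <- mha_fwd(l2$H, P, "v.att", B, Tl, cfg$encoder_heads, FALSE,
                     batch$mask)
      dp <- dropout_fwd(att$out, cfg$dropout_attention, train)
      ln <- layernorm_fwd(l2$H + dp$Y, P[["v.ln.g"]], P[["v.ln.b"]])
      H[[mod]] <- ln$Y
      cache$voice <- list(l1 = l1, l2 = l2, att = att, dp = dp, ln = ln)
    } else if (mod == "text") {
      # the narrative embedding is constant across a sample's timesteps,
      # and the encoder is position-wise: encode once per sample and tile
      br <- dense_branch_fwd(batch$X_t, P, key, cfg$dropout_encoder, train)
      H[[mod]] <- br$H[grp, , drop = FALSE] * mvec
      cache[[mod]] <- br
    } else {
      X <- batch[[paste0("X_", key)]] * mvec
      br <- dense_branch_fwd(X, P, key, cfg$dropout_encoder, train)
      H[[mod]] <- br$H
      cache[[mod]] <- br
    }
  }

  # fusion: per-modality self-attention, masked temporal mean pooling,
  # learned convex modality weights, weighted recombination
  nvalid <- rowSums(batch$mask)
  Amods <- list()
  pools <- list()
  fus_att <- list()
  for (mod in mods) {
    key <- modality_keys[[mod]]
    att <- mha_fwd(H[[mod]], P, paste0("fus.", key, ".att"), B, Tl,
                   cfg$fusion_heads, FALSE, batch$mask)
    Amods[[mod]] <- att$out
    pools[[mod]] <- rowsum(att$out * mvec, grp) / nvalid
    fus_att[[mod]] <- att
  }
  hc <- do.call(cbind, pools)
  logits <- add_bias(hc %*% t(P[["fus.Wc"]]), P[["fus.bc"]])
  alpha <- softmax_rows(logits)
  colnames(alpha) <- mods
  Hf <- 0
  for (j in seq_along(mods)) {
    Hf <- Hf + Amods[[mods[j]]] * rep(alpha[, j], each = Tl)
  }
  cache$fusion <- list(H = H, fus_att = fus_att, Amods = Amods, hc = hc,
                       alpha = alpha, nvalid = nvalid, grp = grp)

  # temporal block
  t1 <- bilstm_fwd(Hf, P, "tmp.lstm1", B, Tl)
  td1 <- dropout_fwd(t1$H, cfg$dropout_temporal, train)
  if (cfg$residual_per_layer) {
    S1 <- Hf + td1$Y
    t2 <- bilstm_fwd(S1, P, "tmp.lstm2", B, Tl)
    td2 <- dropout_fwd(t2$H, cfg$dropout_temporal, train)
    S2 <- S1 + td2$Y
  } else {
    t2 <- bilstm_fwd(td1$Y, P, "tmp.lstm2", B, Tl)
    td2 <- dropout_fwd(t2$H, cfg$dropout_temporal, train)
    S2 <- Hf + td2$Y
  }
  tatt <- mha_fwd(S2, P, "tmp.att", B, Tl, cfg$encoder_heads, TRUE,
                  batch$mask)
  tdp <- dropout_fwd(tatt$out, cfg$dropout_attention, train)
  tln <- layernorm_fwd(S2 + tdp$Y, P[["tmp.ln.g"]], P[["tmp.ln.b"]])
  cache$temporal <- list(Hf = Hf, t1 = t1, td1 = td1, t2 = t2, td2 = td2,
                         tatt = tatt, tdp = tdp, tln = tln)

  # prediction head on the final (target) timestep
  last_rows <- seq_len(B) * Tl
  hT <- tln$Y[last_rows, , drop = FALSE]
  h1 <- linear_fwd(hT, P[["head.d1.W"]], P[["head.d1.b"]])
  g1 <- gelu_fwd(h1$Y)
  hd1 <- dropout_fwd(g1$Y, cfg$dropout_head, train)
  h2l <- linear_fwd(hd1$Y, P[["head.d2.W"]], P[["head.d2.b"]])
  g2 <- gelu_fwd(h2l$Y)
  hd2 <- dropout_fwd(g2$Y, cfg$dropout_head, train)
  h3 <- linear_fwd(hd2$Y, P[["head.d3.W"]], P[["head.d3.b"]])
  g3 <- gelu_fwd(h3$Y)
  hln <- layernorm_fwd(g3$Y, P[["head.ln.g"]], P[["head.ln.b"]])
  out <- linear_fwd(hln$Y, P[["head.out.W"]], P[["head.out.b"]])
  cache$head <- list(last_rows = last_rows, h1 = h1, g1 = g1, hd1 = hd1,
                     h2l = h2l, g2 = g2, hd2 = hd2, h3 = h3, g3 = g3,
                     hln = hln, out = out)

  list(yhat = as.numeric(out$Y), alpha = alpha, cache = cache)
}

# Backward pass; dyhat is the length-B gradient of the loss wrt yhat.
# Returns the named gradient list.
dcan_backward <- function(model, fwd, dyhat) {
  cfg <- model$config
  P <- model$params
  cache <- fwd$cache
  B <- cache$B
  Tl <- cache$T
  G <- new.env()
  G$g <- list()

  hd <- cache$head
  dOut <- matrix(dyhat, ncol = 1)
  o <- linear_bwd(dOut, hd$out, P[["head.out.W"]])
  gacc(G, "head.out.W", o$dW); gacc(G, "head.out.b", o$db)
  ln <- layernorm_bwd(o$dX, hd$hln, P[["head.ln.g"]])
  gacc(G, "head.ln.g", ln$dg); gacc(G, "head.ln.b", ln$db)
  dg3 <- gelu_bwd(ln$dX, hd$h3$Y, hd$g3$Phi)
  l3 <- linear_bwd(dg3, hd$h3, P[["head.d3.W"]])
  gacc(G, "head.d3.W", l3$dW); gacc(G, "head.d3.b", l3$db)
  dd2 <- gelu_bwd(dropout_bwd(l3$dX, hd$hd2), hd$h2l$Y, hd$g2$Phi)
  l2 <- linear_bwd(dd2, hd$h2l, P[["head.d2.W"]])
  gacc(G, "head.d2.W", l2$dW); gacc(G, "head.d2.b", l2$db)
  dd1 <- gelu_bwd(dropout_bwd(l2$dX, hd$hd1), hd$h1$Y, hd$g1$Phi)
  l1 <- linear_bwd(dd1, hd$h1, P[["head.d1.W"]])
  gacc(G, "head.d1.W", l1$dW); gacc(G, "head.d1.b", l1$db)

  tp <- cache$temporal
  dHt <- matrix(0, B * Tl, cfg$hidden_dim)
  dHt[hd$last_rows, ] <- l1$dX
  tln <- layernorm_bwd(dHt, tp$tln, P[["tmp.ln.g"]])
  gacc(G, "tmp.ln.g", tln$dg); gacc(G, "tmp.ln.b", tln$db)
  dS2 <- tln$dX
  datt <- dropout_bwd(dS2, tp$tdp)
  dS2 <- dS2 + mha_bwd(datt, tp$tatt, P, "tmp.att", B, Tl, G)
  if (cfg$residual_per_layer) {
    dt2H <- dropout_bwd(dS2, tp$td2)
    dS1 <- dS2 + bilstm_bwd(dt2H, tp$t2, P, "tmp.lstm2", B, Tl, G)
    dt1H <- dropout_bwd(dS1, tp$td1)
    dHf <- dS1 + bilstm_bwd(dt1H, tp$t1, P, "tmp.lstm1", B, Tl, G)
  } else {
    dt2H <- dropout_bwd(dS2, tp$td2)
    dd1H <- bilstm_bwd(dt2H, tp$t2, P, "tmp.lstm2", B, Tl, G)
    dt1H <- dropout_bwd(dd1H, tp$td1)
    dHf <- dS2 + bilstm_bwd(dt1H, tp$t1, P, "tmp.lstm1", B, Tl, G)
  }

  fs <- cache$fusion
  mods <- cfg$modalities
  alpha <- fs$alpha
  dalpha <- matrix(0, B, length(mods))
  dAmods <- list()
  for (j in seq_along(mods)) {
    mod <- mods[j]
    av <- rep(alpha[, j], each = Tl)
    dAmods[[mod]] <- dHf * av
    contrib <- rowSums(fs$Amods[[mod]] * dHf)
    dalpha[, j] <- rowsum(contrib, fs$grp)
  }
  dlogits <- softmax_rows_bwd(dalpha, alpha)
  gacc(G, "fus.Wc", crossprod(dlogits, fs$hc))
  gacc(G, "fus.bc", colSums(dlogits))
  dhc <- dlogits %*% P[["fus.Wc"]]
  h <- cfg$hidden_dim
  dH <- list()
  for (j in seq_along(mods)) {
    mod <- mods[j]
    key <- modality_keys[[mod]]
    dpool <- dhc[, ((j - 1) * h + 1):(j * h), drop = FALSE]
    # mean-pool backward: distribute over valid timesteps
    dA_from_pool <- (dpool / fs$nvalid)[fs$grp, , drop = FALSE] * cache$mvec
    dA <- dAmods[[mod]] + dA_from_pool
    dH[[mod]] <- mha_bwd(dA, fs$fus_att[[mod]], P,
                         paste0("fus.", key, ".att"), B, Tl, G)
  }

  for (mod in mods) {
    key <- modality_keys[[mod]]
    if (mod == "voice") {
      vc <- cache$voice
      ln <- layernorm_bwd(dH[[mod]], vc$ln, P[["v.ln.g"]])
      gacc(G, "v.ln.g", ln$dg); gacc(G, "v.ln.b", ln$db)
      dres <- ln$dX
      datt <- dropout_bwd(dres, vc$dp)
      dH2 <- dres + mha_bwd(datt, vc$att, P, "v.att", B, Tl, G)
      dH1 <- bilstm_bwd(dH2, vc$l2, P, "v.lstm2", B, Tl, G)
      bilstm_bwd(dH1, vc$l1, P, "v.lstm1", B, Tl, G)
    } else if (mod == "text") {
      dB <- rowsum(dH[[mod]] * cache$mvec, fs$grp)
      dense_branch_bwd(dB, cache[[mod]], P, key, G)
    } else {
      dense_branch_bwd(dH[[mod]], cache[[mod]], P, key, G)
    }
  }
  G$g
}

#' Run the voice encoder on one sequence
#'
#' Stacked bidirectional LSTMs followed by multi-head self-attention with a
#' residual connection and layer normalisation. Exposed for inspection and
#' testing; inference mode (no dropout).
#'
#' @param model A `dcan_model` containing the voice branch.
#' @param X `T x D_v` voice feature matrix.
#' @return `T x hidden_dim` encoded sequence.
#' @export
encode_voice <- function(model, X) {
  stopifnot("voice" %in% model$config$modalities,
            ncol(X) == model$config$D[["voice"]])
  Tl <- nrow(X)
  mask <- matrix(1, 1, Tl)
  P <- model$params
  l1 <- bilstm_fwd(X, P, "v.lstm1", 1, Tl)
  l2 <- bilstm_fwd(l1$H, P, "v.lstm2", 1, Tl)
  att <- mha_fwd(l2$H, P, "v.att", 1, Tl, model$config$encoder_heads,
                 FALSE, mask)
  layernorm_fwd(l2$H + att$out, P[["v.ln.g"]], P[["v.ln.b"]])$Y
}

#' Run a position-wise dense encoder branch on one sequence
#'
#' Two stacked position-wise dense layers with GELU activations and layer
#' normalisation, applied independently per timestep (used for the
#' clinical, meta and text modalities). Inference mode.
#'
#' @param model A `dcan_model`.
#' @param X `T x D` input block.
#' @param branch One of `"clinical"`, `"meta"`, `"text"`.
#' @return `T x hidden_dim` encoded sequence.
#' @export
encode_dense_branch <- function(model, X,
                                branch = c("clinical", "meta", "text")) {
  branch <- match.arg(branch)
  stopifnot(branch %in% model$config$modalities,
            ncol(X) == model$config$D[[branch]])
  dense_branch_fwd(X, model$params, modality_keys[[branch]], 0, FALSE)$H
}

#' Dynamic attention fusion of encoded modality sequences
#'
#' Applies per-modality multi-head self-attention, pools each attended
#' sequence over time, derives convex modality weights from the
#' concatenated pooled context through a learned softmax layer, and
#' returns the weighted combination of the attended sequences together
#' with the weights.
#'
#' @param model A `dcan_model`.
#' @param H Named list of `T x hidden_dim` encoded sequences, one per
#'   modality in `model$config$modalities`.
#' @return List with `H_f` (`T x hidden_dim`) and `alpha` (named weights
#'   summing to 1).
#' @export
dynamic_fusion <- function(model, H) {
  cfg <- model$config
  mods <- cfg$modalities
  stopifnot(setequal(names(H), mods))
  Tl <- nrow(H[[1]])
  mask <- matrix(1, 1, Tl)
  P <- model$params
  Amods <- list(); pools <- list()
  for (mod in mods) {
    att <- mha_fwd(H[[mod]], P, paste0("fus.", modality_keys[[mod]], ".att"),
                   1, Tl, cfg$fusion_heads, FALSE, mask)
    Amods[[mod]] <- att$out
    pools[[mod]] <- colMeans(att$out)
  }
  hc <- matrix(unlist(pools), nrow = 1)
  alpha <- softmax_rows(add_bias(hc %*% t(P[["fus.Wc"]]), P[["fus.bc"]]))
  Hf <- 0
  for (j in seq_along(mods)) Hf <- Hf + alpha[1, j] * Amods[[mods[j]]]
  list(H_f = Hf, alpha = setNames(as.numeric(alpha), mods))
}

#' Causally masked temporal block
#'
#' Two stacked bidirectional LSTM layers with residual connections followed
#' by causally masked multi-head self-attention, a residual add and layer
#' normalisation. The attention sublayer's output at position i is exactly
#' invariant to value perturbations at positions j > i. Inference mode.
#'
#' @param model A `dcan_model`.
#' @param Hf `T x hidden_dim` fused sequence.
#' @return `T x hidden_dim` sequence.
#' @export
temporal_block <- function(model, Hf) {
  cfg <- model$config
  Tl <- nrow(Hf)
  mask <- matrix(1, 1, Tl)
  P <- model$params
  t1 <- bilstm_fwd(Hf, P, "tmp.lstm1", 1, Tl)
  S1 <- if (cfg$residual_per_layer) Hf + t1$H else t1$H
  t2 <- bilstm_fwd(S1, P, "tmp.lstm2", 1, Tl)
  S2 <- if (cfg$residual_per_layer) S1 + t2$H else Hf + t2$H
  att <- mha_fwd(S2, P, "tmp.att", 1, Tl, cfg$encoder_heads, TRUE, mask)
  layernorm_fwd(S2 + att$out, P[["tmp.ln.g"]], P[["tmp.ln.b"]])$Y
}

#' Prediction head
#'
#' Maps the final-timestep representation through three GELU dense layers,
#' layer normalisation and a linear output neuron to the scalar motor-UPDRS
#' prediction. Inference mode.
#'
#' @param model A `dcan_model`.
#' @param H `T x hidden_dim` output of [temporal_block()].
#' @return Scalar prediction.
#' @export
prediction_head <- function(model, H) {
  P <- model$params
  hT <- H[nrow(H), , drop = FALSE]
  a1 <- gelu(add_bias(hT %*% P[["head.d1.W"]], P[["head.d1.b"]]))
  a2 <- gelu(add_bias(a1 %*% P[["head.d2.W"]], P[["head.d2.b"]]))
  a3 <- gelu(add_bias(a2 %*% P[["head.d3.W"]], P[["head.d3.b"]]))
  n <- layernorm_fwd(a3, P[["head.ln.g"]], P[["head.ln.b"]])$Y
  as.numeric(n %*% P[["head.out.W"]] + P[["head.out.b"]])
}

#' @export
print.dcan_model <- function(x, ...) {
  cat("Dynamic context-aware network\n")
  cat("  modalities:", paste(x$config$modalities, collapse = ", "), "\n")
  cat("  hidden dim:", x$config$hidden_dim,
      "| heads:", x$config$encoder_heads, "\n")
  cat("  parameters:", format(x$n_parameters, big.mark = ","), "\n")
  invisible(x)
}
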