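test_that("gelu is the exact Gaussian-CDF form", {
  expect_equal(gelu(0), 0)
  expect_equal(gelu(10), 10, tolerance = 1e-6)
  # erf-based oracle for x = 1: 1 * Phi(1) via the complementary error fn
  phi1 <- 0.5 * pracma::erfc(-1 / sqrt(2))
  expect_equal(gelu(1), phi1, tolerance = 1e-12)
  x <- seq(-4, 4, by = 0.25)
  expect_equal(gelu(x), x * pnorm(x), tolerance = 1e-12)
  # compiled forward/backward agree with the R reference
  X <- matrix(seq(-3, 3, length.out = 12), 3, 4)
  cf <- dcanet:::gelu_fwd(X)
  expect_equal(cf$Y, gelu(X), tolerance = 1e-12)
  expect_equal(dcanet:::gelu_bwd(matrix(1, 3, 4), X, cf$Phi),
               pnorm(X) + X * dnorm(X), tolerance = 1e-12)
})

test_that("scaled dot-product attention matches its dense oracle", {
  set.seed(12)
  Q <- matrix(rnorm(32), 4, 8)
  K <- matrix(rnorm(32), 4, 8)
  V <- matrix(rnorm(32), 4, 8)
  S <- Q %*% t(K) / sqrt(8)
  A <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  expect_equal(scaled_dot_attention(Q, K, V), A %*% V, tolerance = 1e-12)
  # T = 1 returns V; zero queries/keys give the column mean of V
  expect_equal(scaled_dot_attention(Q[1, , drop = FALSE],
                                    K[1, , drop = FALSE],
                                    V[1, , drop = FALSE]),
               V[1, , drop = FALSE], tolerance = 1e-12)
  Z <- matrix(0, 4, 8)
  out <- scaled_dot_attention(Z, Z, V)
  for (i in 1:4) expect_equal(out[i, ], colMeans(V), tolerance = 1e-12)
})

test_that("the compiled multi-head kernel reproduces the reference per head", {
  set.seed(3)
  T <- 5; h <- 8; nh <- 2; dk <- h / nh
  Q <- matrix(rnorm(T * h), T, h)
  K <- matrix(rnorm(T * h), T, h)
  V <- matrix(rnorm(T * h), T, h)
  mask <- matrix(1, 1, T)
  core <- dcanet:::.mha_forward_cpp(Q, K, V, 1L, T, nh, FALSE, mask)
  for (head in seq_len(nh)) {
    cols <- ((head - 1) * dk + 1):(head * dk)
    ref <- scaled_dot_attention(Q[, cols], K[, cols], V[, cols])
    expect_equal(core$O[, cols], ref, tolerance = 1e-12)
  }
  # causal kernel equals the reference under causal_mask
  corec <- dcanet:::.mha_forward_cpp(Q, K, V, 1L, T, nh, TRUE, mask)
  for (head in seq_len(nh)) {
    cols <- ((head - 1) * dk + 1):(head * dk)
    ref <- scaled_dot_attention(Q[, cols], K[, cols], V[, cols],
                                mask = causal_mask(T))
    expect_equal(corec$O[, cols], ref, tolerance = 1e-12)
  }
})

test_that("causal mask allows exactly the past at every position", {
  expect_equal(causal_mask(1), matrix(TRUE, 1, 1))
  M <- causal_mask(6)
  expect_false(any(M[upper.tri(M)]))
  expect_true(all(M[lower.tri(M, diag = TRUE)]))
  for (i in 1:6) expect_equal(sum(M[i, ]), i)
})

test_that("encoders conserve shapes, normalise and act position-wise", {
  setup <- tiny_model_setup()
  m <- setup$model
  Tl <- setup$config$sequence_length
  X <- matrix(rnorm(Tl * 146), Tl, 146)
  Hv <- encode_voice(m, X)
  expect_equal(dim(Hv), c(Tl, 16))
  expect_identical(Hv, encode_voice(m, X))
  # layer-norm rows are standardised before the affine transform
  ln <- dcanet:::layernorm_fwd(matrix(rnorm(40), 5, 8), rep(1, 8),
                               rep(0, 8))
  expect_equal(rowMeans(ln$Y), rep(0, 5), tolerance = 1e-9)
  expect_equal(apply(ln$Y, 1, function(r) mean(r^2)), rep(1, 5),
               tolerance = 1e-2)
  # dense branches: perturbing timestep j changes only row j
  Xc <- matrix(rnorm(Tl * 9), Tl, 9)
  Hc <- encode_dense_branch(m, Xc, "clinical")
  expect_equal(dim(Hc), c(Tl, 16))
  Xc2 <- Xc
  Xc2[3, ] <- Xc2[3, ] + 1
  Hc2 <- encode_dense_branch(m, Xc2, "clinical")
  expect_equal(Hc[-3, ], Hc2[-3, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(Hc[3, ], Hc2[3, ])))
})

test_that("dynamic fusion returns convex weights and a convex combination", {
  setup <- tiny_model_setup()
  m <- setup$model
  Tl <- setup$config$sequence_length
  set.seed(9)
  H <- list(voice = matrix(rnorm(Tl * 16), Tl, 16),
            clinical = matrix(rnorm(Tl * 16), Tl, 16),
            meta = matrix(rnorm(Tl * 16), Tl, 16),
            text = matrix(rnorm(Tl * 16), Tl, 16))
  fus <- dynamic_fusion(m, H)
  expect_equal(sum(fus$alpha), 1, tolerance = 1e-6)
  expect_true(all(fus$alpha >= 0))
  expect_equal(dim(fus$H_f), c(Tl, 16))
  # convex hull check: H_f lies within the pointwise min/max of the
  # attended modality streams
  att <- lapply(names(H), function(mod) {
    dcanet:::mha_fwd(H[[mod]], m$params,
                     paste0("fus.", dcanet:::modality_keys[[mod]], ".att"),
                     1, Tl, m$config$fusion_heads, FALSE,
                     matrix(1, 1, Tl))$out
  })
  lo <- Reduce(pmin, att)
  hi <- Reduce(pmax, att)
  expect_true(all(fus$H_f >= lo - 1e-9 & fus$H_f <= hi + 1e-9))
  # identical attended streams collapse to that stream (sum(alpha) = 1)
  for (mod in names(H)[-1]) {
    for (suffix in c("Wq", "Wk", "Wv", "Wo", "bq", "bk", "bv", "bo")) {
      m$params[[paste0("fus.", dcanet:::modality_keys[[mod]], ".att.",
                       suffix)]] <-
        m$params[[paste0("fus.v.att.", suffix)]]
    }
  }
  Hsame <- list(voice = H$voice, clinical = H$voice, meta = H$voice,
                text = H$voice)
  fus2 <- dynamic_fusion(m, Hsame)
  common <- dcanet:::mha_fwd(H$voice, m$params, "fus.v.att", 1, Tl,
                             m$config$fusion_heads, FALSE,
                             matrix(1, 1, Tl))$out
  expect_equal(fus2$H_f, common, tolerance = 1e-9)
})

test_that("the temporal attention sublayer is causally masked", {
  setup <- tiny_model_setup()
  m <- setup$model
  Tl <- setup$config$sequence_length
  set.seed(4)
  Hf <- matrix(rnorm(Tl * 16), Tl, 16)
  # isolate the masked attention sublayer
  att1 <- dcanet:::mha_fwd(Hf, m$params, "tmp.att", 1, Tl,
                           m$config$encoder_heads, TRUE, matrix(1, 1, Tl))
  Hf2 <- Hf
  Hf2[Tl, ] <- Hf2[Tl, ] + 5
  att2 <- dcanet:::mha_fwd(Hf2, m$params, "tmp.att", 1, Tl,
                           m$config$encoder_heads, TRUE, matrix(1, 1, Tl))
  expect_equal(att1$out[1:(Tl - 1), ], att2$out[1:(Tl - 1), ],
               tolerance = 1e-12)
  # full temporal block keeps shape
  expect_equal(dim(temporal_block(m, Hf)), c(Tl, 16))
})

test_that("the prediction head is scalar, bias-recoverable and robust", {
  setup <- tiny_model_setup()
  m <- setup$model
  Tl <- setup$config$sequence_length
  H <- matrix(rnorm(Tl * 16), Tl, 16)
  expect_length(prediction_head(m, H), 1)
  m0 <- m
  m0$params[["head.out.W"]][] <- 0
  m0$params[["head.out.b"]] <- 3.5
  expect_equal(prediction_head(m0, H), 3.5)
  expect_true(is.finite(prediction_head(m, H * 1e3)))
  expect_true(is.finite(prediction_head(m, -H * 1e3)))
})

test_that("full model: alpha normalisation, padding invariance, determinism", {
  setup <- tiny_model_setup()
  sfs <- setup$fs
  m <- setup$model
  rows <- which(sfs$windows$target_idx == 3)[1:3]  # padded windows
  b <- dcanet:::gather_batch(sfs, rows)
  expect_true(any(b$mask == 0))
  f1 <- dcanet:::dcan_forward(m, b, train = FALSE)
  expect_equal(unname(rowSums(f1$alpha)), rep(1, 3), tolerance = 1e-6)
  expect_true(all(f1$alpha >= 0))
  # changing values at masked timesteps leaves predictions unchanged
  b2 <- b
  mvec <- as.numeric(t(b2$mask))
  b2$X_v[mvec == 0, ] <- 99
  b2$X_c[mvec == 0, ] <- -42
  b2$X_m[mvec == 0, ] <- 7
  f2 <- dcanet:::dcan_forward(m, b2, train = FALSE)
  expect_equal(f1$yhat, f2$yhat, tolerance = 1e-12)
  # inference is deterministic; training mode is seed-reproducible
  f3 <- dcanet:::dcan_forward(m, b, train = FALSE)
  expect_identical(f1$yhat, f3$yhat)
  set.seed(5); t1 <- dcanet:::dcan_forward(m, b, train = TRUE)$yhat
  set.seed(5); t2 <- dcanet:::dcan_forward(m, b, train = TRUE)$yhat
  expect_identical(t1, t2)
  # two builds with the same config report the same parameter count
  expect_equal(build_model(setup$config, seed = 1)$n_parameters,
               build_model(setup$config, seed = 2)$n_parameters)
})

test_that("analytic gradients match finite differences through the network", {
  setup <- tiny_model_setup()
  sfs <- setup$fs
  m <- setup$model
  b <- dcanet:::gather_batch(sfs, 1:3)
  fwd <- dcanet:::dcan_forward(m, b, train = FALSE)
  dy <- dcanet:::huber_grad_yhat(b$y, fwd$yhat, 2)
  g <- dcanet:::dcan_backward(m, fwd, dy)
  lossfn <- function(model) {
    f <- dcanet:::dcan_forward(model, b, train = FALSE)
    huber_loss(b$y, f$yhat, 2)
  }
  eps <- 1e-5
  set.seed(11)
  for (nm in c("v.lstm1.f.Wx", "v.att.Wq", "c.d1.W", "t.d2.W", "fus.Wc",
               "fus.m.att.Wv", "tmp.lstm2.b.Wh", "tmp.att.Wo", "head.d1.W",
               "head.out.W")) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(2, length(p)))) {
      m2 <- m; m2$params[[nm]][i] <- p[i] + eps
      m3 <- m; m3$params[[nm]][i] <- p[i] - eps
      fd <- (lossfn(m2) - lossfn(m3)) / (2 * eps)
      expect_equal(g[[nm]][i], fd, tolerance = 1e-3)
    }
  }
})

test_that("modality-subset models run and expose re-normalised weights", {
  setup <- tiny_model_setup()
  sfs <- setup$fs
  cfg <- model_config(hidden_dim = 16, fusion_heads = 2, encoder_heads = 2,
                      sequence_length = setup$config$sequence_length,
                      modalities = c("clinical", "text"))
  m <- build_model(cfg, seed = 3)
  b <- dcanet:::gather_batch(sfs, 1:4)
  f <- dcanet:::dcan_forward(m, b, train = FALSE)
  expect_length(f$yhat, 4)
  expect_equal(ncol(f$alpha), 2)
  expect_equal(unname(rowSums(f$alpha)), rep(1, 4), tolerance = 1e-6)
})
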