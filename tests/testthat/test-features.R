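test_that("quadratic-order denoising reproduces degree-<=2 polynomials", {
  x <- seq(0, 5, length.out = 24)
  for (coefs in list(c(3, 0, 0), c(1, -2, 0), c(0.5, 1.2, -0.7))) {
    y <- coefs[1] + coefs[2] * x + coefs[3] * x^2
    expect_equal(savgol_denoise(y, 5, 2), y, tolerance = 1e-9)
  }
  expect_equal(savgol_denoise(rep(4, 10), 5, 2), rep(4, 10),
               tolerance = 1e-12)
  # shorter than the window: unchanged
  expect_equal(savgol_denoise(c(1, 9, 2), 5, 2), c(1, 9, 2))
  expect_error(savgol_denoise(1:10, 4, 2), "odd")
})

test_that("denoiser matches a local least-squares oracle on random series", {
  set.seed(31)
  y <- rnorm(20)
  out <- savgol_denoise(y, 5, 2)
  for (i in 3:18) {
    w <- y[(i - 2):(i + 2)]
    tt <- -2:2
    fit <- lm(w ~ tt + I(tt^2))
    expect_equal(out[i], unname(coef(fit)[1]), tolerance = 1e-9)
  }
  # causal variant only uses trailing visits
  outc <- savgol_denoise(y, 5, 2, causal = TRUE)
  y2 <- y
  y2[15:20] <- y2[15:20] + 100
  outc2 <- savgol_denoise(y2, 5, 2, causal = TRUE)
  expect_equal(outc[1:14], outc2[1:14], tolerance = 1e-9)
})

test_that("temporal derivatives divide by actual day gaps", {
  tt <- c(0, 3, 10, 11, 20)
  y <- 2 * tt + 1
  d <- temporal_derivatives(y, tt)
  expect_equal(d$velocity, c(0, 2, 2, 2, 2), tolerance = 1e-12)
  expect_equal(d$acceleration[3:5], c(0, 0, 0), tolerance = 1e-12)
  expect_equal(temporal_derivatives(rep(5, 4), c(1, 2, 4, 8))$velocity,
               rep(0, 4))
  set.seed(5)
  yr <- rnorm(8)
  tr <- sort(runif(8, 0, 50))
  dr <- temporal_derivatives(yr, tr)
  expect_equal(dr$velocity[-1], diff(yr) / diff(tr), tolerance = 1e-12)
  expect_equal(dr$acceleration[-1], diff(dr$velocity) / diff(tr),
               tolerance = 1e-12)
  expect_error(temporal_derivatives(1:3, c(0, 1, 1)), "strictly increasing")
})

test_that("trailing rolling statistics match brute-force and e1071 oracles", {
  expect_equal(rolling_statistics(c(1, 2, 3), 3, "mean"), c(1, 1.5, 2))
  expect_equal(rolling_statistics(rep(7, 5), 3, "sd"), rep(0, 5))
  set.seed(8)
  y <- rnorm(15)
  for (w in c(3, 5)) {
    for (st in c("mean", "sd", "skewness", "kurtosis")) {
      got <- rolling_statistics(y, w, st)
      for (i in seq_along(y)) {
        win <- y[max(1, i - w + 1):i]
        n <- length(win)
        exp_val <- switch(st,
          mean = mean(win),
          sd = if (n < 2) 0 else sd(win),
          skewness = if (n < 3) 0 else e1071::skewness(win, type = 2),
          kurtosis = if (n < 4) 0 else e1071::kurtosis(win, type = 2))
        expect_equal(got[i], exp_val, tolerance = 1e-9)
      }
    }
  }
  expect_error(rolling_statistics(y, 3, "median"), "arg")
})

test_that("within-patient z-scores are stabilised and clipped", {
  expect_equal(within_patient_zscore(rep(3, 6)), rep(0, 6))
  y <- c(rep(0, 30), 1000)
  z <- within_patient_zscore(y, eps = 0.01, clip = 5)
  expect_equal(z[31], 5)
  set.seed(2)
  x <- rnorm(12)
  expect_equal(within_patient_zscore(x, 0.01, 5),
               pmin(pmax((x - mean(x)) / (sd(x) + 0.01), -5), 5),
               tolerance = 1e-12)
  # causal mode ignores later visits
  zc <- within_patient_zscore(x, causal = TRUE)
  x2 <- x
  x2[10:12] <- 99
  expect_equal(within_patient_zscore(x2, causal = TRUE)[1:9], zc[1:9])
})

test_that("composite voice indices follow their closed forms", {
  ci <- composite_indices(rep(0.005, 4), rep(0.03, 4), rep(20, 4),
                          rep(0.5, 4))
  expect_equal(ci$instability_index, rep(0, 4))
  expect_equal(ci$quality_ratio, rep(20 / 0.500001, 4), tolerance = 1e-9)
  set.seed(3)
  j <- runif(6); s <- runif(6); h <- runif(6, 10, 30); n <- runif(6, 0, 1)
  ci2 <- composite_indices(j, s, h, n)
  mm <- function(x) (x - min(x)) / (max(x) - min(x))
  expect_equal(ci2$instability_index, (mm(j) + mm(s)) / 2, tolerance = 1e-12)
  expect_equal(ci2$quality_ratio, h / (n + 1e-6), tolerance = 1e-12)
})

test_that("voice block has the 146-column manifest and composes sub-ops", {
  coh <- small_cohort(1, c(12, 12), seed = 21)
  s <- coh[[1]]
  cfg <- feature_config()
  V <- build_voice_features(s, cfg)
  expect_equal(ncol(V), 146)
  expect_equal(nrow(V), nrow(s$visits))
  expect_true(all(is.finite(V)))
  # column-by-column equality with composing the sub-operations directly
  x <- s$visits[["Shimmer"]]
  den <- savgol_denoise(x, cfg$savgol_window, cfg$savgol_polyorder)
  expect_equal(unname(V[, "Shimmer__raw"]), x)
  expect_equal(unname(V[, "Shimmer__denoised"]), den)
  expect_equal(unname(V[, "Shimmer__velocity"]),
               temporal_derivatives(den, s$visits$test_time)$velocity)
  expect_equal(unname(V[, "Shimmer__roll_mean"]),
               rolling_statistics(x, 3, "mean"))
  expect_equal(unname(V[, "Shimmer__roll_skew"]),
               rolling_statistics(x, 5, "skewness"))
  expect_equal(unname(V[, "Shimmer__zscore"]),
               within_patient_zscore(x, cfg$zscore_eps, cfg$zscore_clip))
  comp <- composite_indices(s$visits[["Jitter(%)"]], x, s$visits[["HNR"]],
                            s$visits[["NHR"]])
  expect_equal(unname(V[, "quality_ratio"]), comp$quality_ratio)
  # determinism
  expect_identical(V, build_voice_features(s, cfg))
  # degenerate single- and two-visit series stay finite
  for (k in 1:2) {
    short <- manual_series(seq_len(k) * 10)
    Vs <- build_voice_features(short, cfg)
    expect_true(all(is.finite(Vs)))
    expect_equal(nrow(Vs), k)
  }
})

test_that("clinical block uses only lagged UPDRS", {
  s <- manual_series(c(20, 22, 21, 25, 24, 26))
  C <- build_clinical_features(s)
  expect_equal(ncol(C), 9)
  expect_equal(unname(C[3, "updrs_lag1"]), 22)
  expect_equal(unname(C[3, "updrs_lag2"]), 20)
  expect_equal(unname(C[4, "delta"]), 21 - 22)
  expect_equal(unname(C[, "visit_number"]), 1:6)
  # perturbing the score at visit t leaves row t's features unchanged
  s2 <- manual_series(c(20, 22, 21, 99, 24, 26))
  C2 <- build_clinical_features(s2)
  expect_equal(C[4, ], C2[4, ])
  expect_equal(C[1:3, ], C2[1:3, ])
  # stage code from the lag-1 score, progression code from the dead band
  s3 <- manual_series(c(10, 30, 30.2, 28))
  C3 <- build_clinical_features(s3)
  expect_equal(unname(C3[, "stage_code"]), c(0, 0, 1, 1))
  expect_equal(unname(C3[, "progression_code"]), c(0, 0, 1, 0))
})

test_that("meta block carries constant demographics plus test time", {
  s <- manual_series(c(12, 15, 13), times = c(0, 6, 13), age = 71, sex = 1)
  M <- build_meta_features(s)
  expect_equal(dim(M), c(3, 3))
  expect_equal(unname(M[, "age"]), rep(71, 3))
  expect_equal(unname(M[, "sex"]), rep(1, 3))
  expect_equal(unname(M[, "test_time"]), c(0, 6, 13))
})

test_that("supervised windows count, pad and guard against leakage", {
  s <- manual_series(c(10, 11, 12, 13, 14))
  cfg <- feature_config(sequence_length = 3)
  blocks <- list(voice = build_voice_features(s, cfg),
                 clinical = build_clinical_features(s, cfg),
                 meta = build_meta_features(s))
  w <- make_supervised_windows(blocks, s, cfg)
  expect_length(w, 3)
  expect_equal(sapply(w, `[[`, "target_visit_index"), 3:5)
  expect_equal(sapply(w, `[[`, "y"), c(12, 13, 14))
  expect_true(all(sapply(w, function(x) nrow(x$X_v)) == 3))
  expect_equal(w[[1]]$mask, c(1, 1, 1))
  # long sequence length: left-padding and mask accounting
  cfg8 <- feature_config(sequence_length = 8)
  w8 <- make_supervised_windows(blocks, s, cfg8)
  expect_equal(w8[[1]]$mask, c(rep(0, 5), rep(1, 3)))
  expect_equal(unname(w8[[1]]$X_v[1:5, ]),
               matrix(0, 5, ncol(blocks$voice)))
  expect_error(make_supervised_windows(blocks, s,
                                       feature_config(sequence_length = 2)),
               "sequence_length")
})

test_that("no feature cell depends on target-or-later UPDRS", {
  set.seed(99)
  base <- rnorm(9, 25, 3)
  s <- manual_series(base)
  cfg <- feature_config(sequence_length = 4)
  build_blocks <- function(series) {
    list(voice = build_voice_features(series, cfg),
         clinical = build_clinical_features(series, cfg),
         meta = build_meta_features(series))
  }
  w <- make_supervised_windows(build_blocks(s), s, cfg)
  for (k in seq_along(w)) {
    i <- w[[k]]$target_visit_index
    pert <- base
    pert[i:length(pert)] <- pert[i:length(pert)] + rnorm(length(pert) - i + 1,
                                                         10, 5)
    sp <- manual_series(pert)
    wp <- make_supervised_windows(build_blocks(sp), sp, cfg)
    expect_equal(w[[k]]$X_v, wp[[k]]$X_v, tolerance = 1e-12)
    expect_equal(w[[k]]$X_c, wp[[k]]$X_c, tolerance = 1e-12)
    expect_equal(w[[k]]$X_m, wp[[k]]$X_m, tolerance = 1e-12)
    expect_false(isTRUE(all.equal(w[[k]]$y, wp[[k]]$y)))
  }
})
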