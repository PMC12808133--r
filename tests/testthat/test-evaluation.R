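test_that("regression metrics satisfy their identities", {
  y <- c(1, 2, 3, 4)
  m <- regression_metrics(y, y)
  expect_equal(unlist(m[c("MAE", "MSE", "RMSE", "R2")]),
               c(MAE = 0, MSE = 0, RMSE = 0, R2 = 1))
  m2 <- regression_metrics(y, rep(mean(y), 4))
  expect_equal(m2$R2, 0)
  # hand-computed four-point oracle
  yh <- c(1.5, 1.5, 3.5, 4.5)
  m3 <- regression_metrics(y, yh)
  expect_equal(m3$MAE, mean(abs(y - yh)))
  expect_equal(m3$MSE, mean((y - yh)^2))
  expect_equal(m3$RMSE^2, m3$MSE, tolerance = 1e-9)
  expect_equal(m3$R2, 1 - sum((y - yh)^2) / sum((y - mean(y))^2))
  flat <- regression_metrics(rep(2, 3), c(1, 2, 3))
  expect_false(flat$r2_defined)
  expect_true(is.na(flat$R2))
})

test_that("repeated patient-level folds keep every bookkeeping guarantee", {
  ids <- sprintf("S%02d", 1:42)
  tab <- repeated_patient_kfold(ids, k = 5, repeats = 8, seed = 3)
  expect_equal(nrow(tab), 42 * 8)
  for (r in 1:8) {
    rep_tab <- tab[tab$repetition == r, ]
    sizes <- table(rep_tab$fold)
    expect_true(all(sizes %in% c(8, 9)))
    expect_setequal(rep_tab$subject_id, ids)
    expect_equal(anyDuplicated(rep_tab$subject_id), 0)
  }
  # each patient tested exactly 8 times overall
  expect_true(all(table(tab$subject_id) == 8))
  # different repetitions shuffle differently
  expect_false(identical(tab$subject_id[tab$repetition == 1],
                         tab$subject_id[tab$repetition == 2]))
  # deterministic given the seed
  expect_identical(tab, repeated_patient_kfold(ids, 5, 8, 3))
  expect_error(repeated_patient_kfold(ids[1:3], k = 5), "exceeds")
})

test_that("cross-validation aggregation matches closed forms", {
  folds <- data.frame(MAE = c(1, 2, 3), MSE = c(1, 4, 9),
                      RMSE = c(1, 2, 3), R2 = c(0.9, 0.8, 0.7))
  s <- aggregate_cv(folds)
  rmse <- s[s$metric == "RMSE", ]
  expect_equal(rmse$mean, 2)
  expect_equal(rmse$sd, 1)
  expect_equal(rmse$range, 2)
  half <- qt(0.975, 2) * 1 / sqrt(3)
  expect_equal(rmse$ci_lo, 2 - half)
  expect_equal(rmse$ci_hi, 2 + half)
  expect_equal(rmse$cv_pct, 50)
  # CI contains the mean; identical metrics give zero-width CI
  same <- aggregate_cv(data.frame(MAE = rep(1, 5), MSE = rep(1, 5),
                                  RMSE = rep(1, 5), R2 = rep(0.5, 5)))
  expect_equal(same$ci_lo, same$mean)
  expect_equal(same$ci_hi, same$mean)
  # 40 random fold values against a direct recomputation
  set.seed(14)
  f40 <- data.frame(MAE = runif(40), MSE = runif(40), RMSE = runif(40),
                    R2 = runif(40))
  s40 <- aggregate_cv(f40)
  for (metric in c("MAE", "MSE", "RMSE", "R2")) {
    x <- f40[[metric]]
    row <- s40[s40$metric == metric, ]
    expect_equal(row$mean, mean(x))
    expect_equal(row$sd, sd(x))
    expect_equal(row$range, max(x) - min(x))
    expect_equal(row$ci_hi - row$ci_lo,
                 2 * qt(0.975, 39) * sd(x) / sqrt(40))
  }
})

test_that("paired t-test matches the textbook formula and flags ties", {
  a <- c(1, 2, 3, 4, 5)
  b <- c(1.2, 2.1, 3.4, 3.9, 5.3)
  res <- paired_t_test(a, b)
  d <- a - b
  t_manual <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$t, t_manual, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_manual), 4), tolerance = 1e-12)
  expect_false(res$tie)
  # antisymmetry
  expect_equal(paired_t_test(b, a)$t, -res$t, tolerance = 1e-12)
  # identical samples: exact tie, t = 0, p = 1
  tie <- paired_t_test(a, a)
  expect_true(tie$tie)
  expect_equal(tie$t, 0)
  expect_equal(tie$p, 1)
})

test_that("Kendall's W agrees with a brute-force computation", {
  # identical rankings across raters
  R <- matrix(rep(1:4, 3), 4, 3)
  expect_equal(kendalls_w(R), 1)
  # two exactly reversed rankings of 3 items: hand formula gives W = 0
  rev2 <- cbind(1:3, 3:1)
  Rsum <- rowSums(rev2)
  S <- sum((Rsum - mean(Rsum))^2)
  expect_equal(kendalls_w(rev2), 12 * S / (2^2 * (27 - 3)))
  expect_equal(kendalls_w(rev2), 0)
  # random ranks against the tie-corrected formula computed directly
  set.seed(6)
  for (rep in 1:5) {
    raw <- matrix(sample(1:3, 5 * 4, TRUE) + runif(20), 5, 4)
    got <- kendalls_w(raw)
    Rm <- apply(raw, 2, rank)
    S <- sum((rowSums(Rm) - mean(rowSums(Rm)))^2)
    Tj <- apply(Rm, 2, function(x) {
      tt <- table(x)
      sum(tt^3 - tt)
    })
    W <- 12 * S / (4^2 * (125 - 5) - 4 * sum(Tj))
    expect_equal(got, W, tolerance = 1e-12)
    expect_gte(got, 0)
    expect_lte(got, 1)
  }
  expect_error(kendalls_w(matrix(1, 1, 3)), "degenerate")
})

test_that("Bland-Altman statistics follow their formulas", {
  y <- c(10, 12, 14, 16)
  ba0 <- bland_altman(y, y)
  expect_equal(unlist(ba0), c(bias = 0, loa_lower = 0, loa_upper = 0))
  ba2 <- bland_altman(y, y + 2)
  expect_equal(ba2$bias, 2)
  expect_equal(ba2$loa_upper - ba2$loa_lower, 0)
  set.seed(8)
  yh <- y + rnorm(4)
  ba <- bland_altman(y, yh)
  d <- yh - y
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$loa_lower, mean(d) - 1.96 * sd(d))
  expect_equal(ba$loa_upper, mean(d) + 1.96 * sd(d))
})

test_that("fold execution never mixes patients across train and test", {
  coh <- small_cohort(6, c(8, 10), seed = 91)
  fs <- build_feature_set(coh, feature_config(sequence_length = 4))
  ids <- names(fs$patients)
  tab <- repeated_patient_kfold(ids, k = 3, repeats = 2, seed = 2)
  for (r in 1:2) {
    for (f in 1:3) {
      test_ids <- tab$subject_id[tab$repetition == r & tab$fold == f]
      train_ids <- setdiff(ids, test_ids)
      expect_length(intersect(train_ids, test_ids), 0)
    }
  }
  expect_error(dcanet:::run_fold(fs, ids, ids[1], model_config(),
                                 train_config(), 1),
               "intersect|disjoint|TRUE")
})

test_that("a small cross-validation run produces a coherent report", {
  coh <- small_cohort(6, c(10, 12), seed = 55)
  cv <- cv_spec(k = 3, repeats = 1, seed = 4, windows_per_patient = 8,
                feature_config = feature_config(sequence_length = 4))
  mcfg <- model_config(hidden_dim = 8, fusion_heads = 2, encoder_heads = 2,
                       sequence_length = 4)
  tcfg <- train_config(max_epochs = 2, early_stop_patience = 2)
  rep <- run_cv(coh, mcfg, tcfg, cv)
  expect_s3_class(rep, "cv_report")
  expect_equal(nrow(rep$folds), 3)
  expect_equal(rep$folds$RMSE^2, rep$folds$MSE, tolerance = 1e-9)
  expect_true(all(rep$folds$R2 <= 1))
  summ <- rep$summary
  expect_equal(summ$range, summ$max - summ$min, tolerance = 1e-12)
  expect_true(all(summ$ci_lo <= summ$mean + 1e-12 &
                    summ$mean <= summ$ci_hi + 1e-12))
})

test_that("the ablation runner shares folds and reports percent changes", {
  coh <- small_cohort(6, c(10, 12), seed = 65)
  cv <- cv_spec(k = 3, repeats = 1, seed = 9, windows_per_patient = 6,
                feature_config = feature_config(sequence_length = 4))
  tcfg <- train_config(max_epochs = 2, early_stop_patience = 2)
  mcfg <- ablation_model_config(sequence_length = 4, hidden_dim = 8,
                                fusion_heads = 2, encoder_heads = 2)
  res <- ablation_runner(coh, cv,
                         configurations = list(
                           "Clinical only" = "clinical",
                           "Clinical+Meta" = c("clinical", "meta")),
                         model_cfg = mcfg, train_cfg = tcfg)
  expect_equal(nrow(res$table), 2)
  expect_equal(res$table$pct_change_vs_clinical[1], 0)
  f1 <- res$folds[["Clinical only"]]
  f2 <- res$folds[["Clinical+Meta"]]
  # identical fold assignments across configurations
  expect_equal(f1[, c("repetition", "fold")], f2[, c("repetition", "fold")])
  expect_equal(dim(res$rank_matrix), c(2, 3))
  expect_error(ablation_runner(coh, cv,
                               configurations = list(x = "imaging")),
               "unknown modality")
  # percent-change formula on injected RMSE means
  expect_equal(100 * (0.6727 - 0.7273) / 0.7273, -7.5, tolerance = 0.01)
})

test_that("classical baselines run under identical folds", {
  skip_if_not_installed("glmnet")
  skip_if_not_installed("ranger")
  skip_if_not_installed("xgboost")
  coh <- small_cohort(6, c(10, 12), seed = 75)
  cv <- cv_spec(k = 2, repeats = 1, seed = 13, windows_per_patient = 8,
                feature_config = feature_config(sequence_length = 4))
  res <- baseline_harness(coh, cv,
                          baselines = c("ridge", "random_forest"))
  expect_setequal(unique(res$folds$baseline), c("ridge", "random_forest"))
  expect_equal(nrow(res$folds), 4)
  expect_true(all(is.finite(res$folds$RMSE)))
  expect_true(all(c("baseline", "MAE", "RMSE", "R2") %in%
                    names(res$summary)))
  # ridge with near-infinite regularisation predicts ~ the training mean
  fs <- build_feature_set(coh, cv$feature_config)
  sfs <- apply_scalers(fs, fit_scalers(fs))
  rows <- seq_len(nrow(sfs$windows))
  X <- dcanet:::flatten_windows(sfs, rows)
  y <- sfs$windows$y
  fit <- glmnet::glmnet(X, y, alpha = 0, lambda = 1e9)
  pred <- as.numeric(predict(fit, X))
  expect_equal(pred, rep(mean(y), length(y)), tolerance = 0.05)
  expect_lte(abs(regression_metrics(y, pred)$R2), 0.05)
})
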