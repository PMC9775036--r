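sim_small <- generate_survival_data(generator_config(
  n_samples = 110, n_genes = 30, n_causal = 4, random_seed = 21,
  unlabeled_fraction = 0, test_fraction = 0.25))
train_small <- partition_subsets(sim_small)$labeled
test_small <- partition_subsets(sim_small)$test

test_that("level augmentation adds one feature per forest to the gene set", {
  m <- fit_cascade(train_small, tiny_cascade_cfg(1))
  expect_equal(m$levels[[1]]$n_features, n_genes(train_small) + 4)
  if (length(m$levels) > 1)
    expect_equal(m$levels[[2]]$n_features, n_genes(train_small) + 4)
  # configurable multi-feature augmentation
  m3 <- fit_cascade(train_small, tiny_cascade_cfg(1, features_per_forest = 3,
                                                  max_levels = 1))
  expect_equal(m3$levels[[1]]$n_features, n_genes(train_small) + 4 * 3)
})

test_that("fits are bit-reproducible under a fixed seed", {
  m1 <- fit_cascade(train_small, tiny_cascade_cfg(5))
  m2 <- fit_cascade(train_small, tiny_cascade_cfg(5))
  expect_identical(cascade_predict_risk(m1, test_small$X),
                   cascade_predict_risk(m2, test_small$X))
  expect_identical(m1$val_history, m2$val_history)
})

test_that("prediction is id-aligned and consistent with the stored baseline", {
  m <- fit_cascade(train_small, tiny_cascade_cfg(2))
  eta <- cascade_predict_risk(m, train_small$X)
  # self-consistency: training-set predictions are the baseline's eta
  expect_equal(eta, m$train_eta, tolerance = 1e-12)

  # permuting gene columns (ids intact) changes nothing
  perm <- sample(n_genes(test_small))
  expect_equal(cascade_predict_risk(m, test_small$X[, perm]),
               cascade_predict_risk(m, test_small$X), tolerance = 1e-12)

  # duplicated sample rows get duplicated scores
  X2 <- test_small$X[c(1, 1, 2), ]
  rownames(X2) <- c("a", "b", "c")
  eta2 <- cascade_predict_risk(m, X2)
  expect_equal(unname(eta2[1]), unname(eta2[2]), tolerance = 1e-12)

  # unknown/missing genes are reported by symbol
  expect_error(cascade_predict_risk(m, test_small$X[, -3]),
               test_small$gene_ids[3])
})

test_that("survival curves from the cascade are valid and risk-ordered", {
  m <- fit_cascade(train_small, tiny_cascade_cfg(3, max_levels = 1))
  times <- c(0, quantile(train_small$time, c(0.25, 0.5, 0.75)))
  S <- cascade_predict_survival(m, test_small$X, times)
  expect_equal(unname(S[, 1]), rep(1, nrow(S)))
  expect_true(all(S > 0 & S <= 1))
  expect_true(all(diff(t(S)) <= 1e-12))
  eta <- cascade_predict_risk(m, test_small$X)
  hi <- which.max(eta); lo <- which.min(eta)
  expect_true(all(S[hi, -1] <= S[lo, -1] + 1e-12))
  # closed-form composition with the Breslow baseline
  H <- dfsc:::eval_cumhaz(m$baseline, times)
  expect_equal(S, exp(-outer(exp(eta), H)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("a depth-limited fit equals the truncated deeper cascade", {
  m1 <- fit_cascade(train_small, tiny_cascade_cfg(4, max_levels = 1))
  m2 <- fit_cascade(train_small, tiny_cascade_cfg(4, max_levels = 2, patience = 1))
  t1 <- truncate_cascade(m2, 1)
  expect_equal(cascade_predict_risk(m1, test_small$X),
               cascade_predict_risk(t1, test_small$X), tolerance = 1e-12)
  expect_equal(m1$baseline$cumulative_hazard, t1$baseline$cumulative_hazard,
               tolerance = 1e-12)
})

test_that("retained depth maximizes the validation history", {
  m <- fit_cascade(train_small, tiny_cascade_cfg(6, max_levels = 3, patience = 2))
  expect_equal(unname(m$best_val_cindex), max(m$val_history))
  expect_equal(length(m$levels), which.max(m$val_history))
})

test_that("degenerate training inputs are rejected", {
  expect_error(fit_cascade(subset_samples(train_small, 1:10), tiny_cascade_cfg(1)),
               ">= 20")
  few_events <- train_small
  few_events$event[] <- 0
  few_events$event[1:3] <- 1
  expect_error(fit_cascade(few_events, tiny_cascade_cfg(1)), ">= 5 events")
})

test_that("out-of-fold forest features do not memorize pure-noise outcomes", {
  # the prediction features a forest feeds forward must be honest: on data
  # with no signal, in-fold features rank the training outcomes optimistically
  # while out-of-fold features sit at chance
  c_oof <- c_leak <- numeric(8)
  for (s in 1:8) {
    sim <- generate_survival_data(generator_config(
      n_samples = 80, n_genes = 40, n_causal = 0, random_seed = 400 + s,
      unlabeled_fraction = 0, test_fraction = 0))
    tr <- sim$dataset
    cfg <- tiny_cascade_cfg(s, max_levels = 1)
    ft <- unique(quantile(tr$time, probs = seq(0.1, 0.9, length.out = 10)))
    full <- dfsc:::fit_survival_forest(tr$X, tr$time, tr$event, "standard",
                                       cfg, 1000 + s)
    f_in <- dfsc:::forest_features(full, tr$X, ft, numeric(0))
    fold <- dfsc:::stratified_folds(tr$event, 3, 2000 + s)
    f_out <- numeric(n_samples(tr))
    for (fd in 1:3) {
      hold <- which(fold == fd)
      sub <- dfsc:::fit_survival_forest(tr$X[-hold, ], tr$time[-hold],
                                        tr$event[-hold], "standard", cfg,
                                        3000 + 10 * s + fd)
      f_out[hold] <- dfsc:::forest_features(sub, tr$X[hold, , drop = FALSE],
                                            ft, numeric(0))
    }
    c_leak[s] <- concordance_index(tr$time, tr$event, drop(f_in))
    c_oof[s] <- concordance_index(tr$time, tr$event, f_out)
  }
  expect_lt(abs(mean(c_oof) - 0.5), 0.05)
  expect_gt(mean(c_leak), mean(c_oof) + 0.1)
})
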