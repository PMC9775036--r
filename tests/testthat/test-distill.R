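test_that("soften is a temperature-scaled softmax with the right limits", {
  expect_equal(soften(c(0, 0), 1), c(0.5, 0.5))
  expect_equal(soften(c(2, 0), 2), c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-12)
  # high-temperature limit: uniform
  expect_equal(soften(c(5, -5), 1000), c(0.5, 0.5), tolerance = 1e-2)
  # low-temperature limit: one-hot at the argmax
  expect_equal(soften(c(1, 0.5, -2), 1e-4), c(1, 0, 0), tolerance = 1e-12)
  # shift invariance
  s <- rnorm(5)
  expect_equal(soften(s + 100, 2), soften(s, 2), tolerance = 1e-12)
  # matrix input is handled row-wise
  M <- rbind(c(2, 0), c(0, 0))
  expect_equal(soften(M, 2), rbind(soften(c(2, 0), 2), c(0.5, 0.5)),
               tolerance = 1e-12)
  expect_error(soften(c(1, 2), 0), "temperature")
  expect_error(soften(c(1, 2), -1), "temperature")
})

test_that("distillation loss is soft cross-entropy with the 0 log 0 convention", {
  expect_equal(distillation_loss(c(0.5, 0.5), c(0.5, 0.5)), log(2), tolerance = 1e-12)
  expect_equal(distillation_loss(c(1, 0), c(1, 0)), 0)
  expect_equal(distillation_loss(c(0.8, 0.2), c(0.6, 0.4)),
               -(0.8 * log(0.6) + 0.2 * log(0.4)), tolerance = 1e-12)
  expect_error(distillation_loss(c(0.7, 0.2), c(0.5, 0.5)), "normalized")
  expect_error(distillation_loss(c(0.5, 0.5), c(0.5, 0.5, 0)), "shape")
})

test_that("Gibbs' inequality: cross-entropy is minimized at the teacher", {
  set.seed(404)
  for (rep in 1:300) {
    k <- sample(2:6, 1)
    P <- soften(rnorm(k, sd = 2), 1)
    Q <- soften(rnorm(k, sd = 2), 1)
    hP <- distillation_loss(P, P)  # entropy of P
    expect_equal(hP, -sum(ifelse(P > 0, P * log(P), 0)), tolerance = 1e-12)
    expect_gte(distillation_loss(P, Q) + 1e-12, hP)
  }
})

sim_ssl <- generate_survival_data(generator_config(
  n_samples = 140, n_genes = 30, n_causal = 4, beta_magnitude = 1.2,
  random_seed = 31, unlabeled_fraction = 0.3, test_fraction = 0.2))
parts_ssl <- partition_subsets(sim_ssl)
teacher <- fit_cascade(parts_ssl$labeled, tiny_cascade_cfg(7, max_levels = 1))

test_that("pseudo-labels impute median survival and respect confidence gating", {
  pl <- pseudo_label(teacher, parts_ssl$unlabeled,
                     distillation_config(confidence_threshold = 0))
  expect_equal(nrow(pl), n_samples(parts_ssl$unlabeled))
  expect_true(all(is.finite(pl$imputed_time) & pl$imputed_time > 0))
  expect_true(all(pl$imputed_event == 1))
  soft <- attr(pl, "soft")
  expect_equal(unname(rowSums(soft)), rep(1, nrow(soft)), tolerance = 1e-9)
  expect_equal(unname(apply(soft, 1, max)), pl$confidence, tolerance = 1e-12)

  # the imputed time is where the teacher's curve crosses one half
  eta <- cascade_predict_risk(teacher, parts_ssl$unlabeled$X)
  grid <- teacher$baseline$event_times
  S <- predict_survival_function(eta, teacher$baseline, grid)
  i <- 1
  expected <- if (any(S[i, ] <= 0.5)) grid[which(S[i, ] <= 0.5)[1]] else max(grid)
  expect_equal(pl$imputed_time[i], expected)

  # teacher's highest-risk unlabeled sample is imputed an earlier time than
  # its lowest-risk one
  expect_lte(pl$imputed_time[which.max(eta)], pl$imputed_time[which.min(eta)])

  # degenerate gates
  expect_equal(nrow(pseudo_label(teacher, parts_ssl$unlabeled,
                                 distillation_config(confidence_threshold = 1))), 0)
  empty <- subset_samples(parts_ssl$unlabeled, integer(0))
  expect_equal(nrow(pseudo_label(teacher, empty, distillation_config())), 0)

  # as-censored sensitivity option
  plc <- pseudo_label(teacher, parts_ssl$unlabeled,
                      distillation_config(confidence_threshold = 0,
                                          pseudo_as_censored = TRUE))
  expect_true(all(plc$imputed_event == 0))
})

test_that("the semi-supervised loop degenerates exactly to the supervised fit", {
  cfg <- tiny_cascade_cfg(9, max_levels = 1)
  sup <- fit_cascade(parts_ssl$labeled, cfg)

  # zero unlabeled samples
  empty <- subset_samples(parts_ssl$unlabeled, integer(0))
  expect_message(m0 <- fit_dfsc(parts_ssl$labeled, empty, cfg, distillation_config()),
                 "supervised")
  expect_identical(cascade_predict_risk(m0, parts_ssl$test$X),
                   cascade_predict_risk(sup, parts_ssl$test$X))

  # confidence threshold of 1 rejects every pseudo-label
  m1 <- fit_dfsc(parts_ssl$labeled, parts_ssl$unlabeled, cfg,
                 distillation_config(confidence_threshold = 1))
  expect_identical(cascade_predict_risk(m1, parts_ssl$test$X),
                   cascade_predict_risk(sup, parts_ssl$test$X))
  expect_equal(m1$dfsc$selected_round, 0L)
})

test_that("the returned model never loses to the supervised fit on validation", {
  cfg <- tiny_cascade_cfg(13, max_levels = 1)
  m <- fit_dfsc(parts_ssl$labeled, parts_ssl$unlabeled, cfg,
                distillation_config(confidence_threshold = 0.5, max_rounds = 2))
  h <- m$dfsc$history
  expect_equal(max(h$val_cindex), h$val_cindex[h$round == m$dfsc$selected_round])
  expect_gte(h$val_cindex[h$round == m$dfsc$selected_round], h$val_cindex[1])

  # pseudo-labeled rows never enter the labeled validation split
  expect_length(intersect(paste0(".pseudo_", m$dfsc$audit$sample_id),
                          m$validation_ids), 0)
  expect_true(all(m$dfsc$audit$sample_id %in% parts_ssl$unlabeled$sample_ids))
})
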