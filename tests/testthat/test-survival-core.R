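make_ds <- function(time, event) {
  n <- length(time)
  survival_dataset(matrix(0, n, 1), time = time, event = event,
                   sample_ids = paste0("s", seq_len(n)), gene_ids = "g1")
}

test_that("risk sets follow the time_i >= time_j convention, ties included", {
  ds <- make_ds(c(1, 2, 3), c(1, 1, 1))
  expect_setequal(risk_set(ds, 1), 1:3)
  expect_setequal(risk_set(ds, 3), 3)

  ds_tie <- make_ds(c(2, 2, 5), c(1, 1, 1))
  expect_setequal(risk_set(ds_tie, 1), 1:3)

  ds_unl <- survival_dataset(matrix(0, 2, 1), time = c(1, NA), event = c(1, NA))
  expect_error(risk_set(ds_unl, 2), "unlabeled")
})

test_that("log partial likelihood matches hand values and handles censoring", {
  # two subjects, both events, eta = 0: 1/2 * 1/1
  expect_equal(cox_partial_likelihood(c(0, 0), make_ds(c(1, 2), c(1, 1))),
               log(0.5), tolerance = 1e-12)
  # a lone uncensored subject is its own risk set
  expect_equal(cox_partial_likelihood(3.7, make_ds(5, 1)), 0)
  # censored subjects only enter risk sets
  ds <- make_ds(c(1, 2, 3), c(1, 0, 1))
  eta <- c(1, 0, -1)
  expect_equal(cox_partial_likelihood(eta, ds), bf_cox_loglik(eta, ds$time, ds$event),
               tolerance = 1e-12)
  # empty product for all-censored data
  expect_warning(ll <- cox_partial_likelihood(c(0, 0), make_ds(c(1, 2), c(0, 0))),
                 "censored")
  expect_identical(ll, 0)
})

test_that("log partial likelihood agrees with brute-force risk-set enumeration", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(3:30, 1)
    d <- random_surv_vectors(n)
    if (sum(d$event) == 0) d$event[1] <- 1
    eta <- rnorm(n, sd = 2)
    ds <- make_ds(d$time, d$event)
    expect_equal(cox_partial_likelihood(eta, ds),
                 bf_cox_loglik(eta, d$time, d$event), tolerance = 1e-10)
    # translation invariance of the partial likelihood
    expect_equal(cox_partial_likelihood(eta + 13.7, ds),
                 cox_partial_likelihood(eta, ds), tolerance = 1e-10)
  }
})

test_that("Breslow baseline increments are d_k over the risk-set exp sum", {
  ds <- make_ds(c(1, 2, 3, 4), c(1, 0, 0, 0))
  bl <- breslow_baseline(rep(0, 4), ds)
  expect_equal(bl$event_times, 1)
  expect_equal(bl$cumulative_hazard, 1 / 4)

  expect_error(breslow_baseline(rep(0, 2), make_ds(c(1, 2), c(0, 0))), "no events")
})

test_that("shifting eta rescales the baseline but leaves survival invariant", {
  set.seed(7)
  d <- random_surv_vectors(20); d$event[1] <- 1
  ds <- make_ds(d$time, d$event)
  eta <- rnorm(20)
  bl0 <- breslow_baseline(eta, ds)
  bl1 <- breslow_baseline(eta + 2, ds)
  expect_equal(bl1$cumulative_hazard, bl0$cumulative_hazard * exp(-2), tolerance = 1e-10)
  t_eval <- c(0, sort(d$time))
  expect_equal(predict_survival_function(eta + 2, bl1, t_eval),
               predict_survival_function(eta, bl0, t_eval), tolerance = 1e-10)
})

test_that("Breslow cumulative hazard equals Nelson-Aalen when eta = 0 (no ties)", {
  set.seed(11)
  time <- sort(rexp(25)) + cumsum(rep(1e-4, 25))  # enforce distinct times
  event <- rbinom(25, 1, 0.7); event[1] <- 1
  ds <- make_ds(time, event)
  bl <- breslow_baseline(rep(0, 25), ds)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, ctype = 1)
  na <- fit$cumhaz[fit$n.event > 0]
  expect_equal(bl$cumulative_hazard, na, tolerance = 1e-10)
})

test_that("survival predictions are proper monotone curves", {
  ds <- make_ds(c(1, 2, 3, 4), c(1, 1, 0, 1))
  eta <- c(0.5, -0.5, 0, 1)
  bl <- breslow_baseline(eta, ds)

  expect_equal(drop(predict_survival_function(eta, bl, 0)), rep(1, 4))
  # closed form at a fixed cumulative hazard
  bl_fixed <- structure(list(event_times = 1, cumulative_hazard = 0.5),
                        class = "baseline_hazard")
  expect_equal(drop(predict_survival_function(0, bl_fixed, 2)), exp(-0.5),
               tolerance = 1e-12)

  S <- predict_survival_function(eta, bl, seq(0, 5, by = 0.25))
  expect_true(all(S > 0 & S <= 1))
  expect_true(all(diff(t(S)) <= 1e-12))              # non-increasing in t
  ord <- order(eta)                                   # monotone decreasing in eta
  expect_true(all(diff(S[ord, ncol(S)]) <= 1e-12))
  expect_error(predict_survival_function(eta, bl, -1), "non-negative")
})

test_that("dataset construction validates outcomes and identifiers", {
  X <- matrix(rnorm(6), 3, 2)
  expect_error(survival_dataset(X, time = c(-1, 1, 2), event = c(1, 1, 0)),
               "non-negative")
  expect_error(survival_dataset(X, time = c(1, 1, 2), event = c(2, 1, 0)), "0 or 1")
  expect_error(survival_dataset(X, time = c(1, 2), event = c(1, 0)), "one entry")
  Xna <- X; Xna[1, 1] <- NA
  expect_error(survival_dataset(Xna, time = c(1, 1, 2), event = c(1, 1, 0)), "missing")
  ds <- survival_dataset(X, time = c(1, NA, 2), event = c(1, NA, 0))
  expect_equal(ds$labeled_mask, c(TRUE, FALSE, TRUE))
  expect_equal(n_samples(labeled_subset(ds)), 2)
})

test_that("tabular loader round-trips expression and clinical files", {
  dir <- withr::local_tempdir()
  sim <- generate_survival_data(generator_config(
    n_samples = 30, n_genes = 8, n_causal = 2, random_seed = 5))
  write_simulation(sim, dir)
  ds <- read_survival_data(file.path(dir, "expr.tsv"), file.path(dir, "clinical.tsv"))
  expect_equal(ds$X, sim$dataset$X)
  expect_equal(ds$time, sim$dataset$time)
  expect_equal(ds$labeled_mask, sim$dataset$labeled_mask)
  # genes-as-rows dialect
  tx <- data.frame(gene_id = ds$gene_ids, t(ds$X), check.names = FALSE)
  tfile <- file.path(dir, "expr_t.tsv")
  write.table(tx, tfile, sep = "\t", quote = FALSE, row.names = FALSE)
  ds_t <- read_survival_data(tfile, file.path(dir, "clinical.tsv"), transpose = TRUE)
  expect_equal(ds_t$X, ds$X)
})
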