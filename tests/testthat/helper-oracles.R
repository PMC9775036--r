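# Independent brute-force oracles and small fixtures used across tests.
# These deliberately re-derive quantities with explicit loops so they
# cannot share bugs with the vectorized implementations they check.

# Cox log partial likelihood by explicit risk-set enumeration (Breslow ties).
bf_cox_loglik <- function(eta, time, event) {
  total <- 0
  for (j in seq_along(time)) {
    if (event[j] == 1) {
      R <- which(time >= time[j])
      total <- total + eta[j] - log(sum(exp(eta[R])))
    }
  }
  total
}

# Harrell concordance by explicit pair enumeration.
bf_cindex <- function(time, event, risk) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# Random right-censored dataset on vectors (possibly with ties).
random_surv_vectors <- function(n, tie_prob = 0.3) {
  time <- round(rexp(n, 0.2), digits = if (runif(1) < tie_prob) 0 else 3) + 0.5
  event <- rbinom(n, 1, 0.7)
  list(time = time, event = event)
}

toy_labeled_dataset <- function(n = 40, p = 10, seed = 42, beta = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%03d", 1:n), sprintf("g%03d", 1:p)))
  eta <- if (is.null(beta)) rep(0, n) else drop(X %*% beta)
  time <- rexp(n, 0.2 * exp(eta)) + 0.01
  event <- rbinom(n, 1, 0.75)
  survival_dataset(X, time = time, event = event)
}

# Small cascade configuration keeping unit tests fast.
tiny_cascade_cfg <- function(seed = 1, ...) {
  args <- list(n_trees_per_forest = 20, max_levels = 2, oof_folds = 3,
               n_penalties = 4, random_seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(cascade_config, args)
}

# Desk-scale benchmark configuration used by the simulation-based checks.
bench_cascade_cfg <- function(seed = 1, ...) {
  args <- list(n_trees_per_forest = 50, max_levels = 2, patience = 1,
               oof_folds = 3, random_seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(cascade_config, args)
}

bench_distill_cfg <- function(seed = 1, ...) {
  distillation_config(max_rounds = 2, random_seed = seed, ...)
}
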