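#' Configuration for the synthetic survival-data generator
#'
#' Defines a gene-expression-like cohort with known prognostic ground
#' truth: block-correlated standardized Gaussian expression, a sparse set
#' of truly prognostic genes acting through a proportional-hazards model,
#' right censoring tuned to a target rate, and a labeled / unlabeled /
#' test partition shaped like a semi-supervised study design.
#'
#' @param n_samples Total cohort size.
#' @param n_genes Number of genes `p` (typically `p >> n`).
#' @param n_causal Number of truly prognostic genes.
#' @param beta_magnitude Absolute log-hazard-ratio per unit expression for
#'   causal genes (signs alternate).
#' @param baseline_rate Baseline hazard rate `lambda0 > 0` (events per
#'   study time unit for a sample with `eta = 0`).
#' @param censoring_rate Target expected fraction of censored samples, in
#'   `[0, 1)`.
#' @param correlation_block_size,block_rho Genes are grouped into
#'   exchangeable-correlation blocks of this size with pairwise
#'   correlation `block_rho` (co-expression emulation).
#' @param unlabeled_fraction,test_fraction Fractions of the cohort whose
#'   outcomes are withheld (unlabeled pool) and held out for testing; the
#'   remainder is labeled training data.
#' @param weibull_shape Shape of the event-time distribution (1 =
#'   exponential). Censoring times share the shape, so the censoring rate
#'   has a closed form at any shape.
#' @param n_labeled,n_unlabeled,n_test Optional explicit partition counts;
#'   when given they override the fractions (used by [tcga_like_preset()]).
#' @param random_seed Integer seed; the full generation path is
#'   deterministic given the config.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_samples = 300, n_genes = 1000, n_causal = 10,
                             beta_magnitude = 1, baseline_rate = 0.1,
                             censoring_rate = 0.3,
                             correlation_block_size = 10, block_rho = 0.4,
                             unlabeled_fraction = 0.25, test_fraction = 0.25,
                             weibull_shape = 1,
                             n_labeled = NULL, n_unlabeled = NULL, n_test = NULL,
                             random_seed = 1) {
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              n_causal = as.integer(n_causal), beta_magnitude = beta_magnitude,
              baseline_rate = baseline_rate, censoring_rate = censoring_rate,
              correlation_block_size = as.integer(correlation_block_size),
              block_rho = block_rho,
              unlabeled_fraction = unlabeled_fraction,
              test_fraction = test_fraction, weibull_shape = weibull_shape,
              n_labeled = n_labeled, n_unlabeled = n_unlabeled, n_test = n_test,
              random_seed = as.integer(random_seed))
  check_number(cfg$n_causal, "n_causal", 0, cfg$n_genes)
  check_number(cfg$baseline_rate, "baseline_rate", 1e-12)
  check_number(cfg$censoring_rate, "censoring_rate", 0, 1 - 1e-9)
  check_number(cfg$block_rho, "block_rho", 0, 1 - 1e-9)
  check_number(cfg$weibull_shape, "weibull_shape", 1e-9)
  if (!is.null(n_labeled)) {
    cfg$n_labeled <- as.integer(n_labeled)
    cfg$n_unlabeled <- as.integer(n_unlabeled %||% 0)
    cfg$n_test <- as.integer(n_test %||% 0)
    cfg$n_samples <- cfg$n_labeled + cfg$n_unlabeled + cfg$n_test
  } else {
    check_number(cfg$unlabeled_fraction, "unlabeled_fraction", 0, 1)
    check_number(cfg$test_fraction, "test_fraction", 0, 1)
    if (cfg$unlabeled_fraction + cfg$test_fraction >= 1)
      stop_dfsc("unlabeled_fraction + test_fraction must leave a labeled remainder")
  }
  structure(cfg, class = "generator_config")
}

partition_counts <- function(config) {
  n <- config$n_samples
  if (!is.null(config$n_labeled))
    return(c(labeled = config$n_labeled, unlabeled = config$n_unlabeled,
             test = config$n_test))
  n_unl <- round(n * config$unlabeled_fraction)
  n_test <- round(n * config$test_fraction)
  n_lab <- n - n_unl - n_test
  if (n_lab <= 0) stop_dfsc("partition leaves no labeled samples")
  c(labeled = n_lab, unlabeled = n_unl, test = n_test)
}

# Expected censoring fraction when both event and censoring times are
# Weibull with a common shape: P(C < T* | eta) = lc / (lT + lc) on the
# rate scale, independent of shape.
solve_censoring_rate <- function(lambda_t, target) {
  if (target <= 0) return(0)
  f <- function(log_lc) mean(exp(log_lc) / (lambda_t + exp(log_lc))) - target
  lo <- log(min(lambda_t)) - 20; hi <- log(max(lambda_t)) + 20
  if (f(lo) > 0 || f(hi) < 0)
    stop_dfsc("cannot solve censoring rate target ", target)
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-10)$root)
}

#' Generate a synthetic survival cohort with ground truth
#'
#' Draws expression from block-correlated standard Gaussians (standardized
#' per gene), event times from a proportional-hazards Weibull model
#' `T* ~ Weibull(shape, rate = lambda0 * exp(x beta))`, censoring times
#' from a same-shape Weibull whose rate is solved so the expected
#' censoring fraction matches `censoring_rate`, and withholds outcomes for
#' the unlabeled partition.
#'
#' @param config A [generator_config()].
#' @return A list with elements `dataset` (a [survival_dataset()]; test and
#'   labeled rows carry outcomes, unlabeled rows are `NA`) and `truth`
#'   (causal gene ids, true `beta`, per-sample true `eta`, full withheld
#'   outcomes, partition assignment, realized censoring fraction).
#' @examples
#' sim <- generate_survival_data(generator_config(n_samples = 60, n_genes = 30,
#'                                                n_causal = 3, random_seed = 7))
#' table(sim$truth$partition)
#' @export
generate_survival_data <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_samples; p <- config$n_genes
  counts <- partition_counts(config)
  with_seed(config$random_seed, {
    # block-correlated Gaussian: x = sqrt(rho) z_block + sqrt(1-rho) noise
    bs <- max(1L, config$correlation_block_size)
    block_of <- rep(seq_len(ceiling(p / bs)), each = bs)[seq_len(p)]
    Z <- matrix(stats::rnorm(n * max(block_of)), n)
    X <- sqrt(config$block_rho) * Z[, block_of, drop = FALSE] +
      sqrt(1 - config$block_rho) * matrix(stats::rnorm(n * p), n, p)
    X <- scale(X)
    attr(X, "scaled:center") <- attr(X, "scaled:scale") <- NULL
    gene_ids <- sprintf("g%04d", seq_len(p))
    sample_ids <- sprintf("s%04d", seq_len(n))
    dimnames(X) <- list(sample_ids, gene_ids)

    causal <- sort(sample.int(p, config$n_causal))
    beta <- numeric(p)
    if (config$n_causal > 0)
      beta[causal] <- config$beta_magnitude * rep_len(c(1, -1), config$n_causal)
    eta <- drop(X %*% beta)

    lambda_t <- config$baseline_rate * exp(eta)
    shape <- config$weibull_shape
    t_event <- (stats::rexp(n) / lambda_t)^(1 / shape)
    lambda_c <- solve_censoring_rate(lambda_t, config$censoring_rate)
    t_cens <- if (lambda_c > 0) (stats::rexp(n) / lambda_c)^(1 / shape) else rep(Inf, n)
    time <- pmin(t_event, t_cens)
    event <- as.double(t_event <= t_cens)

    part <- rep(c("labeled", "unlabeled", "test"), times = counts)
    part <- sample(part)
    obs_time <- time; obs_event <- event
    obs_time[part == "unlabeled"] <- NA_real_
    obs_event[part == "unlabeled"] <- NA_real_

    dataset <- survival_dataset(X, time = obs_time, event = obs_event,
                                sample_ids = sample_ids, gene_ids = gene_ids)
    truth <- list(causal_genes = gene_ids[causal], beta = stats::setNames(beta, gene_ids),
                  eta = stats::setNames(eta, sample_ids),
                  time = stats::setNames(time, sample_ids),
                  event = stats::setNames(event, sample_ids),
                  partition = stats::setNames(part, sample_ids),
                  censoring_fraction = mean(event == 0))
    list(dataset = dataset, truth = truth)
  })
}

# Cohort designs mirroring the four TCGA gene-expression studies the
# method was benchmarked on (sample partition sizes and gene counts).
.tcga_presets <- list(
  BRCA = c(labeled = 248, unlabeled = 245, test = 120, genes = 20502),
  CESC = c(labeled = 120, unlabeled = 110, test = 60, genes = 20502),
  COAD = c(labeled = 110, unlabeled = 85, test = 60, genes = 20501),
  PAAD = c(labeled = 65, unlabeled = 61, test = 50, genes = 20502)
)

#' Generator presets shaped like the TCGA benchmark cohorts
#'
#' Returns a [generator_config()] whose labeled / unlabeled / test counts
#' match the named cohort design (scaled by `scale`), with the gene count
#' capped at 2000 for desk-scale runs.
#'
#' @param name One of `"BRCA"`, `"CESC"`, `"COAD"`, `"PAAD"`.
#' @param scale Multiplier in (0, 1] applied to the partition counts.
#' @param ... Further arguments passed to [generator_config()].
#' @return A `generator_config`.
#' @examples
#' cfg <- tcga_like_preset("PAAD")
#' c(cfg$n_labeled, cfg$n_unlabeled, cfg$n_test)  # 65 61 50
#' @export
tcga_like_preset <- function(name, scale = 1, ...) {
  if (!name %in% names(.tcga_presets))
    stop_dfsc("unknown preset '", name, "'; available: ",
              paste(names(.tcga_presets), collapse = ", "))
  check_number(scale, "scale", 1e-9, 1)
  row <- .tcga_presets[[name]]
  generator_config(
    n_genes = min(2000L, as.integer(round(scale * row[["genes"]]))),
    n_labeled = as.integer(round(scale * row[["labeled"]])),
    n_unlabeled = as.integer(round(scale * row[["unlabeled"]])),
    n_test = as.integer(round(scale * row[["test"]])),
    ...
  )
}

#' Write a simulated cohort to plain-text files
#'
#' Writes `expr.tsv` (samples as rows), `clinical.tsv` (blank outcomes for
#' unlabeled rows) and `truth.tsv` into `dir`.
#'
#' @param sim Result of [generate_survival_data()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- sim$dataset
  expr <- data.frame(sample_id = ds$sample_ids, ds$X, check.names = FALSE)
  utils::write.table(expr, file.path(dir, "expr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  clin <- data.frame(sample_id = ds$sample_ids, time = ds$time, event = ds$event)
  utils::write.table(clin, file.path(dir, "clinical.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  tr <- sim$truth
  truth <- data.frame(sample_id = ds$sample_ids, eta = tr$eta,
                      time = tr$time, event = tr$event, partition = tr$partition)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Split a simulated cohort into its partitions
#'
#' @param sim Result of [generate_survival_data()].
#' @return List of [survival_dataset()]s: `labeled`, `unlabeled`, `test`.
#' @export
partition_subsets <- function(sim) {
  part <- sim$truth$partition
  out <- lapply(c(labeled = "labeled", unlabeled = "unlabeled", test = "test"),
                function(p) subset_samples(sim$dataset, which(part == p)))
  # test rows keep their outcomes; unlabeled rows are NA by construction
  out
}
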