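#' Configuration for stable-LASSO gene ranking
#'
#' @param n_subsamples Number of subsamples `B` (>= 50 recommended).
#' @param subsample_fraction Fraction of labeled samples drawn without
#'   replacement per subsample, in (0, 1).
#' @param n_penalties Size of the log-spaced L1 penalty grid per fit.
#' @param penalty_grid Optional explicit penalty grid (positive reals);
#'   overrides the automatic log-spaced grid.
#' @param top_k Number of genes reported.
#' @param screen_top Variance pre-screen threshold: when `p` exceeds it,
#'   only the `screen_top` most-variable genes enter the subsampled fits
#'   (screened-out genes score 0); `NULL` disables.
#' @param random_seed Integer seed.
#' @return A `stability_config` list.
#' @export
stability_config <- function(n_subsamples = 100, subsample_fraction = 0.5,
                             n_penalties = 10, top_k = 20, screen_top = 5000,
                             penalty_grid = NULL, random_seed = 1) {
  if (!is.null(penalty_grid) && any(penalty_grid <= 0))
    stop_dfsc("penalty_grid entries must be positive")
  cfg <- list(n_subsamples = as.integer(n_subsamples),
              subsample_fraction = subsample_fraction,
              n_penalties = as.integer(n_penalties), top_k = as.integer(top_k),
              screen_top = screen_top,
              penalty_grid = if (!is.null(penalty_grid)) sort(penalty_grid, decreasing = TRUE),
              random_seed = as.integer(random_seed))
  if (cfg$n_subsamples < 1) stop_dfsc("n_subsamples must be >= 1")
  check_number(cfg$subsample_fraction, "subsample_fraction", 1e-9, 1 - 1e-9)
  if (cfg$top_k < 1) stop_dfsc("top_k must be >= 1")
  structure(cfg, class = "stability_config")
}

#' Stable-LASSO gene ranking
#'
#' Fits an L1-penalized Cox model on `B` event-stratified subsamples of
#' the labeled data, over a log-spaced penalty grid; a gene's stability
#' score is the fraction of subsamples in which its coefficient is
#' nonzero at any grid penalty. Scores close to 1 mark genes whose
#' selection is robust to perturbing the training set. Reported p-values
#' are per-gene univariate Cox Wald tests on the full data, with a
#' Benjamini-Hochberg adjusted column.
#'
#' @param dataset A [survival_dataset()]; labeled rows are used.
#' @param config A [stability_config()].
#' @return A data.frame of class `stability_report` with columns
#'   `gene_symbol`, `stable_score`, `p_value`, `p_adjusted`, sorted by
#'   score (top `top_k` rows); all per-gene scores are kept in
#'   `attr(, "all_scores")`, and constant genes are flagged in
#'   `attr(, "degenerate_genes")`.
#' @export
stability_select <- function(dataset, config = stability_config()) {
  stopifnot(inherits(config, "stability_config"))
  lab <- labeled_subset(dataset)
  n <- n_samples(lab); p <- n_genes(lab)
  n_events <- sum(lab$event)
  if (n_events < 5) stop_dfsc("need >= 5 events for stability selection")
  if (any(lab$time <= 0)) stop_dfsc("follow-up times must be positive")

  v <- apply(lab$X, 2, stats::var)
  degenerate <- lab$gene_ids[v < 1e-12]
  active <- lab$gene_ids[v >= 1e-12]
  if (!is.null(config$screen_top) && length(active) > config$screen_top)
    active <- active[order(v[active], decreasing = TRUE)[seq_len(config$screen_top)]]
  Xa <- lab$X[, active, drop = FALSE]
  y <- survival::Surv(lab$time, lab$event)

  # penalty grid anchored at the full-data lambda_max (unless given);
  # glmnet pads failed path heads with a 9.9e35 placeholder, so filter
  grid <- config$penalty_grid
  if (is.null(grid)) {
    path <- suppressWarnings(glmnet::glmnet(Xa, y, family = "cox", alpha = 1,
                                            nlambda = 10))
    lmax <- max(path$lambda[path$lambda < 1e30])
    grid <- exp(seq(log(lmax), log(lmax * 0.01), length.out = config$n_penalties))
  }

  # event-stratified subsamples without replacement; candidate lists are
  # ordered by sample id so results do not depend on input row order
  n_ev_sub <- max(2L, round(n_events * config$subsample_fraction))
  n_cs_sub <- round(sum(lab$event == 0) * config$subsample_fraction)
  ev_idx <- which(lab$event == 1); ev_idx <- ev_idx[order(lab$sample_ids[ev_idx])]
  cs_idx <- which(lab$event == 0); cs_idx <- cs_idx[order(lab$sample_ids[cs_idx])]
  hits <- stats::setNames(numeric(length(active)), active)
  used <- 0L
  with_seed(derive_seed(config$random_seed, 4242), {
    for (b in seq_len(config$n_subsamples)) {
      idx <- c(sample(ev_idx, n_ev_sub),
               if (n_cs_sub > 0) sample(cs_idx, n_cs_sub))
      idx <- idx[order(lab$sample_ids[idx])]
      # glmnet wants a decreasing path of >= 2 penalties
      fit_grid <- if (length(grid) > 1) grid else c(grid * 1.5, grid)
      fit <- tryCatch(
        suppressWarnings(
          glmnet::glmnet(Xa[idx, , drop = FALSE], y[idx, ], family = "cox",
                         alpha = 1, lambda = fit_grid)),
        error = function(e) NULL)
      if (is.null(fit)) next
      keep_cols <- fit$lambda %in% grid
      nz <- rowSums(abs(as.matrix(fit$beta[, keep_cols, drop = FALSE])) > 0) > 0
      hits[names(nz)[nz]] <- hits[names(nz)[nz]] + 1
      used <- used + 1L
    }
  })
  if (used == 0L) stop_dfsc("all subsampled fits failed")
  scores <- stats::setNames(numeric(p), lab$gene_ids)
  scores[active] <- hits / used

  ord <- order(scores, decreasing = TRUE)
  top <- utils::head(ord, config$top_k)
  pvals <- vapply(top, function(j) {
    g <- lab$X[, j]
    if (stats::var(g) < 1e-12) return(NA_real_)
    fit <- tryCatch(survival::coxph(y ~ g), error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    summary(fit)$coefficients[1, "Pr(>|z|)"]
  }, numeric(1))

  out <- data.frame(gene_symbol = lab$gene_ids[top],
                    stable_score = as.numeric(scores[top]),
                    p_value = pvals,
                    p_adjusted = stats::p.adjust(pvals, method = "BH"))
  rownames(out) <- NULL
  structure(out, all_scores = scores, degenerate_genes = degenerate,
            class = c("stability_report", "data.frame"))
}

#' Pearson correlation matrix for a gene set
#'
#' @param dataset A [survival_dataset()].
#' @param genes Character vector of gene ids present in the dataset.
#' @return Symmetric correlation matrix in `[-1, 1]` with unit diagonal;
#'   correlations involving constant genes are reported as 0 and the
#'   genes flagged in `attr(, "degenerate_genes")` (with a warning).
#' @export
gene_correlation_matrix <- function(dataset, genes) {
  missing <- setdiff(genes, dataset$gene_ids)
  if (length(missing)) stop_dfsc("genes not in dataset: ", paste(missing, collapse = ", "))
  X <- dataset$X[, genes, drop = FALSE]
  v <- apply(X, 2, stats::var)
  flat <- genes[v < 1e-12]
  cm <- suppressWarnings(stats::cor(X))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 1
  if (length(flat)) {
    warning("constant gene(s) have undefined correlations, reported as 0: ",
            paste(flat, collapse = ", "))
    attr(cm, "degenerate_genes") <- flat
  }
  cm
}

#' Write a stability report as TSV
#'
#' Columns `gene_symbol`, `stable_score`, `p_value` (plus `p_adjusted`).
#'
#' @param report A `stability_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_stability_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
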