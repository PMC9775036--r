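#' Model specifications for the evaluation harness
#'
#' A `model_spec` bundles a fitting routine with risk / survival
#' prediction so [cross_validate()] and [compare_models()] can treat
#' methods uniformly. Built-in specs:
#' \describe{
#'   \item{`"dfsc"`}{the semi-supervised cascade ([fit_dfsc()]; uses the
#'     unlabeled pool when the harness provides one).}
#'   \item{`"cascade"`}{the supervised cascade ([fit_cascade()]).}
#'   \item{`"lasso_cox"`}{L1-penalized Cox baseline (glmnet, penalty by
#'     internal cross-validation).}
#'   \item{`"rsf"`}{a single random survival forest baseline.}
#' }
#'
#' @param name One of `"dfsc"`, `"cascade"`, `"lasso_cox"`, `"rsf"`.
#' @param cascade_cfg,distill_cfg Configurations for the cascade-based
#'   specs (defaults used when `NULL`).
#' @param label Optional display label (defaults to `name`).
#' @return A `model_spec` list with elements `label`, `fit(train,
#'   unlabeled, seed)`, `predict_risk(fit, X)` and
#'   `predict_survival(fit, X, times)`.
#' @export
model_spec <- function(name = c("dfsc", "cascade", "lasso_cox", "rsf"),
                       cascade_cfg = NULL, distill_cfg = NULL, label = NULL) {
  name <- match.arg(name)
  spec <- switch(name,
    cascade = list(
      fit = function(train, unlabeled, seed) {
        cfg <- cascade_cfg %||% cascade_config()
        cfg$random_seed <- derive_seed(seed, 11)
        fit_cascade(train, cfg)
      },
      predict_risk = cascade_predict_risk,
      predict_survival = cascade_predict_survival),
    dfsc = list(
      fit = function(train, unlabeled, seed) {
        ccfg <- cascade_cfg %||% cascade_config()
        dcfg <- distill_cfg %||% distillation_config()
        ccfg$random_seed <- derive_seed(seed, 11)
        dcfg$random_seed <- derive_seed(seed, 12)
        if (is.null(unlabeled) || n_samples(unlabeled) == 0)
          fit_cascade(train, ccfg)
        else
          suppressMessages(fit_dfsc(train, unlabeled, ccfg, dcfg))
      },
      predict_risk = cascade_predict_risk,
      predict_survival = cascade_predict_survival),
    lasso_cox = list(
      fit = function(train, unlabeled, seed) {
        lab <- labeled_subset(train)
        y <- survival::Surv(lab$time, lab$event)
        foldid <- stratified_folds(lab$event, 5, derive_seed(seed, 21))
        cv <- glmnet::cv.glmnet(lab$X, y, family = "cox", alpha = 1,
                                foldid = foldid, nlambda = 30)
        eta <- drop(stats::predict(cv$glmnet.fit, newx = lab$X,
                                   type = "link", s = cv$lambda.min))
        list(cv = cv, lambda = cv$lambda.min,
             baseline = breslow_baseline(eta, lab), gene_ids = lab$gene_ids)
      },
      predict_risk = function(fit, X) {
        drop(stats::predict(fit$cv$glmnet.fit,
                            newx = as.matrix(X)[, fit$gene_ids, drop = FALSE],
                            type = "link", s = fit$lambda))
      },
      predict_survival = function(fit, X, times) {
        eta <- drop(stats::predict(fit$cv$glmnet.fit,
                                   newx = as.matrix(X)[, fit$gene_ids, drop = FALSE],
                                   type = "link", s = fit$lambda))
        predict_survival_function(eta, fit$baseline, times)
      }),
    rsf = list(
      fit = function(train, unlabeled, seed) {
        lab <- labeled_subset(train)
        cfg <- cascade_cfg %||% cascade_config()
        rf <- fit_survival_forest(lab$X, lab$time, lab$event, "standard",
                                  cfg, derive_seed(seed, 31))
        ft <- unique(stats::quantile(lab$time, probs = seq(0.1, 0.9, length.out = 10)))
        list(rf = rf, feat_times = ft, gene_ids = lab$gene_ids)
      },
      predict_risk = function(fit, X) {
        pred <- stats::predict(fit$rf,
                               data = as.matrix(X)[, fit$gene_ids, drop = FALSE],
                               num.threads = 1)
        log1p(rowSums(chf_at_times(pred, fit$feat_times)))
      },
      predict_survival = function(fit, X, times) {
        pred <- stats::predict(fit$rf,
                               data = as.matrix(X)[, fit$gene_ids, drop = FALSE],
                               num.threads = 1)
        exp(-chf_at_times(pred, times))
      })
  )
  structure(c(spec, list(label = label %||% name)), class = "model_spec")
}

brier_grid_times <- function(time, event) {
  et <- time[event == 1]
  unique(stats::quantile(et, probs = seq(0.1, 0.8, length.out = 8)))
}

#' Cross-validated evaluation of a survival model
#'
#' Event-stratified k-fold cross-validation: for each fold the model is
#' fitted on the remaining folds (an optional unlabeled pool is available
#' to every training fold but never evaluated) and scored on the held-out
#' fold with Harrell's concordance and the integrated IPCW Brier score
#' over the 10\%-80\% event-time quantile grid. Folds too small for a
#' metric (e.g. leave-one-out) get `NA`; a pooled row over all
#' out-of-fold predictions is always included.
#'
#' @param dataset A [survival_dataset()] of labeled samples.
#' @param spec A [model_spec()].
#' @param k Number of folds (>= 2).
#' @param seed Integer seed controlling folds and model fits.
#' @param unlabeled Optional unlabeled [survival_dataset()].
#' @return An `evaluation_report`: data.frame with columns `model`,
#'   `fold` (`"1"..k` and `"pooled"`), `cindex`, `ibrier`, plus
#'   `attr(, "summary")` holding per-model means and standard deviations.
#' @export
cross_validate <- function(dataset, spec, k = 5, seed = 1, unlabeled = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  lab <- labeled_subset(dataset)
  n <- n_samples(lab)
  k <- as.integer(k)
  if (k < 2 || k > n) stop_dfsc("k must be between 2 and the number of labeled samples")
  fold <- stratified_folds(lab$event, k, derive_seed(seed, 555))
  if (k <= sum(lab$event) && any(tabulate(fold[lab$event == 1], k) == 0))
    stop_dfsc("a fold has zero events; use fewer folds")

  rows <- list(); pooled_risk <- numeric(n)
  for (fd in seq_len(k)) {
    test_idx <- which(fold == fd)
    train <- subset_samples(lab, setdiff(seq_len(n), test_idx))
    test <- subset_samples(lab, test_idx)
    fit <- spec$fit(train, unlabeled, derive_seed(seed, fd))
    risk <- spec$predict_risk(fit, test$X)
    pooled_risk[test_idx] <- risk
    ci <- tryCatch(concordance_index(test$time, test$event, risk),
                   error = function(e) NA_real_)
    ib <- tryCatch({
      grid <- brier_grid_times(test$time, test$event)
      integrated_brier(test$time, test$event,
                       spec$predict_survival(fit, test$X, grid), grid)
    }, error = function(e) NA_real_)
    rows[[fd]] <- data.frame(model = spec$label, fold = as.character(fd),
                             cindex = ci, ibrier = ib)
  }
  pooled_ci <- tryCatch(concordance_index(lab$time, lab$event, pooled_risk),
                        error = function(e) NA_real_)
  out <- rbind(do.call(rbind, rows),
               data.frame(model = spec$label, fold = "pooled",
                          cindex = pooled_ci, ibrier = NA_real_))
  per_fold <- out[out$fold != "pooled", ]
  summ <- data.frame(model = spec$label,
                     mean_cindex = mean(per_fold$cindex, na.rm = TRUE),
                     sd_cindex = stats::sd(per_fold$cindex[!is.na(per_fold$cindex)]),
                     mean_ibrier = mean(per_fold$ibrier, na.rm = TRUE),
                     sd_ibrier = stats::sd(per_fold$ibrier[!is.na(per_fold$ibrier)]),
                     pooled_cindex = pooled_ci)
  structure(out, summary = summ, class = c("evaluation_report", "data.frame"))
}

#' Paired cross-validated comparison of several models
#'
#' Runs [cross_validate()] for every spec with identical folds (same
#' seed), so per-fold metrics are directly comparable. A failing spec is
#' reported with `NA` metrics and the remaining specs are kept.
#'
#' @param dataset A labeled [survival_dataset()].
#' @param specs List of [model_spec()] objects (>= 2).
#' @param k,seed,unlabeled As in [cross_validate()].
#' @return An `evaluation_report` with one block of rows per model and a
#'   combined `attr(, "summary")`.
#' @export
compare_models <- function(dataset, specs, k = 5, seed = 1, unlabeled = NULL) {
  if (length(specs) < 2) stop_dfsc("need at least two model specs to compare")
  reports <- lapply(specs, function(sp) {
    tryCatch(cross_validate(dataset, sp, k = k, seed = seed, unlabeled = unlabeled),
             error = function(e) {
               warning("spec '", sp$label, "' failed: ", conditionMessage(e))
               structure(data.frame(model = sp$label, fold = "pooled",
                                    cindex = NA_real_, ibrier = NA_real_),
                         summary = data.frame(model = sp$label,
                                              mean_cindex = NA_real_, sd_cindex = NA_real_,
                                              mean_ibrier = NA_real_, sd_ibrier = NA_real_,
                                              pooled_cindex = NA_real_),
                         class = c("evaluation_report", "data.frame"))
             })
  })
  out <- do.call(rbind, lapply(reports, as.data.frame))
  summ <- do.call(rbind, lapply(reports, attr, "summary"))
  rownames(out) <- rownames(summ) <- NULL
  structure(out, summary = summ, class = c("evaluation_report", "data.frame"))
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report (per-fold metrics):\n")
  print.data.frame(x, row.names = FALSE)
  s <- attr(x, "summary")
  if (!is.null(s)) {
    cat("\nsummary:\n")
    print.data.frame(s, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
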