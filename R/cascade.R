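#' Configuration of the deep survival forest cascade
#'
#' A cascade level holds an ensemble of survival forests (half standard
#' log-rank forests, half completely-random forests for diversity); each
#' forest contributes out-of-fold prediction features that are
#' concatenated with the original genes and fed both to an elastic-net
#' Cox link (producing the level's risk score) and to the next level's
#' forests. Levels are grown until the held-out validation concordance
#' stops improving.
#'
#' @param n_forests_per_level Even integer >= 2; first half are standard
#'   log-rank survival forests, second half completely-random forests
#'   (uniformly random split feature and threshold).
#' @param n_trees_per_forest Trees per forest.
#' @param max_levels Maximum cascade depth.
#' @param patience Levels without validation improvement before stopping.
#' @param elasticnet_l1_ratio Elastic-net mixing parameter in `[0, 1]`
#'   (1 = lasso) for the per-level Cox link.
#' @param n_penalties Size of the log-spaced penalty-strength grid
#'   searched per level; the penalty maximizing validation concordance is
#'   kept.
#' @param validation_fraction Fraction of labeled samples held out
#'   (event-stratified) to score levels and stop growth.
#' @param oof_folds Folds used to compute out-of-fold forest features for
#'   link training (leakage control).
#' @param features_per_forest Prediction features each forest emits: the
#'   ensemble log-risk, plus survival probabilities at
#'   `features_per_forest - 1` quantile times when larger than 1.
#' @param min_node_size Minimal terminal-node size of the survival trees.
#' @param mtry Candidate features per split for the standard forests
#'   (default `floor(sqrt(p))`).
#' @param forest_time_bins Forest training responses use follow-up times
#'   coarsened to this many quantile bins (log-rank splitting cost grows
#'   with the number of distinct death times); `0` disables. Cox links,
#'   baseline hazards and all metrics always use exact times.
#' @param screen_top Optional variance pre-screen: keep this many
#'   most-variable genes as the pass-through feature set (recommended for
#'   `p > 5000`); `NULL` keeps all genes.
#' @param random_seed Integer seed; fits are bit-reproducible given the
#'   seed and data.
#' @return A `cascade_config` list.
#' @export
cascade_config <- function(n_forests_per_level = 4, n_trees_per_forest = 100,
                           max_levels = 5, patience = 1,
                           elasticnet_l1_ratio = 0.5, n_penalties = 5,
                           validation_fraction = 0.2, oof_folds = 3,
                           features_per_forest = 1, min_node_size = 15,
                           mtry = NULL, forest_time_bins = 30,
                           screen_top = NULL, random_seed = 1) {
  cfg <- list(n_forests_per_level = as.integer(n_forests_per_level),
              n_trees_per_forest = as.integer(n_trees_per_forest),
              max_levels = as.integer(max_levels), patience = as.integer(patience),
              elasticnet_l1_ratio = elasticnet_l1_ratio,
              n_penalties = as.integer(n_penalties),
              validation_fraction = validation_fraction,
              oof_folds = as.integer(oof_folds),
              features_per_forest = as.integer(features_per_forest),
              min_node_size = as.integer(min_node_size), mtry = mtry,
              forest_time_bins = as.integer(forest_time_bins),
              screen_top = screen_top, random_seed = as.integer(random_seed))
  if (cfg$n_forests_per_level < 2 || cfg$n_forests_per_level %% 2 != 0)
    stop_dfsc("n_forests_per_level must be an even integer >= 2")
  if (cfg$max_levels < 1) stop_dfsc("max_levels must be >= 1")
  if (cfg$patience < 1) stop_dfsc("patience must be >= 1")
  check_number(cfg$elasticnet_l1_ratio, "elasticnet_l1_ratio", 0, 1)
  check_number(cfg$validation_fraction, "validation_fraction", 1e-9, 1 - 1e-9)
  if (cfg$oof_folds < 2) stop_dfsc("oof_folds must be >= 2")
  if (cfg$features_per_forest < 1) stop_dfsc("features_per_forest must be >= 1")
  structure(cfg, class = "cascade_config")
}

# Coarsen follow-up times onto a quantile grid (forest training only).
coarsen_times <- function(time, bins) {
  if (bins <= 0 || length(unique(time)) <= bins) return(time)
  qs <- unique(stats::quantile(time, probs = seq(0, 1, length.out = bins + 1)))
  qs[pmax(1L, findInterval(time, qs))]
}

fit_survival_forest <- function(features, time, event, type, config, seed) {
  tb <- coarsen_times(time, config$forest_time_bins)
  args <- list(x = features, y = survival::Surv(tb, event),
               num.trees = config$n_trees_per_forest,
               min.node.size = config$min_node_size,
               num.threads = 1, seed = seed, verbose = FALSE,
               write.forest = TRUE)
  if (type == "random") {
    args$splitrule <- "extratrees"; args$num.random.splits <- 1; args$mtry <- 1
  } else if (!is.null(config$mtry)) {
    args$mtry <- min(config$mtry, ncol(features))
  }
  do.call(ranger::ranger, args)
}

# Evaluate a ranger survival prediction's CHF on a fixed time grid
# (step-function interpolation), so features share a scale across folds.
chf_at_times <- function(pred, grid) {
  chf <- pred$chf
  if (is.null(dim(chf))) chf <- matrix(chf, nrow = 1)  # single-row predictions
  idx <- findInterval(grid, pred$unique.death.times)
  chf <- cbind(0, chf)
  chf[, idx + 1L, drop = FALSE]
}

forest_features <- function(forest, features, feat_times, extra_times) {
  pred <- stats::predict(forest, data = features, num.threads = 1)
  H <- chf_at_times(pred, feat_times)
  out <- log1p(rowSums(H))  # ensemble mortality on the log scale
  if (length(extra_times)) {
    He <- chf_at_times(pred, extra_times)
    out <- cbind(out, exp(-He))
  }
  as.matrix(out)
}

level_seed <- function(config, level, forest, fold = 0L)
  derive_seed(config$random_seed, level, forest, fold)

#' Fit a deep survival forest cascade
#'
#' Grows cascade levels one at a time on the labeled rows of `train`.
#' At each level every forest is trained on the current augmented
#' features; the features it feeds forward for the training rows are
#' out-of-fold (each row predicted by a forest that never saw it), while
#' validation and test rows use the full forest. An elastic-net Cox model
#' on `[original genes, level forest outputs]` supplies the level's risk
#' score and its validation concordance; growth stops when validation
#' concordance fails to improve for `patience` levels, and only levels up
#' to the best score are kept.
#'
#' @param train A [survival_dataset()]; only labeled rows are used.
#'   Needs >= 20 labeled samples with >= 5 events.
#' @param config A [cascade_config()].
#' @param validation_ids Optional explicit sample ids to use as the
#'   validation split (they must be labeled rows of `train`); by default
#'   an event-stratified fraction `validation_fraction` is drawn. Used by
#'   [fit_dfsc()] to keep pseudo-labeled rows out of validation.
#' @param use_oof Internal switch for the leakage-control features; keep
#'   the default `TRUE` (setting `FALSE` feeds in-fold forest predictions
#'   to the Cox links, which overfits and exists only so the leakage
#'   guard can be demonstrated).
#' @return An object of class `cascade_model` with the retained levels,
#'   Breslow baseline hazard, validation history and training metadata.
#' @seealso [cascade_predict_risk()], [cascade_predict_survival()],
#'   [fit_dfsc()]
#' @export
fit_cascade <- function(train, config = cascade_config(), validation_ids = NULL,
                        use_oof = TRUE) {
  stopifnot(inherits(config, "cascade_config"))
  lab <- labeled_subset(train)
  n <- n_samples(lab); p <- n_genes(lab)
  if (p < 1) stop_dfsc("no genes in training data")
  if (n < 20) stop_dfsc("need >= 20 labeled samples, got ", n)
  if (sum(lab$event) < 5) stop_dfsc("need >= 5 events, got ", sum(lab$event))
  if (any(lab$time <= 0)) stop_dfsc("follow-up times must be positive to fit the cascade")

  # validation split (event-stratified unless explicit ids are given)
  if (is.null(validation_ids)) {
    k <- max(2L, round(1 / config$validation_fraction))
    fold <- stratified_folds(lab$event, k, derive_seed(config$random_seed, 999))
    val_idx <- which(fold == 1L)
  } else {
    val_idx <- match(validation_ids, lab$sample_ids)
    if (anyNA(val_idx)) stop_dfsc("validation_ids must be labeled samples of `train`")
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (sum(lab$event[tr_idx]) < 2 || sum(lab$event[val_idx]) < 1)
    stop_dfsc("validation split leaves too few events")

  # pass-through gene set (optional variance screen for very large p)
  sel_genes <- lab$gene_ids
  if (!is.null(config$screen_top) && p > config$screen_top) {
    v <- apply(lab$X, 2, stats::var)
    sel_genes <- lab$gene_ids[order(v, decreasing = TRUE)[seq_len(config$screen_top)]]
  }
  F0_tr <- lab$X[tr_idx, sel_genes, drop = FALSE]
  F0_val <- lab$X[val_idx, sel_genes, drop = FALSE]
  time_tr <- lab$time[tr_idx]; event_tr <- lab$event[tr_idx]
  y_tr <- survival::Surv(time_tr, event_tr)
  feat_times <- unique(stats::quantile(time_tr, probs = seq(0.1, 0.9, length.out = 10)))
  extra_times <- if (config$features_per_forest > 1)
    unique(stats::quantile(time_tr[event_tr == 1],
                           probs = seq(0.25, 0.75, length.out = config$features_per_forest - 1)))
  else numeric(0)

  nf <- config$n_forests_per_level
  types <- rep(c("standard", "random"), each = nf / 2)
  levels <- list(); val_hist <- numeric(0); fit_eta_hist <- list()
  best_score <- -Inf; best_level <- 0L; n_bad <- 0L
  cur_tr <- F0_tr; cur_val <- F0_val

  for (lev in seq_len(config$max_levels)) {
    oof_fold <- stratified_folds(event_tr, config$oof_folds,
                                 derive_seed(config$random_seed, lev, 77))
    feats_tr <- NULL; feats_val <- NULL; forests <- vector("list", nf)
    for (f in seq_len(nf)) {
      full <- fit_survival_forest(cur_tr, time_tr, event_tr, types[f], config,
                                  level_seed(config, lev, f))
      forests[[f]] <- full
      if (use_oof) {
        ftr <- matrix(NA_real_, nrow(cur_tr), config$features_per_forest)
        for (fd in seq_len(config$oof_folds)) {
          hold <- which(oof_fold == fd)
          sub <- fit_survival_forest(cur_tr[-hold, , drop = FALSE],
                                     time_tr[-hold], event_tr[-hold], types[f],
                                     config, level_seed(config, lev, f, fd))
          ftr[hold, ] <- forest_features(sub, cur_tr[hold, , drop = FALSE],
                                         feat_times, extra_times)
        }
      } else {
        ftr <- forest_features(full, cur_tr, feat_times, extra_times)
      }
      feats_tr <- cbind(feats_tr, ftr)
      feats_val <- cbind(feats_val,
                         forest_features(full, cur_val, feat_times, extra_times))
    }
    colnames(feats_tr) <- colnames(feats_val) <-
      paste0(".level", lev, "_feat", seq_len(ncol(feats_tr)))
    A_tr <- cbind(F0_tr, feats_tr)
    A_val <- cbind(F0_val, feats_val)

    # path may truncate at small penalties on hard data; selection below
    # only considers the penalties actually returned
    link <- suppressWarnings(
      glmnet::glmnet(A_tr, y_tr, family = "cox",
                     alpha = config$elasticnet_l1_ratio,
                     nlambda = config$n_penalties))
    eta_val_all <- stats::predict(link, newx = A_val, type = "link")
    scores <- apply(eta_val_all, 2, function(e)
      tryCatch(concordance_index(lab$time[val_idx], lab$event[val_idx], e),
               error = function(err) NA_real_))
    if (all(is.na(scores))) stop_dfsc("validation split has no comparable pairs")
    pick <- unname(which.max(scores))  # first max -> strongest penalty on ties
    val_c <- unname(scores[pick])

    levels[[lev]] <- list(forests = forests, link = link,
                          lambda = link$lambda[pick],
                          n_features = ncol(A_tr), val_cindex = val_c)
    val_hist[lev] <- val_c
    fit_eta_hist[[lev]] <- drop(stats::predict(link, newx = A_tr, type = "link",
                                               s = link$lambda[pick]))
    if (val_c > best_score + 1e-12) {
      best_score <- val_c; best_level <- lev; n_bad <- 0L
    } else {
      n_bad <- n_bad + 1L
      if (n_bad >= config$patience) break
    }
    cur_tr <- A_tr; cur_val <- A_val
  }

  model <- structure(list(
    levels = levels[seq_len(best_level)], config = config,
    gene_ids = lab$gene_ids, selected_feature_ids = sel_genes,
    feat_times = feat_times, extra_times = extra_times,
    val_history = val_hist, best_level = best_level,
    best_val_cindex = best_score,
    validation_ids = lab$sample_ids[val_idx],
    fit_eta = stats::setNames(fit_eta_hist[[best_level]], lab$sample_ids[tr_idx]),
    train_data = list(X = lab$X, time = lab$time, event = lab$event,
                      sample_ids = lab$sample_ids)
  ), class = "cascade_model")

  eta_all <- cascade_predict_risk(model, lab$X)
  model$train_eta <- eta_all
  model$baseline <- breslow_baseline(eta_all, lab)
  model
}

#' @export
print.cascade_model <- function(x, ...) {
  cat(sprintf("cascade_model: %d level(s), %d genes, validation C-index %.3f\n",
              length(x$levels), length(x$gene_ids), x$best_val_cindex))
  invisible(x)
}

align_genes <- function(model, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    if (ncol(X) != length(model$gene_ids))
      stop_dfsc("X has no gene names and the wrong number of columns")
    colnames(X) <- model$gene_ids
  }
  missing <- setdiff(model$gene_ids, colnames(X))
  if (length(missing))
    stop_dfsc("genes missing from X: ", paste(utils::head(missing, 10), collapse = ", "),
              if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10))
  X[, model$gene_ids, drop = FALSE]
}

#' Predict the cascade's log-risk score
#'
#' Runs `X` through every retained level (forest features recomputed with
#' the stored full forests, augmented with the pass-through genes) and
#' returns the final level's elastic-net Cox linear predictor. Columns
#' are aligned to the training genes by name; unknown or missing genes
#' are an error.
#'
#' @param model A fitted [fit_cascade()] model.
#' @param X Expression matrix with named gene columns.
#' @return Named numeric vector of per-sample log-risk `eta`.
#' @export
cascade_predict_risk <- function(model, X) {
  X <- align_genes(model, X)
  F0 <- X[, model$selected_feature_ids, drop = FALSE]
  cur <- F0
  eta <- NULL
  for (lev in seq_along(model$levels)) {
    L <- model$levels[[lev]]
    feats <- NULL
    for (f in seq_along(L$forests))
      feats <- cbind(feats, forest_features(L$forests[[f]], cur,
                                            model$feat_times, model$extra_times))
    colnames(feats) <- paste0(".level", lev, "_feat", seq_len(ncol(feats)))
    A <- cbind(F0, feats)
    eta <- drop(stats::predict(L$link, newx = A, type = "link", s = L$lambda))
    cur <- A
  }
  stats::setNames(eta, rownames(X))
}

#' Predict survival curves from a fitted cascade
#'
#' Composes the cascade risk score with the Breslow baseline hazard:
#' `S(t | x) = exp(-H0(t) exp(eta(x)))`.
#'
#' @inheritParams cascade_predict_risk
#' @param times Non-negative evaluation times.
#' @return Matrix of survival probabilities (samples x times).
#' @export
cascade_predict_survival <- function(model, X, times) {
  eta <- cascade_predict_risk(model, X)
  predict_survival_function(eta, model$baseline, times)
}

#' Truncate a cascade to its first levels
#'
#' Rebuilds the model using only the first `n_levels` levels (the
#' baseline hazard and training risk scores are recomputed), e.g. to
#' compare the full cascade against its own level-1 ensemble.
#'
#' @param model A `cascade_model`.
#' @param n_levels Number of leading levels to keep.
#' @return A `cascade_model`.
#' @export
truncate_cascade <- function(model, n_levels) {
  n_levels <- as.integer(n_levels)
  if (n_levels < 1 || n_levels > length(model$levels))
    stop_dfsc("n_levels must be between 1 and ", length(model$levels))
  out <- model
  out$levels <- model$levels[seq_len(n_levels)]
  out$best_level <- n_levels
  td <- model$train_data
  lab <- survival_dataset(td$X, time = td$time, event = td$event,
                          sample_ids = td$sample_ids, gene_ids = model$gene_ids)
  out$train_eta <- cascade_predict_risk(out, td$X)
  out$baseline <- breslow_baseline(out$train_eta, lab)
  out
}

#' Save / load a fitted cascade model
#'
#' Serializes the whole model (config, per-level forests and Cox link
#' coefficients, baseline hazard) to a single archive file.
#'
#' @param model A `cascade_model`.
#' @param path File path.
#' @return `path` (save) or the restored `cascade_model` (load).
#' @export
save_cascade <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_cascade
#' @export
load_cascade <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "cascade_model")) stop_dfsc("file does not contain a cascade_model")
  model
}
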