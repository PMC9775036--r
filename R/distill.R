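#' Configuration of the teacher-student distillation loop
#'
#' Controls how a fitted cascade (the teacher) pseudo-labels unlabeled
#' samples and how the student is trained on the enlarged dataset.
#' Survival models have no native classes, so the teacher's log-risk is
#' discretized into `n_risk_bins` quantile bins; bin scores are softened
#' with temperature `temperature` into the soft label distribution whose
#' maximum is the pseudo-label's confidence.
#'
#' @param temperature Softmax temperature `tau > 0`; large values flatten
#'   the soft distribution towards uniform, small values sharpen it
#'   towards one-hot.
#' @param n_risk_bins Number of risk classes (>= 2) the teacher's training
#'   log-risk range is cut into.
#' @param max_rounds Maximum teacher-student rounds (>= 1).
#' @param confidence_threshold Minimum soft-label confidence for a
#'   pseudo-label to enter student training, in `[0, 1]`.
#' @param pseudo_as_censored Treat pseudo-labeled samples as censored at
#'   the imputed time instead of as events (sensitivity option).
#' @param random_seed Integer seed for the loop's internal splits.
#' @return A `distillation_config` list.
#' @export
distillation_config <- function(temperature = 2, n_risk_bins = 4,
                                max_rounds = 3, confidence_threshold = 0.7,
                                pseudo_as_censored = FALSE, random_seed = 1) {
  cfg <- list(temperature = temperature, n_risk_bins = as.integer(n_risk_bins),
              max_rounds = as.integer(max_rounds),
              confidence_threshold = confidence_threshold,
              pseudo_as_censored = isTRUE(pseudo_as_censored),
              random_seed = as.integer(random_seed))
  check_number(cfg$temperature, "temperature", 1e-12)
  if (cfg$n_risk_bins < 2) stop_dfsc("n_risk_bins must be >= 2")
  if (cfg$max_rounds < 1) stop_dfsc("max_rounds must be >= 1")
  check_number(cfg$confidence_threshold, "confidence_threshold", 0, 1)
  structure(cfg, class = "distillation_config")
}

#' Temperature-scaled softmax
#'
#' `P(y) = exp(f[y] / tau) / sum_y' exp(f[y'] / tau)`, computed with
#' max-subtraction. As `tau -> Inf` the output approaches uniform; as
#' `tau -> 0+` it approaches one-hot at the argmax. Adding a constant to
#' all scores leaves the result unchanged.
#'
#' @param scores Numeric vector of bin scores, or a matrix with one row
#'   per sample.
#' @param temperature Scalar `tau > 0`.
#' @return Probability vector (or row-stochastic matrix) of the same shape.
#' @examples
#' soften(c(2, 0), temperature = 2)  # ~ (0.731, 0.269)
#' @export
soften <- function(scores, temperature) {
  check_number(temperature, "temperature", 1e-300)
  if (!all(is.finite(scores))) stop_dfsc("scores must be finite")
  if (is.matrix(scores)) {
    z <- scores / temperature
    z <- z - apply(z, 1, max)
    e <- exp(z)
    e / rowSums(e)
  } else {
    z <- scores / temperature
    e <- exp(z - max(z))
    e / sum(e)
  }
}

#' Distillation loss (soft cross-entropy)
#'
#' Mean over samples of `-sum_y PT(y) log PS(y)`, the cross-entropy of
#' the student's soft distribution under the teacher's. Minimized over
#' the student exactly at `PS = PT` (Gibbs' inequality), where it equals
#' the teacher's entropy; `0 * log 0` is taken as 0.
#'
#' @param teacher,student Probability vectors, or matrices with one
#'   distribution per row; rows must sum to 1.
#' @return Non-negative scalar (per-sample mean).
#' @examples
#' distillation_loss(c(0.5, 0.5), c(0.5, 0.5))  # log(2)
#' @export
distillation_loss <- function(teacher, student) {
  PT <- if (is.matrix(teacher)) teacher else matrix(teacher, nrow = 1)
  PS <- if (is.matrix(student)) student else matrix(student, nrow = 1)
  if (!identical(dim(PT), dim(PS))) stop_dfsc("teacher and student shapes differ")
  if (any(PT < 0) || any(PS < 0)) stop_dfsc("distributions must be non-negative")
  if (any(abs(rowSums(PT) - 1) > 1e-6) || any(abs(rowSums(PS) - 1) > 1e-6))
    stop_dfsc("rows must be normalized probability distributions")
  ll <- ifelse(PT > 0, PT * log(pmax(PS, 0)), 0)  # 0 log 0 = 0; PS=0 with PT>0 -> -Inf
  mean(-rowSums(ll))
}

# Soft risk-class construction for a teacher model. The teacher's training
# log-risk is z-scored (the Cox linear predictor's scale is arbitrary, so
# any confidence gate must be scale-invariant) and cut into quantile bins.
# A sample's bin score is the log probability mass of that bin under a
# Gaussian kernel centred at the sample's standardized risk, with
# bandwidth half the mean spacing of the bin centers: samples confidently
# inside one bin (in particular, clearly extreme-risk samples) approach
# one-hot membership, while samples near a boundary stay ambiguous.
risk_bins <- function(train_eta, n_bins) {
  mu <- mean(train_eta)
  sd <- stats::sd(train_eta)
  if (!is.finite(sd) || sd < 1e-12) sd <- 1
  z <- (train_eta - mu) / sd
  breaks <- stats::quantile(z, probs = seq_len(n_bins - 1) / n_bins, names = FALSE)
  centers <- stats::quantile(z, probs = (seq_len(n_bins) - 0.5) / n_bins,
                             names = FALSE)
  h <- max(mean(diff(centers)) / 2, 1e-6)
  list(mu = mu, sd = sd, breaks = breaks, centers = centers, bandwidth = h)
}

soft_risk_distribution <- function(eta, bins, temperature) {
  z <- (eta - bins$mu) / bins$sd
  bounds <- c(-Inf, bins$breaks, Inf)
  P <- vapply(seq_len(length(bounds) - 1), function(k)
    stats::pnorm((bounds[k + 1] - z) / bins$bandwidth) -
      stats::pnorm((bounds[k] - z) / bins$bandwidth),
    numeric(length(z)))
  P <- matrix(P, nrow = length(z))
  rownames(P) <- names(eta)
  soften(log(pmax(P, 1e-300)), temperature)
}

#' Pseudo-label unlabeled samples with a fitted cascade
#'
#' The teacher predicts each unlabeled sample's survival curve on its
#' baseline event-time grid; the imputed event time is the median
#' survival time (first grid time where the curve drops to 0.5 or below,
#' or the last observed event time if it never does). The teacher's
#' log-risk is mapped to a temperature-softened distribution over risk
#' bins; only pseudo-labels whose maximum soft probability reaches
#' `confidence_threshold` are returned.
#'
#' @param teacher A fitted [fit_cascade()] model.
#' @param unlabeled A [survival_dataset()] (its outcome columns, if any,
#'   are ignored); may have zero rows.
#' @param config A [distillation_config()].
#' @return A data.frame of class `pseudo_labels` with columns
#'   `sample_id`, `imputed_time`, `imputed_event`, `confidence`, and the
#'   soft distributions in `attr(, "soft")`.
#' @export
pseudo_label <- function(teacher, unlabeled, config = distillation_config()) {
  stopifnot(inherits(teacher, "cascade_model"), inherits(config, "distillation_config"))
  empty <- data.frame(sample_id = character(0), imputed_time = numeric(0),
                      imputed_event = numeric(0), confidence = numeric(0))
  if (n_samples(unlabeled) == 0)
    return(structure(empty, soft = NULL, class = c("pseudo_labels", "data.frame")))
  eta <- cascade_predict_risk(teacher, unlabeled$X)
  grid <- teacher$baseline$event_times
  S <- predict_survival_function(eta, teacher$baseline, grid)
  imputed <- apply(S, 1, function(s) {
    hit <- which(s <= 0.5)
    if (length(hit)) grid[hit[1]] else grid[length(grid)]
  })
  bins <- risk_bins(teacher$train_eta, config$n_risk_bins)
  soft <- soft_risk_distribution(eta, bins, config$temperature)
  conf <- apply(soft, 1, max)
  keep <- conf >= config$confidence_threshold
  out <- data.frame(sample_id = unlabeled$sample_ids,
                    imputed_time = as.numeric(imputed),
                    imputed_event = if (config$pseudo_as_censored) 0 else 1,
                    confidence = as.numeric(conf))[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, soft = soft[keep, , drop = FALSE],
            class = c("pseudo_labels", "data.frame"))
}

#' Fit a semi-supervised deep survival forest (teacher-student loop)
#'
#' Round 0 fits a supervised cascade on the labeled data. Each following
#' round pseudo-labels the unlabeled pool with the current teacher,
#' refits a student cascade on labeled plus accepted pseudo-labeled rows
#' (the labeled validation split is reused every round, so pseudo rows
#' never enter validation), tracks the distillation loss between teacher
#' and student soft risk distributions on the pseudo pool, and promotes
#' the student to teacher. The model with the best labeled-validation
#' concordance across rounds is returned, so the result is never worse
#' than the supervised fit on that criterion.
#'
#' @param labeled A [survival_dataset()] of labeled samples.
#' @param unlabeled A [survival_dataset()] whose outcomes are unknown
#'   (may be empty: the supervised fit is returned with a notice).
#' @param cascade_cfg A [cascade_config()].
#' @param distill_cfg A [distillation_config()].
#' @return A `cascade_model` with an extra `dfsc` element holding the
#'   round history, the pseudo-label audit table (`sample_id`,
#'   `imputed_time`, `confidence`, `round`) and the selected round.
#' @export
fit_dfsc <- function(labeled, unlabeled, cascade_cfg = cascade_config(),
                     distill_cfg = distillation_config()) {
  stopifnot(inherits(distill_cfg, "distillation_config"))
  labeled <- labeled_subset(labeled)
  model0 <- fit_cascade(labeled, cascade_cfg)
  val_ids <- model0$validation_ids
  val_idx <- match(val_ids, labeled$sample_ids)
  score_of <- function(model) {
    eta <- cascade_predict_risk(model, labeled$X[val_idx, , drop = FALSE])
    concordance_index(labeled$time[val_idx], labeled$event[val_idx], eta)
  }
  history <- data.frame(round = 0L, n_pseudo = 0L,
                        val_cindex = score_of(model0), distill_loss = NA_real_)
  audit <- data.frame(sample_id = character(0), imputed_time = numeric(0),
                      confidence = numeric(0), round = integer(0))
  best <- model0; best_score <- history$val_cindex[1]; best_round <- 0L

  n_unl <- if (is.null(unlabeled)) 0L else n_samples(unlabeled)
  if (n_unl == 0L) {
    message("no unlabeled samples: returning the supervised cascade fit")
    best$dfsc <- list(history = history, audit = audit, selected_round = 0L)
    return(best)
  }

  teacher <- model0
  for (r in seq_len(distill_cfg$max_rounds)) {
    pl <- pseudo_label(teacher, unlabeled, distill_cfg)
    if (nrow(pl) == 0) break
    audit <- rbind(audit, data.frame(sample_id = pl$sample_id,
                                     imputed_time = pl$imputed_time,
                                     confidence = pl$confidence, round = r))
    pidx <- match(pl$sample_id, unlabeled$sample_ids)
    comb <- survival_dataset(
      rbind(labeled$X, unlabeled$X[pidx, , drop = FALSE]),
      time = c(labeled$time, pl$imputed_time),
      event = c(labeled$event, pl$imputed_event),
      sample_ids = c(labeled$sample_ids, paste0(".pseudo_", pl$sample_id)),
      gene_ids = labeled$gene_ids)
    student <- fit_cascade(comb, cascade_cfg, validation_ids = val_ids)
    # distillation tracking: student's soft risk distributions against the
    # teacher's, over the accepted pseudo pool, in the teacher's bins
    bins <- risk_bins(teacher$train_eta, distill_cfg$n_risk_bins)
    eta_s <- cascade_predict_risk(student, unlabeled$X[pidx, , drop = FALSE])
    PS <- soft_risk_distribution(eta_s, bins, distill_cfg$temperature)
    dl <- distillation_loss(attr(pl, "soft"), PS)
    sc <- score_of(student)
    history <- rbind(history, data.frame(round = r, n_pseudo = nrow(pl),
                                         val_cindex = sc, distill_loss = dl))
    if (sc > best_score + 1e-12) {
      best <- student; best_score <- sc; best_round <- r
    } else break  # labeled-validation concordance stopped improving
    teacher <- student
  }
  best$dfsc <- list(history = history, audit = audit, selected_round = best_round)
  best
}
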