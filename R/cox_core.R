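#' Risk set at a sample's observed time
#'
#' The index set of labeled samples still event-free and under observation
#' at sample `j`'s observed time, i.e. `{i : T_i >= T_j}` over labeled
#' samples. The subject itself is included (standard Cox convention).
#'
#' @param dataset A [survival_dataset()].
#' @param j Index of a labeled sample.
#' @return Integer vector of sample indices (into `dataset`).
#' @export
risk_set <- function(dataset, j) {
  j <- as.integer(j)
  if (j < 1L || j > n_samples(dataset)) stop_dfsc("sample index out of range")
  if (!dataset$labeled_mask[j])
    stop_dfsc("sample ", dataset$sample_ids[j], " has no observed outcome (unlabeled)")
  lab <- which(dataset$labeled_mask)
  lab[dataset$time[lab] >= dataset$time[j]]
}

# Core log partial likelihood on plain vectors (Breslow ties).
# Risk-set sums are computed once by sorting; log-domain with max shift.
cox_loglik_vec <- function(eta, time, event) {
  stopifnot(length(eta) == length(time), length(time) == length(event))
  if (!all(is.finite(eta))) stop_dfsc("eta must be finite")
  if (sum(event) == 0) {
    warning("all samples censored: partial likelihood is an empty product")
    return(0)
  }
  ord <- order(time, decreasing = TRUE)
  eta_o <- eta[ord]
  m <- max(eta)
  # log cumulative sum of exp(eta) over samples with time >= t, walking
  # from the latest time backwards; ties share the same denominator.
  cs <- cumsum(exp(eta_o - m))
  t_o <- time[ord]
  # for each sample j, denominator index = last position in ord with time >= t_j
  pos <- findInterval(-time, sort(-t_o))  # rank among descending times, ties -> last
  log_denom <- log(cs[pos]) + m
  sum(event * (eta - log_denom))
}

#' Cox log partial likelihood
#'
#' Log of the Cox partial likelihood for a fixed linear predictor, with
#' Breslow handling of tied event times: censored subjects contribute only
#' through risk sets. Computed in the log domain with max-subtraction so
#' large forest-derived scores cannot overflow.
#'
#' @param eta Per-sample log-risk, aligned with the labeled samples of
#'   `dataset` (or with all samples; unlabeled entries are ignored).
#' @param dataset A [survival_dataset()].
#' @return The log partial likelihood (a single number, <= 0 for eta = 0).
#' @examples
#' ds <- survival_dataset(matrix(0, 2, 1), time = c(1, 2), event = c(1, 1))
#' cox_partial_likelihood(c(0, 0), ds)  # log(1/2)
#' @export
cox_partial_likelihood <- function(eta, dataset) {
  lab <- which(dataset$labeled_mask)
  if (length(eta) == n_samples(dataset)) eta <- eta[lab]
  if (length(eta) != length(lab))
    stop_dfsc("eta must align with the labeled samples")
  cox_loglik_vec(eta, dataset$time[lab], dataset$event[lab])
}

#' Breslow estimator of the cumulative baseline hazard
#'
#' Increments `d_k / sum_{i in R(t_k)} exp(eta_i)` at each distinct event
#' time `t_k`, where `d_k` counts events at `t_k`.
#'
#' @inheritParams cox_partial_likelihood
#' @return An object of class `baseline_hazard`: list with sorted distinct
#'   `event_times` and the aligned non-decreasing `cumulative_hazard`.
#' @export
breslow_baseline <- function(eta, dataset) {
  lab <- which(dataset$labeled_mask)
  if (length(eta) == n_samples(dataset)) eta <- eta[lab]
  if (length(eta) != length(lab)) stop_dfsc("eta must align with the labeled samples")
  time <- dataset$time[lab]; event <- dataset$event[lab]
  if (sum(event) == 0) stop_dfsc("no events: baseline hazard is undefined")
  if (!all(is.finite(eta))) stop_dfsc("eta must be finite")
  ut <- sort(unique(time[event == 1]))
  m <- max(eta)
  inc <- vapply(ut, function(tk) {
    d <- sum(event == 1 & time == tk)
    d / (exp(m) * sum(exp(eta[time >= tk] - m)))
  }, numeric(1))
  structure(list(event_times = ut, cumulative_hazard = cumsum(inc)),
            class = "baseline_hazard")
}

# Step-function evaluation of the cumulative baseline hazard: 0 before the
# first event time, last value after the last.
eval_cumhaz <- function(baseline, t) {
  idx <- findInterval(t, baseline$event_times)
  c(0, baseline$cumulative_hazard)[idx + 1L]
}

#' Predicted survival probabilities from a baseline hazard
#'
#' `S(t | x) = exp(-H0(t) * exp(eta))` under proportional hazards.
#'
#' @param eta Per-sample log-risk.
#' @param baseline A `baseline_hazard` from [breslow_baseline()].
#' @param t Non-negative evaluation time(s).
#' @return A matrix of survival probabilities, `length(eta)` rows x
#'   `length(t)` columns, values in (0, 1].
#' @export
predict_survival_function <- function(eta, baseline, t) {
  if (any(t < 0)) stop_dfsc("t must be non-negative")
  if (!all(is.finite(eta))) stop_dfsc("eta must be finite")
  H <- eval_cumhaz(baseline, t)
  out <- exp(-outer(exp(eta), H))
  dimnames(out) <- list(names(eta), NULL)
  out
}
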