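#' Harrell's concordance index
#'
#' A pair `(i, j)` is comparable iff `time_i < time_j` and sample `i` had
#' the event; it is concordant when the earlier event carries the higher
#' predicted risk. Risk ties count 1/2. Returns
#' `(concordant + 0.5 * tied) / comparable`.
#'
#' @param time,event,risk Aligned numeric vectors: follow-up time, event
#'   indicator in `{0, 1}`, predicted risk (higher = worse prognosis).
#' @return Concordance in `[0, 1]`; 0.5 is random ranking.
#' @examples
#' concordance_index(c(2, 4, 5), c(1, 0, 1), c(0.5, 0.2, 0.9))  # 0.5
#' @export
concordance_index <- function(time, event, risk) {
  stopifnot(length(time) == length(event), length(time) == length(risk))
  if (anyNA(time) || anyNA(event) || anyNA(risk)) stop_dfsc("missing values in inputs")
  comp <- outer(time, time, "<") & (event == 1)   # rows i: earlier, uncensored
  n_comp <- sum(comp)
  if (n_comp == 0) stop_dfsc("no comparable pairs (all censored or all times tied)")
  conc <- sum(comp & outer(risk, risk, ">"))
  ties <- sum(comp & outer(risk, risk, "=="))
  (conc + 0.5 * ties) / n_comp
}

# Kaplan-Meier estimate of the censoring survival function G(t), with
# left-limit evaluation G(t-) for event weights.
censoring_km <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  list(times = fit$time, surv = fit$surv)
}

eval_km <- function(km, t, left = FALSE) {
  # left = TRUE evaluates G(t-): strictly-before step
  idx <- if (left) findInterval(t, km$times, left.open = TRUE)
         else findInterval(t, km$times)
  c(1, km$surv)[idx + 1L]
}

#' Inverse-probability-of-censoring-weighted Brier score at time t
#'
#' Mean squared distance between observed survival status at `t` and the
#' predicted survival probability, reweighted by the Kaplan-Meier estimate
#' of the censoring distribution: subjects with an event before `t` weigh
#' `1 / G(T_i-)`, subjects still at risk past `t` weigh `1 / G(t)`, and
#' subjects censored before `t` contribute nothing.
#'
#' @param time,event Observed follow-up data.
#' @param surv_prob Predicted `S(t | x_i)` per sample.
#' @param t Evaluation time.
#' @param censor_km Optional censoring Kaplan-Meier (as returned by the
#'   internal estimator); by default estimated from `time`, `event`.
#' @return The weighted Brier score (in `[0, 1]` under valid weights).
#' @export
brier_score <- function(time, event, surv_prob, t, censor_km = NULL) {
  stopifnot(length(time) == length(event), length(time) == length(surv_prob))
  km <- censor_km %||% censoring_km(time, event)
  n <- length(time)
  had_event <- time <= t & event == 1
  at_risk <- time > t
  w <- numeric(n)
  if (any(had_event)) {
    g <- eval_km(km, time[had_event], left = TRUE)
    if (any(g <= 0)) stop_dfsc("censoring survival is 0 at an event time <= t; use a smaller t")
    w[had_event] <- 1 / g
  }
  if (any(at_risk)) {
    gt <- eval_km(km, t)
    if (gt <= 0) stop_dfsc("censoring survival is 0 at t; use a smaller t")
    w[at_risk] <- 1 / gt
  }
  resid <- numeric(n)
  resid[had_event] <- (0 - surv_prob[had_event])^2
  resid[at_risk] <- (1 - surv_prob[at_risk])^2
  sum(w * resid) / n
}

#' Integrated Brier score over a time grid
#'
#' Trapezoidal average of [brier_score()] over `grid`, normalized by the
#' grid span, giving one scalar summary of prediction error.
#'
#' @param time,event Observed follow-up data.
#' @param surv_curves Matrix of predicted survival probabilities, samples
#'   as rows, one column per grid time.
#' @param grid Increasing evaluation times.
#' @return The integrated Brier score.
#' @export
integrated_brier <- function(time, event, surv_curves, grid) {
  if (length(grid) == 0) stop_dfsc("empty time grid")
  surv_curves <- as.matrix(surv_curves)
  stopifnot(ncol(surv_curves) == length(grid), nrow(surv_curves) == length(time))
  km <- censoring_km(time, event)
  bs <- vapply(seq_along(grid), function(k)
    brier_score(time, event, surv_curves[, k], grid[k], censor_km = km),
    numeric(1))
  if (length(grid) == 1) return(bs)
  span <- diff(range(grid))
  sum(diff(grid) * (utils::head(bs, -1) + utils::tail(bs, -1)) / 2) / span
}
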