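# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Numerically stable log(sum(exp(x)))
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Derive a child RNG seed from a base seed and integer tags.
# Kept below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  s <- as.double(seed) %% 2147483647
  for (t in tags) s <- (s * 69069 + as.double(t) * 7919 + 1) %% 2147483647
  as.integer(s)
}

# Evaluate expr with a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_dfsc <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop_dfsc(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper))
  x
}

# Event-stratified assignment of n samples to k folds; returns integer fold
# ids. The fold counter continues across the event/censored groups so total
# fold sizes stay balanced (within one) as well as event-balanced.
stratified_folds <- function(event, k, seed) {
  with_seed(seed, {
    fold <- integer(length(event))
    offset <- 0L
    for (grp in list(which(event == 1), which(event != 1))) {
      if (length(grp)) {
        grp <- sample(grp)
        fold[grp] <- ((offset + seq_along(grp) - 1L) %% k) + 1L
        offset <- offset + length(grp)
      }
    }
    fold
  })
}
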