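#' Joint log-probability of a state path and a sequence
#'
#' Computes `log P(pi, x) = sum_t [log a_{pi[t-1],pi[t]} + log b_{pi[t]}(x_t)]`
#' with `pi[0] = I`, plus the end weight of the final state when the model
#' carries explicit end weights. Any zero factor gives `-Inf`.
#'
#' @param h an [hmm()] object.
#' @param x a sequence ([hmm_sequence()] or string).
#' @param states character vector of state names (or integer state indices)
#'   of length `n`, the path `pi_1..pi_n` (the silent start is implicit).
#' @return the log joint probability (possibly `-Inf`).
#' @export
path_log_prob <- function(h, x, states) {
  sym <- .encode_seq(h, x)
  n <- length(sym)
  idx <- if (is.numeric(states)) as.integer(states) else .state_indices(h, states)
  if (length(idx) != n)
    stop(sprintf("path length %d does not match sequence length %d",
                 length(idx), n))
  lg <- .hmm_logs(h)
  from <- c(1L, idx[-n] + 1L)              # rows of lt: 1 = I, j+1 = state j
  lp <- sum(lg$lt[cbind(from, idx)]) + sum(lg$le[cbind(idx, sym)]) +
    unname(lg$lend[idx[n]])
  if (is.nan(lp)) -Inf else lp
}

## numerically stable log(sum(exp(v)))
.lse <- function(v) {
  mx <- max(v)
  if (mx == -Inf) return(-Inf)
  mx + log(sum(exp(v - mx)))
}

#' Total log-probability of a sequence (forward algorithm)
#'
#' Sums the joint probability over all state paths, in log space with
#' log-sum-exp. The result is the denominator for conditional path
#' probabilities `P(pi | x) = exp(log P(pi, x) - log P(x))`.
#'
#' @inheritParams path_log_prob
#' @return `log P(x)`.
#' @export
forward_log_prob <- function(h, x) {
  sym <- .encode_seq(h, x)
  lg <- .hmm_logs(h)
  m <- h$m
  alpha <- lg$lt[1L, ] + lg$le[cbind(seq_len(m), sym[1L])]
  if (length(sym) > 1L) {
    body <- lg$lt[-1L, , drop = FALSE]     # m x m, from x to
    for (t in 2L:length(sym)) {
      alpha <- apply(body + alpha, 2L, .lse) +
        lg$le[cbind(seq_len(m), sym[t])]
    }
  }
  .lse(alpha + lg$lend)
}

#' Total log-probability of the paths consistent with a labelling
#'
#' Runs the forward algorithm restricted, at every position, to the states
#' whose label matches the labelling. A finite result means at least one
#' positive-probability state path realizes the labelling, i.e. the
#' labelling is consistent with the model; `-Inf` means no such path
#' exists. Used to flag consensus labellings that voting procedures can
#' produce but the model cannot.
#'
#' @inheritParams path_log_prob
#' @param labels character vector of per-position labels, length `n`.
#' @return log of the summed joint probability of all matching paths.
#' @export
labelling_log_prob <- function(h, x, labels) {
  sym <- .encode_seq(h, x)
  if (length(labels) == 1L && nchar(labels) > 1L)
    labels <- strsplit(labels, "", fixed = TRUE)[[1L]]
  if (length(labels) != length(sym))
    stop("labelling length does not match sequence length")
  lg <- .hmm_logs(h)
  m <- h$m
  mask <- function(t) ifelse(h$labels == labels[t], 0, -Inf)
  alpha <- lg$lt[1L, ] + lg$le[cbind(seq_len(m), sym[1L])] + mask(1L)
  if (length(sym) > 1L) {
    body <- lg$lt[-1L, , drop = FALSE]
    for (t in 2L:length(sym)) {
      alpha <- apply(body + alpha, 2L, .lse) +
        lg$le[cbind(seq_len(m), sym[t])] + mask(t)
    }
  }
  .lse(alpha + lg$lend)
}
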