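#' Construct a hidden Markov model
#'
#' Builds an HMM over a finite symbol alphabet with a silent start state
#' `"I"`, per-state emission distributions, and per-state labels (for
#' example `"i"`, `"M"`, `"o"` for inside/membrane/outside in transmembrane
#' topology models). The start state emits nothing and has no incoming
#' transitions; every path starts there at position 0.
#'
#' Termination: by default every state may end a path with weight 1, i.e.
#' the model defines a distribution over state paths of each fixed length.
#' If `ends` is supplied, each state's outgoing transition probabilities
#' plus its end weight must sum to one, and the end weight of a path's last
#' state enters its joint probability.
#'
#' @param states character vector of state names (must not contain `"I"`).
#' @param labels character vector of labels, one per state.
#' @param trans numeric `(m+1) x m` matrix of transition probabilities; row
#'   1 is the start state `"I"`, rows `2..m+1` follow `states`; columns
#'   follow `states`.
#' @param emis numeric `m x length(alphabet)` matrix of emission
#'   probabilities, rows follow `states`, columns follow `alphabet`.
#' @param alphabet character vector of single-character symbols.
#' @param ends optional numeric vector of per-state termination weights.
#' @return an object of class `"hmm"`.
#' @seealso [validate_hmm()], [read_hmm()], [decode_kbest()]
#' @examples
#' h <- hmm(
#'   states = c("A", "B"), labels = c("i", "o"),
#'   trans = rbind(I = c(1, 0), A = c(0.5, 0.5), B = c(0.1, 0.9)),
#'   emis = rbind(A = c(0.9, 0.1), B = c(0.2, 0.8)),
#'   alphabet = c("x", "y")
#' )
#' validate_hmm(h)
#' @export
hmm <- function(states, labels, trans, emis, alphabet, ends = NULL) {
  states <- as.character(states)
  m <- length(states)
  stopifnot(m >= 1, length(labels) == m)
  trans <- as.matrix(trans)
  emis <- as.matrix(emis)
  if (!identical(dim(trans), c(m + 1L, m)))
    stop("trans must be an (m+1) x m matrix (row 1 = start state I)")
  if (!identical(dim(emis), c(m, length(alphabet))))
    stop("emis must be an m x |alphabet| matrix")
  if (any(nchar(alphabet) != 1L))
    stop("alphabet symbols must be single characters")
  if ("I" %in% states)
    stop("'I' is reserved for the silent start state")
  dimnames(trans) <- list(c("I", states), states)
  dimnames(emis) <- list(states, alphabet)
  if (!is.null(ends)) {
    stopifnot(length(ends) == m)
    ends <- stats::setNames(as.numeric(ends), states)
  }
  structure(
    list(
      states = states,
      labels = stats::setNames(as.character(labels), states),
      alphabet = as.character(alphabet),
      trans = trans,
      emis = emis,
      ends = ends,
      m = m
    ),
    class = "hmm"
  )
}

#' @export
print.hmm <- function(x, ...) {
  cat(sprintf(
    "Hidden Markov model: %d states, %d symbols, labels {%s}%s\n",
    x$m, length(x$alphabet),
    paste(sort(unique(x$labels)), collapse = ","),
    if (is.null(x$ends)) "" else ", explicit end weights"
  ))
  cat("states:", paste(utils::head(x$states, 12L), collapse = " "),
      if (x$m > 12L) "..." else "", "\n")
  invisible(x)
}

#' Validate an HMM's structural invariants
#'
#' Checks, without raising errors, that every transition row is stochastic
#' (including end weights when present), that every emission row is
#' stochastic, that probabilities are non-negative, that every state has a
#' label, and that every state is reachable from the start state through
#' positive-probability transitions. Row sums are checked to a tolerance of
#' `1e-9`.
#'
#' @param h an [hmm()] object.
#' @param tol numeric tolerance for stochasticity checks.
#' @return character vector of human-readable violations; empty if the
#'   model is well formed.
#' @export
validate_hmm <- function(h, tol = 1e-9) {
  out <- character()
  if (!inherits(h, "hmm")) return("not an hmm object")
  if (any(h$trans < 0)) {
    bad <- rownames(h$trans)[apply(h$trans < 0, 1L, any)]
    out <- c(out, sprintf("negative transition probability in row '%s'", bad))
  }
  if (any(h$emis < 0)) {
    bad <- rownames(h$emis)[apply(h$emis < 0, 1L, any)]
    out <- c(out, sprintf("negative emission probability for state '%s'", bad))
  }
  endw <- if (is.null(h$ends)) rep(0, h$m) else h$ends
  if (!is.null(h$ends) && any(endw < 0))
    out <- c(out, "negative end weight")
  rs <- rowSums(h$trans) + c(0, endw)
  bad <- which(abs(rs - 1) > tol)
  if (length(bad))
    out <- c(out, sprintf(
      "transition row for '%s' sums to %.12g, not 1",
      rownames(h$trans)[bad], rs[bad]
    ))
  es <- rowSums(h$emis)
  bad <- which(abs(es - 1) > tol)
  if (length(bad))
    out <- c(out, sprintf(
      "emission row for state '%s' sums to %.12g, not 1",
      h$states[bad], es[bad]
    ))
  if (any(is.na(h$labels) | !nzchar(h$labels)))
    out <- c(out, sprintf(
      "state '%s' has no label", h$states[is.na(h$labels) | !nzchar(h$labels)]
    ))
  ## reachability from I over positive edges
  reach <- rep(FALSE, h$m)
  frontier <- which(h$trans[1L, ] > 0)
  reach[frontier] <- TRUE
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, function(s)
      which(h$trans[s + 1L, ] > 0))))
    nxt <- nxt[!reach[nxt]]
    reach[nxt] <- TRUE
    frontier <- nxt
  }
  if (!all(reach))
    out <- c(out, sprintf(
      "state '%s' is unreachable from the start state", h$states[!reach]
    ))
  out
}

#' Create a sequence object
#'
#' A sequence is a vector of single-character symbols indexed `1..n`;
#' position 0 is reserved for the silent start state of the model it is
#' decoded against.
#'
#' @param symbols a single string or a character vector of single-character
#'   symbols.
#' @param id sequence identifier.
#' @return an object of class `"hmm_sequence"` with fields `id` and
#'   `symbols`.
#' @export
hmm_sequence <- function(symbols, id = "seq") {
  if (length(symbols) == 1L && nchar(symbols) > 1L)
    symbols <- strsplit(symbols, "", fixed = TRUE)[[1L]]
  stopifnot(length(symbols) >= 1L, all(nchar(symbols) == 1L))
  structure(list(id = as.character(id), symbols = as.character(symbols)),
            class = "hmm_sequence")
}

#' @export
print.hmm_sequence <- function(x, ...) {
  n <- length(x$symbols)
  cat(sprintf(">%s (%d symbols)\n%s%s\n", x$id, n,
              paste(utils::head(x$symbols, 60L), collapse = ""),
              if (n > 60L) "..." else ""))
  invisible(x)
}

## ---- internal helpers ------------------------------------------------------

.as_seq <- function(x) {
  if (inherits(x, "hmm_sequence")) x else hmm_sequence(x)
}

## encode sequence symbols as 1-based alphabet indices
.encode_seq <- function(h, x) {
  x <- .as_seq(x)
  idx <- match(x$symbols, h$alphabet)
  if (anyNA(idx))
    stop(sprintf("sequence '%s' contains symbols outside the model alphabet: %s",
                 x$id, paste(unique(x$symbols[is.na(idx)]), collapse = " ")))
  idx
}

## log-space parameter matrices shared by every decoder, computed once so
## that all engines add bitwise-identical factors
.hmm_logs <- function(h) {
  list(
    lt = log(h$trans),                          # (m+1) x m, row 1 = I
    le = log(h$emis),                           # m x |alphabet|
    lend = if (is.null(h$ends)) rep(0, h$m) else log(h$ends)
  )
}

.state_indices <- function(h, states) {
  idx <- match(states, h$states)
  if (anyNA(idx))
    stop(sprintf("unknown state(s): %s",
                 paste(unique(states[is.na(idx)]), collapse = " ")))
  idx
}

## round half away from zero (base round() is banker's rounding)
.round_half_up <- function(x) floor(x + 0.5)
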