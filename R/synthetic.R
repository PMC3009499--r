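## Seeded generators: random HMMs, sampled sequences with known generating
## paths, and the membrane-protein-like fixtures used throughout the tests.

## run code under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

#' Generate a random valid HMM
#'
#' Draws a connected random model: a random cycle through all states
#' guarantees reachability from the start state and an outgoing edge for
#' every state; each remaining potential edge is present independently
#' with probability `sparsity`. Present edges get independent uniform
#' weights, normalized row-wise. Emission rows are normalized uniforms.
#' Output is fully determined by `seed`.
#'
#' @param m number of states.
#' @param n_symbols alphabet size (symbols are letters `a`, `b`, ...).
#' @param label_set labels to assign (uniformly at random) to states.
#' @param sparsity probability of each optional transition edge.
#' @param seed integer seed.
#' @param with_ends if `TRUE`, give every state a random termination
#'   weight (its transition row then sums to one including the end
#'   weight).
#' @return a valid [hmm()] (passes [validate_hmm()]).
#' @export
random_hmm <- function(m, n_symbols = 4L, label_set = c("i", "M", "o"),
                       sparsity = 0.5, seed = 1L, with_ends = FALSE) {
  stopifnot(m >= 1L, n_symbols >= 1L, sparsity >= 0, sparsity <= 1)
  .with_seed(seed, {
    perm <- sample.int(m)
    mask <- matrix(runif((m + 1L) * m) < sparsity, m + 1L, m)
    mask[1L, perm[1L]] <- TRUE                        # I -> first cycle state
    for (t in seq_len(m))                             # cycle keeps all reachable
      mask[perm[t] + 1L, perm[if (t == m) 1L else t + 1L]] <- TRUE
    w <- matrix(runif((m + 1L) * m), m + 1L, m) * mask
    ends <- NULL
    if (with_ends) {
      ends <- runif(m, 0.05, 0.3)
      w[-1L, ] <- w[-1L, ] / rowSums(w[-1L, , drop = FALSE]) * (1 - ends)
      w[1L, ] <- w[1L, ] / sum(w[1L, ])
    } else {
      w <- w / rowSums(w)
    }
    e <- matrix(runif(m * n_symbols), m, n_symbols)
    e <- e / rowSums(e)
    h <- hmm(
      states = sprintf("s%02d", seq_len(m)),
      labels = sample(label_set, m, replace = TRUE),
      trans = w, emis = e,
      alphabet = letters[seq_len(n_symbols)],
      ends = ends
    )
    v <- validate_hmm(h)
    if (length(v)) stop(paste("generated model invalid:", v[1L]))
    h
  })
}

#' Sample a sequence (and its generating path) from an HMM
#'
#' Performs a stochastic walk of exactly `n` emitting steps from the start
#' state, recording the emitted symbols and the state path that produced
#' them. When the model has explicit end weights, the walk is conditioned
#' on surviving `n` steps (transition rows are renormalized over
#' non-terminal moves). Deterministic under `seed`.
#'
#' @param h an [hmm()] object.
#' @param n sequence length, `>= 1`.
#' @param seed integer seed.
#' @param id identifier for the sampled sequence.
#' @return list with `sequence` (an [hmm_sequence()]) and `path` (a
#'   `scored_path` whose `log_joint` is recomputed with
#'   [path_log_prob()]).
#' @export
sample_sequence <- function(h, n, seed = 1L, id = sprintf("sim%d", seed)) {
  stopifnot(n >= 1L)
  m <- h$m
  rows <- h$trans
  rs <- rowSums(rows)
  if (any(rs[-1L] <= 0))
    stop(sprintf("state '%s' has no outgoing transitions; cannot sample",
                 h$states[which(rs[-1L] <= 0)[1L]]))
  norm <- rows / rs
  cum <- if (m == 1L) matrix(1, nrow(rows), 1L) else t(apply(norm, 1L, cumsum))
  cume <- t(apply(h$emis, 1L, cumsum))
  .with_seed(seed, {
    path <- integer(n)
    sym <- integer(n)
    cur <- 0L                                    # 0 = start state
    for (t in seq_len(n)) {
      cur <- findInterval(runif(1L), cum[cur + 1L, ]) + 1L
      path[t] <- cur
      sym[t] <- findInterval(runif(1L), cume[cur, ]) + 1L
    }
    sq <- hmm_sequence(h$alphabet[sym], id = id)
    list(sequence = sq,
         path = .scored_path(h, path, path_log_prob(h, sq, path), NA_integer_))
  })
}

#' Toy membrane-protein HMM
#'
#' A small fixed 14-state labelled model over a reduced 4-symbol residue
#' alphabet (`F`,`L` hydrophobic; `R`,`E` hydrophilic/charged), emulating
#' the architecture of transmembrane topology models: an inside loop
#' (label `i`), an inside-to-outside helix submodule and an
#' outside-to-inside helix submodule (label `M`), and an outside loop
#' (label `o`). Each helix submodule runs through five deterministic
#' states and one self-looping core state, giving mean helix lengths of
#' 22 and 21 residues and a minimum of 6, so helices far shorter than a
#' membrane crossing never occur. Inside loops are biased towards `R`,
#' outside loops towards `E`, helices strongly towards `F`/`L`, and
#' loops are long relative to helices, so sampled sequences carry
#' recoverable topology signal. Each submodule has exactly one
#' self-looping state and all dwell probabilities are pairwise
#' distinct, so a labelling has a unique state decomposition and
#' distinct state paths never tie in joint probability by
#' construction — [mirror_hmm()] then introduces exact ties
#' deliberately. Both orientations are possible starts.
#'
#' @return a valid [hmm()].
#' @export
toy_membrane_hmm <- function() {
  states <- c("in", paste0("mio", 1:6), "out", paste0("moi", 1:6))
  labels <- c("i", rep("M", 6L), "o", rep("M", 6L))
  m <- length(states)
  tr <- matrix(0, m + 1L, m, dimnames = list(c("I", states), states))
  tr["I", "in"] <- 0.5
  tr["I", "out"] <- 0.5
  tr["in", "in"] <- 0.96; tr["in", "mio1"] <- 0.04
  for (j in 1:5) tr[paste0("mio", j), paste0("mio", j + 1L)] <- 1
  tr["mio6", "mio6"] <- 16 / 17; tr["mio6", "out"] <- 1 / 17
  tr["out", "out"] <- 0.95; tr["out", "moi1"] <- 0.05
  for (j in 1:5) tr[paste0("moi", j), paste0("moi", j + 1L)] <- 1
  tr["moi6", "moi6"] <- 15 / 16; tr["moi6", "in"] <- 1 / 16
  # Exactly one self-looping state per submodule, each with a distinct
  # dwell probability. A labelling then has a unique state
  # decomposition, and shifting run lengths between twin states (the
  # two loops, or the two helix directions) changes the transition
  # product, so exact probability ties between distinct state paths do
  # not arise by construction.
  e_in <- c(F = 0.08, L = 0.07, R = 0.55, E = 0.30)
  e_ou <- c(F = 0.08, L = 0.07, R = 0.30, E = 0.55)
  e_m  <- c(F = 0.55, L = 0.35, R = 0.05, E = 0.05)
  em <- t(vapply(labels, function(l)
    switch(l, i = e_in, o = e_ou, M = e_m), numeric(4L)))
  rownames(em) <- states
  hmm(states, labels, tr, em, alphabet = c("F", "L", "R", "E"))
}

#' Mirror-symmetric dual-topology HMM
#'
#' The [toy_membrane_hmm()] duplicated into two parameter-identical
#' branches reached from the start state with equal probability; branch
#' `b` has its `i` and `o` labels swapped. Every path through branch `a`
#' therefore has a mirror path through branch `b` of exactly equal joint
#' probability but opposite sidedness — the situation of dual-topology
#' membrane proteins, whose two correct topologies differ only in
#' sidedness. Swapping the labels and exchanging the branches maps the
#' model onto itself.
#'
#' @return a valid [hmm()] with 24 states.
#' @export
mirror_hmm <- function() {
  base <- toy_membrane_hmm()
  m <- base$m
  states <- c(paste0("a_", base$states), paste0("b_", base$states))
  swap <- c(i = "o", M = "M", o = "i")
  labels <- c(unname(base$labels), unname(swap[base$labels]))
  tr <- matrix(0, 2L * m + 1L, 2L * m,
               dimnames = list(c("I", states), states))
  tr[1L, seq_len(m)] <- base$trans[1L, ] / 2
  tr[1L, m + seq_len(m)] <- base$trans[1L, ] / 2
  tr[1L + seq_len(m), seq_len(m)] <- base$trans[-1L, ]
  tr[1L + m + seq_len(m), m + seq_len(m)] <- base$trans[-1L, ]
  em <- rbind(base$emis, base$emis)
  rownames(em) <- states
  hmm(states, labels, tr, em, alphabet = base$alphabet)
}
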