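# Shared fixtures for the test suite. All models here are small enough
# for exhaustive path enumeration, so they double as oracle substrates.

# Two-state fully-connected model over a binary alphabet; generic
# parameters (no ties except by construction).
two_state_hmm <- function() {
  hmm(
    states = c("A", "B"),
    labels = c("i", "o"),
    trans = rbind(c(0.6, 0.4),    # I ->
                  c(0.7, 0.3),    # A ->
                  c(0.2, 0.8)),   # B ->
    emis = rbind(c(0.9, 0.1),
                 c(0.25, 0.75)),
    alphabet = c("x", "y")
  )
}

# A chain A -> B -> C -> A ... with deterministic transitions: exactly one
# path of positive probability for any sequence length.
chain_hmm <- function() {
  hmm(
    states = c("A", "B", "C"),
    labels = c("i", "M", "o"),
    trans = rbind(c(1, 0, 0),
                  c(0, 1, 0),
                  c(0, 0, 1),
                  c(1, 0, 0)),
    emis = matrix(c(0.5, 0.5,
                    0.9, 0.1,
                    0.2, 0.8), 3, 2, byrow = TRUE),
    alphabet = c("x", "y")
  )
}

# A model with deliberate exact score ties: two states with identical
# parameters, so every path has a twin of equal probability.
twin_state_hmm <- function() {
  hmm(
    states = c("A1", "A2", "B"),
    labels = c("i", "i", "o"),
    trans = rbind(c(0.25, 0.25, 0.5),
                  c(0.2, 0.2, 0.6),
                  c(0.2, 0.2, 0.6),
                  c(0.45, 0.45, 0.1)),
    emis = rbind(c(0.8, 0.2),
                 c(0.8, 0.2),
                 c(0.3, 0.7)),
    alphabet = c("x", "y")
  )
}

# Shorthand builders.
seq_of <- function(chars) hmm_sequence(strsplit(chars, "")[[1L]], id = "t")

# Random decoding instance small enough for enumeration.
tiny_instance <- function(seed, m_max = 4L, n_max = 8L) {
  set.seed(seed)
  m <- sample.int(m_max - 1L, 1L) + 1L
  h <- random_hmm(m, n_symbols = sample(2:3, 1L), sparsity = runif(1, 0.3, 0.9),
                  seed = seed, with_ends = runif(1) < 0.3)
  n <- sample.int(n_max - 1L, 1L) + 1L
  x <- sample_sequence(h, n, seed = seed + 1L)$sequence
  list(h = h, x = x, m = m, n = n)
}

expect_same_paths <- function(a, b, tol = 1e-9) {
  expect_equal(length(a$paths), length(b$paths))
  for (i in seq_along(a$paths)) {
    expect_equal(a$paths[[i]]$log_joint, b$paths[[i]]$log_joint,
                 tolerance = tol)
    expect_identical(a$paths[[i]]$state_idx, b$paths[[i]]$state_idx)
  }
}
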