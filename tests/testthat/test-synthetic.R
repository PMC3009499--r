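test_that("random models are valid, seeded-deterministic, and seed-sensitive", {
  for (s in 1:25) expect_length(validate_hmm(random_hmm(5, seed = s)), 0)
  a <- random_hmm(6, seed = 99)
  b <- random_hmm(6, seed = 99)
  expect_identical(a, b)
  d <- random_hmm(6, seed = 100)
  expect_false(identical(a$trans, d$trans))
  # with_ends models satisfy the extended row-sum invariant
  expect_length(validate_hmm(random_hmm(4, seed = 7, with_ends = TRUE)), 0)
})

test_that("sampled sequences are reproducible and carry a finite generating score", {
  h <- random_hmm(4, seed = 11)
  a <- sample_sequence(h, 30, seed = 5)
  b <- sample_sequence(h, 30, seed = 5)
  expect_identical(a$sequence$symbols, b$sequence$symbols)
  expect_identical(a$path$state_idx, b$path$state_idx)
  expect_true(is.finite(a$path$log_joint))
  expect_equal(a$path$log_joint,
               path_log_prob(h, a$sequence, a$path$state_idx),
               tolerance = 1e-12)
})

test_that("one-state emission frequencies converge to the emission vector", {
  h <- hmm(states = "A", labels = "i",
           trans = matrix(1, 2, 1),
           emis = matrix(c(0.2, 0.3, 0.5), 1, 3),
           alphabet = c("a", "b", "c"))
  sx <- sample_sequence(h, 10000, seed = 123)
  freq <- table(factor(sx$sequence$symbols, levels = c("a", "b", "c"))) / 10000
  # 3 sigma of a binomial proportion at n = 1e4
  for (i in 1:3) {
    p <- h$emis[1, i]
    expect_lt(abs(freq[[i]] - p), 3 * sqrt(p * (1 - p) / 10000))
  }
})

test_that("membrane fixture has alternating architecture and ~22-residue helices", {
  h <- toy_membrane_hmm()
  expect_length(validate_hmm(h), 0)
  lens <- c()
  for (s in 1:40) {
    sx <- sample_sequence(h, 400, seed = 1000 + s)
    lab <- labelling_of(h, sx$path)
    # i and o segments never touch: a membrane run separates side changes
    r <- rle(lab)
    ii <- which(r$values == "i"); oo <- which(r$values == "o")
    expect_false(any(abs(outer(ii, oo, "-")) == 1L))
    tp <- topology_of(lab)
    if (tp$helix_count > 1L) {
      interior <- tp$helices[-tp$helix_count, , drop = FALSE]
      lens <- c(lens, interior[, 2] - interior[, 1] + 1)
    }
  }
  expect_gte(min(lens), 6)            # minimum helix length by construction
  expect_gt(mean(lens), 18)
  expect_lt(mean(lens), 26)
})

test_that("sampled side labels alternate between i and o across helices", {
  h <- toy_membrane_hmm()
  for (s in 1:10) {
    sx <- sample_sequence(h, 300, seed = 2000 + s)
    r <- rle(labelling_of(h, sx$path))
    side <- r$values[r$values != "M"]
    if (length(side) > 1)
      expect_true(all(side[-1] != side[-length(side)]))
  }
})

test_that("mirror model is its own image under branch exchange and label swap", {
  mh <- mirror_hmm()
  expect_length(validate_hmm(mh), 0)
  m <- mh$m / 2
  perm <- c(m + seq_len(m), seq_len(m))      # swap the two branches
  tr_perm <- mh$trans[c(1L, perm + 1L), perm]
  expect_identical(unname(tr_perm), unname(mh$trans))
  em_perm <- mh$emis[perm, ]
  expect_identical(unname(em_perm), unname(mh$emis))
  swap <- c(i = "o", M = "M", o = "i")
  expect_identical(unname(swap[mh$labels[perm]]), unname(mh$labels))
})

test_that("every decoded path of the mirror model has an equal-scoring mirror", {
  mh <- mirror_hmm()
  m <- mh$m / 2
  for (s in 1:5) {
    sx <- sample_sequence(mh, 100, seed = 3000 + s)
    res <- decode_kbest(mh, sx$sequence, k = 20, complete_ties = TRUE)
    lj <- vapply(res$paths, `[[`, 0, "log_joint")
    keys <- vapply(res$paths, function(p)
      paste(p$state_idx, collapse = ","), "")
    for (p in res$paths) {
      mirror <- ifelse(p$state_idx <= m, p$state_idx + m, p$state_idx - m)
      j <- match(paste(mirror, collapse = ","), keys)
      expect_false(is.na(j))
      expect_identical(lj[j], p$log_joint)    # bitwise equal
    }
  }
})
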