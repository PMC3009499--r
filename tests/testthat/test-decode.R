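test_that("merge_candidates reproduces a hand-worked multi-list merge", {
  # Two predecessor lists with multiplicative continuation factors:
  #   C1 = (0.5, 0.2) with factor 0.5 -> (0.25, 0.10)
  #   C2 = (0.4, 0.1) with factor 1.0 -> (0.40, 0.10)
  # The two best continuations are 0.40 (C2 rank 1) then 0.25 (C1 rank 1).
  out <- merge_candidates(
    list(C1 = log(c(0.5, 0.2)), C2 = log(c(0.4, 0.1))),
    factors = c(C1 = log(0.5), C2 = 0),
    k = 2
  )
  expect_equal(out$score, log(c(0.40, 0.25)), tolerance = 1e-12)
  expect_identical(out$pred, c("C2", "C1"))
  expect_identical(out$rank, c(1L, 1L))
})

test_that("merge_candidates consumes each list in rank order and stops at k", {
  out <- merge_candidates(
    list(A = log(c(0.9, 0.8, 0.7)), B = log(c(0.85, 0.1))),
    factors = c(A = 0, B = 0), k = 4
  )
  expect_identical(out$pred, c("A", "B", "A", "A"))
  expect_identical(out$rank, c(1L, 1L, 2L, 3L))
  expect_equal(nrow(out), 4L)
})

test_that("viterbi equals the best path of full enumeration", {
  for (s in 1:20) {
    inst <- tiny_instance(s)
    vb <- viterbi(inst$h, inst$x)
    en <- kbest_enum(inst$h, inst$x, k = 1)
    expect_equal(vb$log_joint, en$paths[[1]]$log_joint, tolerance = 1e-12)
    expect_identical(vb$state_idx, en$paths[[1]]$state_idx)
  }
})

test_that("deterministic chain model yields its single path at any k", {
  h <- chain_hmm()
  x <- seq_of("xyxyxy")
  res <- decode_kbest(h, x, k = 5)
  expect_length(res$paths, 1L)     # only one positive-probability path
  expect_identical(res$paths[[1]]$state_idx, rep(1:3, 2))
  expect_equal(res$paths[[1]]$log_joint, path_log_prob(h, x, rep(1:3, 2)),
               tolerance = 1e-12)
})

test_that("tree and naive engines agree bitwise on random instances", {
  for (s in 21:60) {
    inst <- tiny_instance(s, m_max = 6L, n_max = 12L)
    k <- sample.int(16L, 1L)
    a <- decode_kbest(inst$h, inst$x, k = k, engine = "tree")
    b <- decode_kbest(inst$h, inst$x, k = k, engine = "naive")
    expect_equal(length(a$paths), length(b$paths))
    for (i in seq_along(a$paths)) {
      expect_identical(a$paths[[i]]$state_idx, b$paths[[i]]$state_idx)
      expect_identical(a$paths[[i]]$log_joint, b$paths[[i]]$log_joint)
    }
  }
})

test_that("decoded scores round-trip through independent path scoring", {
  for (s in 61:75) {
    inst <- tiny_instance(s, m_max = 5L, n_max = 10L)
    res <- decode_kbest(inst$h, inst$x, k = 8)
    for (p in res$paths)
      expect_equal(p$log_joint, path_log_prob(inst$h, inst$x, p$state_idx),
                   tolerance = 1e-9)
  }
})

test_that("decoded lists are strictly ordered with documented tie-breaking", {
  # twin states A1/A2 have identical parameters: every path has an
  # exact-score twin; ties must order by lexicographic state indices.
  h <- twin_state_hmm()
  x <- seq_of("xxy")
  res <- decode_kbest(h, x, k = 27)
  lj <- vapply(res$paths, `[[`, 0, "log_joint")
  expect_true(all(diff(lj) <= 0))
  for (i in seq_len(length(res$paths) - 1L)) {
    if (lj[i] == lj[i + 1L]) {
      a <- res$paths[[i]]$state_idx
      b <- res$paths[[i + 1L]]$state_idx
      d <- which(a != b)[1L]
      expect_lt(a[d], b[d])
    }
  }
})

test_that("complete_ties extends exactly through the boundary tie class", {
  h <- twin_state_hmm()
  x <- seq_of("xx")
  base <- decode_kbest(h, x, k = 9)           # all paths: 3^2 = 9
  lj_all <- vapply(base$paths, `[[`, 0, "log_joint")
  for (k in 1:8) {
    ext <- decode_kbest(h, x, k = k, complete_ties = TRUE)
    kk <- length(ext$paths)
    expect_gte(kk, k)
    if (kk < 9) expect_true(lj_all[kk] != lj_all[kk + 1L])
    nai <- decode_kbest(h, x, k = k, engine = "naive", complete_ties = TRUE)
    expect_equal(length(nai$paths), kk)
  }
})

test_that("top-k lists are prefixes of top-(k+1) lists", {
  for (s in 76:95) {
    inst <- tiny_instance(s, m_max = 5L, n_max = 10L)
    a <- decode_kbest(inst$h, inst$x, k = 6)
    b <- decode_kbest(inst$h, inst$x, k = 7)
    for (i in seq_along(a$paths))
      expect_identical(a$paths[[i]]$state_idx, b$paths[[i]]$state_idx)
  }
})

test_that("requesting more paths than exist returns all of them once each", {
  h <- two_state_hmm()
  x <- seq_of("xy")
  res <- decode_kbest(h, x, k = 50)
  expect_length(res$paths, 4L)     # 2^2 paths, all positive here
  keys <- vapply(res$paths, function(p) paste(p$state_idx, collapse = ","), "")
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("probability mass of an exhaustive decode is conserved", {
  for (s in 96:110) {
    inst <- tiny_instance(s, m_max = 3L, n_max = 6L)
    res <- decode_kbest(inst$h, inst$x, k = inst$h$m^length(inst$x$symbols))
    fw <- forward_log_prob(inst$h, inst$x)
    mass <- sum(exp(vapply(res$paths, `[[`, 0, "log_joint") - fw))
    expect_equal(mass, 1, tolerance = 1e-9)
  }
})

test_that("no-path instances are reported as empty results, not errors", {
  # chain model cannot emit "x" at position 2 with positive probability?
  # build a model where the only start state cannot emit the first symbol
  h <- hmm(
    states = c("A", "B"),
    labels = c("i", "o"),
    trans = rbind(c(1, 0), c(0, 1), c(1, 0)),
    emis = rbind(c(1, 0), c(1, 0)),     # neither state emits "y"
    alphabet = c("x", "y")
  )
  x <- seq_of("xy")
  res <- decode_kbest(h, x, k = 3)
  expect_length(res$paths, 0L)
  vb <- viterbi(h, x)
  expect_true(isTRUE(vb$no_path))
  expect_identical(vb$log_joint, -Inf)
})

test_that("the compressed tree stays far below the naive backpointer size", {
  h <- toy_membrane_hmm()
  x <- sample_sequence(h, 600, seed = 11)$sequence
  res <- decode_kbest(h, x, k = 40, audit = TRUE)
  expect_lt(res$stats$peak_path_nodes / res$stats$naive_cells, 0.10)
  expect_gt(res$stats$merges, 0)
  expect_gt(res$stats$prunes, 0)
})

test_that("a deterministic chain compresses to a single state-node run", {
  h <- chain_hmm()
  x <- seq_of(paste(rep("xyx", 4), collapse = ""))
  res <- decode_kbest(h, x, k = 3, return_tree = TRUE)
  runs <- vapply(res$tree, function(nd) length(nd$run), 0L)
  # all live non-root state nodes merged into one long run
  expect_equal(sum(runs), length(x$symbols))
  expect_lte(length(runs[runs > 0]), 2L)
})

test_that("paths_table reports ranks, conditional probabilities and labels", {
  h <- toy_membrane_hmm()
  sx <- sample_sequence(h, 60, seed = 3)
  res <- decode_kbest(h, sx$sequence, k = 5)
  tab <- paths_table(res, h, sx$sequence)
  expect_identical(tab$rank, seq_len(nrow(tab)))
  expect_true(all(tab$conditional_prob > 0 & tab$conditional_prob <= 1))
  expect_true(all(nchar(tab$labelling) == 60))
})
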