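test_that("hmm constructor stores dimensions, names and labels", {
  h <- two_state_hmm()
  expect_s3_class(h, "hmm")
  expect_equal(h$m, 2L)
  expect_identical(h$states, c("A", "B"))
  expect_identical(unname(h$labels), c("i", "o"))
  expect_equal(dim(h$trans), c(3L, 2L))
  expect_equal(dim(h$emis), c(2L, 2L))
})

test_that("validate_hmm accepts valid models and reports each violation class", {
  expect_length(validate_hmm(two_state_hmm()), 0)
  expect_length(validate_hmm(chain_hmm()), 0)
  expect_length(validate_hmm(toy_membrane_hmm()), 0)

  h <- two_state_hmm()
  h$trans[2, 1] <- -0.1
  expect_true(any(grepl("negative", validate_hmm(h), ignore.case = TRUE)))

  h <- two_state_hmm()
  h$trans[2, ] <- c(0.5, 0.4)          # row sums to 0.9
  expect_true(length(validate_hmm(h)) > 0)

  h <- two_state_hmm()
  h$emis[1, ] <- c(0.7, 0.7)
  expect_true(length(validate_hmm(h)) > 0)
})

test_that("validate_hmm flags states unreachable from the start state", {
  h <- hmm(
    states = c("A", "B"),
    labels = c("i", "o"),
    trans = rbind(c(1, 0),     # I -> A only
                  c(1, 0),     # A -> A only: B unreachable
                  c(0.5, 0.5)),
    emis = rbind(c(0.5, 0.5), c(0.5, 0.5)),
    alphabet = c("x", "y")
  )
  expect_true(any(grepl("reach", validate_hmm(h), ignore.case = TRUE)))
})

test_that("explicit end weights are included in the row-sum invariant", {
  h <- hmm(
    states = c("A", "B"),
    labels = c("i", "o"),
    trans = rbind(c(0.5, 0.5),
                  c(0.4, 0.4),   # + end 0.2 = 1
                  c(0.3, 0.3)),  # + end 0.4 = 1
    emis = rbind(c(0.5, 0.5), c(0.5, 0.5)),
    alphabet = c("x", "y"),
    ends = c(0.2, 0.4)
  )
  expect_length(validate_hmm(h), 0)
  h$ends <- c(0.3, 0.4)            # rows no longer sum to one
  expect_true(length(validate_hmm(h)) > 0)
})

test_that("hmm_sequence validates symbols lazily against the model at use", {
  s <- hmm_sequence(c("x", "y", "x"), id = "s1")
  expect_s3_class(s, "hmm_sequence")
  expect_equal(length(s$symbols), 3L)
  h <- two_state_hmm()
  expect_error(path_log_prob(h, hmm_sequence(c("x", "z"), id = "bad"),
                             c(1L, 1L)))
})

test_that("path_log_prob equals the hand-computed product for a short path", {
  h <- two_state_hmm()
  x <- seq_of("xy")
  # I->A (0.6) * e_A(x) (0.9) * A->B (0.3) * e_B(y) (0.75); end weight 1
  expect_equal(path_log_prob(h, x, c(1L, 2L)),
               log(0.6) + log(0.9) + log(0.3) + log(0.75))
  # zero-probability transition gives -Inf
  h0 <- chain_hmm()
  expect_identical(path_log_prob(h0, seq_of("xx"), c(1L, 3L)), -Inf)
})

test_that("forward probability equals the sum over all paths", {
  h <- two_state_hmm()
  x <- seq_of("xyx")
  total <- 0
  for (a in 1:2) for (b in 1:2) for (cc in 1:2)
    total <- total + exp(path_log_prob(h, x, c(a, b, cc)))
  expect_equal(forward_log_prob(h, x), log(total), tolerance = 1e-12)
})

test_that("labelling-constrained forward partitions the total probability", {
  h <- two_state_hmm()     # labels: A = "i", B = "o"
  x <- seq_of("xy")
  labs <- list(c("i", "i"), c("i", "o"), c("o", "i"), c("o", "o"))
  mass <- sum(vapply(labs, function(l) exp(labelling_log_prob(h, x, l)), 0))
  expect_equal(mass, exp(forward_log_prob(h, x)), tolerance = 1e-12)
  # the single-labelling mass matches the single path here
  expect_equal(labelling_log_prob(h, x, c("i", "o")),
               path_log_prob(h, x, c(1L, 2L)), tolerance = 1e-12)
})
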