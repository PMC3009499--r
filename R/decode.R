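## k-best decoding: engine-independent plumbing, the naive matrix engine,
## the exhaustive enumeration engine, and classical Viterbi.
##
## All engines consume the same log-parameter matrices (.hmm_logs) and add
## factors in the same order (partial score + [log a + log b]), so that
## scores agree bitwise across engines and exact score ties are broken
## identically: tied paths are ordered by lexicographic comparison of their
## state-index sequences (lower index earlier in h$states wins).

## fixed-width lexicographic key for an integer state sequence
.lex_key <- function(idx) paste(sprintf("%05d", idx), collapse = "")

## order candidate indices by score (desc), breaking exact ties by the
## lexicographic key of the state sequence seq_fn(t) returns for candidate t
.order_candidates <- function(scores, seq_fn) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  r <- rle(s)
  if (any(r$lengths > 1L)) {
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (g in which(r$lengths > 1L)) {
      span <- starts[g]:ends[g]
      keys <- vapply(o[span], function(t) .lex_key(seq_fn(t)), "")
      o[span] <- o[span][order(keys)]
    }
  }
  o
}

.scored_path <- function(h, idx, log_joint, rank) {
  structure(
    list(states = unname(h$states[idx]), state_idx = unname(idx),
         log_joint = unname(log_joint), rank = rank),
    class = "scored_path"
  )
}

#' @export
print.scored_path <- function(x, ...) {
  if (!length(x$state_idx)) {
    cat("<no positive-probability path>\n")
    return(invisible(x))
  }
  cat(sprintf("path rank %s, log P(path, x) = %.6f\n",
              ifelse(is.na(x$rank), "?", x$rank), x$log_joint))
  cat(paste(utils::head(x$states, 20L), collapse = " "),
      if (length(x$states) > 20L) "..." else "", "\n")
  invisible(x)
}

.kbest_result <- function(h, paths_idx, scores, k, stats, engine) {
  paths <- vector("list", length(paths_idx))
  for (r in seq_along(paths_idx))
    paths[[r]] <- .scored_path(h, paths_idx[[r]], scores[r], r)
  structure(
    list(paths = paths, k = length(paths), k_requested = as.integer(k),
         stats = stats, engine = engine),
    class = "kbest_result"
  )
}

#' @export
print.kbest_result <- function(x, ...) {
  cat(sprintf("k-best decode (%s engine): %d of %d requested paths\n",
              x$engine, x$k, x$k_requested))
  if (x$k) {
    lj <- vapply(x$paths, `[[`, 0, "log_joint")
    cat(sprintf("  log joint range: %.4f .. %.4f\n", lj[1L], lj[x$k]))
  }
  s <- x$stats
  cat(sprintf("  peak path nodes %d / naive cells %d; peak state nodes %d; %d merges, %d prunes\n",
              s$peak_path_nodes, s$naive_cells, s$peak_state_nodes,
              s$merges_performed, s$prunes_performed))
  invisible(x)
}

.decoder_stats <- function(peak_path_nodes, peak_state_nodes, naive_cells,
                           merges = 0L, prunes = 0L) {
  list(peak_path_nodes = as.numeric(peak_path_nodes),
       peak_state_nodes = as.numeric(peak_state_nodes),
       naive_cells = as.numeric(naive_cells),
       merges_performed = as.numeric(merges),
       prunes_performed = as.numeric(prunes))
}

#' Heap-merge of sorted predecessor score lists
#'
#' The probability step of the k-best recurrence: the k best scores for a
#' state are the k largest values of `pred_lists[[c]][r] + factors[c]` over
#' all predecessors `c` and ranks `r`, obtained as the first k steps of a
#' `|Pred|`-way mergesort, so only `O(k + |Pred|)` candidates are touched.
#'
#' Exact score ties are broken by predecessor order as given, then by source
#' rank. (The decoders embed this merge with a stronger tie rule —
#' lexicographic comparison of the realized state sequences — which needs
#' sequence context this standalone operation does not have.)
#'
#' @param pred_lists list of numeric vectors, each sorted non-increasing
#'   (the k-best log scores at each predecessor).
#' @param factors numeric vector, one log transition+emission factor per
#'   predecessor (`log(a_cv) + log(b_v(x_i))`).
#' @param k maximum number of merged candidates to return.
#' @return a data.frame with columns `score`, `pred` (predecessor index or
#'   name), `rank` (1-based rank within the predecessor list), at most `k`
#'   rows, scores non-increasing. Empty when every candidate is `-Inf`.
#' @examples
#' merge_candidates(
#'   list(C1 = log(c(0.5, 0.2)), C2 = log(c(0.4, 0.1))),
#'   factors = c(log(0.5), log(1.0)), k = 2
#' )
#' @export
merge_candidates <- function(pred_lists, factors, k) {
  stopifnot(length(pred_lists) == length(factors), k >= 1)
  p <- length(pred_lists)
  ptr <- rep(1L, p)
  heads <- vapply(seq_len(p), function(c) {
    if (length(pred_lists[[c]])) pred_lists[[c]][1L] + factors[c] else -Inf
  }, 0)
  heads[is.nan(heads)] <- -Inf
  sc <- numeric(0); pr <- integer(0); rk <- integer(0)
  while (length(sc) < k) {
    best <- which.max(heads)
    if (!length(best) || !is.finite(heads[best])) break
    sc <- c(sc, heads[best]); pr <- c(pr, best); rk <- c(rk, ptr[best])
    ptr[best] <- ptr[best] + 1L
    nxt <- if (ptr[best] <= length(pred_lists[[best]]))
      pred_lists[[best]][ptr[best]] + factors[best] else -Inf
    heads[best] <- if (is.nan(nxt)) -Inf else nxt
  }
  pred <- if (!is.null(names(pred_lists))) names(pred_lists)[pr] else pr
  data.frame(score = sc, pred = pred, rank = rk,
             stringsAsFactors = FALSE)
}

#' Naive k-best decoder (full backpointer matrix)
#'
#' The straightforward list-Viterbi algorithm: for every position-state
#' pair it stores the k highest-scoring partial paths, keeping the complete
#' `(n+1) x m x k` backpointer structure in memory. Serves as the reference
#' implementation against which the compressed-tree engine is checked.
#'
#' @inheritParams path_log_prob
#' @param k number of paths requested (`k' <= k` are returned when fewer
#'   positive-probability paths exist).
#' @param complete_ties logical. When the k-th and (k+1)-th best paths
#'   have exactly equal probability, "the k best" is not a well-defined
#'   selection; with `complete_ties = TRUE` the returned list is
#'   extended past `k` through the whole boundary tie class instead of
#'   splitting it by the lexicographic tie rule. Useful whenever path
#'   sets are aggregated afterwards (e.g. grouping by topology), where
#'   an arbitrarily split tie class would bias the aggregate. Note that
#'   which members of an exactly tied boundary class survive the
#'   truncations can additionally depend on `k` itself: mathematically
#'   tied paths can have their partial scores split by one ulp of
#'   summation-order rounding mid-sequence and re-collapse to an exact
#'   tie only at the end, so tie handling is reliable at the level of
#'   the tie class, not of individual tied members.
#' @return a `kbest_result`: ranked [`scored_path`][path_log_prob] list plus
#'   decoder statistics.
#' @seealso [decode_kbest()] for the engine-selecting front end,
#'   [kbest_enum()] for the exhaustive reference.
#' @export
kbest_naive <- function(h, x, k, complete_ties = FALSE) {
  stopifnot(k >= 1)
  sym <- .encode_seq(h, x)
  n <- length(sym)
  m <- h$m
  lg <- .hmm_logs(h)
  lt_sub <- lg$lt[-1L, , drop = FALSE]
  S <- vector("list", n); BC <- vector("list", n); BR <- vector("list", n)

  backtrack <- function(i, j, r) {
    out <- integer(i)
    while (i >= 1L) {
      out[i] <- j
      cc <- BC[[i]][[j]][r]; rr <- BR[[i]][[j]][r]
      j <- cc; r <- rr; i <- i - 1L
    }
    out
  }

  S[[1L]] <- vector("list", m); BC[[1L]] <- vector("list", m); BR[[1L]] <- vector("list", m)
  for (j in seq_len(m)) {
    sc <- lg$lt[1L, j] + lg$le[j, sym[1L]]
    if (is.finite(sc)) {
      S[[1L]][[j]] <- sc; BC[[1L]][[j]] <- 0L; BR[[1L]][[j]] <- 0L
    } else {
      S[[1L]][[j]] <- numeric(0); BC[[1L]][[j]] <- integer(0); BR[[1L]][[j]] <- integer(0)
    }
  }
  if (n > 1L) for (i in 2L:n) {
    S[[i]] <- vector("list", m); BC[[i]] <- vector("list", m); BR[[i]] <- vector("list", m)
    ed <- lg$le[, sym[i]]
    for (j in seq_len(m)) {
      f <- lt_sub[, j] + ed[j]
      cs <- numeric(0); cc <- integer(0); cr <- integer(0)
      for (c in which(is.finite(f))) {
        prev <- S[[i - 1L]][[c]]
        if (length(prev)) {
          cs <- c(cs, prev + f[c])
          cc <- c(cc, rep(c, length(prev)))
          cr <- c(cr, seq_along(prev))
        }
      }
      if (length(cs)) {
        ord <- .order_candidates(cs, function(t) backtrack(i - 1L, cc[t], cr[t]))
        sel <- utils::head(ord, k)
        S[[i]][[j]] <- cs[sel]; BC[[i]][[j]] <- cc[sel]; BR[[i]][[j]] <- cr[sel]
      } else {
        S[[i]][[j]] <- numeric(0); BC[[i]][[j]] <- integer(0); BR[[i]][[j]] <- integer(0)
      }
    }
  }
  ## final selection across states, applying end weights
  fs <- numeric(0); fj <- integer(0); fr <- integer(0)
  for (j in seq_len(m)) {
    sj <- S[[n]][[j]]
    if (length(sj) && is.finite(lg$lend[j])) {
      fs <- c(fs, sj + lg$lend[j])
      fj <- c(fj, rep(j, length(sj)))
      fr <- c(fr, seq_along(sj))
    }
  }
  stats <- .decoder_stats(
    peak_path_nodes = k * m * (n + 1),
    peak_state_nodes = m * (n + 1),
    naive_cells = k * m * (n + 1)
  )
  if (!length(fs))
    return(.kbest_result(h, list(), numeric(0), k, stats, "naive"))
  ord <- .order_candidates(fs, function(t) backtrack(n, fj[t], fr[t]))
  kk <- min(length(ord), k)
  if (complete_ties && kk > 0L) {
    bound <- fs[ord[kk]]
    while (kk < length(ord) && fs[ord[kk + 1L]] == bound) kk <- kk + 1L
  }
  sel <- ord[seq_len(kk)]
  paths_idx <- lapply(sel, function(t) backtrack(n, fj[t], fr[t]))
  .kbest_result(h, paths_idx, fs[sel], k, stats, "naive")
}

#' Exhaustive k-best reference by full path enumeration
#'
#' Scores every one of the `m^n` state sequences and returns the top k.
#' Only feasible for tiny instances; used as an independent correctness
#' oracle for the dynamic-programming engines.
#'
#' @inheritParams kbest_naive
#' @param max_paths refuse to enumerate more than this many paths.
#' @return a `kbest_result` (stats are those of full enumeration:
#'   `peak_path_nodes = m^n`).
#' @export
kbest_enum <- function(h, x, k, max_paths = 2^21) {
  stopifnot(k >= 1)
  sym <- .encode_seq(h, x)
  n <- length(sym)
  m <- h$m
  if (m^n > max_paths)
    stop(sprintf("m^n = %g exceeds max_paths = %g", m^n, max_paths))
  lg <- .hmm_logs(h)
  lt_sub <- lg$lt[-1L, , drop = FALSE]
  ## big-endian path index: lexicographic order == numeric order
  v <- lg$lt[1L, ] + lg$le[cbind(seq_len(m), sym[1L])]
  last <- seq_len(m)
  if (n > 1L) for (t in 2L:n) {
    P <- length(v)
    ed <- lg$le[, sym[t]]
    f <- as.vector(t(lt_sub[last, , drop = FALSE])) + rep(ed, times = P)
    v <- rep(v, each = m) + f
    last <- rep(seq_len(m), times = P)
  }
  v <- v + lg$lend[last]
  keep <- which(is.finite(v))
  stats <- .decoder_stats(peak_path_nodes = m^n, peak_state_nodes = m^n,
                          naive_cells = k * m * (n + 1))
  if (!length(keep))
    return(.kbest_result(h, list(), numeric(0), k, stats, "enum"))
  o <- order(-v[keep], keep)          # exact ties: lower (lex-smaller) index
  sel <- keep[utils::head(o, k)]
  paths_idx <- lapply(sel, function(ix) {
    ix0 <- ix - 1L
    out <- integer(n)
    for (t in n:1L) {
      out[t] <- ix0 %% m + 1L
      ix0 <- ix0 %/% m
    }
    out
  })
  .kbest_result(h, paths_idx, v[sel], k, stats, "enum")
}

#' Most probable state path (Viterbi)
#'
#' Classical Viterbi decoding. Equal-probability paths are ordered by the
#' same global tie rule as the k-best engines (lexicographic on state
#' indices), so `viterbi(h, x)` always equals the first path of
#' `decode_kbest(h, x, k = 1)`.
#'
#' @inheritParams path_log_prob
#' @return a `scored_path`; when no positive-probability path exists, a
#'   `scored_path` with empty states, `log_joint = -Inf` and field
#'   `no_path = TRUE`.
#' @export
viterbi <- function(h, x) {
  sym <- .encode_seq(h, x)
  n <- length(sym)
  m <- h$m
  lg <- .hmm_logs(h)
  lt_sub <- lg$lt[-1L, , drop = FALSE]
  V <- lg$lt[1L, ] + lg$le[cbind(seq_len(m), sym[1L])]
  BP <- matrix(0L, n, m)
  bt <- function(i, j) {
    out <- integer(i)
    while (i >= 1L) {
      out[i] <- j
      j <- BP[i, j]
      i <- i - 1L
    }
    out
  }
  if (n > 1L) for (i in 2L:n) {
    ed <- lg$le[, sym[i]]
    Vnew <- rep(-Inf, m)
    for (j in seq_len(m)) {
      f <- lt_sub[, j] + ed[j]
      cand <- V + f
      cand[is.nan(cand)] <- -Inf
      mx <- max(cand)
      if (is.finite(mx)) {
        best <- which(cand == mx)
        if (length(best) > 1L) {
          keys <- vapply(best, function(c) .lex_key(bt(i - 1L, c)), "")
          best <- best[order(keys)]
        }
        Vnew[j] <- mx
        BP[i, j] <- best[1L]
      }
    }
    V <- Vnew
  }
  fin <- V + lg$lend
  fin[is.nan(fin)] <- -Inf
  mx <- max(fin)
  if (!is.finite(mx))
    return(structure(list(states = character(0), state_idx = integer(0),
                          log_joint = -Inf, rank = NA_integer_,
                          no_path = TRUE), class = "scored_path"))
  best <- which(fin == mx)
  if (length(best) > 1L) {
    keys <- vapply(best, function(j) .lex_key(bt(n, j)), "")
    best <- best[order(keys)]
  }
  .scored_path(h, bt(n, best[1L]), mx, 1L)
}

#' Decode the k most probable state paths
#'
#' Front end to the two exact k-best engines. `"naive"` keeps the full
#' `(n+1) x m x k` backpointer matrix; `"tree"` is the memory-efficient
#' decoder that maintains a compressed tree of path nodes and state nodes,
#' pruning backpointers no longer reachable from the current frontier and
#' merging uniquely-linked state-node runs online. Both return identical
#' paths in identical order (scores agree bitwise; exact ties are broken by
#' lexicographic comparison of state-index sequences).
#'
#' @inheritParams kbest_naive
#' @param engine `"tree"` (default) or `"naive"`.
#' @param audit logical; for the tree engine, re-derive all structural
#'   counters, reachability, and the no-mergeable-pair condition from
#'   scratch after every position, stopping with an internal-consistency
#'   error on any mismatch. Changes asymptotic cost; default off.
#' @param return_tree logical; for the tree engine, attach a snapshot of
#'   the final compressed tree (`$tree`: per state node its state run, live
#'   path count, and children) to the result.
#' @return a `kbest_result` with elements `paths` (list of `scored_path`,
#'   ranks `1..k'`), `k`, `k_requested`, `stats` (peak live path/state node
#'   counts, `naive_cells = k*m*(n+1)`, merge and prune counters) and
#'   `engine`.
#' @examples
#' h <- toy_membrane_hmm()
#' sx <- sample_sequence(h, n = 80, seed = 7)
#' res <- decode_kbest(h, sx$sequence, k = 10)
#' res$stats$peak_path_nodes / res$stats$naive_cells
#' @export
decode_kbest <- function(h, x, k, engine = c("tree", "naive"),
                         audit = FALSE, return_tree = FALSE,
                         complete_ties = FALSE) {
  engine <- match.arg(engine)
  if (engine == "naive") return(kbest_naive(h, x, k, complete_ties))
  stopifnot(k >= 1)
  sym <- .encode_seq(h, x)
  n <- length(sym)
  m <- h$m
  lg <- .hmm_logs(h)
  raw <- kbest_tree_cpp(m, lg$lt, lg$le, lg$lend, sym, as.integer(k),
                        isTRUE(audit), isTRUE(return_tree),
                        isTRUE(complete_ties))
  if (length(raw$audit_failures)) {
    stop(structure(
      class = c("kpaths_audit_error", "error", "condition"),
      list(message = paste0("compressed-tree internal audit failed:\n  ",
                            paste(raw$audit_failures, collapse = "\n  ")),
           call = sys.call())
    ))
  }
  stats <- .decoder_stats(raw$peak_path_nodes, raw$peak_state_nodes,
                          k * m * (n + 1), raw$merges, raw$prunes)
  res <- .kbest_result(h, raw$paths, raw$scores, k, stats, "tree")
  if (isTRUE(return_tree)) res$tree <- raw$tree
  res
}

#' Tabulate a k-best result
#'
#' @param res a `kbest_result`.
#' @param h,x the model and sequence it was decoded from (used to attach
#'   labellings and conditional probabilities).
#' @return a data.frame with columns `rank`, `log_joint`,
#'   `conditional_prob`, `labelling`, `states`.
#' @export
paths_table <- function(res, h, x) {
  if (!res$k)
    return(data.frame(rank = integer(0), log_joint = numeric(0),
                      conditional_prob = numeric(0), labelling = character(0),
                      states = character(0)))
  lfwd <- forward_log_prob(h, x)
  data.frame(
    rank = vapply(res$paths, `[[`, 0L, "rank"),
    log_joint = vapply(res$paths, `[[`, 0, "log_joint"),
    conditional_prob = vapply(res$paths, function(p)
      exp(p$log_joint - lfwd), 0),
    labelling = vapply(res$paths, function(p)
      paste(labelling_of(h, p), collapse = ""), ""),
    states = vapply(res$paths, function(p)
      paste(p$states, collapse = ","), ""),
    stringsAsFactors = FALSE
  )
}
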