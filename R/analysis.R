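## Turning k decoded paths into topology predictions: grouping, consensus
## construction (three variants), confidence reporting, and exploration of
## proteins with more than one true topology.

#' Group decoded paths by predicted topology
#'
#' Partitions the paths of a k-best result by their topology key
#' `(helix_count, sidedness)`. Each group carries its members' labellings
#' and topologies and a weight: the summed conditional probabilities
#' `P(path | x) = exp(log_joint - log P(x))` of its members, with the
#' forward total as denominator. Groups are returned sorted by weight
#' (descending), ties broken by helix count then sidedness.
#'
#' @param h an [hmm()] object.
#' @param x the decoded sequence.
#' @param res a `kbest_result` from [decode_kbest()].
#' @param membrane the membrane label symbol.
#' @return list of `"topology_group"` objects, each with fields
#'   `helix_count`, `sidedness`, `members` (list of `path`, `labelling`,
#'   `topology`, `cond_prob`), `weight`, `size`, `n`.
#' @export
group_paths <- function(h, x, res, membrane = "M") {
  if (!inherits(res, "kbest_result") || res$k == 0L)
    stop("group_paths needs a non-empty kbest_result")
  lfwd <- forward_log_prob(h, x)
  labs <- lapply(res$paths, function(p) labelling_of(h, p))
  tops <- lapply(labs, topology_of, membrane = membrane)
  keys <- vapply(tops, function(tp)
    paste(tp$helix_count, tp$sidedness, sep = "\r"), "")
  w <- vapply(res$paths, function(p) exp(p$log_joint - lfwd), 0)
  groups <- lapply(split(seq_along(keys), keys), function(ix) {
    tp <- tops[[ix[1L]]]
    structure(
      list(
        helix_count = tp$helix_count,
        sidedness = tp$sidedness,
        members = lapply(ix, function(t)
          list(path = res$paths[[t]], labelling = labs[[t]],
               topology = tops[[t]], cond_prob = w[t])),
        weight = sum(w[ix]),
        size = length(ix),
        n = tp$n
      ),
      class = "topology_group"
    )
  })
  hc <- vapply(groups, `[[`, 0, "helix_count")
  sd_ <- vapply(groups, `[[`, "", "sidedness")
  wt <- vapply(groups, `[[`, 0, "weight")
  unname(groups[order(-wt, hc, sd_)])
}

#' @export
print.topology_group <- function(x, ...) {
  cat(sprintf("topology group: %d helices, sidedness '%s', %d paths, weight %.4g\n",
              x$helix_count, x$sidedness, x$size, x$weight))
  invisible(x)
}

#' Heaviest topology group
#'
#' The group whose members carry the largest total conditional probability;
#' consensus labellings are formed from it. Deterministic under ties
#' (helix count, then sidedness).
#'
#' @param groups output of [group_paths()].
#' @return a `"topology_group"`.
#' @export
heaviest_group <- function(groups) {
  if (!length(groups)) stop("no groups")
  groups[[1L]]
}

## fill the non-helix gaps around the (repaired) consensus helices, voting
## per gap among the members' own gap labels, weighted by conditional
## probability; for alternating membrane labellings this reproduces the
## alternation of sides implied by the sidedness
.fill_labelling <- function(n, hel, sidedness, members, membrane = "M") {
  H <- if (is.null(hel)) 0L else nrow(hel)
  if (H == 0L)
    return(rep(sidedness, n))
  gap_label <- function(g) {
    votes <- list()
    for (mb in members) {
      pos <- if (g == 0L) 1L else mb$topology$helices[g, 2L] + 1L
      if (pos <= n && mb$labelling[pos] != membrane) {
        l <- mb$labelling[pos]
        votes[[l]] <- (if (is.null(votes[[l]])) 0 else votes[[l]]) + mb$cond_prob
      }
    }
    if (!length(votes)) return(NA_character_)
    vv <- unlist(votes)
    names(vv)[order(-vv, names(vv))][1L]
  }
  lab <- rep(NA_character_, n)
  for (hh in seq_len(H)) lab[hel[hh, 1L]:hel[hh, 2L]] <- membrane
  bounds <- c(0L, hel[, 2L])           # gap g runs after helix g
  starts <- c(1L, hel[, 2L] + 1L)
  ends <- c(hel[, 1L] - 1L, n)
  prev <- NA_character_
  for (g in 0L:H) {
    if (starts[g + 1L] > ends[g + 1L]) next
    l <- gap_label(g)
    if (is.na(l)) {
      l <- if (!is.na(prev) && all(c(prev, "i", "o") %in% c("i", "o")))
        setdiff(c("i", "o"), prev) else if (sidedness %in% c("i", "o"))
          sidedness else "o"
    }
    lab[starts[g + 1L]:ends[g + 1L]] <- l
    prev <- l
  }
  lab
}

.consensus_obj <- function(labels, method, group, h = NULL, x = NULL,
                           membrane = "M") {
  tp <- topology_of(labels, membrane = membrane)
  structure(
    list(
      labels = labels,
      method = method,
      topology = tp,
      topology_consistent =
        tp$helix_count == group$helix_count &&
        identical(tp$sidedness, group$sidedness),
      model_consistent = if (!is.null(h) && !is.null(x))
        is.finite(labelling_log_prob(h, x, labels)) else NA
    ),
    class = "consensus_labelling"
  )
}

#' @export
print.consensus_labelling <- function(x, ...) {
  cat(sprintf("consensus (%s): %d helices, sidedness '%s'%s%s\n",
              x$method, x$topology$helix_count, x$topology$sidedness,
              if (isTRUE(x$topology_consistent)) "" else " [topology differs from group]",
              if (is.na(x$model_consistent)) ""
              else if (x$model_consistent) " [model-consistent]"
              else " [NOT model-consistent]"))
  cat(paste(utils::head(x$labels, 60L), collapse = ""),
      if (length(x$labels) > 60L) "..." else "", "\n")
  invisible(x)
}

#' Boundary-averaging consensus of a topology group
#'
#' For each helix ordinal, the consensus helix starts (ends) at the
#' rounded mean of the members' helix starts (ends); rounding is half away
#' from zero on 1-based inclusive coordinates. If rounding makes adjacent
#' helices collide, the later boundary is shifted right by the minimal
#' amount (falling back to a leftward pass at the sequence end), so the
#' output is always a well-formed labelling with the group's own helix
#' count and sidedness. Non-helix gaps are filled by the members' side
#' labels, which alternate from the sidedness in membrane models.
#'
#' @param group a `"topology_group"`.
#' @param h,x optionally, the model and sequence: when given, the
#'   consensus is also checked for consistency with the model (does any
#'   positive-probability path realize it?).
#' @param membrane the membrane label symbol.
#' @return a `"consensus_labelling"` with fields `labels`, `method`,
#'   `topology`, `topology_consistent`, `model_consistent`.
#' @export
consensus_boundary_average <- function(group, h = NULL, x = NULL,
                                       membrane = "M") {
  n <- group$n
  H <- group$helix_count
  if (H == 0L)
    return(.consensus_obj(rep(group$sidedness, n), "boundary-average",
                          group, h, x, membrane))
  sm <- vapply(group$members, function(mb) mb$topology$helices[, 1L],
               numeric(H))
  em <- vapply(group$members, function(mb) mb$topology$helices[, 2L],
               numeric(H))
  if (H == 1L) { sm <- rbind(sm); em <- rbind(em) }
  s <- .round_half_up(rowMeans(sm))
  e <- .round_half_up(rowMeans(em))
  ## repair: keep helices disjoint with at least one non-helix position
  ## between them, and preserve the sidedness at position 1
  lower <- if (identical(group$sidedness, "membrane-start")) 1 else 2
  s[1L] <- max(min(s[1L], n), lower)
  e[1L] <- max(e[1L], s[1L])
  if (H > 1L) for (hh in 2L:H) {
    s[hh] <- max(s[hh], e[hh - 1L] + 2)
    e[hh] <- max(e[hh], s[hh])
  }
  if (e[H] > n) {
    e[H] <- n
    s[H] <- min(s[H], e[H])
    if (H > 1L) for (hh in H:2L) {
      if (s[hh] < e[hh - 1L] + 2) {
        e[hh - 1L] <- s[hh] - 2
        s[hh - 1L] <- min(s[hh - 1L], e[hh - 1L])
      }
    }
    if (s[1L] < lower)
      stop("sequence too short to hold the group's helix count")
  }
  hel <- cbind(start = s, end = e)
  lab <- .fill_labelling(n, hel, group$sidedness, group$members, membrane)
  .consensus_obj(lab, "boundary-average", group, h, x, membrane)
}

## members of a group, or the paths of a full result, as (labelling, weight)
.vote_members <- function(x, h = NULL, seq = NULL) {
  if (inherits(x, "topology_group")) return(x$members)
  if (inherits(x, "kbest_result")) {
    stopifnot(x$k > 0L)
    if (is.null(h)) stop("voting on a kbest_result needs the hmm")
    w <- if (!is.null(seq)) {
      lfwd <- forward_log_prob(h, seq)
      vapply(x$paths, function(p) exp(p$log_joint - lfwd), 0)
    } else rep(1, x$k)
    lapply(seq_len(x$k), function(t) {
      lb <- labelling_of(h, x$paths[[t]])
      list(path = x$paths[[t]], labelling = lb,
           topology = topology_of(lb), cond_prob = w[t])
    })
  } else stop("expected a topology_group or kbest_result")
}

#' Per-position voting consensus
#'
#' Each path votes, at every position, for its own label with its
#' conditional probability as the vote weight (raw counts when weights are
#' unavailable); the winning label is taken per position. Analogous to
#' posterior decoding, and like it the result can be a labelling no
#' positive-probability path realizes: this is flagged, never repaired.
#'
#' @param x a `"topology_group"` or a `kbest_result`.
#' @param h,seq the model and sequence; needed for weights when `x` is a
#'   `kbest_result`, and for the model-consistency flag.
#' @param membrane the membrane label symbol.
#' @return a `"consensus_labelling"`.
#' @export
consensus_position_vote <- function(x, h = NULL, seq = NULL, membrane = "M") {
  members <- .vote_members(x, h, seq)
  n <- length(members[[1L]]$labelling)
  labs <- vapply(members, `[[`, character(n), "labelling")
  if (n == 1L) labs <- rbind(labs)
  w <- vapply(members, `[[`, 0, "cond_prob")
  lab <- vapply(seq_len(n), function(t) {
    tot <- tapply(w, labs[t, ], sum)
    names(tot)[order(-tot, names(tot))][1L]
  }, "")
  group <- if (inherits(x, "topology_group")) x else {
    tp <- members[[1L]]$topology
    list(helix_count = tp$helix_count, sidedness = tp$sidedness, n = n)
  }
  .consensus_obj(lab, "position-vote", group, h, seq, membrane)
}

#' Helix-voting consensus of a topology group
#'
#' For each helix ordinal, the members vote (weighted by conditional
#' probability) on the helix's `(start, length)` pair and the modal pair
#' wins; ties prefer the smaller start, then the shorter helix. The
#' resulting helices are painted over the members' side labels. As with
#' per-position voting the result may be inconsistent with the model; it
#' is flagged, never repaired.
#'
#' @inheritParams consensus_boundary_average
#' @return a `"consensus_labelling"`.
#' @export
consensus_helix_vote <- function(group, h = NULL, x = NULL, membrane = "M") {
  n <- group$n
  H <- group$helix_count
  if (H == 0L)
    return(.consensus_obj(rep(group$sidedness, n), "helix-vote",
                          group, h, x, membrane))
  hel <- matrix(0L, H, 2L, dimnames = list(NULL, c("start", "end")))
  for (hh in seq_len(H)) {
    key <- vapply(group$members, function(mb)
      sprintf("%06d %06d", mb$topology$helices[hh, 1L],
              mb$topology$helices[hh, 2L] - mb$topology$helices[hh, 1L] + 1L),
      "")
    w <- vapply(group$members, `[[`, 0, "cond_prob")
    tot <- tapply(w, key, sum)
    win <- names(tot)[order(-tot, names(tot))][1L]
    sl <- as.integer(strsplit(win, " ", fixed = TRUE)[[1L]])
    hel[hh, ] <- c(sl[1L], min(sl[1L] + sl[2L] - 1L, n))
  }
  ## paint helices over the voted side background (no repair)
  bg_hel <- hel[order(hel[, 1L]), , drop = FALSE]
  lab <- .fill_labelling(n, bg_hel, group$sidedness, group$members, membrane)
  for (hh in seq_len(H)) lab[hel[hh, 1L]:hel[hh, 2L]] <- membrane
  .consensus_obj(lab, "helix-vote", group, h, x, membrane)
}

#' Decoding confidence from the k best paths
#'
#' Summarizes how much of the conditional probability space the k best
#' paths occupy and how much they agree. If every path predicts the same
#' number of helices, that count is strong supporting evidence; a large
#' total conditional probability of the top k paths predicts that a good
#' labelling is among them. The total is classified into the reporting
#' bands `< 0.01`, `0.01 - 0.5` and `0.5 - 1`.
#'
#' @inheritParams group_paths
#' @return a `"confidence_report"`: `k`, `total_conditional_prob`, `band`,
#'   `helix_counts_agree`, and `group_table` (one row per topology group:
#'   helix count, sidedness, size, weight).
#' @export
confidence_report <- function(h, x, res, membrane = "M") {
  groups <- group_paths(h, x, res, membrane = membrane)
  total <- sum(vapply(groups, `[[`, 0, "weight"))
  hc <- vapply(groups, `[[`, 0, "helix_count")
  band <- if (total < 0.01) "< 0.01" else if (total < 0.5) "0.01 - 0.5" else "0.5 - 1"
  structure(
    list(
      k = res$k,
      total_conditional_prob = total,
      band = band,
      helix_counts_agree = length(unique(hc)) == 1L,
      group_table = data.frame(
        helix_count = hc,
        sidedness = vapply(groups, `[[`, "", "sidedness"),
        size = vapply(groups, `[[`, 0L, "size"),
        weight = vapply(groups, `[[`, 0, "weight"),
        stringsAsFactors = FALSE
      )
    ),
    class = "confidence_report"
  )
}

#' @export
print.confidence_report <- function(x, ...) {
  cat(sprintf("confidence over top %d paths: total conditional probability %.4g (band %s)\n",
              x$k, x$total_conditional_prob, x$band))
  cat(sprintf("helix counts %s across paths; %d topology group(s)\n",
              if (x$helix_counts_agree) "agree" else "differ",
              nrow(x$group_table)))
  print(x$group_table)
  invisible(x)
}

#' The g heaviest topology groups with their consensus labellings
#'
#' Exploration tool for sequences that may have more than one true
#' explanation, such as dual-topology membrane proteins, whose two correct
#' topologies differ only in sidedness: with `g = 2` the two heaviest
#' groups expose both orientations, each summarized by its
#' boundary-average consensus.
#'
#' @param groups output of [group_paths()].
#' @param g number of groups to return.
#' @param h,x optional model and sequence for the consensus consistency
#'   flags.
#' @param membrane the membrane label symbol.
#' @return list with `groups` (list of `list(group, consensus)`),
#'   `requested`, and `complete` (`FALSE` when fewer than `g` groups
#'   exist).
#' @export
top_groups <- function(groups, g = 2L, h = NULL, x = NULL, membrane = "M") {
  stopifnot(g >= 1L)
  take <- utils::head(groups, g)
  structure(
    list(
      groups = lapply(take, function(gr)
        list(group = gr,
             consensus = consensus_boundary_average(gr, h, x, membrane))),
      requested = as.integer(g),
      complete = length(groups) >= g
    ),
    class = "top_groups"
  )
}

#' @export
print.top_groups <- function(x, ...) {
  cat(sprintf("top %d topology group(s)%s\n", length(x$groups),
              if (x$complete) "" else sprintf(" (fewer than the %d requested)",
                                              x$requested)))
  for (gg in x$groups) {
    print(gg$group)
    print(gg$consensus)
  }
  invisible(x)
}
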