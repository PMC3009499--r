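---
title: "Memory-efficient k-best decoding and topology analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Memory-efficient k-best decoding and topology analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(kpaths)
```

## The problem

A hidden Markov model assigns every state path $\pi = \pi_1 \dots \pi_n$
through an observed sequence $x$ a joint probability

$$P(x, \pi) = a_{I\,\pi_1} \prod_{t=1}^{n} e_{\pi_t}(x_t)
  \prod_{t=2}^{n} a_{\pi_{t-1}\,\pi_t} \;(\cdot\, a_{\pi_n\,E}),$$

where the final factor applies only when the model has explicit end
weights. Viterbi decoding finds the single most probable path. Many
biological questions, however, hinge on the *shape* of the posterior path
distribution, not on its mode alone: when a protein's membrane topology is
ambiguous, the best path may represent only a sliver of the probability
mass, and the biologically correct topology may live in the second- or
tenth-best path. This package decodes the $k$ best paths exactly and then
analyses them — grouping by predicted topology, weighting groups by
conditional probability mass, and forming consensus labellings.

## Naive list-Viterbi and its memory cost

The naive generalisation of Viterbi keeps, in each state at each position,
the $k$ best scoring path prefixes ending there, each with a back pointer.
This is exact, and `kbest_naive()` implements it as the reference engine.
Its memory is $\Theta(k\,m\,n)$ back pointers for $m$ states and sequence
length $n$ — at $k = 100$ paths through a 12-state model and a 2,000-residue
sequence, 2.4 million cells, nearly all of which are never used by any of
the $k$ final paths.

## The compressed path-node tree

The memory-efficient engine (`decode_kbest(engine = "tree")`, implemented
in C++) stores only what the surviving candidates can still reach. Two node
kinds form a tree rooted at the start:

* a **path node** represents one ranked path prefix in one state at one
  position, and holds a parent pointer into the tree;
* a **state node** summarises a maximal run of positions through which a
  set of prefixes passes the *same* state without branching; consecutive
  extensions in the same state extend the run in place instead of
  allocating a node per position.

After each position, candidates that can no longer enter any state's
top-$k$ list are pruned, and their ancestors are released as soon as their
reference counts drop to zero; sibling runs that have become identical are
merged. The frontier therefore carries at most $k\,m$ live leaves, and the
interior of the tree stays near the size of the *distinct* history the $k$
best paths actually share. On long sequences the peak number of path nodes
is typically well under 1% of the naive cell count (the package's
acceptance checks require under 10% at $m = 12$, $n = 2000$, $k = 100$).
Setting `audit = TRUE` re-verifies the structural invariants (reference
counts, run integrity, reachability) at every position.

Both engines consume identical log-space parameter matrices and break
exact score ties identically — lexicographically by state index — so their
outputs agree bitwise, which the test suite exercises against a third,
brute-force enumeration oracle on small instances.

### Exact ties and `complete_ties`

When the $k$-th and $(k{+}1)$-th best scores are *exactly* equal, "the
$k$ best paths" is ill-defined: any tie-breaking rule silently drops some
members of the boundary tie class, which biases any downstream aggregation
over the returned list. `decode_kbest(complete_ties = TRUE)` extends the
returned list through the entire boundary tie class, so that aggregates
such as topology-group weights are invariant to the tie-breaking order.
This matters for deliberately symmetric models (see below); in generic
models exact ties essentially never occur.

## From paths to topologies

Each state carries a label — here `i` (inside loop), `M` (membrane helix),
`o` (outside loop) — so a state path projects to a labelling, and a
labelling reduces to a **topology**: the ordered membrane-helix intervals
plus the *sidedness* (the label of the first residue). The analysis layer:

* `group_paths()` partitions decoded paths by topology and weights each
  group by its total conditional probability
  $\sum_{\pi \in g} P(x,\pi)/P(x)$, with $P(x)$ from the forward
  algorithm;
* three consensus builders summarise a group as one labelling:
  `consensus_boundary_average()` (helices paired in order, boundaries
  averaged — always consistent with the group's topology),
  `consensus_position_vote()` and `consensus_helix_vote()`
  (per-position/per-helix weighted votes, which can in principle leave the
  group's topology and are flagged when they do);
* `confidence_report()` bands each sequence by how much conditional mass
  the $k$ paths captured and how dominant the heaviest group is;
* `tau_correct()` (every helix boundary within $\tau$ residues of truth)
  and `phobius_correct()` (same topology and every true helix overlapped
  by at least 5 residues) score predictions against known labellings.

## Worked example

```{r example}
h <- toy_membrane_hmm()
sim <- sample_sequence(h, 300, seed = 42)
res <- decode_kbest(h, sim$sequence, k = 50)
head(paths_table(res, h, sim$sequence), 3)

groups <- group_paths(h, sim$sequence, res)
length(groups)
top <- heaviest_group(groups)
c(helices = top$helix_count, weight = round(top$weight, 4))

cons <- consensus_boundary_average(top, h, sim$sequence)
cons$topology
same_topology(cons$topology, topology_of(labelling_of(h, sim$path)))
```

## Dual-topology models

Some membrane proteins insert in both orientations. `mirror_hmm()` builds
a model with two parameter-identical branches whose `i`/`o` labels are
swapped: every path has an exactly equal-probability mirror of opposite
sidedness. Decoding with `complete_ties = TRUE` returns both members of
every mirror pair, and the two heaviest topology groups then have equal
helix counts, opposite sidedness, and weights equal to machine precision —
the signature by which dual-topology candidates can be recognised.

```{r mirror}
mh <- mirror_hmm()
sx <- sample_sequence(mh, 150, seed = 7)
g <- group_paths(mh, sx$sequence,
                 decode_kbest(mh, sx$sequence, k = 50, complete_ties = TRUE))
data.frame(sidedness = sapply(g[1:2], `[[`, "sidedness"),
           helices = sapply(g[1:2], `[[`, "helix_count"),
           weight = sapply(g[1:2], `[[`, "weight"))
```

## Design of the synthetic fixtures

`toy_membrane_hmm()` is built so that its path distribution is *honest*
for these analyses:

* **Detectable helices.** Viterbi-style decoding smooths away segments
  whose emission evidence is smaller than the cost of the entry and exit
  transitions; with these emission tables that break-even point is roughly
  4–5 residues. Each helix submodule therefore passes through five
  deterministic states plus one self-looping core state, so helices are
  at least 6 residues long (mean 21–22) and never fall below the
  detectability threshold.
* **Few self-loops.** Spreading a helix's duration over several
  self-looping states would split its probability mass across
  combinatorially many duration partitions, so each *path* becomes
  rare even when the *topology* is certain. One self-looping state per
  submodule keeps path probability concentrated.
* **No accidental ties.** Exact ties arise when two distinct state paths
  have identical probability — e.g. twin states with equal dwell and
  emission parameters, or run lengths that can be reallocated between
  states with equal dwell probabilities. Here every submodule has exactly
  one self-looping state and the four dwell probabilities are pairwise
  distinct, so a labelling determines its state decomposition uniquely and
  distinct paths never tie. Exact ties are then introduced *only*
  deliberately, by the mirror construction.

## Limitations

* Scores are exact log-space sums of `log()`-transformed parameters;
  "bitwise equality" between engines is relative to that shared
  association order. Mathematically tied paths can have partial sums
  split by one ulp of summation-order rounding mid-sequence, so which
  individual members of an exact boundary tie class survive truncation
  can depend on `k`; tie handling is reliable at the level of the tie
  class (which `complete_ties = TRUE` returns whole), not of its
  members.
* `k` controls work and memory; the conditional mass captured by the top
  $k$ paths can be small for long, ambiguous sequences, and
  `confidence_report()` should be consulted before trusting a consensus.
* The topology layer assumes the three-letter label scheme; models with
  richer label sets project onto it via the `membrane` argument of
  `group_paths()`.
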