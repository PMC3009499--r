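#' Labelling of a state path
#'
#' Substitutes each path state by its label, giving the per-position
#' labelling the path implies. Many state paths can share one labelling.
#'
#' @param h an [hmm()] object.
#' @param path a `scored_path`, or a character vector of state names.
#' @return character vector of labels, length `n`.
#' @export
labelling_of <- function(h, path) {
  states <- if (inherits(path, "scored_path")) path$states else as.character(path)
  lab <- h$labels[states]
  if (anyNA(lab))
    stop(sprintf("state(s) without a label: %s",
                 paste(unique(states[is.na(lab)]), collapse = " ")))
  unname(lab)
}

#' Topology of a labelling
#'
#' The topology of a membrane protein is its number of membrane-spanning
#' helices together with its sidedness — whether the first residue lies
#' inside or outside the membrane. Helices are the maximal runs of the
#' membrane label; sidedness is the label of position 1 (the literal
#' `"membrane-start"` when the labelling begins mid-helix, a case real
#' proteins do not present but arbitrary labellings can).
#'
#' @param lab a labelling: character vector, single string, or a consensus
#'   labelling object.
#' @param membrane the membrane label symbol.
#' @return an object of class `"hmm_topology"`: `helices` (two-column
#'   matrix of 1-based inclusive `start`,`end`), `helix_count`,
#'   `sidedness`, `n`, and `alternating` (do the non-membrane segments
#'   alternate between exactly two sides? `NA` unless the label alphabet
#'   is within the three-letter `i`/`M`/`o` membrane alphabet).
#' @examples
#' topology_of("iiiMMMMMooo")
#' @export
topology_of <- function(lab, membrane = "M") {
  if (inherits(lab, "consensus_labelling")) lab <- lab$labels
  if (length(lab) == 1L && nchar(lab) > 1L)
    lab <- strsplit(lab, "", fixed = TRUE)[[1L]]
  n <- length(lab)
  if (n == 0L) stop("empty labelling")
  r <- rle(lab == membrane)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hel <- cbind(start = starts[r$values], end = ends[r$values])
  sided <- if (lab[1L] == membrane) "membrane-start" else lab[1L]
  alternating <- NA
  if (all(lab %in% c("i", membrane, "o"))) {
    sides <- lab[starts[!r$values]]
    alternating <- length(sides) <= 1L || all(sides[-1L] != sides[-length(sides)])
  }
  structure(
    list(helices = hel, helix_count = nrow(hel), sidedness = sided,
         n = n, alternating = alternating),
    class = "hmm_topology"
  )
}

#' @export
print.hmm_topology <- function(x, ...) {
  cat(sprintf("topology: %d helices, sidedness '%s' (n = %d)\n",
              x$helix_count, x$sidedness, x$n))
  if (x$helix_count)
    cat(paste(sprintf("  helix %d: %d..%d", seq_len(x$helix_count),
                      x$helices[, 1L], x$helices[, 2L]), collapse = "\n"), "\n")
  invisible(x)
}

#' Do two topologies match?
#'
#' The grouping key: two topologies are the same iff they agree in helix
#' count and sidedness. Helix boundary positions are deliberately ignored.
#'
#' @param a,b `"hmm_topology"` objects.
#' @return logical.
#' @export
same_topology <- function(a, b) {
  a$helix_count == b$helix_count && identical(a$sidedness, b$sidedness)
}

#' Lenient topology correctness (overlap measure)
#'
#' A prediction is correct under this measure if it has the correct
#' topology (helix count and sidedness) and each true helix overlaps its
#' corresponding predicted helix — paired in order, h-th with h-th — in at
#' least five positions. Helices being typically around twenty-two
#' residues long, this measure is lax about boundary placement.
#'
#' @param pred,truth `"hmm_topology"` objects.
#' @param min_overlap minimum positional overlap per helix pair.
#' @return logical.
#' @export
phobius_correct <- function(pred, truth, min_overlap = 5L) {
  if (!same_topology(pred, truth)) return(FALSE)
  if (truth$helix_count == 0L) return(TRUE)
  ov <- pmax(
    0L,
    pmin(pred$helices[, 2L], truth$helices[, 2L]) -
      pmax(pred$helices[, 1L], truth$helices[, 1L]) + 1L
  )
  all(ov >= min_overlap)
}

#' Strict topology correctness (boundary tolerance measure)
#'
#' A prediction is correct at tolerance `tau` if it has the correct
#' topology and every predicted helix boundary lies within `tau` residues
#' of the corresponding true boundary (helices paired in order; inclusive
#' residue coordinates compared on both the start and the end).
#' Correctness is monotone in `tau`.
#'
#' @inheritParams phobius_correct
#' @param tau integer tolerance, `>= 0`.
#' @return logical.
#' @export
tau_correct <- function(pred, truth, tau) {
  stopifnot(tau >= 0)
  if (!same_topology(pred, truth)) return(FALSE)
  if (truth$helix_count == 0L) return(TRUE)
  all(abs(pred$helices[, 1L] - truth$helices[, 1L]) <= tau) &&
    all(abs(pred$helices[, 2L] - truth$helices[, 2L]) <= tau)
}

#' Segment table of a labelling
#'
#' Collapses a labelling into maximal same-label segments, with the
#' membrane label reported as `helix` and `i`/`o` as `inside`/`outside`
#' (other labels pass through). Coordinates are 1-based inclusive.
#'
#' @inheritParams topology_of
#' @return data.frame with columns `feature`, `start`, `end`.
#' @export
labelling_segments <- function(lab, membrane = "M") {
  if (inherits(lab, "consensus_labelling")) lab <- lab$labels
  if (length(lab) == 1L && nchar(lab) > 1L)
    lab <- strsplit(lab, "", fixed = TRUE)[[1L]]
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  feat <- ifelse(r$values == membrane, "helix",
                 ifelse(r$values == "i", "inside",
                        ifelse(r$values == "o", "outside", r$values)))
  data.frame(feature = feat, start = starts, end = ends,
             stringsAsFactors = FALSE)
}

#' Write labellings as GFF3-style segment records
#'
#' @param labs named list (or single labelling) of labellings.
#' @param file output path.
#' @param source source field for column 2.
#' @return invisibly, the lines written.
#' @export
write_gff3 <- function(labs, file, source = "kpaths") {
  if (!is.list(labs)) labs <- list(seq = labs)
  if (is.null(names(labs))) names(labs) <- paste0("seq", seq_along(labs))
  lines <- "##gff-version 3"
  for (id in names(labs)) {
    seg <- labelling_segments(labs[[id]])
    lines <- c(lines, sprintf("%s\t%s\t%s\t%d\t%d\t.\t.\t.\tID=%s.%d",
                              id, source, seg$feature, seg$start, seg$end,
                              id, seq_len(nrow(seg))))
  }
  writeLines(lines, file)
  invisible(lines)
}
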