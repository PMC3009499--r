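## Plain-text HMM definition format and FASTA sequence I/O.
##
## HMM format (one model per file):
##   # comments and blank lines are ignored anywhere
##   ALPHABET F L R E              single-character symbols, one line
##   STATES                        then one "name label" pair per line
##   in1 i
##   ...
##   TRANSITIONS                   sparse triplets "from to prob";
##   I in1 0.5                     'I' is the silent start state
##   ...
##   EMISSIONS                     triplets "state symbol prob"
##   in1 F 0.15
##   ...
##   ENDS                          optional: "state weight" termination
##   in1 0.2                       weights (rows then sum to 1 with them)
## Omitted triplets are zero. Probabilities are written with full double
## precision so that write_hmm/read_hmm round-trips exactly.

#' Read an HMM definition file
#'
#' Parses the package's plain-text HMM format (see the format description
#' in this help page's source file, or [write_hmm()] output for an
#' example). Reading back a written model reproduces it exactly.
#'
#' @param path file path.
#' @return an [hmm()] object.
#' @export
read_hmm <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- trimws(raw)
  raw <- raw[nzchar(raw) & !startsWith(raw, "#")]
  if (!length(raw)) stop(sprintf("'%s': empty HMM file", path))
  section <- NA_character_
  alphabet <- NULL
  st_name <- character(); st_lab <- character()
  tr <- list(); em <- list(); en <- list()
  for (ln in raw) {
    parts <- strsplit(ln, "[[:space:]]+")[[1L]]
    kw <- toupper(parts[1L])
    if (kw == "ALPHABET") { alphabet <- parts[-1L]; section <- NA; next }
    if (kw %in% c("STATES", "TRANSITIONS", "EMISSIONS", "ENDS")) {
      section <- kw; next
    }
    if (is.na(section))
      stop(sprintf("'%s': line '%s' outside any section", path, ln))
    if (section == "STATES") {
      if (length(parts) != 2L)
        stop(sprintf("'%s': STATES line '%s' is not 'name label'", path, ln))
      st_name <- c(st_name, parts[1L]); st_lab <- c(st_lab, parts[2L])
    } else if (section == "TRANSITIONS") {
      if (length(parts) != 3L)
        stop(sprintf("'%s': TRANSITIONS line '%s' is not 'from to prob'", path, ln))
      tr[[length(tr) + 1L]] <- parts
    } else if (section == "EMISSIONS") {
      if (length(parts) != 3L)
        stop(sprintf("'%s': EMISSIONS line '%s' is not 'state symbol prob'", path, ln))
      em[[length(em) + 1L]] <- parts
    } else {
      if (length(parts) != 2L)
        stop(sprintf("'%s': ENDS line '%s' is not 'state weight'", path, ln))
      en[[length(en) + 1L]] <- parts
    }
  }
  if (is.null(alphabet)) stop(sprintf("'%s': missing ALPHABET", path))
  if (!length(st_name)) stop(sprintf("'%s': missing STATES", path))
  m <- length(st_name)
  trm <- matrix(0, m + 1L, m)
  for (t in tr) {
    if (t[2L] == "I")
      stop(sprintf("'%s': transition into the start state", path))
    fi <- if (t[1L] == "I") 1L else match(t[1L], st_name) + 1L
    ti <- match(t[2L], st_name)
    if (is.na(fi) || is.na(ti))
      stop(sprintf("'%s': unknown state in transition '%s'", path,
                   paste(t, collapse = " ")))
    trm[fi, ti] <- as.numeric(t[3L])
  }
  emm <- matrix(0, m, length(alphabet))
  for (t in em) {
    si <- match(t[1L], st_name)
    ci <- match(t[2L], alphabet)
    if (is.na(si) || is.na(ci))
      stop(sprintf("'%s': unknown state or symbol in emission '%s'", path,
                   paste(t, collapse = " ")))
    emm[si, ci] <- as.numeric(t[3L])
  }
  ends <- NULL
  if (length(en)) {
    ends <- rep(0, m)
    for (t in en) {
      si <- match(t[1L], st_name)
      if (is.na(si))
        stop(sprintf("'%s': unknown state in ENDS: '%s'", path, t[1L]))
      ends[si] <- as.numeric(t[2L])
    }
  }
  hmm(st_name, st_lab, trm, emm, alphabet, ends = ends)
}

#' Write an HMM definition file
#'
#' @param h an [hmm()] object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_hmm <- function(h, path) {
  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    "# kpaths HMM text format",
    paste(c("ALPHABET", h$alphabet), collapse = " "),
    "STATES",
    paste(h$states, h$labels),
    "TRANSITIONS"
  )
  for (fi in seq_len(h$m + 1L)) {
    nz <- which(h$trans[fi, ] > 0)
    from <- if (fi == 1L) "I" else h$states[fi - 1L]
    if (length(nz))
      lines <- c(lines, paste(from, h$states[nz], num(h$trans[fi, nz])))
  }
  lines <- c(lines, "EMISSIONS")
  for (si in seq_len(h$m)) {
    nz <- which(h$emis[si, ] > 0)
    if (length(nz))
      lines <- c(lines, paste(h$states[si], h$alphabet[nz], num(h$emis[si, nz])))
  }
  if (!is.null(h$ends)) {
    nz <- which(h$ends > 0)
    lines <- c(lines, "ENDS", paste(h$states[nz], num(h$ends[nz])))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' Standard FASTA dialect; the identifier is the header text up to the
#' first whitespace. Arbitrary single-character residue alphabets are
#' accepted (sequences are read as raw strings, not validated against a
#' nucleotide or protein alphabet).
#'
#' @param path FASTA file path.
#' @return named list of [hmm_sequence()] objects.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  out <- lapply(seq_along(ss), function(i)
    hmm_sequence(as.character(ss[[i]]), id = ids[i]))
  stats::setNames(out, ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs a list of [hmm_sequence()] objects (or named character
#'   strings).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "hmm_sequence")) seqs <- list(seqs)
  chr <- vapply(seqs, function(s) {
    if (inherits(s, "hmm_sequence")) paste(s$symbols, collapse = "") else as.character(s)
  }, "")
  ids <- if (!is.null(names(seqs)) && all(nzchar(names(seqs)))) names(seqs)
  else vapply(seqs, function(s)
    if (inherits(s, "hmm_sequence")) s$id else "seq", "")
  ss <- Biostrings::BStringSet(chr)
  names(ss) <- ids
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read reference labellings
#'
#' Reference (truth) labellings are stored as FASTA of label strings, one
#' record per sequence, ids matching the sequence file.
#'
#' @param path FASTA file of label strings.
#' @return named list of character label vectors.
#' @export
read_labellings <- function(path) {
  lapply(read_fasta(path), function(s) s$symbols)
}
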