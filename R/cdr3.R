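# CDR3 length, positional-frequency (sequence-logo data), motif and
# conserved-anchor analysis.

#' Motif specification for CDR3 scanning
#'
#' @param patterns contiguous residue runs to scan for (uppercase).
#' @param central_window 1-based inclusive position range defining the
#'   central region of the CDR3 loop (default 6-9).
#' @param require_in_window count a hit only when its span intersects the
#'   central window.
#' @return object of class `motif_spec`.
#' @export
motif_spec <- function(patterns = c("GGG", "GGGG", "NNNN"),
                       central_window = c(6L, 9L), require_in_window = FALSE) {
  stopifnot(length(patterns) > 0, all(patterns == toupper(patterns)),
            length(central_window) == 2L, central_window[1] >= 1L,
            central_window[1] <= central_window[2])
  structure(list(patterns = patterns,
                 central_window = as.integer(central_window),
                 require_in_window = require_in_window),
            class = "motif_spec")
}

#' Detect motif occurrences in CDR3 sequences
#'
#' Finds all (including overlapping) occurrences of each pattern. With
#' `require_in_window`, a hit counts only when its span `[start, start +
#' nchar(pattern) - 1]` intersects the central window. Because runs
#' contain their sub-runs, every GGGG hit implies GGG hits.
#'
#' @param cdr3 character vector of uppercase CDR3 sequences.
#' @param spec a [motif_spec()].
#' @return data.frame: seq_index, cdr3, pattern, start (1-based); zero rows
#'   when nothing matches.
#' @export
detect_motif <- function(cdr3, spec = motif_spec()) {
  stopifnot(inherits(spec, "motif_spec"))
  assert_aa(cdr3, "cdr3")
  hits <- list()
  for (pat in spec$patterns) {
    m <- gregexpr(paste0("(?=", pat, ")"), cdr3, perl = TRUE)
    for (i in seq_along(cdr3)) {
      starts <- as.integer(m[[i]])
      starts <- starts[starts > 0]
      if (!length(starts)) next
      if (spec$require_in_window) {
        ends <- starts + nchar(pat) - 1L
        keep <- starts <= spec$central_window[2] & ends >= spec$central_window[1]
        starts <- starts[keep]
      }
      if (length(starts))
        hits[[length(hits) + 1L]] <- data.frame(seq_index = i, cdr3 = cdr3[i],
                                                pattern = pat, start = starts,
                                                stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(seq_index = integer(), cdr3 = character(),
                      pattern = character(), start = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$seq_index, out$pattern, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' CDR3 length distribution per group
#'
#' @param cdr3 character vector of sequences.
#' @param groups optional grouping vector (same length); a single group
#'   when `NULL`.
#' @return data.frame: group, length, count; attributes `range` (named list
#'   of per-group min/max).
#' @export
length_distribution <- function(cdr3, groups = NULL) {
  stopifnot(length(cdr3) > 0)
  if (is.null(groups)) groups <- rep("all", length(cdr3))
  lens <- nchar(cdr3)
  tab <- as.data.frame(table(group = groups, length = lens), stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  names(tab)[3] <- "count"
  tab$length <- as.integer(tab$length)
  tab <- tab[order(tab$group, tab$length), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "range") <- lapply(split(lens, groups), range)
  tab
}

#' Fraction of CDR3 sequences with length in a range
#'
#' @param cdr3 sequences.
#' @param range inclusive integer range, e.g. `c(12, 14)`.
#' @return fraction in `[0, 1]`.
#' @export
cdr3_length_fraction <- function(cdr3, range = c(12L, 14L)) {
  stopifnot(length(cdr3) > 0)
  mean(nchar(cdr3) >= range[1] & nchar(cdr3) <= range[2])
}

#' Positional residue-frequency matrix (sequence-logo data)
#'
#' Left anchoring indexes positions 1..L from the N-terminal cysteine;
#' right anchoring indexes -1..-L from the C-terminus. Frequencies at each
#' position are computed over the sequences covering it and sum to 1;
#' positions with no coverage are omitted.
#'
#' @param cdr3 sequences.
#' @param anchoring `"left"` or `"right"`.
#' @return matrix positions x 20 residues with `n_sequences` attribute;
#'   rownames are signed position labels.
#' @export
positional_matrix <- function(cdr3, anchoring = c("left", "right")) {
  anchoring <- match.arg(anchoring)
  assert_aa(cdr3, "cdr3")
  lens <- nchar(cdr3)
  maxlen <- max(lens)
  mat <- matrix(0, maxlen, length(AA_ALPHABET),
                dimnames = list(NULL, AA_ALPHABET))
  chars <- strsplit(cdr3, "")
  for (i in seq_along(chars)) {
    cc <- chars[[i]]
    pos <- if (anchoring == "left") seq_along(cc) else maxlen - length(cc) + seq_along(cc)
    for (k in seq_along(cc)) mat[pos[k], cc[k]] <- mat[pos[k], cc[k]] + 1
  }
  cov <- rowSums(mat)
  keep <- cov > 0
  mat <- mat[keep, , drop = FALSE] / cov[keep]
  rownames(mat) <- if (anchoring == "left") as.character(which(keep)) else
    as.character(which(keep) - maxlen - 1L)
  attr(mat, "n_sequences") <- length(cdr3)
  attr(mat, "anchoring") <- anchoring
  mat
}

#' Test for the conserved CDR3-alpha tyrosine ("Tyr-95")
#'
#' The riboflavin-recognition tyrosine encoded by TRAJ33 sits 5 residues
#' from the CDR3-alpha C-terminus in canonical sequences (germline ending
#' ...NYQLIW). The test is therefore TRUE iff the residue at 0-based index
#' `length - 5` is `Y`. Sequences shorter than 6 residues cannot carry the
#' slot and return FALSE with a warning.
#'
#' @param cdr3 character vector.
#' @return logical vector.
#' @export
#' @examples
#' tyr95_test("CAVMDSNYQLIW")  # TRUE
tyr95_test <- function(cdr3) {
  lens <- nchar(cdr3)
  short <- lens < 6L
  if (any(short))
    warning("sequence(s) shorter than 6 residues: Tyr-95 slot undefined, returning FALSE")
  out <- !short & substr(cdr3, lens - 4L, lens - 4L) == "Y"
  out
}

#' Conserved-anchor and terminal-residue summary
#'
#' Reports the fractions of sequences carrying the conserved cysteine at
#' position 1, alanine at position 2 and valine at position 3, the fraction
#' whose final residue is one of the J-encoded terminals L/I/T/F/W, and the
#' fraction of residues within the last `k` positions that fall in that
#' set.
#'
#' @param cdr3 sequences.
#' @param k number of C-terminal residues summarized.
#' @return named list of fractions.
#' @export
terminal_conservation <- function(cdr3, k = 3L) {
  stopifnot(length(cdr3) > 0)
  lens <- nchar(cdr3)
  lastk <- substr(cdr3, pmax(1L, lens - k + 1L), lens)
  lastk_chars <- unlist(strsplit(lastk, ""))
  list(
    frac_c1 = mean(substr(cdr3, 1, 1) == "C"),
    frac_a2 = mean(substr(cdr3, 2, 2) == "A"),
    frac_v3 = mean(substr(cdr3, 3, 3) == "V"),
    last_residue_conserved = mean(substr(cdr3, lens, lens) %in% JEND_RESIDUES),
    lastk_residue_fraction = mean(lastk_chars %in% JEND_RESIDUES)
  )
}
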