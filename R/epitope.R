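# Fuzzy CDR3-epitope matching against a local McPAS-style reference table,
# with in-silico +1/+2 insertions or -1/-2 deletions of the query.

#' Percent similarity between two CDR3 sequences
#'
#' Defined as 100 x (number of matching positions in an optimal global
#' alignment with match = 1, mismatch = 0, gap = 0 scoring) / max(length
#' of query, length of reference). The alignment score under that scheme
#' equals the longest-common-subsequence length, so the measure reduces to
#' percent identity for equal-length ungapped matches, is symmetric,
#' lies in `[0, 100]`, and equals 100 iff the strings are identical.
#'
#' @param query,reference uppercase amino-acid strings (vectorized,
#'   recycled).
#' @return numeric vector of percentages.
#' @export
#' @examples
#' cdr3_similarity("CASSF", "CASTF")  # 80
cdr3_similarity <- function(query, reference) {
  assert_aa(query, "query")
  assert_aa(reference, "reference")
  matches <- .lcs_length(query, reference)
  n <- max(length(query), length(reference))
  q <- rep_len(query, n); r <- rep_len(reference, n)
  100 * matches / pmax(nchar(q), nchar(r))
}

#' Central-region percent similarity
#'
#' Windowed variant of [cdr3_similarity()] comparing only the central
#' loops: each sequence is trimmed to positions 4..L-4 (the region between
#' the conserved N-terminal anchors and the J-encoded ending) before
#' alignment. Sequences too short to have a central region (L < 8) are
#' compared whole.
#'
#' @param query,reference uppercase amino-acid strings.
#' @return numeric percentage.
#' @export
central_similarity <- function(query, reference) {
  trim <- function(x) {
    L <- nchar(x)
    ifelse(L >= 8L, substr(x, 4L, L - 4L), x)
  }
  cdr3_similarity(trim(query), trim(reference))
}

#' Read a McPAS-style CDR3-epitope reference table
#'
#' Expects CSV columns `CDR3_alpha`, `CDR3_beta` (either may be empty per
#' row), `Epitope`, `Pathology`, and optionally a source identifier column.
#' Each nonempty chain field becomes one reference entry; sequences are
#' uppercased and duplicates retained.
#'
#' @param path CSV file.
#' @return data.frame: cdr3_aa, chain (`alpha`/`beta`), epitope, pathology,
#'   source_id.
#' @export
read_reference <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("CDR3_alpha", "CDR3_beta", "Epitope", "Pathology")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("reference table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  src <- if ("Source" %in% names(df)) df$Source else paste0("row", seq_len(nrow(df)))
  one_chain <- function(col, chain) {
    s <- toupper(trimws(df[[col]]))
    keep <- !is.na(s) & nzchar(s)
    data.frame(cdr3_aa = s[keep], chain = rep(chain, sum(keep)),
               epitope = df$Epitope[keep],
               pathology = df$Pathology[keep], source_id = src[keep],
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_chain("CDR3_alpha", "alpha"), one_chain("CDR3_beta", "beta"))
  rownames(out) <- NULL
  out
}

# all query variants with exactly d deletions (any positions)
deletion_variants <- function(query, d) {
  L <- nchar(query)
  if (d == 0L) return(list(list(seq = query, edits = character())))
  if (d >= L) return(list())
  chars <- strsplit(query, "")[[1]]
  combos <- combn(L, d, simplify = FALSE)
  lapply(combos, function(pos) {
    list(seq = paste(chars[-pos], collapse = ""),
         edits = sprintf("del@%d:%s", pos, chars[pos]))
  })
}

# all single insertions at internal positions (first and last residue kept
# as anchors), residues restricted to `alphabet`
insertion_step <- function(variant, alphabet) {
  q <- variant$seq
  L <- nchar(q)
  if (L < 2L) return(list())
  out <- list()
  for (p in 2:L) {
    pre <- substr(q, 1L, p - 1L); post <- substr(q, p, L)
    for (r in alphabet) {
      out[[length(out) + 1L]] <- list(
        seq = paste0(pre, r, post),
        edits = c(variant$edits, sprintf("ins@%d:%s", p, r)))
    }
  }
  out
}

#' Best reference match for a query CDR3 under an indel budget
#'
#' Enumerates query variants carrying exactly `d` amino-acid deletions
#' (`d <= max_deletions`, any positions) or exactly `i` insertions
#' (`i <= max_insertions`, internal positions only so the Cys anchor and
#' terminal residue are preserved; insertions and deletions are never mixed
#' within one variant) and reports the (variant, reference) pair with
#' maximal [cdr3_similarity()]. Ties are broken by smaller indel budget,
#' then lexicographic epitope, then lexicographic reference sequence.
#' Insertion residues are drawn, per reference, from the residues occurring
#' in that reference: inserting any other residue cannot add an aligned
#' match, so the optimum over the full 20-letter alphabet is unchanged.
#'
#' @param query uppercase amino-acid string.
#' @param references data.frame from [read_reference()] (or with columns
#'   cdr3_aa, epitope, pathology; optionally chain, source_id).
#' @param max_insertions,max_deletions budgets, each 0..2.
#' @return list of class `epitope_hit`: query, best_reference (one-row
#'   data.frame), similarity_pct, indel_budget_used, edit_operations
#'   (character vector), n_variants.
#' @export
perturbed_match <- function(query, references, max_insertions = 2L, max_deletions = 2L) {
  stopifnot(max_insertions >= 0L, max_insertions <= 2L,
            max_deletions >= 0L, max_deletions <= 2L)
  if (is.null(references) || nrow(references) == 0L)
    stop("reference set is empty", call. = FALSE)
  assert_aa(query, "query")
  assert_aa(references$cdr3_aa, "reference cdr3_aa")

  del_vars <- list(list(seq = query, edits = character()))
  if (max_deletions >= 1L) del_vars <- c(del_vars, deletion_variants(query, 1L))
  if (max_deletions >= 2L) del_vars <- c(del_vars, deletion_variants(query, 2L))

  best <- NULL
  n_variants <- 0L
  consider <- function(sim, budget, ref_row, edits) {
    cand <- list(sim = sim, budget = budget, ref = ref_row, edits = edits)
    if (is.null(best)) { best <<- cand; return(invisible()) }
    better <- (sim > best$sim) ||
      (sim == best$sim && budget < best$budget) ||
      (sim == best$sim && budget == best$budget &&
         (ref_row$epitope < best$ref$epitope ||
            (ref_row$epitope == best$ref$epitope && ref_row$cdr3_aa < best$ref$cdr3_aa)))
    if (better) best <<- cand
    invisible()
  }
  for (k in seq_len(nrow(references))) {
    ref <- references[k, , drop = FALSE]
    alphabet <- unique(strsplit(ref$cdr3_aa, "")[[1]])
    ins_vars <- list(list(seq = query, edits = character()))
    if (max_insertions >= 1L) {
      one <- insertion_step(list(seq = query, edits = character()), alphabet)
      ins_vars <- c(ins_vars, one)
      if (max_insertions >= 2L)
        ins_vars <- c(ins_vars, unlist(lapply(one, insertion_step, alphabet = alphabet),
                                       recursive = FALSE))
    }
    vars <- c(del_vars, ins_vars[-1L])
    n_variants <- n_variants + length(vars)
    seqs <- vapply(vars, `[[`, "", "seq")
    sims <- 100 * .lcs_length(seqs, ref$cdr3_aa) / pmax(nchar(seqs), nchar(ref$cdr3_aa))
    for (v in seq_along(vars)) {
      consider(sims[v], length(vars[[v]]$edits), ref, vars[[v]]$edits)
    }
  }
  structure(list(query = query, best_reference = best$ref,
                 similarity_pct = best$sim, indel_budget_used = best$budget,
                 edit_operations = best$edits, n_variants = n_variants),
            class = "epitope_hit")
}

#' @export
print.epitope_hit <- function(x, ...) {
  cat(sprintf("query %s -> %s (%s, %s): %.1f%% similarity, %d indel(s)%s\n",
              x$query, x$best_reference$cdr3_aa, x$best_reference$epitope,
              x$best_reference$pathology, x$similarity_pct, x$indel_budget_used,
              if (length(x$edit_operations))
                paste0(" [", paste(x$edit_operations, collapse = ", "), "]") else ""))
  invisible(x)
}

#' Match many queries against a reference table
#'
#' @param queries character vector of CDR3 sequences.
#' @param references data.frame from [read_reference()].
#' @param max_insertions,max_deletions budgets per query.
#' @return data.frame with one row per query: query, best reference
#'   sequence, epitope, pathology, similarity_pct, indel_budget_used,
#'   edits (comma-separated).
#' @export
match_epitopes <- function(queries, references, max_insertions = 1L, max_deletions = 1L) {
  rows <- lapply(queries, function(q) {
    h <- perturbed_match(q, references, max_insertions, max_deletions)
    data.frame(query = q, reference = h$best_reference$cdr3_aa,
               epitope = h$best_reference$epitope,
               pathology = h$best_reference$pathology,
               similarity_pct = h$similarity_pct,
               indel_budget_used = h$indel_budget_used,
               edits = paste(h$edit_operations, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
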