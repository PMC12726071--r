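# Chain pairing, canonical classification, usage tables and diversity.

#' Canonical MAIT TCR definition
#'
#' The canonical receptor is a TRAV1-2 alpha chain joined to TRAJ33, TRAJ20
#' or TRAJ12, typically paired with TRBV6-1, TRBV6-4 or TRBV20-1 beta
#' chains. Membership is tested after gene-name normalization
#' ([normalize_gene_symbol()]).
#'
#' @param canonical_trav,canonical_traj,canonical_trbv gene sets.
#' @param trbv_family_mode if `TRUE`, any TRBV6-family gene counts as
#'   canonical.
#' @return object of class `canonical_definition`.
#' @export
canonical_definition <- function(canonical_trav = "TRAV1-2",
                                 canonical_traj = c("TRAJ33", "TRAJ20", "TRAJ12"),
                                 canonical_trbv = c("TRBV6-1", "TRBV6-4", "TRBV20-1"),
                                 trbv_family_mode = FALSE) {
  stopifnot(length(canonical_trav) > 0, length(canonical_traj) > 0,
            length(canonical_trbv) > 0)
  structure(list(canonical_trav = canonical_trav, canonical_traj = canonical_traj,
                 canonical_trbv = canonical_trbv, trbv_family_mode = trbv_family_mode),
            class = "canonical_definition")
}

#' Pair alpha and beta chains per barcode
#'
#' Considers only productive, high-confidence TRA/TRB contigs. Redundant
#' identical contigs (same chain, V, J and CDR3) are collapsed, keeping the
#' highest UMI count. Per barcode: 1 TRA + 1 TRB gives `paired_single`;
#' 2 TRA + 1 TRB gives `dual_alpha` (categorized by TRAV1-2 membership of
#' each alpha); more than 2 TRA or more than 1 TRB gives `multiplet`
#' (excluded from repertoire statistics); single-chain barcodes give
#' `alpha_only`/`beta_only`; no qualifying contig gives `none`. Alpha
#' chains are ordered TRAV1-2 first, then by UMI count (descending), then
#' by CDR3 (lexicographic), so the primary alpha of a `one_trav12` dual
#' cell is its TRAV1-2 chain.
#'
#' @param contigs contig table from [read_contigs()] (or the generator).
#' @return data.frame of clonotype calls, one row per barcode: pairing
#'   status, dual category, TRAV1-2 status, and the chain fields
#'   `a1_v/a1_j/a1_cdr3`, `a2_*`, `b_v/b_d/b_j/b_cdr3`.
#' @export
pair_chains <- function(contigs) {
  need <- c("barcode", "chain", "v_gene", "j_gene", "cdr3", "productive",
            "high_confidence", "umis")
  stopifnot(all(need %in% names(contigs)))
  ok <- contigs$productive & contigs$high_confidence & contigs$chain %in% c("TRA", "TRB")
  use <- contigs[ok, , drop = FALSE]
  # collapse redundant identical contigs, keeping the highest UMI support
  key <- paste(use$barcode, use$chain, use$v_gene, use$j_gene, use$cdr3, sep = "\r")
  ord <- order(key, -use$umis)
  use <- use[ord, , drop = FALSE]
  use <- use[!duplicated(key[ord]), , drop = FALSE]
  barcodes <- unique(contigs$barcode)
  groups <- split(use, factor(use$barcode, levels = barcodes))
  groups <- Filter(nrow, groups)
  res <- lapply(groups, function(d) {
    a <- d[d$chain == "TRA", , drop = FALSE]
    b <- d[d$chain == "TRB", , drop = FALSE]
    nA <- nrow(a); nB <- nrow(b)
    status <- if (nB > 1L || nA > 2L) "multiplet"
      else if (nA == 1L && nB == 1L) "paired_single"
      else if (nA == 2L && nB == 1L) "dual_alpha"
      else if (nA >= 1L && nB == 0L) "alpha_only"
      else if (nA == 0L && nB == 1L) "beta_only"
      else "none"
    if (nA > 0L) {
      ord <- order(a$v_gene != "TRAV1-2", -a$umis, a$cdr3)
      a <- a[ord, , drop = FALSE]
    }
    chainf <- function(d, i, f) if (nrow(d) >= i) d[[f]][i] else NA_character_
    dual_category <- NA_character_
    trav12_status <- NA_character_
    if (status %in% c("paired_single", "dual_alpha", "alpha_only")) {
      n12 <- sum(a$v_gene[seq_len(min(nA, 2L))] == "TRAV1-2")
      trav12_status <- if (n12 >= 1L) "positive" else "negative"
      if (status == "dual_alpha")
        dual_category <- c("neither", "one_trav12", "both_trav12")[n12 + 1L]
    }
    data.frame(barcode = d$barcode[1], pairing_status = status,
               dual_category = dual_category, trav12_status = trav12_status,
               a1_v = chainf(a, 1L, "v_gene"), a1_j = chainf(a, 1L, "j_gene"),
               a1_cdr3 = chainf(a, 1L, "cdr3"),
               a2_v = chainf(a, 2L, "v_gene"), a2_j = chainf(a, 2L, "j_gene"),
               a2_cdr3 = chainf(a, 2L, "cdr3"),
               b_v = chainf(b, 1L, "v_gene"), b_d = chainf(b, 1L, "d_gene"),
               b_j = chainf(b, 1L, "j_gene"), b_cdr3 = chainf(b, 1L, "cdr3"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(barcode = character(), pairing_status = character(),
                      dual_category = character(), trav12_status = character(),
                      a1_v = character(), a1_j = character(), a1_cdr3 = character(),
                      a2_v = character(), a2_j = character(), a2_cdr3 = character(),
                      b_v = character(), b_d = character(), b_j = character(),
                      b_cdr3 = character(), stringsAsFactors = FALSE)
  }
  missing_bc <- setdiff(barcodes, out$barcode)
  if (length(missing_bc)) {
    empty <- out[rep(NA_integer_, length(missing_bc)), , drop = FALSE]
    empty$barcode <- missing_bc
    empty$pairing_status <- "none"
    out <- rbind(out, empty)
  }
  out <- out[match(barcodes, out$barcode), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify paired TCRs as canonical or noncanonical
#'
#' Adds classification columns to clonotype calls: `trav12_status`
#' (positive iff any alpha chain is canonical TRAV1-2), `canonical_traj`
#' (primary alpha J in TRAJ33/20/12), `canonical_trbv` (beta V in the
#' canonical set, or any TRBV6 family member under `trbv_family_mode`), and
#' `fully_canonical` (TRAV1-2 with canonical J). Rows whose pairing status
#' is not `paired_single`/`dual_alpha` get `NA` classification.
#'
#' @param calls output of [pair_chains()].
#' @param defn a [canonical_definition()].
#' @return `calls` with classification columns appended.
#' @export
classify_tcr <- function(calls, defn = canonical_definition()) {
  stopifnot(inherits(defn, "canonical_definition"))
  gene_cols <- c("a1_v", "a1_j", "a2_v", "a2_j", "b_v")
  vals <- unlist(calls[gene_cols], use.names = FALSE)
  bad <- vals[!is.na(vals) & grepl("\\*", vals)]
  if (length(bad))
    stop("unnormalized gene name(s) with allele suffix: ",
         paste(unique(bad), collapse = ", "),
         " - normalization happens at read time (read_contigs)", call. = FALSE)
  eligible <- calls$pairing_status %in% c("paired_single", "dual_alpha")
  trav12 <- (calls$a1_v %in% defn$canonical_trav) |
    (!is.na(calls$a2_v) & calls$a2_v %in% defn$canonical_trav)
  can_j <- calls$a1_j %in% defn$canonical_traj
  can_bv <- if (defn$trbv_family_mode) {
    grepl("^TRBV6($|-)", calls$b_v) | calls$b_v %in% defn$canonical_trbv
  } else calls$b_v %in% defn$canonical_trbv
  calls$trav12_status <- ifelse(eligible, ifelse(trav12, "positive", "negative"), calls$trav12_status)
  calls$canonical_traj <- ifelse(eligible, can_j, NA)
  calls$canonical_trbv <- ifelse(eligible, can_bv, NA)
  calls$fully_canonical <- ifelse(eligible, trav12 & can_j, NA)
  calls
}

#' V/J gene usage tables per group
#'
#' Counts each cell once (dual-alpha cells contribute their primary alpha,
#' the TRAV1-2 chain when present). Returns long-format counts and
#' proportions over TRAV (`a1_v`), TRAJ (`a1_j`) and TRBV (`b_v`) per
#' group; proportions sum to 1 within each group and gene class. Dual-alpha
#' cells are excluded by default so group denominators match the
#' single-paired analysis.
#'
#' @param calls classified clonotype calls carrying the grouping columns.
#' @param group_by character vector of column names in `calls` to group by
#'   (e.g. `"subset"`, `"trav12_status"`, `"condition"`).
#' @param include_dual include dual-alpha cells in the denominators.
#' @return data.frame: group columns, gene_class, gene, count, proportion.
#' @export
usage_table <- function(calls, group_by = "subset", include_dual = FALSE) {
  keep <- calls$pairing_status == "paired_single" |
    (include_dual & calls$pairing_status == "dual_alpha")
  d <- calls[keep, , drop = FALSE]
  stopifnot(all(group_by %in% names(d)))
  classes <- c(TRAV = "a1_v", TRAJ = "a1_j", TRBV = "b_v")
  out <- list()
  for (cl in names(classes)) {
    col <- classes[[cl]]
    grp <- interaction(d[group_by], drop = TRUE, sep = "|")
    if (nrow(d) == 0L) next
    tab <- as.data.frame(table(group = grp, gene = d[[col]]),
                         stringsAsFactors = FALSE)
    tab <- tab[tab$Freq > 0, , drop = FALSE]
    tot <- tapply(tab$Freq, tab$group, sum)
    tab$proportion <- tab$Freq / as.vector(tot[tab$group])
    gvals <- do.call(rbind, strsplit(tab$group, "|", fixed = TRUE))
    gdf <- as.data.frame(gvals, stringsAsFactors = FALSE)
    names(gdf) <- group_by
    out[[cl]] <- cbind(gdf, data.frame(gene_class = cl, gene = tab$gene,
                                       count = tab$Freq,
                                       proportion = tab$proportion,
                                       stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Shared and unique gene sets between groups
#'
#' @param usage a [usage_table()] result.
#' @param gene_class one of `"TRAV"`, `"TRAJ"`, `"TRBV"`.
#' @param group_col grouping column to compare across.
#' @return list with `shared` (genes used by more than one group) and
#'   `unique` (named list of genes private to each group).
#' @export
gene_overlap <- function(usage, gene_class = "TRAV", group_col = "subset") {
  d <- usage[usage$gene_class == gene_class, , drop = FALSE]
  sets <- split(d$gene, d[[group_col]])
  all_genes <- unlist(sets, use.names = FALSE)
  shared <- sort(unique(all_genes[duplicated(all_genes)]))
  uniq <- lapply(sets, function(g) sort(setdiff(g, shared)))
  list(shared = shared, unique = uniq)
}

#' Repertoire diversity indices
#'
#' Shannon entropy (natural log), Gini-Simpson index, richness, and Pielou
#' evenness over a vector of category counts.
#'
#' @param counts nonnegative counts (e.g. clonotype or gene usage counts).
#' @param metric one of `"shannon"`, `"simpson"`, `"richness"`, `"pielou"`.
#' @return a single number.
#' @export
#' @examples
#' diversity_index(rep(5, 4), "shannon")  # log(4)
diversity_index <- function(counts, metric = c("shannon", "simpson", "richness", "pielou")) {
  metric <- match.arg(metric)
  if (any(counts < 0) || any(is.na(counts)))
    stop("counts must be nonnegative", call. = FALSE)
  if (sum(counts) <= 0) stop("all-zero counts: diversity undefined", call. = FALSE)
  counts <- counts[counts > 0]
  p <- counts / sum(counts)
  switch(metric,
         shannon = -sum(p * log(p)),
         simpson = 1 - sum(p^2),
         richness = length(p),
         pielou = {
           if (length(p) < 2L)
             stop("pielou evenness requires richness >= 2", call. = FALSE)
           -sum(p * log(p)) / log(length(p))
         })
}
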