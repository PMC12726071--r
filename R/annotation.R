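# QC filtering, normalization, MAIT lineage gating, CD4/CD8/DN subset
# assignment, and the minimal rank-sum differential-expression operation.

#' Quality-control thresholds
#'
#' Two shipped presets: `"discovery"` removes cells with more than 6,000 detected
#' genes or more than 5% mitochondrial content; `"validation"` removes cells
#' with more than 3,000 detected genes or more than 8% mitochondrial
#' content. Both inequalities are strict ("more than"), so a cell sitting
#' exactly on a threshold is kept.
#'
#' @param preset `"discovery"` or `"validation"`, or `NULL` when supplying custom
#'   thresholds.
#' @param max_genes_detected,max_mito_fraction custom thresholds (ignored
#'   when a preset is named).
#' @return object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(preset = c("discovery", "validation"),
                          max_genes_detected = NULL, max_mito_fraction = NULL) {
  if (is.null(preset)) {
    stopifnot(!is.null(max_genes_detected), !is.null(max_mito_fraction))
    name <- "custom"
  } else {
    preset <- match.arg(preset)
    vals <- list(discovery = list(genes = 6000L, mito = 0.05),
                 validation = list(genes = 3000L, mito = 0.08))[[preset]]
    max_genes_detected <- vals$genes
    max_mito_fraction <- vals$mito
    name <- preset
  }
  stopifnot(max_genes_detected > 0, max_mito_fraction > 0, max_mito_fraction < 1)
  structure(list(max_genes_detected = as.integer(max_genes_detected),
                 max_mito_fraction = max_mito_fraction, preset_name = name),
            class = "qc_thresholds")
}

#' Apply QC filtering to a cell table
#'
#' Partitions cells into kept and removed sets. A cell is removed iff
#' `n_genes_detected > max_genes_detected` OR
#' `mito_fraction > max_mito_fraction` (strict inequalities). The partition
#' is exact: `kept` and `removed` are disjoint and their union is the input.
#'
#' @param cells data.frame with columns `n_genes_detected`, `mito_fraction`.
#' @param thresholds a [qc_thresholds()].
#' @return list with data.frames `kept` and `removed`.
#' @export
apply_qc <- function(cells, thresholds) {
  stopifnot(inherits(thresholds, "qc_thresholds"),
            all(c("n_genes_detected", "mito_fraction") %in% names(cells)))
  drop <- cells$n_genes_detected > thresholds$max_genes_detected |
    cells$mito_fraction > thresholds$max_mito_fraction
  list(kept = cells[!drop, , drop = FALSE], removed = cells[drop, , drop = FALSE])
}

#' Compute per-cell QC metrics from a count matrix
#'
#' Derives detected-gene counts (number of genes with nonzero counts) and
#' the mitochondrial fraction (share of counts on genes whose symbol starts
#' with `mito_prefix`) from a full count matrix.
#'
#' @param counts gene x cell matrix (sparse or dense) with gene rownames.
#' @param mito_prefix prefix identifying mitochondrial genes.
#' @return data.frame with barcode, n_genes_detected, mito_fraction.
#' @export
compute_cell_metrics <- function(counts, mito_prefix = "MT-") {
  tot <- Matrix::colSums(counts)
  mito <- startsWith(rownames(counts), mito_prefix)
  mt <- if (any(mito)) Matrix::colSums(counts[mito, , drop = FALSE]) else rep(0, ncol(counts))
  data.frame(barcode = colnames(counts),
             n_genes_detected = as.integer(Matrix::colSums(counts > 0)),
             mito_fraction = ifelse(tot > 0, mt / tot, 0),
             stringsAsFactors = FALSE)
}

#' Library-size normalization (counts per 10K, log1p)
#'
#' @param counts gene x cell matrix.
#' @return matrix of `log1p(1e4 * count / library_size)` values, sparse if
#'   the input was sparse.
#' @export
normalize_cp10k <- function(counts) {
  libsize <- Matrix::colSums(counts)
  scale <- ifelse(libsize > 0, 1e4 / libsize, 0)
  out <- counts %*% Matrix::Diagonal(x = scale)
  dimnames(out) <- dimnames(counts)
  if (methods::is(out, "sparseMatrix")) {
    out <- methods::as(out, "CsparseMatrix")
    out@x <- log1p(out@x)
    out
  } else log1p(out)
}

#' Otsu threshold of a numeric score
#'
#' Splits a (bimodal) distribution at the cut maximizing between-class
#' variance over a fixed histogram grid.
#'
#' @param x numeric vector.
#' @param nbins histogram resolution.
#' @return the threshold value.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  stopifnot(length(x) > 1)
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  breaks <- seq(r[1], r[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[nbins]
  between <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Valley threshold between the two modes of a bimodal score
#'
#' Locates the two modes by deterministic 2-means (centers initialized at
#' the extremes) and places the threshold at the kernel-density minimum
#' between the mode centers. Falls back to [otsu_threshold()] when the
#' centers are closer than `min_sep` (no clear bimodality).
#'
#' @param x numeric vector.
#' @param min_sep minimal center separation accepted as bimodal.
#' @return the threshold value.
#' @export
valley_threshold <- function(x, min_sep = 0.5) {
  x <- x[is.finite(x)]
  stopifnot(length(x) > 1)
  if (diff(range(x)) == 0) return(x[1])
  km <- kmeans(x, centers = matrix(range(x), ncol = 1))
  cs <- sort(km$centers[, 1])
  if (diff(cs) < min_sep) return(otsu_threshold(x))
  d <- stats::density(x, n = 512)
  inside <- d$x > cs[1] & d$x < cs[2]
  if (!any(inside)) return(mean(cs))
  d$x[inside][which.min(d$y[inside])]
}

#' Score cells for MAIT lineage and call the lineage
#'
#' The MAIT score of a cell is the mean normalized (CP10K, log1p)
#' expression of the marker set (default KLRB1, ZBTB16, IL18R1, SLC4A10).
#' A cell is called MAIT iff its score exceeds a threshold (Otsu split of
#' the score distribution by default, or a fixed value) AND the CD3E
#' transcript is detected (CD3 gate, excluding NK-like contaminants).
#'
#' @param norm_counts normalized gene x cell matrix from [normalize_cp10k()].
#' @param markers marker gene set.
#' @param cd3_gene gene whose detection gates T lineage.
#' @param threshold fixed score threshold; `NULL` for a data-driven split.
#' @param method data-driven split when `threshold` is `NULL`: `"valley"`
#'   places the cut at the density minimum between the two 2-means modes
#'   (robust when the MAIT population vastly outnumbers contaminants, where
#'   Otsu's between-class criterion drifts into the majority mode);
#'   `"otsu"` uses [otsu_threshold()]. Valley falls back to Otsu when the
#'   two modes are not separated.
#' @return data.frame with barcode, score, cd3_detected, lineage
#'   (`"MAIT"`/`"other"`), plus the threshold used as attribute
#'   `"threshold"`.
#' @export
score_mait_lineage <- function(norm_counts,
                               markers = c("KLRB1", "ZBTB16", "IL18R1", "SLC4A10"),
                               cd3_gene = "CD3E", threshold = NULL,
                               method = c("valley", "otsu")) {
  method <- match.arg(method)
  missing <- setdiff(c(markers, cd3_gene), rownames(norm_counts))
  if (length(missing))
    stop("marker gene(s) absent from the panel: ", paste(missing, collapse = ", "),
         call. = FALSE)
  score <- Matrix::colSums(norm_counts[markers, , drop = FALSE]) / length(markers)
  if (is.null(threshold)) {
    threshold <- if (method == "valley") valley_threshold(score) else otsu_threshold(score)
  }
  cd3 <- as.vector(norm_counts[cd3_gene, ] > 0)
  out <- data.frame(barcode = colnames(norm_counts), score = as.vector(score),
                    cd3_detected = cd3,
                    lineage = ifelse(score > threshold & cd3, "MAIT", "other"),
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  out
}

# ---- ADT handling and the dual-modality subset rule -------------------------

#' Centered log-ratio (CLR) transform of ADT counts
#'
#' Within-cell CLR: for each cell, `log(x) - mean(log(x))` over its tags,
#' with zeros replaced by 0.5 before taking logs. Invariant to scaling all
#' of a cell's tags by a common positive factor (exactly so when all counts
#' are positive).
#'
#' @param adt cells x tags count matrix.
#' @return cells x tags matrix of CLR values.
#' @export
clr_adt <- function(adt) {
  x <- pmax(adt, 0.5)
  lx <- log(x)
  lx - rowMeans(lx)
}

#' Per-tag positive/negative gate on CLR values
#'
#' `"mixture"` splits the tag's CLR values into two groups by 2-means
#' (initialized at the extremes, deterministic) and thresholds at the
#' midpoint of the two centers; if the centers are closer than `min_sep`
#' the distribution is judged unimodal and the method falls back to the
#' quantile gate with a warning. `"quantile"` thresholds at the given
#' quantile.
#'
#' @param clr_values numeric vector (one tag, all cells).
#' @param method `"mixture"` or `"quantile"`.
#' @param param quantile used by the quantile method/fallback.
#' @param min_sep minimal center separation accepted as bimodal.
#' @return list with `positive` (logical vector) and `threshold`.
#' @export
adt_gate <- function(clr_values, method = c("mixture", "quantile"),
                     param = 0.9, min_sep = 0.5) {
  method <- match.arg(method)
  thr <- if (method == "mixture") {
    km <- kmeans(clr_values, centers = matrix(range(clr_values), ncol = 1))
    cs <- sort(km$centers[, 1])
    if (diff(cs) < min_sep) {
      warning("CLR distribution looks unimodal; falling back to quantile gate")
      quantile(clr_values, param, names = FALSE)
    } else mean(cs)
  } else quantile(clr_values, param, names = FALSE)
  list(positive = clr_values > thr, threshold = thr)
}

#' The dual-modality subset rule
#'
#' Parameters of [assign_subset()]. CD8 status is read from the CD8B
#' transcript (not CD8A, which is detectable in all MAIT cells) together
#' with the anti-CD8 antibody barcode; CD4 analogously.
#'
#' @param cd8_transcript_gene,cd4_transcript_gene transcript genes.
#' @param transcript_min_count minimal count treated as "detectable".
#' @param cd8_adt,cd4_adt ADT tag names.
#' @param adt_positive_method,adt_threshold_param passed to [adt_gate()].
#' @return object of class `subset_rule`.
#' @export
subset_rule <- function(cd8_transcript_gene = "CD8B", cd4_transcript_gene = "CD4",
                        transcript_min_count = 1L,
                        cd8_adt = "ADT-CD8", cd4_adt = "ADT-CD4",
                        adt_positive_method = "mixture", adt_threshold_param = 0.9) {
  stopifnot(transcript_min_count >= 1L)
  structure(list(cd8_transcript_gene = cd8_transcript_gene,
                 cd4_transcript_gene = cd4_transcript_gene,
                 transcript_min_count = as.integer(transcript_min_count),
                 cd8_adt = cd8_adt, cd4_adt = cd4_adt,
                 adt_positive_method = adt_positive_method,
                 adt_threshold_param = adt_threshold_param),
            class = "subset_rule")
}

#' Assign CD4/CD8/DN/DP subsets to MAIT cells
#'
#' A cell is CD8-positive iff its CD8B transcript count reaches
#' `transcript_min_count` AND its CD8 ADT is gated positive; CD4-positive
#' analogously. Subset is `DP` if both, `CD8`/`CD4` if exactly one, `DN` if
#' neither. Deterministic given the data.
#'
#' @param counts raw gene x cell count matrix (MAIT cells).
#' @param adt cells x tags ADT count matrix (same cells, rows named by
#'   barcode).
#' @param rule a [subset_rule()].
#' @return character vector of subsets, named by barcode.
#' @export
assign_subset <- function(counts, adt, rule = subset_rule()) {
  for (tag in c(rule$cd8_adt, rule$cd4_adt)) {
    if (!tag %in% colnames(adt))
      stop("ADT tag missing from the table: ", tag, call. = FALSE)
  }
  for (g in c(rule$cd8_transcript_gene, rule$cd4_transcript_gene)) {
    if (!g %in% rownames(counts))
      stop("transcript gene missing from the matrix: ", g, call. = FALSE)
  }
  stopifnot(identical(colnames(counts), rownames(adt)))
  clr <- clr_adt(adt)
  g8 <- adt_gate(clr[, rule$cd8_adt], rule$adt_positive_method, rule$adt_threshold_param)
  g4 <- adt_gate(clr[, rule$cd4_adt], rule$adt_positive_method, rule$adt_threshold_param)
  cd8 <- as.vector(counts[rule$cd8_transcript_gene, ] >= rule$transcript_min_count) & g8$positive
  cd4 <- as.vector(counts[rule$cd4_transcript_gene, ] >= rule$transcript_min_count) & g4$positive
  subset <- ifelse(cd8 & cd4, "DP", ifelse(cd8, "CD8", ifelse(cd4, "CD4", "DN")))
  stats::setNames(subset, colnames(counts))
}

#' Two-group differential expression by unpaired Wilcoxon rank-sum test
#'
#' Per gene: rank-sum statistic (W), two-sided p-value (normal
#' approximation with midrank ties), Benjamini-Hochberg adjusted p, and the
#' log fold change defined as the difference of group means on the
#' normalized (CP10K, log1p) scale.
#'
#' @param normA,normB normalized gene x cell matrices (same gene rows) for
#'   the two groups; each needs at least 2 cells.
#' @return data.frame: gene, statistic, p_value, p_adj, logFC, ordered by
#'   p_adj.
#' @export
marker_de <- function(normA, normB) {
  if (is.null(dim(normA)) || ncol(normA) < 2L || is.null(dim(normB)) || ncol(normB) < 2L)
    stop("each group needs at least 2 cells", call. = FALSE)
  stopifnot(identical(rownames(normA), rownames(normB)))
  genes <- rownames(normA)
  A <- as.matrix(normA); B <- as.matrix(normB)
  stat <- p <- numeric(length(genes))
  for (i in seq_along(genes)) {
    wt <- suppressWarnings(wilcox.test(A[i, ], B[i, ], exact = FALSE))
    stat[i] <- unname(wt$statistic)
    p[i] <- wt$p.value
  }
  p[is.na(p)] <- 1
  out <- data.frame(gene = genes, statistic = stat, p_value = p,
                    p_adj = p.adjust(p, method = "BH"),
                    logFC = rowMeans(A) - rowMeans(B),
                    stringsAsFactors = FALSE)
  out[order(out$p_adj, out$p_value), ]
}
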