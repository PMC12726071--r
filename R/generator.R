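# CDR3-alpha sequence sampler and the full repertoire generator.

#' Sample a CDR3-alpha amino-acid sequence
#'
#' Draws a CDR3-alpha string with the conserved Cys/Ala anchor at positions
#' 1-2. Canonical sequences (TRAV1-2 joined to TRAJ33/20/12) have lengths in
#' `length_range` (default 12-14), a TRAJ-specific 5-residue ending whose
#' tyrosine sits 5 residues from the C-terminus (the "Tyr-95" slot), and a
#' valine at position 3. Noncanonical sequences draw their length from
#' `length_range` (default 7-23), place valine at position 3 with probability
#' `motif_params$v_at_pos3_prob`, and plant a central GGG/GGGG (or NNNN) run
#' with the configured probabilities so that motif prevalence is recoverable
#' downstream.
#'
#' Uses R's global RNG stream; seed via [set.seed()] or let
#' [generate_repertoire()] manage seeding.
#'
#' @param canonical logical flag.
#' @param length_range inclusive integer length range to draw from (minimum
#'   5; canonical sampling requires at least 10 to fit anchors + J ending).
#' @param motif_params list with elements `gly_motif_prob`, `gggg_frac`,
#'   `nnnn_prob`, `v_at_pos3_prob` (noncanonical only; missing entries
#'   default to 0, `gggg_frac` to 0.5).
#' @param j_gene canonical joining gene (one of TRAJ33/TRAJ12/TRAJ20)
#'   selecting the J-encoded ending; ignored for noncanonical draws.
#' @return a single amino-acid string, with attributes `gly_planted`,
#'   `gggg_planted`, `nnnn_planted`, `v3_planted` (logicals).
#' @export
#' @examples
#' set.seed(1)
#' sample_cdr3_alpha(TRUE, c(12L, 12L), j_gene = "TRAJ33")
sample_cdr3_alpha <- function(canonical, length_range,
                              motif_params = list(), j_gene = "TRAJ33") {
  stopifnot(length(length_range) == 2L, length_range[1] <= length_range[2])
  if (length_range[1] < 5L)
    stop("CDR3 length < 5 cannot satisfy the anchor constraints", call. = FALSE)
  len <- if (length_range[1] == length_range[2]) length_range[1] else
    sample(seq.int(length_range[1], length_range[2]), 1L)
  if (canonical) {
    if (!j_gene %in% names(CANONICAL_J_SUFFIX))
      stop("j_gene must be one of ", paste(names(CANONICAL_J_SUFFIX), collapse = "/"),
           call. = FALSE)
    if (len < 10L)
      stop("canonical CDR3 length must be >= 10 to fit anchors and J ending",
           call. = FALSE)
    suffix <- CANONICAL_J_SUFFIX[[j_gene]]
    mid <- paste(sample(AA_ALPHABET, len - 3L - nchar(suffix), replace = TRUE),
                 collapse = "")
    out <- paste0("CAV", mid, suffix)
    attr(out, "gly_planted") <- FALSE
    attr(out, "gggg_planted") <- FALSE
    attr(out, "nnnn_planted") <- FALSE
    attr(out, "v3_planted") <- TRUE
    return(out)
  }
  gp <- function(nm, default) if (is.null(motif_params[[nm]])) default else motif_params[[nm]]
  gly_p <- gp("gly_motif_prob", 0)
  gggg_frac <- gp("gggg_frac", 0.5)
  nnnn_p <- gp("nnnn_prob", 0)
  v3_p <- gp("v_at_pos3_prob", 0)
  res <- sample(AA_ALPHABET, len, replace = TRUE)
  res[1] <- "C"; res[2] <- "A"
  v3 <- runif(1) < v3_p
  # draw position 3 from the alphabet minus V when not forced, so the
  # realised V-at-3 frequency equals v_at_pos3_prob exactly
  res[3] <- if (v3) "V" else sample(setdiff(AA_ALPHABET, "V"), 1L)
  res[len] <- sample(JEND_RESIDUES, 1L, prob = c(0.35, 0.2, 0.2, 0.15, 0.1))
  gly <- runif(1) < gly_p
  gggg <- FALSE
  nnnn <- FALSE
  plant <- function(res, pattern) {
    k <- nchar(pattern)
    len <- length(res)
    # run confined to positions 4..len-1 (anchors preserved), preferring
    # starts whose span intersects the central window 6..9
    lo <- 4L; hi <- len - k
    if (hi < lo) return(NULL)
    starts <- seq.int(lo, hi)
    central <- starts[starts <= 9L & (starts + k - 1L) >= 6L]
    s <- if (length(central)) {
      if (length(central) == 1L) central else sample(central, 1L)
    } else max(starts)
    res[s:(s + k - 1L)] <- strsplit(pattern, "")[[1]]
    res
  }
  if (gly) {
    gggg <- runif(1) < gggg_frac
    pat <- if (gggg && len >= 8L) "GGGG" else "GGG"
    gggg <- identical(pat, "GGGG")
    planted <- plant(res, pat)
    if (is.null(planted)) gly <- gggg <- FALSE else res <- planted
  } else if (runif(1) < nnnn_p) {
    planted <- plant(res, "NNNN")
    if (!is.null(planted)) { res <- planted; nnnn <- TRUE }
  }
  out <- paste(res, collapse = "")
  attr(out, "gly_planted") <- gly
  attr(out, "gggg_planted") <- gggg
  attr(out, "nnnn_planted") <- nnnn
  attr(out, "v3_planted") <- v3
  out
}

# sample a CDR3-beta string: conserved CASS start, J-encoded Phe/Tyr-rich end
sample_cdr3_beta <- function() {
  len <- sample(12:16, 1L)
  end <- sample(c("EQYF", "TQYF", "NQFF", "YGYTF", "EQFF"), 1L)
  mid <- paste(sample(AA_ALPHABET, len - 4L - nchar(end), replace = TRUE), collapse = "")
  paste0("CASS", mid, end)
}

#' Generate a synthetic CITE-Seq-like MAIT repertoire
#'
#' Simulates `n_cells` MAIT cells (plus configured contaminants) with gene
#' counts (negative binomial over the marker panel), ADT counts (rounded
#' log-normal), per-cell QC metrics, and paired TCR contigs: every MAIT cell
#' receives one productive TRB contig and one productive TRA contig, plus a
#' second TRA with probability `dual_alpha_prob`. CD8A transcript counts are
#' strictly positive for all MAIT cells; CD8B/CD4 transcripts and CD4/CD8
#' ADT levels are subset-dependent. CDR3-alpha strings follow the configured
#' length, anchor and motif distributions. A ground-truth table records
#' every planted label for recovery testing.
#'
#' @param config a [generator_config()].
#' @return an object of class `mait_bundle`: a list with elements
#'   `cells` (barcode, n_genes_detected, mito_fraction, condition),
#'   `genes` (sparse gene x cell count matrix), `adt` (cell x tag count
#'   matrix), `contigs` (contig table, 10x-style columns) and `truth`
#'   (per-cell ground-truth labels).
#' @export
generate_repertoire <- function(config) {
  validate_generator_config(config)
  if (config$n_cells == 0L)
    stop("empty dataset: n_cells must be positive", call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  n_mait <- config$n_cells
  n_cont <- round(config$contaminant_fraction * n_mait)
  n_tot <- n_mait + n_cont
  barcode <- sprintf("CELL%06d-1", seq_len(n_tot))
  lineage <- c(rep("MAIT", n_mait),
               rep(c("NK", "gdT"), length.out = n_cont))
  subset <- rep(NA_character_, n_tot)
  subset[1:n_mait] <- sample(names(config$subset_probs), n_mait, replace = TRUE,
                             prob = config$subset_probs)
  group <- ifelse(lineage == "MAIT", subset, lineage)
  condition <- sample(names(config$condition_probs), n_tot, replace = TRUE,
                      prob = config$condition_probs)

  # --- TCR structure for MAIT cells ---
  is_mait <- lineage == "MAIT"
  dual <- is_mait & runif(n_tot) < config$dual_alpha_prob
  dual_category <- rep(NA_character_, n_tot)
  dual_category[dual] <- sample(names(config$dual_alpha_category_probs),
                                sum(dual), replace = TRUE,
                                prob = config$dual_alpha_category_probs)
  p_can <- config$canonical_alpha_prob_by_subset[subset] +
    config$condition_canonical_shift[condition]
  p_can <- pmin(pmax(p_can, 0), 1)
  trav12_single <- is_mait & !dual & runif(n_tot) < p_can
  trav12 <- trav12_single | (dual & dual_category %in% c("both_trav12", "one_trav12"))

  alpha1 <- vector("list", n_tot)
  alpha2 <- vector("list", n_tot)
  truth_attr <- matrix(FALSE, n_tot, 4,
                       dimnames = list(NULL, c("gly", "gggg", "nnnn", "v3")))
  make_alpha <- function(canonical_v, subset_i) {
    if (canonical_v) {
      can_j <- runif(1) < config$canonical_traj_prob_given_trav12
      if (can_j) {
        j <- sample(names(CANONICAL_TRAJ), 1L, prob = CANONICAL_TRAJ)
        cdr3 <- sample_cdr3_alpha(TRUE, config$canonical_len_range, j_gene = j)
      } else {
        j <- sample(NONCANONICAL_TRAJ, 1L)
        # noncanonical J on a TRAV1-2 chain: length drawn outside the
        # canonical 12-14 band so that the length-in-band fraction among
        # TRAV1-2+ cells equals the canonical-J rate
        cdr3 <- sample_noncanonical_outside(config, subset_i)
      }
      list(v = CANONICAL_TRAV, j = j, cdr3 = cdr3)
    } else {
      can_j <- runif(1) < config$canonical_traj_prob_given_noncanonical
      j <- if (can_j) sample(names(CANONICAL_TRAJ), 1L, prob = CANONICAL_TRAJ)
           else sample(NONCANONICAL_TRAJ, 1L)
      mp <- list(gly_motif_prob = config$gly_motif_prob,
                 gggg_frac = config$gggg_frac_by_subset[[subset_i]],
                 nnnn_prob = if (subset_i == "CD4") config$nnnn_motif_prob else 0,
                 v_at_pos3_prob = config$v_at_pos3_prob)
      cdr3 <- sample_cdr3_alpha(FALSE, config$noncanonical_len_range, mp)
      list(v = sample(NONCANONICAL_TRAV, 1L), j = j, cdr3 = cdr3)
    }
  }
  for (i in which(is_mait)) {
    if (!dual[i]) {
      alpha1[[i]] <- make_alpha(trav12_single[i], subset[i])
    } else {
      cat_i <- dual_category[i]
      if (cat_i == "both_trav12") {
        a1 <- make_alpha(TRUE, subset[i])
        repeat {
          a2 <- make_alpha(TRUE, subset[i])
          if (!identical(a2$cdr3[[1]], a1$cdr3[[1]])) break
        }
      } else if (cat_i == "one_trav12") {
        a1 <- make_alpha(TRUE, subset[i])
        a2 <- make_alpha(FALSE, subset[i])
      } else {
        a1 <- make_alpha(FALSE, subset[i])
        a2 <- make_alpha(FALSE, subset[i])
      }
      alpha1[[i]] <- a1; alpha2[[i]] <- a2
    }
    a <- alpha1[[i]]
    truth_attr[i, ] <- c(isTRUE(attr(a$cdr3, "gly_planted")),
                         isTRUE(attr(a$cdr3, "gggg_planted")),
                         isTRUE(attr(a$cdr3, "nnnn_planted")),
                         isTRUE(attr(a$cdr3, "v3_planted")))
  }

  # beta chain
  can_trbv <- rep(NA, n_tot)
  beta <- vector("list", n_tot)
  for (i in which(is_mait)) {
    p <- if (trav12[i]) config$canonical_trbv_prob_given_trav12
         else config$canonical_trbv_prob_given_noncanonical
    can_trbv[i] <- runif(1) < p
    v <- if (can_trbv[i]) sample(names(CANONICAL_TRBV), 1L, prob = CANONICAL_TRBV)
         else sample(NONCANONICAL_TRBV, 1L)
    beta[[i]] <- list(v = v, d = sample(c("TRBD1", "TRBD2"), 1L),
                      j = sample(TRBJ_GENES, 1L), cdr3 = sample_cdr3_beta())
  }

  # --- contig table (vectorized assembly) ---
  mi <- which(is_mait)
  di <- which(dual)
  fld <- function(lst, idx, f) vapply(lst[idx], function(x) as.character(x[[f]]), "")
  cg <- list(
    barcode = c(barcode[mi], barcode[di], barcode[mi]),
    chain = c(rep("TRA", length(mi) + length(di)), rep("TRB", length(mi))),
    v_gene = c(fld(alpha1, mi, "v"), fld(alpha2, di, "v"), fld(beta, mi, "v")),
    d_gene = c(rep("", length(mi) + length(di)), fld(beta, mi, "d")),
    j_gene = c(fld(alpha1, mi, "j"), fld(alpha2, di, "j"), fld(beta, mi, "j")),
    cdr3 = c(fld(alpha1, mi, "cdr3"), fld(alpha2, di, "cdr3"), fld(beta, mi, "cdr3")),
    umis = c(rpois(length(mi), 4) + 2L, rpois(length(di), 3) + 1L,
             rpois(length(mi), 5) + 2L)
  )
  contigs <- data.frame(
    barcode = cg$barcode, is_cell = TRUE, high_confidence = TRUE,
    chain = cg$chain, v_gene = cg$v_gene, d_gene = cg$d_gene,
    j_gene = cg$j_gene, cdr3 = cg$cdr3,
    cdr3_nt = strrep("N", nchar(cg$cdr3) * 3L),
    productive = TRUE,
    reads = cg$umis * sample(8:15, length(cg$umis), replace = TRUE),
    umis = cg$umis,
    raw_clonotype_id = paste0("clonotype_", cg$barcode),
    stringsAsFactors = FALSE)
  contigs <- contigs[order(match(contigs$barcode, barcode), contigs$chain, contigs$cdr3), ]
  rownames(contigs) <- NULL

  # --- gene counts ---
  mm <- config$marker_means
  dense <- matrix(0L, nrow(mm), n_tot, dimnames = list(rownames(mm), barcode))
  for (g in rownames(mm)) {
    mu <- mm[g, group]
    dense[g, ] <- rnbinom(n_tot, size = config$nb_size, mu = mu)
  }
  # every MAIT cell has detectable CD8A transcript
  dense["CD8A", is_mait] <- pmax(1L, dense["CD8A", is_mait])
  genes <- Matrix::Matrix(dense, sparse = TRUE)

  # --- ADT counts ---
  am <- config$adt_means
  adt <- matrix(0L, n_tot, nrow(am), dimnames = list(barcode, rownames(am)))
  for (tg in rownames(am)) {
    mu <- am[tg, group]
    adt[, tg] <- as.integer(round(rlnorm(n_tot, meanlog = log(mu), sdlog = 0.4)))
  }

  # --- QC metrics (simulated directly; see vignette) ---
  n_genes_detected <- pmin(as.integer(round(rlnorm(n_tot, log(2200), 0.25))), 5500L)
  mito_fraction <- config$qc_mito_threshold * rbeta(n_tot, 2, 6)
  qc_outlier <- runif(n_tot) < config$qc_outlier_fraction
  if (any(qc_outlier)) {
    kind <- sample(c("genes", "mito"), sum(qc_outlier), replace = TRUE)
    idx <- which(qc_outlier)
    gi <- idx[kind == "genes"]; mi <- idx[kind == "mito"]
    n_genes_detected[gi] <- as.integer(round(runif(length(gi),
                                                   config$qc_gene_threshold + 1L,
                                                   config$qc_gene_threshold * 1.5)))
    mito_fraction[mi] <- runif(length(mi), config$qc_mito_threshold + 0.001, 0.20)
  }

  cells <- data.frame(barcode = barcode, n_genes_detected = n_genes_detected,
                      mito_fraction = mito_fraction, condition = condition,
                      stringsAsFactors = FALSE)
  getf <- function(lst, f) vapply(lst, function(x) if (is.null(x)) NA_character_ else x[[f]], "")
  truth <- data.frame(
    barcode = barcode, lineage = lineage, subset = subset, condition = condition,
    dual_alpha = dual, dual_category = dual_category,
    trav12 = ifelse(is_mait, trav12, NA),
    canonical_trbv = can_trbv,
    cdr3a1 = ifelse(is_mait, vapply(alpha1, function(x) if (is.null(x)) NA_character_ else as.character(x$cdr3), ""), NA),
    cdr3a2 = getf(alpha2, "cdr3"),
    a1_j = getf(alpha1, "j"), a2_j = getf(alpha2, "j"),
    gly_planted = ifelse(is_mait, truth_attr[, "gly"], NA),
    gggg_planted = ifelse(is_mait, truth_attr[, "gggg"], NA),
    nnnn_planted = ifelse(is_mait, truth_attr[, "nnnn"], NA),
    v3_planted = ifelse(is_mait, truth_attr[, "v3"], NA),
    qc_outlier = qc_outlier, stringsAsFactors = FALSE)

  structure(list(cells = cells, genes = genes, adt = adt,
                 contigs = contigs, truth = truth, config = config),
            class = "mait_bundle")
}

# noncanonical-style CDR3 with length outside the canonical band
sample_noncanonical_outside <- function(config, subset_i) {
  lens <- setdiff(seq.int(config$noncanonical_len_range[1], config$noncanonical_len_range[2]),
                  seq.int(config$canonical_len_range[1], config$canonical_len_range[2]))
  len <- if (length(lens) == 1L) lens else sample(lens, 1L)
  mp <- list(gly_motif_prob = config$gly_motif_prob,
             gggg_frac = config$gggg_frac_by_subset[[subset_i]],
             nnnn_prob = if (identical(subset_i, "CD4")) config$nnnn_motif_prob else 0,
             v_at_pos3_prob = config$v_at_pos3_prob)
  sample_cdr3_alpha(FALSE, c(len, len), mp)
}

#' @export
print.mait_bundle <- function(x, ...) {
  cat(sprintf("Synthetic MAIT CITE-Seq bundle: %d cells (%d MAIT), %d genes, %d ADT tags, %d contigs\n",
              nrow(x$cells), sum(x$truth$lineage == "MAIT"), nrow(x$genes),
              ncol(x$adt), nrow(x$contigs)))
  invisible(x)
}
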