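#' Configuration for the synthetic MAIT repertoire generator
#'
#' Builds and validates the parameter set controlling
#' [generate_repertoire()]. Defaults reproduce the repertoire structure of
#' published human blood MAIT CITE-Seq data: subset composition
#' (DN/CD8/CD4 = 50/35/15%), subset-conditional canonical-alpha (TRAV1-2)
#' probabilities, canonical TRAJ33/20/12 and TRBV6-1/6-4/20-1 pairing rates,
#' a 9% dual-alpha rate split 35/40/25 into both/one/neither TRAV1-2
#' categories, CDR3-alpha length and motif structure, and marker-gene/ADT
#' expression means per lineage and subset.
#'
#' @param n_cells number of MAIT cells to simulate (contaminants are added
#'   on top as `round(contaminant_fraction * n_cells)` extra cells).
#' @param seed integer RNG seed; fixed `(config, seed)` gives byte-identical
#'   output from [write_bundle()].
#' @param subset_probs named probability triple over `DN`, `CD8`, `CD4`.
#' @param canonical_alpha_prob_by_subset named probabilities (per subset)
#'   that a single-paired cell's alpha chain is TRAV1-2.
#' @param canonical_traj_prob_given_trav12 probability a TRAV1-2 alpha uses
#'   TRAJ33/20/12.
#' @param canonical_traj_prob_given_noncanonical same, for non-TRAV1-2 alphas.
#' @param canonical_trbv_prob_given_trav12 probability a TRAV1-2 cell pairs
#'   with TRBV6-1/TRBV6-4/TRBV20-1.
#' @param canonical_trbv_prob_given_noncanonical same, for TRAV1-2-negative
#'   cells.
#' @param dual_alpha_prob probability a cell carries two productive alpha
#'   contigs.
#' @param dual_alpha_category_probs named probability triple over
#'   `both_trav12`, `one_trav12`, `neither`.
#' @param gly_motif_prob probability a noncanonical CDR3-alpha carries a
#'   planted GGG/GGGG run in its central region (positions 6-9).
#' @param nnnn_motif_prob probability a CD4-subset noncanonical CDR3-alpha
#'   without a glycine motif carries a planted NNNN run.
#' @param gggg_frac_by_subset named fractions of glycine motifs planted as
#'   GGGG (rest GGG) per subset; CD4 cells favour tetraglycine.
#' @param v_at_pos3_prob probability of valine at CDR3-alpha position 3
#'   (1-based) in noncanonical sequences.
#' @param canonical_len_range,noncanonical_len_range inclusive integer CDR3
#'   length ranges.
#' @param marker_means gene-by-group matrix of negative-binomial means; see
#'   [default_marker_means()].
#' @param adt_means tag-by-group matrix of antibody-derived-tag (ADT) means;
#'   see [default_adt_means()].
#' @param nb_size negative-binomial size (dispersion) for gene counts.
#' @param contaminant_fraction fraction of non-MAIT cells (NK / gamma-delta
#'   T-like) added relative to `n_cells`.
#' @param qc_outlier_fraction fraction of cells planted to violate the QC
#'   thresholds in `qc_gene_threshold` / `qc_mito_threshold`.
#' @param qc_gene_threshold,qc_mito_threshold thresholds above which QC
#'   outliers are planted.
#' @param condition_probs named probabilities over experimental conditions
#'   (recorded as a per-cell covariate).
#' @param condition_canonical_shift named per-condition additive shift
#'   applied to the subset-conditional canonical-alpha probabilities
#'   (clipped to `[0, 1]`); all zero by default.
#'
#' @return an object of class `generator_config` (a validated list).
#' @seealso [study_preset()], [generate_repertoire()]
#' @export
generator_config <- function(n_cells = 1000L,
                             seed = 1L,
                             subset_probs = c(DN = 0.50, CD8 = 0.35, CD4 = 0.15),
                             canonical_alpha_prob_by_subset = c(DN = 0.65, CD8 = 0.85, CD4 = 0.10),
                             canonical_traj_prob_given_trav12 = 0.90,
                             canonical_traj_prob_given_noncanonical = 0.08,
                             canonical_trbv_prob_given_trav12 = 0.90,
                             canonical_trbv_prob_given_noncanonical = 0.30,
                             dual_alpha_prob = 0.09,
                             dual_alpha_category_probs = c(both_trav12 = 0.35, one_trav12 = 0.40, neither = 0.25),
                             gly_motif_prob = 0.25,
                             nnnn_motif_prob = 0.10,
                             gggg_frac_by_subset = c(DN = 0.4, CD8 = 0.2, CD4 = 0.7),
                             v_at_pos3_prob = 0.65,
                             canonical_len_range = c(12L, 14L),
                             noncanonical_len_range = c(7L, 23L),
                             marker_means = default_marker_means(),
                             adt_means = default_adt_means(),
                             nb_size = 2,
                             contaminant_fraction = 0.05,
                             qc_outlier_fraction = 0.02,
                             qc_gene_threshold = 6000L,
                             qc_mito_threshold = 0.05,
                             condition_probs = c(ex_vivo = 1),
                             condition_canonical_shift = NULL) {
  if (is.null(condition_canonical_shift)) {
    condition_canonical_shift <- stats::setNames(rep(0, length(condition_probs)),
                                                 names(condition_probs))
  }
  cfg <- structure(list(
    n_cells = as.integer(n_cells), seed = as.integer(seed),
    subset_probs = subset_probs,
    canonical_alpha_prob_by_subset = canonical_alpha_prob_by_subset,
    canonical_traj_prob_given_trav12 = canonical_traj_prob_given_trav12,
    canonical_traj_prob_given_noncanonical = canonical_traj_prob_given_noncanonical,
    canonical_trbv_prob_given_trav12 = canonical_trbv_prob_given_trav12,
    canonical_trbv_prob_given_noncanonical = canonical_trbv_prob_given_noncanonical,
    dual_alpha_prob = dual_alpha_prob,
    dual_alpha_category_probs = dual_alpha_category_probs,
    gly_motif_prob = gly_motif_prob,
    nnnn_motif_prob = nnnn_motif_prob,
    gggg_frac_by_subset = gggg_frac_by_subset,
    v_at_pos3_prob = v_at_pos3_prob,
    canonical_len_range = as.integer(canonical_len_range),
    noncanonical_len_range = as.integer(noncanonical_len_range),
    marker_means = marker_means,
    adt_means = adt_means,
    nb_size = nb_size,
    contaminant_fraction = contaminant_fraction,
    qc_outlier_fraction = qc_outlier_fraction,
    qc_gene_threshold = as.integer(qc_gene_threshold),
    qc_mito_threshold = qc_mito_threshold,
    condition_probs = condition_probs,
    condition_canonical_shift = condition_canonical_shift
  ), class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (length(cfg$n_cells) != 1L || is.na(cfg$n_cells) || cfg$n_cells < 0L)
    stop("n_cells must be a single nonnegative integer", call. = FALSE)
  check_probvec <- function(p, nm, expected = NULL) {
    if (!is.null(expected) && !setequal(names(p), expected))
      stop(sprintf("configuration error: %s must be named %s", nm,
                   paste(expected, collapse = "/")), call. = FALSE)
    if (any(p < 0 | p > 1))
      stop(sprintf("configuration error: %s has probabilities outside [0,1]", nm), call. = FALSE)
    if (abs(sum(p) - 1) > 1e-9)
      stop(sprintf("configuration error: %s does not sum to 1 (sum = %.12f)", nm, sum(p)),
           call. = FALSE)
  }
  check_probvec(cfg$subset_probs, "subset_probs", c("DN", "CD8", "CD4"))
  check_probvec(cfg$dual_alpha_category_probs, "dual_alpha_category_probs",
                c("both_trav12", "one_trav12", "neither"))
  check_probvec(cfg$condition_probs, "condition_probs")
  scalars <- c("canonical_traj_prob_given_trav12", "canonical_traj_prob_given_noncanonical",
               "canonical_trbv_prob_given_trav12", "canonical_trbv_prob_given_noncanonical",
               "dual_alpha_prob", "gly_motif_prob", "nnnn_motif_prob", "v_at_pos3_prob",
               "contaminant_fraction", "qc_outlier_fraction")
  for (s in scalars) {
    v <- cfg[[s]]
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("configuration error: %s must be a single probability in [0,1]", s),
           call. = FALSE)
  }
  p <- cfg$canonical_alpha_prob_by_subset
  if (!setequal(names(p), c("DN", "CD8", "CD4")) || any(p < 0 | p > 1))
    stop("configuration error: canonical_alpha_prob_by_subset must give one probability per subset DN/CD8/CD4",
         call. = FALSE)
  for (rng in list(cfg$canonical_len_range, cfg$noncanonical_len_range)) {
    if (length(rng) != 2L || rng[1] > rng[2] || rng[1] < 5L)
      stop("configuration error: CDR3 length ranges must be nonempty with minimum >= 5",
           call. = FALSE)
  }
  if (cfg$canonical_len_range[1] < cfg$noncanonical_len_range[1] ||
      cfg$canonical_len_range[2] > cfg$noncanonical_len_range[2])
    stop("configuration error: canonical_len_range must lie within the plausible noncanonical lengths",
         call. = FALSE)
  invisible(cfg)
}

#' The study-condition preset of the synthetic generator
#'
#' Returns a [generator_config()] whose parameters encode the repertoire
#' proportions reported for human blood MAIT cells: subset composition
#' 50% DN / 35% CD8 / 15% CD4; TRAV1-2-negative fractions of 90% (CD4),
#' 15% (CD8) and 35% (DN); 90% canonical TRAJ usage among TRAV1-2-positive
#' and 8% among TRAV1-2-negative cells; 90% canonical TRBV pairing among
#' TRAV1-2-positive cells; a 9% dual-alpha rate split 35/40/25; 25%
#' glycine-motif prevalence and 65% valine at position 3 in noncanonical
#' CDR3-alpha; canonical lengths 12-14 and noncanonical lengths 7-23.
#'
#' @param n_cells,seed passed through to [generator_config()].
#' @param ... further overrides passed to [generator_config()].
#' @return a `generator_config`.
#' @export
study_preset <- function(n_cells = 10000L, seed = 42L, ...) {
  generator_config(n_cells = n_cells, seed = seed, ...)
}

# ---- default expression structure ------------------------------------------

#' Default marker-gene negative-binomial means per lineage/subset
#'
#' A compact (~40 gene) panel covering MAIT identity markers (KLRB1, ZBTB16,
#' IL18R1, CXCR6, SLC4A10), CD3 complex, co-receptor transcripts (CD4, CD8A,
#' CD8B; CD8A is detectable in all MAIT cells), cytotoxic and regulatory
#' programs, activation genes, housekeeping genes and mitochondrial
#' placeholders MT-1..MT-5. Columns are the simulated groups: MAIT subsets
#' DN/CD8/CD4 and contaminant lineages NK and gdT.
#'
#' @return numeric matrix, genes x groups.
#' @export
default_marker_means <- function() {
  g <- function(DN, CD8, CD4, NK, gdT) c(DN = DN, CD8 = CD8, CD4 = CD4, NK = NK, gdT = gdT)
  m <- rbind(
    KLRB1   = g(10,  10,  10,  3,    0.3),
    ZBTB16  = g(5,   5,   5,   0.1,  0.3),
    IL18R1  = g(6,   6,   6,   0.5,  0.5),
    CXCR6   = g(3,   3,   3,   0.1,  0.1),
    SLC4A10 = g(6,   6,   6,   0.05, 0.05),
    CD3D    = g(8,   8,   8,   0.05, 8),
    CD3E    = g(20,  20,  20,  0.05, 20),
    CD3G    = g(6,   6,   6,   0.05, 6),
    CD4     = g(0.1, 0.1, 20,  0.05, 0.1),
    CD8A    = g(12,  12,  12,  1,    1),
    CD8B    = g(0.05, 20, 0.05, 0.05, 0.3),
    NKG7    = g(4,   8,   1,   10,   5),
    GZMA    = g(3,   6,   1,   6,    4),
    GZMK    = g(2,   6,   1,   2,    3),
    GZMB    = g(1,   3,   0.5, 8,    2),
    PRF1    = g(1,   4,   0.5, 8,    2),
    GNLY    = g(1,   4,   0.5, 10,   2),
    KLRG1   = g(1,   3,   0.3, 4,    1),
    EOMES   = g(0.5, 2,   0.2, 3,    0.5),
    TNF     = g(1,   2,   1,   0.5,  1),
    CTLA4   = g(0.3, 0.3, 4,   0.05, 0.2),
    TNFRSF4 = g(0.2, 0.2, 3,   0.05, 0.2),
    IL2RA   = g(0.3, 0.3, 4,   0.05, 0.2),
    FOXP3   = g(0.1, 0.1, 2,   0.05, 0.1),
    IL32    = g(3,   3,   8,   1,    3),
    IFNG    = g(1,   1,   1,   1,    1),
    SELL    = g(1,   0.5, 2,   0.5,  1),
    ICOS    = g(0.5, 0.5, 2,   0.1,  0.5),
    MAL     = g(0.3, 0.3, 1,   0.05, 0.3),
    JUN     = g(6,   2,   2,   2,    2),
    FOS     = g(6,   2,   2,   2,    2),
    DUSP1   = g(4,   1,   1,   1,    1),
    XCL1    = g(3,   0.2, 0.2, 1,    0.3),
    XCL2    = g(2,   0.2, 0.2, 1,    0.3),
    IFITM3  = g(3,   1,   1,   1,    1),
    ACTB    = g(30,  30,  30,  30,   30),
    B2M     = g(25,  25,  25,  25,   25),
    GAPDH   = g(20,  20,  20,  20,   20),
    `MT-1`  = g(2, 2, 2, 2, 2),
    `MT-2`  = g(2, 2, 2, 2, 2),
    `MT-3`  = g(2, 2, 2, 2, 2),
    `MT-4`  = g(1, 1, 1, 1, 1),
    `MT-5`  = g(1, 1, 1, 1, 1)
  )
  m
}

#' Default antibody-derived-tag (ADT) means per lineage/subset
#'
#' Log-normal means for the three surface tags used by the subset rule.
#' CD4/CD8 tags separate their subsets by ~50-fold over background; CD3 is
#' uniformly high on T lineages.
#'
#' @return numeric matrix, tags x groups.
#' @export
default_adt_means <- function() {
  g <- function(DN, CD8, CD4, NK, gdT) c(DN = DN, CD8 = CD8, CD4 = CD4, NK = NK, gdT = gdT)
  rbind(
    `ADT-CD3` = g(100, 100, 100, 5, 100),
    `ADT-CD4` = g(3, 3, 150, 3, 3),
    `ADT-CD8` = g(3, 150, 3, 3, 3)
  )
}

# canonical and noncanonical V/J vocabularies ---------------------------------

CANONICAL_TRAV <- "TRAV1-2"
CANONICAL_TRAJ <- c(TRAJ33 = 0.5, TRAJ12 = 0.3, TRAJ20 = 0.2)
CANONICAL_TRBV <- c(`TRBV6-4` = 0.4, `TRBV6-1` = 0.3, `TRBV20-1` = 0.3)

# noncanonical alpha V genes reported across MAIT subsets
NONCANONICAL_TRAV <- c(
  "TRAV21", "TRAV8-1", "TRAV8-2", "TRAV8-3", "TRAV12-2", "TRAV12-3",
  "TRAV35", "TRAV19", "TRAV18-1", "TRAV16", "TRAV25", "TRAV26-1",
  "TRAV34", "TRAV36", "TRAV40", "TRAV29", "TRAV41", "TRAV13-1",
  "TRAV14", "TRAV20", "TRAV17", "TRAV5", "TRAV1-1", "TRAV39",
  "TRAV9-1", "TRAV10", "TRAV4"
)

NONCANONICAL_TRAJ <- paste0("TRAJ", c(3, 4, 5, 6, 7, 8, 9, 10, 11, 13, 21, 22,
                                      23, 24, 26, 27, 28, 29, 30, 32, 34, 35,
                                      36, 37, 38, 39, 40, 42, 43, 44, 45, 46,
                                      48, 49, 52, 53, 54, 56, 57, 58))

NONCANONICAL_TRBV <- c("TRBV25-1", "TRBV24-1", "TRBV28", "TRBV11-1",
                       "TRBV19", "TRBV5-1", "TRBV7-9", "TRBV4-1", "TRBV27")

TRBJ_GENES <- c(paste0("TRBJ1-", 1:6), paste0("TRBJ2-", 1:7))

# J-anchored canonical CDR3-alpha endings; all carry Tyr 5 residues from the
# C-terminus (the TRAJ33-encoded Tyr-95 convention used across the package)
CANONICAL_J_SUFFIX <- c(TRAJ33 = "YQLIW", TRAJ12 = "YKLIF", TRAJ20 = "YKLSF")
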