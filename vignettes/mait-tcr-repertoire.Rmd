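---
title: "Methods: single-cell MAIT TCR repertoire analysis with maitcr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell MAIT TCR repertoire analysis with maitcr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maitcr)
```

## Scope and model of the data

Mucosal-associated invariant T (MAIT) cells are innate-like T lymphocytes
restricted by MR1. Most human MAIT cells carry a semi-invariant receptor —
a TRAV1-2 alpha chain joined to TRAJ33, TRAJ20 or TRAJ12 and typically
paired with TRBV6-family or TRBV20-1 beta chains — but a substantial
noncanonical TRAV1-2-negative compartment exists, enriched among
CD4-positive MAIT cells. `maitcr` implements the analysis chain needed to
characterize that structure from single-cell CITE-Seq data with paired VDJ
sequencing:

1. **QC filtering** of cells on detected-gene and mitochondrial-content
   thresholds;
2. **lineage gating** of MAIT cells from marker transcripts;
3. **subset assignment** (CD4 / CD8 / DN / DP) by a dual-modality rule that
   requires agreement of transcript and surface-antibody (ADT) evidence;
4. **chain pairing** per cell, including detection of dual TCR-alpha
   cells and exclusion of multiplets;
5. **canonical classification** of each receptor;
6. **CDR3-alpha sequence analysis** (lengths, positional frequencies,
   motifs, conserved anchors); and
7. **fuzzy epitope matching** of CDR3 sequences against a local
   McPAS-style reference with in-silico single/double indels.

A seeded synthetic-data generator stands in for real sequencing output, so
every stage is testable end to end without external downloads.

## The synthetic repertoire generator

`generator_config()` describes one simulated experiment;
`study_preset()` is the package's reference parameterization and encodes
the repertoire proportions reported for human blood MAIT cells profiled
ex vivo and after in-vitro culture:

| parameter | default | meaning |
|---|---|---|
| `subset_probs` | DN 0.50, CD8 0.35, CD4 0.15 | subset composition |
| `canonical_alpha_prob_by_subset` | DN 0.65, CD8 0.85, CD4 0.10 | P(alpha = TRAV1-2) per subset |
| `canonical_traj_prob_given_trav12` | 0.90 | P(TRAJ33/20/12) for TRAV1-2 chains |
| `canonical_traj_prob_given_noncanonical` | 0.08 | same, for other alpha chains |
| `canonical_trbv_prob_given_trav12` | 0.90 | P(TRBV6-1/6-4/20-1) for TRAV1-2 cells |
| `canonical_trbv_prob_given_noncanonical` | 0.30 | same, for TRAV1-2-negative cells |
| `dual_alpha_prob` | 0.09 | P(two productive alpha contigs) |
| `dual_alpha_category_probs` | 0.35 / 0.40 / 0.25 | both / one / neither TRAV1-2 |
| `gly_motif_prob` | 0.25 | central GGG/GGGG in noncanonical CDR3-alpha |
| `v_at_pos3_prob` | 0.65 | valine at CDR3-alpha position 3 |
| `canonical_len_range` | 12–14 aa | canonical CDR3-alpha lengths |
| `noncanonical_len_range` | 7–23 aa | noncanonical CDR3-alpha lengths |

The published beta-chain usage of TRAV1-2-negative cells is described only
qualitatively ("more diverse"); the preset fixes
`canonical_trbv_prob_given_noncanonical = 0.30` as a realistic middle
ground, a choice made once when the generator was designed.

Design choices that the underlying reports do not constrain:

* **Count model.** Gene counts are negative binomial with size 2 per gene
  and group — typical droplet scRNA-seq overdispersion — over a compact
  ~40-gene panel covering the markers the analysis actually consumes
  (lineage markers, CD3 complex, co-receptors, cytotoxic/regulatory/
  activation programs, housekeeping genes, mitochondrial placeholders).
  A full transcriptome adds nothing to the pipeline's logic. Marker means
  were set so that lineage-defining transcripts (KLRB1, SLC4A10, IL18R1,
  ZBTB16, CD3E) are strongly and consistently detected in MAIT cells, as
  they are in real data, giving a clearly bimodal lineage score against
  contaminants. CD8A is clamped to at least one count in every MAIT cell,
  mirroring the observation that CD8A transcript is universally detectable
  regardless of surface phenotype — which is exactly why the subset rule
  reads CD8B instead.
* **ADT counts** are rounded log-normals (sdlog 0.4) with ~50-fold
  separation between positive and negative populations for the CD4/CD8
  tags.
* **QC metrics are simulated directly.** With a 40-gene panel the
  "detected genes per cell" metric cannot reach the thousands that the QC
  thresholds refer to, so the generator draws the per-cell detected-gene
  count (log-normal around 2,200) and mitochondrial fraction (scaled Beta,
  always below the threshold for non-outliers) as explicit per-cell
  metrics, and plants a configurable fraction (default 2%) of QC outliers
  above the thresholds. When the package computes metrics from a real
  full-transcriptome matrix, `compute_cell_metrics()` derives both
  quantities from the counts themselves.
* **Dual-alpha cells** draw their category (both / one / neither TRAV1-2)
  independently of subset; the underlying reports give subset-specific
  tendencies only qualitatively.
* **Contaminants** (default 5% of cells, half NK-like and half
  gamma-delta-T-like) carry no TRA/TRB contigs, high or low CD3 as
  appropriate, and weak MAIT-marker expression. They exercise the lineage
  gate; they are not a realistic model of every non-MAIT cell type in
  blood.
* **CDR3-alpha construction.** All sequences start with the conserved
  Cys-Ala anchor. Canonical sequences end in a TRAJ-specific 5-mer
  (TRAJ33 "YQLIW", TRAJ12 "YKLIF", TRAJ20 "YKLSF") whose tyrosine sits 5
  residues from the C-terminus. Noncanonical sequences place valine at
  position 3 with exactly `v_at_pos3_prob` (the alternative residue is
  drawn from the 19 other amino acids, so the planted rate is exact), end
  in a J-like residue (F/W/L/I/T), and carry a planted GGG/GGGG run
  overlapping positions 6–9 with probability `gly_motif_prob`
  (tetraglycine fraction higher in CD4 cells; NNNN runs planted only in
  CD4 noncanonical sequences, default 10%). On a TRAV1-2 chain with a
  *noncanonical* J the length is drawn outside 12–14, which ties the
  length-in-band fraction among TRAV1-2-positive cells to the canonical-J
  rate — both are J-encoded properties of the same junction.
* **Conditions** (ex vivo, IL-2, IL-2 + Mtb) are an optional covariate;
  by default all cells are "ex_vivo" and the per-condition shift of
  canonical-alpha probabilities is zero, because the magnitude of the
  culture effect is not quantified in the source reports.

What passing tests on these data do and do not show: recovery tests prove
the pipeline's bookkeeping (gating, pairing, classification, counting) is
correct under realistic sampling noise; they cannot prove robustness to
features the generator omits — ambient RNA, doublets, batch effects,
clonal expansion structure, or isotype-control ADT drift.

## Annotation

**QC.** Two presets: 6,000 genes / 5% mitochondrial ("discovery") and 3,000 /
8% ("validation"). Inequalities are strict — cells *exceeding* a threshold are
removed — and "gene counts" is read as detected genes per cell (standard
nFeature semantics), the reading consistent with typical cutoffs at these
magnitudes.

**Lineage.** The MAIT score is the mean log1p CP10K expression of KLRB1,
ZBTB16, IL18R1 and SLC4A10; a cell is MAIT iff the score clears a
threshold *and* CD3E is detected (the CD3 gate removes NK-like cells
whatever their score). The default data-driven threshold is a **valley
split**: the two modes are located by deterministic 2-means and the cut
placed at the kernel-density minimum between them. Otsu's between-class
criterion is available as an option and as the fallback when no
bimodality is detected, but with a ~95:5 MAIT:contaminant mixture it
drifts into the majority mode and needlessly discards real MAIT cells;
the valley split keeps recall above 0.95 at the preset's separation (the
recovery suite asserts this bound on every run).

**Subsets.** CD8-positive means CD8B transcript detected (>= 1 count) AND
anti-CD8 ADT gated positive; CD4 analogously; DP both; DN neither. ADT
gating is per tag: counts are CLR-transformed within each cell (invariant
to per-cell scaling), then thresholded at the midpoint of the two 2-means
centers, falling back to a 90th-percentile gate with a warning if the two
modes are not separated. The original cluster-level gating is deliberately
not reproduced — clustering and embeddings are out of scope here because
the clusters were only a vehicle for the same CD8B + ADT evidence this
per-cell rule consumes directly.

**Differential expression** between groups is an unpaired Wilcoxon
rank-sum test per gene (normal approximation, midrank ties) with
Benjamini–Hochberg adjustment, and log fold change defined as the
difference of group means on the normalized scale.

## Repertoire and CDR3 conventions

* Pairing considers productive, high-confidence TRA/TRB contigs only;
  exact duplicates collapse to the highest-UMI record. 1 TRA + 1 TRB is a
  single pair; 2 TRA + 1 TRB a dual-alpha cell; anything beyond that a
  multiplet, excluded from all repertoire statistics.
* Cells, not chains, are the counting unit. A dual-alpha cell with one
  TRAV1-2 chain is TRAV1-2-positive, and its TRAV1-2 chain is the primary
  alpha used in usage tables. Per-subset percentages use single-paired
  cells as denominators; dual-alpha cells are tabulated separately.
* Diversity: Shannon entropy uses natural log, reported alongside
  Gini-Simpson, richness and Pielou evenness, since the published
  diversity axis is unlabeled; conclusions in this package rest on
  proportions, not on any one index.
* **"Position 95" tyrosine.** IMGT unique numbering is not recoverable
  from a bare CDR3 string, so the conserved tyrosine is operationalized as
  the 5th residue from the C-terminus — where the TRAJ33 germline end
  (...NYQLIW) places it for canonical 12–14-mer junctions. `tyr95_test()`
  documents this convention and is invariant to any prefix edit that
  leaves the last five residues alone.
* **Terminal residues.** The conserved L/I/T/F set is J-segment-encoded
  and therefore sits at the C-terminal end of the junction;
  `terminal_conservation()` reports C-terminal composition accordingly
  (the residues' description as "N-terminal" in the source text is a
  mislabel the package does not reproduce).
* Positions are 1-based in all reports; motif hits are enumerated
  including overlaps, so a GGGG run implies two GGG hits.

## Epitope matching

The published workflow queried a web interface whose similarity metric is
unspecified; this package defines a reproducible one: 100 × (matching
positions in an optimal free-gap global alignment — equivalently the
longest-common-subsequence length) / max(query length, reference length).
It reduces to percent identity for equal-length gapless matches, is
symmetric, and is 100 exactly for identical strings. Published similarity
percentages are therefore not expected to be reproduced numerically, and
they are not used as recovery targets.

In-silico perturbation applies at most two amino-acid insertions or at
most two deletions to the query only — never mixed in one variant,
mirroring the "+1, +2 / −1, −2" design. Insertions are internal (the Cys
anchor and the terminal residue are preserved); deletions are
unrestricted. Per reference, insertion residues are enumerated from the
residues occurring in that reference — inserting any other residue cannot
add an aligned match, so the optimum over the full 20-letter alphabet is
unchanged (the test suite proves this against full-alphabet brute force).
Ties are broken by smaller budget, then epitope, then reference sequence,
making results order-independent. The packaged
`mcpas_synthetic_reference.csv` is a 12-row synthetic stand-in fixture
(canonical MAIT-like junctions plus viral/autoimmune-style entries), not
an excerpt of any database.

## Problem sizes and numerics

Recovery runs use 10,000 simulated MAIT cells (seed 42 by default), where
3 binomial standard errors for the subgroup proportions fall within ±2
percentage points; the full run takes well under a minute. Unit and
property suites use 100–1,000-element problems. Probability vectors must
sum to 1 within 1e-9. Degenerate inputs are defined explicitly: empty QC
input yields two empty tables; an all-zero count vector is a diversity
error; a CDR3 shorter than 6 residues has no Tyr-95 slot (FALSE with a
warning); barcodes with no qualifying contig get pairing status `none`.

## Known limitations

* Subset gating is per cell; the optional cluster-majority smoothing used
  in cluster-level workflows is not implemented.
* The generator plants motifs independently per cell; it does not model
  clonal expansion, so clonotype-frequency-weighted statistics are not
  meaningfully testable on these data.
* Gene-name normalization covers allele suffixes and TRAJ hyphen variants;
  it is not a full IMGT ontology mapper.
* The epitope matcher scores similarity only; it does not model MHC/MR1
  restriction or predict specificity.
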