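# maitcr

Single-cell TCR repertoire analysis for MAIT cells profiled by CITE-Seq.

Mucosal-associated invariant T (MAIT) cells are MR1-restricted innate-like
T lymphocytes. Most carry a semi-invariant receptor — a TRAV1-2 α chain
joined to TRAJ33/20/12, usually paired with TRBV6-1, TRBV6-4 or TRBV20-1 β
chains — but a diverse TRAV1-2⁻ compartment exists and is strongly
enriched among CD4⁺ MAIT cells. Characterizing that compartment from
single-cell data takes a chain of bookkeeping steps that are easy to get
subtly wrong: QC, lineage gating, dual-modality (transcript + antibody
barcode) CD4/CD8/DN subset calls, α/β pairing with dual-α detection,
canonical-vs-noncanonical classification, and CDR3α sequence analysis.
`maitcr` packages that chain as tested R functions for immunologists and
computational biologists working with 10x-style VDJ + expression + ADT
output (or AIRR rearrangement tables).

The quantities at the core are per-group proportions and sequence
statistics of the paired repertoire: for a group of cells \(g\),
\(\hat p_g = n_{g,\text{feature}} / n_g\) (e.g. fraction of single-paired
CD4⁺ cells with a TRAV1-2⁻ α chain), Shannon entropy
\(H = -\sum_i p_i \ln p_i\) over clonotype or gene usage, positional
residue frequencies of CDR3α (sequence-logo data), and a reproducible
CDR3 percent similarity
\(100 \cdot \mathrm{LCS}(q, r) / \max(|q|, |r|)\) — the match count of an
optimal free-gap global alignment — with in-silico +1/+2 insertions or
−1/−2 deletions of the query for fuzzy epitope matching.

Because the real deposited reads cannot be reprocessed at desk scale, the
package ships a seeded synthetic generator whose defaults encode the
published repertoire structure (50/35/15% DN/CD8/CD4; 90/15/35% TRAV1-2⁻
in CD4/CD8/DN; 9% dual-α split 35/40/25; 90% canonical TRAJ and TRBV among
TRAV1-2⁺ cells; 8% canonical TRAJ among TRAV1-2⁻; CDR3α lengths 12–14 vs
7–23; 25% central glycine motifs; 65% valine at position 3). Every
pipeline stage is validated by recovering those planted parameters.

## Worked example

```r
library(maitcr)

res <- run_pipeline(study_preset(n_cells = 2000L, seed = 42L))
res
#> MAIT repertoire pipeline report (seed 42)
#>   subset_DN_pct                        51.6%  (1005 / 1949)
#>   subset_CD8_pct                       33.6%  (655 / 1949)
#>   subset_CD4_pct                       14.8%  (289 / 1949)
#>   subset_DP_pct                         0.0%  (0 / 1949)
#>   trav12_neg_CD4_pct                   89.5%  (238 / 266)
#>   trav12_neg_CD8_pct                   12.4%  (73 / 587)
#>   trav12_neg_DN_pct                    34.7%  (318 / 917)
#>   dual_alpha_pct                        8.8%  (171 / 1941)
#>   dual_both_trav12_pct                 29.2%  (50 / 171)
#>   dual_one_trav12_pct                  44.4%  (76 / 171)
#>   dual_neither_pct                     26.3%  (45 / 171)
#>   canonical_traj_trav12pos_pct         90.7%  (1035 / 1141)
#>   canonical_traj_trav12neg_pct          9.2%  (58 / 629)
#>   canonical_trbv_trav12pos_pct         88.1%  (1005 / 1141)
#>   cdr3a_len_12_14_trav12pos_pct        90.7%  (1035 / 1141)
#>   gly_motif_trav12neg_pct              25.8%  (162 / 629)
#>   v_at_pos3_trav12neg_pct              63.0%  (396 / 629)
```

Reading the report: 2,000 MAIT cells were simulated, 1,949 survived QC
and lineage gating and were assigned subsets by the dual-modality rule;
every percentage is `numerator / denominator` of auditable counts (e.g.
89.5% of the 266 single-paired CD4⁺ cells carry a non-TRAV1-2 α chain).
At n = 2,000 the recovered values scatter a little around the planted
parameters; at n = 10,000 they land within a couple of percentage points.

Individual stages are plain functions — for instance, fuzzy epitope
matching with a single in-silico edit:

```r
ref <- read_reference(system.file("extdata", "mcpas_synthetic_reference.csv",
                                  package = "maitcr"))
perturbed_match("CAVRDTNYQLIW", ref, max_insertions = 1L, max_deletions = 1L)
#> query CAVRDTNYQLIW -> CAVRDSNYQLIW (5-OP-RU, Mycobacterium tuberculosis):
#>   92.3% similarity, 1 indel(s) [ins@6:S]

diversity_index(c(2, 1, 1), "shannon")
#> [1] 1.039721
```

Note `mcpas_synthetic_reference.csv` is a small synthetic fixture, not an
excerpt of any public database.

## Layout

- `R/` — generator, annotation, repertoire, CDR3 and epitope modules plus
  the `run_pipeline()` orchestrator
- `src/` — Rcpp kernel for the alignment match count
- `tests/testthat/` — unit, property and recovery suites with independent
  brute-force oracles
- `vignettes/mait-tcr-repertoire.Rmd` — the methods vignette: model
  assumptions, parameter meanings, numerical conventions, limitations
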