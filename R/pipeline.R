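# End-to-end orchestration: simulate -> annotate -> repertoire -> cdr3
# (-> match), with a consolidated report whose every fraction is the ratio
# of two auditable counts.

#' Run the full MAIT repertoire pipeline on synthetic data
#'
#' Generates a synthetic bundle (or accepts one), applies QC, gates the
#' MAIT lineage, assigns CD4/CD8/DN subsets by the dual-modality rule,
#' pairs and classifies TCR chains, analyzes CDR3-alpha sequences, and
#' optionally matches noncanonical CDR3-alpha sequences against an epitope
#' reference table. Deterministic given the generator seed.
#'
#' @param config a [generator_config()]; ignored when `bundle` is given.
#' @param bundle an existing `mait_bundle`; generated from `config` when
#'   `NULL`.
#' @param qc_preset QC preset name passed to [qc_thresholds()].
#' @param rule a [subset_rule()].
#' @param defn a [canonical_definition()].
#' @param steps pipeline stages to execute after simulation; a subset of
#'   `c("annotate", "repertoire", "cdr3", "match")`. Later stages require
#'   earlier ones.
#' @param reference epitope reference table for the match stage (default:
#'   the packaged synthetic McPAS-style fixture).
#' @param max_match_queries cap on unique noncanonical CDR3-alpha queries
#'   sent to the match stage.
#' @param out_dir optional directory; when given, intermediate tables are
#'   written as CSV so every reported number is traceable.
#' @return list of class `mait_report`: `report` (data.frame metric /
#'   value / numerator / denominator), `tables` (intermediate results),
#'   `seed`.
#' @export
run_pipeline <- function(config = study_preset(n_cells = 2000L),
                         bundle = NULL,
                         qc_preset = "discovery",
                         rule = subset_rule(),
                         defn = canonical_definition(),
                         steps = c("annotate", "repertoire", "cdr3"),
                         reference = NULL,
                         max_match_queries = 25L,
                         out_dir = NULL) {
  stopifnot(all(steps %in% c("annotate", "repertoire", "cdr3", "match")))
  if (is.null(bundle)) bundle <- generate_repertoire(config)
  seed <- bundle$config$seed
  tables <- list()
  report <- list()
  add_metric <- function(metric, num, den) {
    report[[length(report) + 1L]] <<- data.frame(
      metric = metric, value = if (den > 0) 100 * num / den else NA_real_,
      numerator = num, denominator = den, stringsAsFactors = FALSE)
  }
  fail <- function(stage, msg) stop(sprintf("pipeline stage '%s' failed: %s", stage, msg),
                                    call. = FALSE)

  ## annotate -----------------------------------------------------------------
  if (!"annotate" %in% steps) {
    return(structure(list(report = data.frame(), tables = list(bundle = bundle),
                          seed = seed), class = "mait_report"))
  }
  qc <- apply_qc(bundle$cells, qc_thresholds(qc_preset))
  kept_bc <- qc$kept$barcode
  norm <- normalize_cp10k(bundle$genes[, kept_bc, drop = FALSE])
  lin <- score_mait_lineage(norm)
  mait_bc <- lin$barcode[lin$lineage == "MAIT"]
  if (length(mait_bc) < 2L) fail("annotate", "fewer than 2 MAIT cells after gating")
  subset <- assign_subset(bundle$genes[, mait_bc, drop = FALSE],
                          bundle$adt[mait_bc, , drop = FALSE], rule)
  ann <- data.frame(barcode = mait_bc, subset = unname(subset),
                    condition = bundle$cells$condition[match(mait_bc, bundle$cells$barcode)],
                    stringsAsFactors = FALSE)
  tables$qc <- data.frame(kept = nrow(qc$kept), removed = nrow(qc$removed))
  tables$annotation <- ann
  for (s in c("DN", "CD8", "CD4", "DP"))
    add_metric(paste0("subset_", s, "_pct"), sum(ann$subset == s), nrow(ann))

  ## repertoire ---------------------------------------------------------------
  if ("repertoire" %in% steps) {
    contigs <- bundle$contigs[bundle$contigs$barcode %in% mait_bc, , drop = FALSE]
    if (nrow(contigs) == 0L) fail("repertoire", "no contigs for annotated MAIT cells")
    calls <- classify_tcr(pair_chains(contigs), defn)
    calls$subset <- ann$subset[match(calls$barcode, ann$barcode)]
    calls$condition <- ann$condition[match(calls$barcode, ann$barcode)]
    tables$clonotypes <- calls
    singles <- calls[calls$pairing_status == "paired_single", , drop = FALSE]
    duals <- calls[calls$pairing_status == "dual_alpha", , drop = FALSE]
    for (s in c("CD4", "CD8", "DN")) {
      grp <- singles[singles$subset == s, , drop = FALSE]
      add_metric(paste0("trav12_neg_", s, "_pct"),
                 sum(grp$trav12_status == "negative"), nrow(grp))
    }
    add_metric("dual_alpha_pct", nrow(duals), nrow(duals) + nrow(singles))
    for (cat in c("both_trav12", "one_trav12", "neither"))
      add_metric(paste0("dual_", cat, "_pct"), sum(duals$dual_category == cat), nrow(duals))
    pos <- singles[singles$trav12_status == "positive", , drop = FALSE]
    neg <- singles[singles$trav12_status == "negative", , drop = FALSE]
    add_metric("canonical_traj_trav12pos_pct", sum(pos$canonical_traj), nrow(pos))
    add_metric("canonical_traj_trav12neg_pct", sum(neg$canonical_traj), nrow(neg))
    add_metric("canonical_trbv_trav12pos_pct", sum(pos$canonical_trbv), nrow(pos))
    tables$usage <- usage_table(calls, group_by = c("subset", "trav12_status"))
    div_counts <- table(paste(singles$a1_v, singles$a1_j, singles$a1_cdr3))
    tables$diversity <- data.frame(
      metric = c("shannon", "simpson", "richness", "pielou"),
      value = c(diversity_index(div_counts, "shannon"),
                diversity_index(div_counts, "simpson"),
                diversity_index(div_counts, "richness"),
                if (length(div_counts) >= 2) diversity_index(div_counts, "pielou") else NA_real_),
      stringsAsFactors = FALSE)
  }

  ## cdr3 ---------------------------------------------------------------------
  if ("cdr3" %in% steps) {
    if (!"repertoire" %in% steps) fail("cdr3", "requires the repertoire stage")
    pos <- singles[singles$trav12_status == "positive", , drop = FALSE]
    neg <- singles[singles$trav12_status == "negative", , drop = FALSE]
    add_metric("cdr3a_len_12_14_trav12pos_pct",
               sum(nchar(pos$a1_cdr3) >= 12 & nchar(pos$a1_cdr3) <= 14), nrow(pos))
    gly_hits <- detect_motif(neg$a1_cdr3,
                             motif_spec(patterns = c("GGG", "GGGG"),
                                        require_in_window = FALSE))
    add_metric("gly_motif_trav12neg_pct", length(unique(gly_hits$seq_index)), nrow(neg))
    pm <- positional_matrix(neg$a1_cdr3, "left")
    add_metric("v_at_pos3_trav12neg_pct",
               sum(substr(neg$a1_cdr3, 3, 3) == "V"), nrow(neg))
    tables$length_distribution <- length_distribution(
      singles$a1_cdr3, singles$trav12_status)
    tables$positional_trav12neg <- pm
    tables$terminal <- terminal_conservation(singles$a1_cdr3)
  }

  ## match --------------------------------------------------------------------
  if ("match" %in% steps) {
    if (!"cdr3" %in% steps) fail("match", "requires the cdr3 stage")
    if (is.null(reference))
      reference <- read_reference(system.file("extdata",
                                              "mcpas_synthetic_reference.csv",
                                              package = "maitcr"))
    queries <- utils::head(unique(neg$a1_cdr3), max_match_queries)
    tables$epitope_hits <- match_epitopes(queries, reference,
                                          max_insertions = 1L, max_deletions = 1L)
    add_metric("epitope_match_ge90_pct",
               sum(tables$epitope_hits$similarity_pct >= 90), nrow(tables$epitope_hits))
  }

  report <- do.call(rbind, report)
  res <- structure(list(report = report, tables = tables, seed = seed),
                   class = "mait_report")
  if (!is.null(out_dir)) write_report(res, out_dir)
  res
}

write_report <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(res$report, file.path(out_dir, "report.csv"), row.names = FALSE)
  for (nm in names(res$tables)) {
    x <- res$tables[[nm]]
    if (is.data.frame(x))
      write.csv(x, file.path(out_dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  writeLines(c(sprintf("seed: %d", res$seed),
               sprintf("generated: %s", format(Sys.time(), "%Y-%m-%d"))),
             file.path(out_dir, "provenance.txt"))
  invisible(out_dir)
}

#' @export
print.mait_report <- function(x, ...) {
  cat("MAIT repertoire pipeline report (seed ", x$seed, ")\n", sep = "")
  df <- x$report
  if (nrow(df)) {
    for (i in seq_len(nrow(df)))
      cat(sprintf("  %-34s %6.1f%%  (%d / %d)\n", df$metric[i], df$value[i],
                  df$numerator[i], df$denominator[i]))
  }
  invisible(x)
}
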