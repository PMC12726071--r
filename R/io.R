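# File input/output: bundle writing, 10x/AIRR contig parsing, matrix reading.

#' Write a synthetic bundle to disk in standard formats
#'
#' Emits the gene-count matrix as Matrix Market (`matrix.mtx` +
#' `features.tsv` + `barcodes.tsv`), ADT counts as CSV (one row per
#' barcode), per-cell QC metrics as CSV, contigs in both the 10x
#' `filtered_contig_annotations.csv` dialect and AIRR rearrangement TSV, and
#' the ground-truth table as CSV. Re-reading the files reproduces the
#' records exactly.
#'
#' @param bundle a `mait_bundle` from [generate_repertoire()].
#' @param out_dir output directory (created if missing).
#' @return named character vector of file paths, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "mait_bundle"))
  if (nrow(bundle$cells) == 0L) stop("bundle is empty", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir, call. = FALSE)
  paths <- c(
    matrix = file.path(out_dir, "matrix.mtx"),
    features = file.path(out_dir, "features.tsv"),
    barcodes = file.path(out_dir, "barcodes.tsv"),
    adt = file.path(out_dir, "adt.csv"),
    cells = file.path(out_dir, "cell_metrics.csv"),
    contigs_10x = file.path(out_dir, "filtered_contig_annotations.csv"),
    contigs_airr = file.path(out_dir, "airr_rearrangement.tsv"),
    truth = file.path(out_dir, "truth.csv")
  )
  Matrix::writeMM(bundle$genes, paths[["matrix"]])
  writeLines(rownames(bundle$genes), paths[["features"]])
  writeLines(colnames(bundle$genes), paths[["barcodes"]])
  adt_df <- data.frame(barcode = rownames(bundle$adt), bundle$adt,
                       check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(adt_df, paths[["adt"]], row.names = FALSE)
  write.csv(bundle$cells, paths[["cells"]], row.names = FALSE)
  write.csv(bundle$contigs, paths[["contigs_10x"]], row.names = FALSE)
  write_airr(bundle$contigs, paths[["contigs_airr"]])
  write.csv(bundle$truth, paths[["truth"]], row.names = FALSE)
  invisible(paths)
}

write_airr <- function(contigs, path) {
  locus <- contigs$chain
  airr <- data.frame(
    sequence_id = sprintf("%s_contig_%d", contigs$barcode, seq_len(nrow(contigs))),
    cell_id = contigs$barcode,
    locus = locus,
    v_call = contigs$v_gene,
    d_call = contigs$d_gene,
    j_call = contigs$j_gene,
    junction_aa = contigs$cdr3,
    productive = ifelse(contigs$productive, "T", "F"),
    duplicate_count = contigs$umis,
    consensus_count = contigs$reads,
    high_confidence = ifelse(contigs$high_confidence, "T", "F"),
    stringsAsFactors = FALSE)
  write.table(airr, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Read a gene count matrix written as Matrix Market + feature/barcode lists
#'
#' @param dir directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`.
#' @return sparse gene x cell matrix with dimnames.
#' @export
read_count_matrix <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  rownames(m) <- readLines(file.path(dir, "features.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  methods::as(m, "CsparseMatrix")
}

#' Read an ADT count table (CSV, one row per barcode)
#'
#' @param path CSV with a `barcode` column and one column per tag.
#' @return integer matrix, cells x tags, rownames = barcodes.
#' @export
read_adt <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"barcode" %in% names(df)) stop("ADT table lacks a 'barcode' column", call. = FALSE)
  m <- as.matrix(df[setdiff(names(df), "barcode")])
  rownames(m) <- df$barcode
  m
}

#' Read per-cell QC metrics
#' @param path CSV with columns barcode, n_genes_detected, mito_fraction and
#'   optionally condition.
#' @return data.frame.
#' @export
read_cell_metrics <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

# ---- contig parsing ---------------------------------------------------------

#' Normalize a V/D/J gene symbol
#'
#' Strips IMGT allele suffixes (`*01` etc.), removes the hyphen spelling
#' variant in TRAJ names (`TRAJ-33` -> `TRAJ33`), and upper-cases, while
#' preserving dual-name `/DV` designations verbatim.
#'
#' @param x character vector of gene symbols.
#' @return normalized character vector.
#' @export
#' @examples
#' normalize_gene_symbol("TRAV1-2*01")  # "TRAV1-2"
normalize_gene_symbol <- function(x) {
  x <- toupper(trimws(x))
  x <- sub("\\*[0-9]+$", "", x)
  x <- sub("^TRAJ-", "TRAJ", x)
  x
}

TENX_REQUIRED <- c("barcode", "chain", "v_gene", "j_gene", "cdr3", "productive")
AIRR_REQUIRED <- c("cell_id", "locus", "v_call", "j_call", "junction_aa", "productive")

parse_logical_flag <- function(x) {
  if (is.logical(x)) return(x)
  toupper(as.character(x)) %in% c("TRUE", "T", "YES", "1")
}

#' Read VDJ contig annotations
#'
#' Parses either the 10x `filtered_contig_annotations.csv` dialect or an
#' AIRR rearrangement TSV into a normalized contig table. Gene symbols are
#' normalized at read time ([normalize_gene_symbol()]); nonproductive and
#' low-confidence contigs are retained with their flags.
#'
#' @param path input file.
#' @param dialect `"10x-csv"` or `"airr-tsv"`.
#' @return data.frame with columns barcode, chain (`TRA`/`TRB`/`other`),
#'   v_gene, d_gene, j_gene, cdr3, productive, high_confidence, umis.
#' @export
read_contigs <- function(path, dialect = c("10x-csv", "airr-tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "10x-csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    missing <- setdiff(TENX_REQUIRED, names(df))
    if (length(missing))
      stop("10x contig CSV is missing mandatory column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    out <- data.frame(
      barcode = df$barcode,
      chain = ifelse(df$chain %in% c("TRA", "TRB"), df$chain, "other"),
      v_gene = normalize_gene_symbol(df$v_gene),
      d_gene = if ("d_gene" %in% names(df)) normalize_gene_symbol(df$d_gene) else "",
      j_gene = normalize_gene_symbol(df$j_gene),
      cdr3 = toupper(df$cdr3),
      productive = parse_logical_flag(df$productive),
      high_confidence = if ("high_confidence" %in% names(df))
        parse_logical_flag(df$high_confidence) else TRUE,
      umis = if ("umis" %in% names(df)) as.integer(df$umis) else 1L,
      stringsAsFactors = FALSE)
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE)
    missing <- setdiff(AIRR_REQUIRED, names(df))
    if (length(missing))
      stop("AIRR TSV is missing mandatory column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    out <- data.frame(
      barcode = df$cell_id,
      chain = ifelse(df$locus %in% c("TRA", "TRB"), df$locus, "other"),
      v_gene = normalize_gene_symbol(df$v_call),
      d_gene = if ("d_call" %in% names(df)) normalize_gene_symbol(df$d_call) else "",
      j_gene = normalize_gene_symbol(df$j_call),
      cdr3 = toupper(df$junction_aa),
      productive = parse_logical_flag(df$productive),
      high_confidence = if ("high_confidence" %in% names(df))
        parse_logical_flag(df$high_confidence) else TRUE,
      umis = if ("duplicate_count" %in% names(df)) as.integer(df$duplicate_count) else 1L,
      stringsAsFactors = FALSE)
  }
  # TRA contigs carry no D segment
  out$d_gene[out$chain == "TRA"] <- ""
  out$d_gene[is.na(out$d_gene)] <- ""
  out
}
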