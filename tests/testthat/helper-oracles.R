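# Independent oracles and shared fixtures for the test suite.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_aa <- function(len) paste(sample(AA20, len, replace = TRUE), collapse = "")

# --- similarity oracle: brute-force common-subsequence search ---------------
# enumerates every subsequence of the shorter string and checks whether it is
# a subsequence of the other; only feasible for short strings.
is_subseq <- function(sub, s) {
  if (!nzchar(sub)) return(TRUE)
  sc <- strsplit(s, "")[[1]]
  i <- 1L
  for (ch in strsplit(sub, "")[[1]]) {
    while (i <= length(sc) && sc[i] != ch) i <- i + 1L
    if (i > length(sc)) return(FALSE)
    i <- i + 1L
  }
  TRUE
}

oracle_similarity <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  ac <- strsplit(a, "")[[1]]
  best <- 0L
  for (m in 0:(2^length(ac) - 1)) {
    idx <- which(bitwAnd(m, bitwShiftL(1L, seq_along(ac) - 1L)) > 0)
    if (length(idx) <= best) next
    if (is_subseq(paste(ac[idx], collapse = ""), b)) best <- length(idx)
  }
  100 * best / max(nchar(a), nchar(b))
}

# --- motif oracle: plain substring scan -------------------------------------
oracle_motif_any <- function(s, patterns) {
  for (pat in patterns) {
    k <- nchar(pat)
    if (nchar(s) < k) next
    for (i in seq_len(nchar(s) - k + 1L)) {
      if (substr(s, i, i + k - 1L) == pat) return(TRUE)
    }
  }
  FALSE
}

oracle_motif_starts <- function(s, pat) {
  k <- nchar(pat)
  if (nchar(s) < k) return(integer())
  starts <- integer()
  for (i in seq_len(nchar(s) - k + 1L)) {
    if (substr(s, i, i + k - 1L) == pat) starts <- c(starts, i)
  }
  starts
}

# --- pairing oracle: direct case analysis, written independently ------------
oracle_pairing <- function(contigs) {
  out <- list()
  for (bc in unique(contigs$barcode)) {
    d <- contigs[contigs$barcode == bc & contigs$productive &
                   contigs$high_confidence & contigs$chain %in% c("TRA", "TRB"), ]
    if (nrow(d)) {
      # collapse duplicates of the same chain record, keeping max UMI
      d <- d[order(-d$umis), ]
      d <- d[!duplicated(d[c("chain", "v_gene", "j_gene", "cdr3")]), ]
    }
    nA <- sum(d$chain == "TRA"); nB <- sum(d$chain == "TRB")
    status <-
      if (nA == 0 && nB == 0) "none"
      else if (nB > 1 || nA > 2) "multiplet"
      else if (nA == 1 && nB == 1) "paired_single"
      else if (nA == 2 && nB == 1) "dual_alpha"
      else if (nB == 0) "alpha_only"
      else "beta_only"
    n12 <- sum(d$v_gene[d$chain == "TRA"] == "TRAV1-2")
    dual_category <- if (status == "dual_alpha") {
      if (n12 == 2) "both_trav12" else if (n12 == 1) "one_trav12" else "neither"
    } else NA_character_
    trav12 <- if (status %in% c("paired_single", "dual_alpha", "alpha_only")) {
      if (n12 >= 1) "positive" else "negative"
    } else NA_character_
    out[[bc]] <- data.frame(barcode = bc, pairing_status = status,
                            dual_category = dual_category,
                            trav12_status = trav12, stringsAsFactors = FALSE)
  }
  do.call(rbind, unname(out))
}

# random small contig fixture covering duplicates, bad flags, other chains
random_contig_fixture <- function(n_barcodes = 8L) {
  rows <- list()
  vpool <- c("TRAV1-2", "TRAV21", "TRAV8-1", "TRBV6-4", "TRBV28")
  for (b in seq_len(n_barcodes)) {
    n <- sample(0:5, 1)
    if (n == 0) next
    for (k in seq_len(n)) {
      chain <- sample(c("TRA", "TRB", "TRG"), 1, prob = c(0.5, 0.4, 0.1))
      rows[[length(rows) + 1L]] <- data.frame(
        barcode = sprintf("BC%02d", b), chain = chain,
        v_gene = sample(vpool, 1), d_gene = "",
        j_gene = sample(c("TRAJ33", "TRAJ12", "TRAJ28", "TRBJ2-1"), 1),
        cdr3 = random_aa(sample(8:12, 1)),
        productive = runif(1) < 0.85, high_confidence = runif(1) < 0.9,
        umis = sample(1:20, 1), stringsAsFactors = FALSE)
    }
    # occasionally append an exact duplicate with different UMI support
    if (runif(1) < 0.3) {
      dup <- rows[[length(rows)]]
      dup$umis <- sample(1:20, 1)
      rows[[length(rows) + 1L]] <- dup
    }
  }
  do.call(rbind, rows)
}

# tiny hand-built contig table used across pairing tests
make_contigs <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    defaults <- list(barcode = "BC1", chain = "TRA", v_gene = "TRAV1-2",
                     d_gene = "", j_gene = "TRAJ33", cdr3 = "CAVMDSNYQLIW",
                     productive = TRUE, high_confidence = TRUE, umis = 5L)
    defaults[names(r)] <- r
    as.data.frame(defaults, stringsAsFactors = FALSE)
  }))
}

# --- cached study-scale run (shared by recovery tests) ----------------------
.cache <- new.env(parent = emptyenv())

big_bundle <- function() {
  if (is.null(.cache$bundle))
    .cache$bundle <- generate_repertoire(study_preset(n_cells = 10000L, seed = 42L))
  .cache$bundle
}

big_report <- function() {
  if (is.null(.cache$report))
    .cache$report <- run_pipeline(bundle = big_bundle())
  .cache$report
}

report_value <- function(res, metric) {
  res$report$value[res$report$metric == metric]
}
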