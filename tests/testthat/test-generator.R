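# Synthetic repertoire generator: determinism, planted structure, errors.

test_that("generation is deterministic and write_bundle is byte-identical under a fixed seed", {
  cfg <- generator_config(n_cells = 300L, seed = 7L)
  b1 <- generate_repertoire(cfg)
  b2 <- generate_repertoire(cfg)
  expect_identical(b1$contigs, b2$contigs)
  expect_identical(b1$truth, b2$truth)
  expect_identical(as.matrix(b1$genes), as.matrix(b2$genes))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_bundle(b1, d1); p2 <- write_bundle(b2, d2)
  for (nm in names(p1)) {
    expect_identical(unname(tools::md5sum(p1[[nm]])), unname(tools::md5sum(p2[[nm]])),
                     info = nm)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(subset_probs = c(DN = 0.5, CD8 = 0.4, CD4 = 0.4)),
               "sum to 1")
  expect_error(generator_config(dual_alpha_prob = 1.5), "probability")
  expect_error(generator_config(canonical_len_range = c(14L, 12L)), "length range")
  expect_error(generate_repertoire(generator_config(n_cells = 0L)), "empty")
})

test_that("dual_alpha_prob = 0 yields no barcode with two TRA contigs", {
  b <- generate_repertoire(generator_config(n_cells = 400L, seed = 3L,
                                            dual_alpha_prob = 0))
  tra <- b$contigs[b$contigs$chain == "TRA", ]
  expect_true(all(table(tra$barcode) == 1L))
})

test_that("every MAIT cell carries >=1 productive TRA, exactly 1 TRB, and detectable CD8A", {
  b <- generate_repertoire(generator_config(n_cells = 500L, seed = 11L))
  mait <- b$truth$barcode[b$truth$lineage == "MAIT"]
  tra <- table(b$contigs$barcode[b$contigs$chain == "TRA"])
  trb <- table(b$contigs$barcode[b$contigs$chain == "TRB"])
  expect_true(all(mait %in% names(tra)))
  expect_true(all(tra[mait] >= 1L))
  expect_true(all(trb[mait] == 1L))
  expect_true(all(b$genes["CD8A", mait] > 0))
  # dual-alpha truth labels match emitted contig counts exactly
  duals <- b$truth$barcode[which(b$truth$dual_alpha)]
  expect_true(all(tra[duals] == 2L))
  expect_true(all(tra[setdiff(mait, duals)] == 1L))
})

test_that("planted TRAV1-2-negative fraction among CD4 cells matches its probability", {
  b <- big_bundle()
  t <- b$truth
  cd4 <- t[t$lineage == "MAIT" & t$subset == "CD4" & !t$dual_alpha, ]
  ci <- stats::binom.test(sum(!cd4$trav12), nrow(cd4))$conf.int
  expect_true(ci[1] <= 0.90 && 0.90 <= ci[2])
})

test_that("empirical subset, dual-category and conditional TRAJ frequencies converge", {
  b <- big_bundle()
  t <- b$truth[b$truth$lineage == "MAIT", ]
  n <- nrow(t)
  for (s in c("DN", "CD8", "CD4")) {
    p <- c(DN = 0.50, CD8 = 0.35, CD4 = 0.15)[[s]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(t$subset == s) - p), 3 * se)
  }
  duals <- t[which(t$dual_alpha), ]
  for (cat in c("both_trav12", "one_trav12", "neither")) {
    p <- c(both_trav12 = 0.35, one_trav12 = 0.40, neither = 0.25)[[cat]]
    se <- sqrt(p * (1 - p) / nrow(duals))
    expect_lt(abs(mean(duals$dual_category == cat) - p), 3 * se)
  }
  # canonical TRAJ usage conditioned on TRAV1-2, single-paired cells
  singles12 <- t[!t$dual_alpha & t$trav12, ]
  canj <- singles12$a1_j %in% c("TRAJ33", "TRAJ20", "TRAJ12")
  se <- sqrt(0.9 * 0.1 / nrow(singles12))
  expect_lt(abs(mean(canj) - 0.90), 3 * se)
})

test_that("generated CDR3s use only amino-acid letters and truth flags are verifiable by string inspection", {
  b <- generate_repertoire(generator_config(n_cells = 600L, seed = 5L))
  cd <- b$contigs$cdr3
  expect_false(any(grepl("[^ACDEFGHIKLMNPQRSTVWY]", cd)))
  t <- b$truth[b$truth$lineage == "MAIT", ]
  gly <- t$gly_planted
  expect_true(all(grepl("GGG", t$cdr3a1[gly])))
  expect_true(all(grepl("GGGG", t$cdr3a1[which(t$gggg_planted)])))
  expect_true(all(grepl("NNNN", t$cdr3a1[which(t$nnnn_planted)])))
  expect_true(all(substr(t$cdr3a1[t$v3_planted], 3, 3) == "V"))
  expect_true(all(substr(t$cdr3a1[!t$v3_planted], 3, 3) != "V"))
})

test_that("sample_cdr3_alpha honours anchors, the Tyr-95 slot and motif planting", {
  set.seed(1)
  for (i in 1:50) {
    s <- c(sample_cdr3_alpha(TRUE, c(12L, 14L), j_gene = sample(c("TRAJ33", "TRAJ12", "TRAJ20"), 1)))
    L <- nchar(s)
    expect_true(L >= 12 && L <= 14)
    expect_identical(substr(s, 1, 2), "CA")
    expect_identical(substr(s, L - 4, L - 4), "Y")  # 5th residue from the C-terminus
  }
  s <- sample_cdr3_alpha(TRUE, c(12L, 12L), j_gene = "TRAJ33")
  expect_identical(nchar(as.character(s)), 12L)
  for (i in 1:50) {
    s <- c(sample_cdr3_alpha(FALSE, c(10L, 10L), list(gly_motif_prob = 1, gggg_frac = 0)))
    expect_identical(substr(s, 1, 2), "CA")
    starts <- as.integer(gregexpr("(?=GGG)", s, perl = TRUE)[[1]])
    expect_true(any(starts > 0))
    # some GGG run intersects the central window 6-9
    expect_true(any(starts <= 9 & starts + 2 >= 6))
  }
  expect_error(sample_cdr3_alpha(FALSE, c(4L, 4L)), "anchor")
})

test_that("bundle files round-trip through the 10x and AIRR dialects", {
  b <- generate_repertoire(generator_config(n_cells = 120L, seed = 9L))
  d <- withr::local_tempdir()
  paths <- write_bundle(b, d)
  tenx <- read_contigs(paths[["contigs_10x"]], "10x-csv")
  airr <- read_contigs(paths[["contigs_airr"]], "airr-tsv")
  keep <- c("barcode", "chain", "v_gene", "d_gene", "j_gene", "cdr3",
            "productive", "high_confidence", "umis")
  orig <- b$contigs[keep]
  rownames(orig) <- NULL
  expect_identical(tenx[keep], orig)
  expect_identical(airr[keep], orig)
  # AIRR file exposes the schema's mandatory rearrangement fields
  hdr <- names(read.delim(paths[["contigs_airr"]], nrows = 1))
  expect_true(all(c("cell_id", "locus", "v_call", "j_call", "junction_aa",
                    "productive") %in% hdr))
  # count matrix round-trip
  m <- read_count_matrix(d)
  expect_identical(as.matrix(m), as.matrix(b$genes))
  adt <- read_adt(paths[["adt"]])
  expect_identical(adt, b$adt)
  # all barcodes present in both matrix and contig file for MAIT cells
  mait <- b$truth$barcode[b$truth$lineage == "MAIT"]
  expect_true(all(mait %in% colnames(m)))
  expect_true(all(mait %in% tenx$barcode))
})
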