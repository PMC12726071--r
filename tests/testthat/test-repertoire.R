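# Contig parsing, chain pairing, canonical classification, usage, diversity.

test_that("gene symbols are normalized at read time", {
  expect_identical(normalize_gene_symbol("TRAV1-2*01"), "TRAV1-2")
  expect_identical(normalize_gene_symbol("TRAJ-33"), "TRAJ33")
  expect_identical(normalize_gene_symbol("trbv6-4*02"), "TRBV6-4")
  expect_identical(normalize_gene_symbol("TRAV29/DV5"), "TRAV29/DV5")
})

test_that("10x parser normalizes alleles and errors on missing mandatory columns", {
  d <- withr::local_tempdir()
  f <- file.path(d, "contigs.csv")
  df <- data.frame(barcode = "BC1", is_cell = TRUE, high_confidence = TRUE,
                   chain = "TRA", v_gene = "TRAV1-2*01", d_gene = "",
                   j_gene = "TRAJ33*01", cdr3 = "CAVMDSNYQLIW",
                   cdr3_nt = "NNN", productive = "True", reads = 100, umis = 4,
                   raw_clonotype_id = "clonotype1")
  write.csv(df, f, row.names = FALSE)
  ct <- read_contigs(f, "10x-csv")
  expect_identical(ct$v_gene, "TRAV1-2")
  expect_identical(ct$j_gene, "TRAJ33")
  expect_true(ct$productive)
  write.csv(df[setdiff(names(df), "cdr3")], f, row.names = FALSE)
  expect_error(read_contigs(f, "10x-csv"), "cdr3")
})

test_that("AIRR rows map onto contig records", {
  d <- withr::local_tempdir()
  f <- file.path(d, "airr.tsv")
  airr <- data.frame(sequence_id = "s1", cell_id = "BC9", locus = "TRA",
                     v_call = "TRAV1-2*01", d_call = "", j_call = "TRAJ33",
                     junction_aa = "CAVMDSNYQLIW", productive = "T",
                     duplicate_count = 3)
  write.table(airr, f, sep = "\t", row.names = FALSE, quote = FALSE)
  ct <- read_contigs(f, "airr-tsv")
  expect_identical(ct$chain, "TRA")
  expect_identical(ct$barcode, "BC9")
  expect_identical(ct$cdr3, "CAVMDSNYQLIW")
  expect_identical(ct$umis, 3L)
})

test_that("pairing handles single, dual and degenerate barcodes", {
  # 1 TRA + 1 TRB
  calls <- pair_chains(make_contigs(
    list(), list(chain = "TRB", v_gene = "TRBV6-4", j_gene = "TRBJ2-1",
                 d_gene = "TRBD1", cdr3 = "CASSESGNQPQHF")))
  expect_identical(calls$pairing_status, "paired_single")
  expect_identical(calls$trav12_status, "positive")
  # two TRAV1-2 isoforms with different J segments -> dual both_trav12
  calls <- pair_chains(make_contigs(
    list(), list(j_gene = "TRAJ12", cdr3 = "CAVRDDYKLIF"),
    list(chain = "TRB", v_gene = "TRBV6-1", cdr3 = "CASSEFGGTEAFF")))
  expect_identical(calls$pairing_status, "dual_alpha")
  expect_identical(calls$dual_category, "both_trav12")
  # TRAV1-2 coexpressed with a different alpha chain -> one_trav12
  calls <- pair_chains(make_contigs(
    list(v_gene = "TRAV21", j_gene = "TRAJ28", cdr3 = "CAVLSGGGKLIF"),
    list(), list(chain = "TRB", v_gene = "TRBV28", cdr3 = "CASSPRGEQYF")))
  expect_identical(calls$dual_category, "one_trav12")
  expect_identical(calls$trav12_status, "positive")
  expect_identical(calls$a1_v, "TRAV1-2")  # primary alpha is the TRAV1-2 chain
  # >1 TRB is a multiplet; nonproductive contigs are ignored
  calls <- pair_chains(make_contigs(
    list(), list(chain = "TRB", v_gene = "TRBV6-4", cdr3 = "CASSEAFF"),
    list(chain = "TRB", v_gene = "TRBV28", cdr3 = "CASSEQYF")))
  expect_identical(calls$pairing_status, "multiplet")
  calls <- pair_chains(make_contigs(
    list(), list(chain = "TRB", cdr3 = "CASSEAFF", v_gene = "TRBV6-4"),
    list(chain = "TRB", v_gene = "TRBV28", cdr3 = "CASSEQYF", productive = FALSE)))
  expect_identical(calls$pairing_status, "paired_single")
  # redundant identical contigs collapse (highest UMI kept)
  calls <- pair_chains(make_contigs(
    list(umis = 2L), list(umis = 9L),
    list(chain = "TRB", v_gene = "TRBV6-4", cdr3 = "CASSEAFF")))
  expect_identical(calls$pairing_status, "paired_single")
  # only non-TRA/TRB chains -> none
  calls <- pair_chains(make_contigs(list(chain = "TRG", v_gene = "TRGV9",
                                         j_gene = "TRGJ1", cdr3 = "CALWEVF")))
  expect_identical(calls$pairing_status, "none")
})

test_that("pairing equals the brute-force oracle on random small fixtures", {
  set.seed(33)
  for (rep in 1:25) {
    fx <- random_contig_fixture(sample(3:10, 1))
    if (is.null(fx)) next
    got <- pair_chains(fx)
    want <- oracle_pairing(fx)
    got <- got[match(want$barcode, got$barcode), ]
    expect_identical(got$pairing_status, want$pairing_status)
    expect_identical(got$dual_category, want$dual_category)
    expect_identical(got$trav12_status, want$trav12_status)
  }
})

test_that("pairing is invariant to contig input order", {
  set.seed(12)
  fx <- random_contig_fixture(10)
  a <- pair_chains(fx)
  b <- pair_chains(fx[sample(nrow(fx)), ])
  b <- b[match(a$barcode, b$barcode), ]
  rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("canonical classification follows the TRAV1-2/TRAJ33-20-12/TRBV6-20 definition", {
  calls <- pair_chains(make_contigs(
    list(), list(chain = "TRB", v_gene = "TRBV6-4", cdr3 = "CASSEAFF")))
  cls <- classify_tcr(calls)
  expect_true(cls$canonical_traj)
  expect_true(cls$canonical_trbv)
  expect_true(cls$fully_canonical)
  calls <- pair_chains(make_contigs(
    list(v_gene = "TRAV21", j_gene = "TRAJ28", cdr3 = "CAVLKAAGNKLTF"),
    list(chain = "TRB", v_gene = "TRBV28", cdr3 = "CASSEAFF")))
  cls <- classify_tcr(calls)
  expect_identical(cls$trav12_status, "negative")
  expect_false(cls$canonical_traj)
  expect_false(cls$canonical_trbv)
  calls <- pair_chains(make_contigs(
    list(j_gene = "TRAJ42", cdr3 = "CAVRGGSQGNLIF"),
    list(chain = "TRB", v_gene = "TRBV6-4", cdr3 = "CASSEAFF")))
  cls <- classify_tcr(calls)
  expect_identical(cls$trav12_status, "positive")
  expect_false(cls$canonical_traj)
  expect_false(cls$fully_canonical)
  # TRBV6 family mode widens the beta set
  calls <- pair_chains(make_contigs(
    list(), list(chain = "TRB", v_gene = "TRBV6-5", cdr3 = "CASSEAFF")))
  expect_false(classify_tcr(calls)$canonical_trbv)
  expect_true(classify_tcr(calls, canonical_definition(trbv_family_mode = TRUE))$canonical_trbv)
  # unnormalized gene names are rejected
  bad <- pair_chains(make_contigs(list(), list(chain = "TRB", v_gene = "TRBV6-4",
                                               cdr3 = "CASSEAFF")))
  bad$a1_v <- "TRAV1-2*01"
  expect_error(classify_tcr(bad), "unnormalized")
})

test_that("usage tables give per-group proportions that sum to 1, with shared/unique sets", {
  calls <- data.frame(
    barcode = sprintf("b%d", 1:8),
    pairing_status = "paired_single",
    trav12_status = c("positive", "positive", "negative", "negative",
                      "positive", "negative", "negative", "positive"),
    a1_v = c("TRAV1-2", "TRAV1-2", "TRAV21", "TRAV21", "TRAV1-2", "TRAV8-1",
             "TRAV21", "TRAV1-2"),
    a1_j = c("TRAJ33", "TRAJ12", "TRAJ28", "TRAJ42", "TRAJ33", "TRAJ8",
             "TRAJ28", "TRAJ20"),
    b_v = c("TRBV6-4", "TRBV6-1", "TRBV28", "TRBV28", "TRBV20-1", "TRBV19",
            "TRBV28", "TRBV6-4"),
    subset = c("CD8", "CD8", "CD4", "CD4", "DN", "CD4", "DN", "DN"),
    stringsAsFactors = FALSE)
  u <- usage_table(calls, group_by = "subset")
  sums <- tapply(u$proportion, list(u$subset, u$gene_class), sum)
  expect_true(all(abs(sums - 1) < 1e-12, na.rm = TRUE))
  cd4 <- u[u$subset == "CD4" & u$gene_class == "TRAV", ]
  expect_equal(cd4$proportion[cd4$gene == "TRAV21"], 2 / 3)
  # two cells each of two genes -> 0.5 / 0.5
  two <- usage_table(calls[c(1, 2, 3, 4), ], group_by = "pairing_status")
  trav <- two[two$gene_class == "TRAV", ]
  expect_equal(sort(trav$proportion), c(0.5, 0.5))
  ov <- gene_overlap(u, "TRAJ", "subset")
  expect_true("TRAJ28" %in% ov$unique$CD4 || "TRAJ28" %in% ov$shared)
  # disjoint usage between groups -> empty shared set
  dis <- usage_table(calls[c(1, 3), ], group_by = "subset")
  expect_length(gene_overlap(dis, "TRAJ", "subset")$shared, 0)
})

test_that("diversity indices match closed forms and the vegan oracle", {
  expect_equal(diversity_index(rep(5, 4), "shannon"), log(4))
  expect_equal(diversity_index(c(10, 0, 0), "shannon"), 0)
  expect_equal(diversity_index(c(10, 0, 0), "simpson"), 0)
  expect_identical(diversity_index(c(10, 0, 0), "richness"), 1L)
  expect_equal(diversity_index(c(2, 1, 1), "shannon"), 1.0397, tolerance = 1e-4)
  expect_equal(diversity_index(rep(3, 6), "pielou"), 1)
  expect_error(diversity_index(c(0, 0)), "all-zero")
  expect_error(diversity_index(c(-1, 2)), "nonnegative")
  expect_error(diversity_index(c(5, 0), "pielou"), "richness")
  skip_if_not_installed("vegan")
  set.seed(2)
  for (i in 1:10) {
    x <- sample(0:30, 8, TRUE)
    if (sum(x) == 0) next
    expect_equal(diversity_index(x, "shannon"), unname(vegan::diversity(x, "shannon")))
    expect_equal(diversity_index(x, "simpson"), unname(vegan::diversity(x, "simpson")))
  }
})

test_that("entropy is bounded by log-richness and simpson by 1 - 1/richness", {
  set.seed(14)
  for (i in 1:50) {
    x <- sample(1:50, sample(2:12, 1), TRUE)
    r <- diversity_index(x, "richness")
    expect_lte(diversity_index(x, "shannon"), log(r) + 1e-12)
    expect_lte(diversity_index(x, "simpson"), 1 - 1 / r + 1e-12)
    expect_gte(diversity_index(x, "simpson"), 0)
  }
  # equality iff uniform
  expect_equal(diversity_index(rep(7, 5), "shannon"), log(5))
})
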