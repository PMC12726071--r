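# Percent similarity, reference parsing, and indel-perturbed matching.

test_that("similarity matches hand-checked values and the brute-force oracle", {
  expect_equal(cdr3_similarity("CASSF", "CASTF"), 80)
  expect_equal(cdr3_similarity("CAS", "CASAAA"), 50)
  expect_equal(cdr3_similarity("CASSF", "CASSF"), 100)
  set.seed(21)
  for (i in 1:30) {
    a <- random_aa(sample(3:7, 1))
    b <- random_aa(sample(3:7, 1))
    expect_equal(cdr3_similarity(a, b), oracle_similarity(a, b))
  }
})

test_that("similarity is symmetric, bounded, and 100 iff identical", {
  set.seed(22)
  for (i in 1:100) {
    a <- random_aa(sample(4:14, 1))
    b <- if (runif(1) < 0.2) a else random_aa(sample(4:14, 1))
    s <- cdr3_similarity(a, b)
    expect_equal(s, cdr3_similarity(b, a))
    expect_gte(s, 0); expect_lte(s, 100)
    expect_identical(s == 100, a == b)
  }
  expect_error(cdr3_similarity("CASX1", "CASSF"), "alphabet")
  expect_error(cdr3_similarity("", "CASSF"), "alphabet")
})

test_that("central-region similarity compares the trimmed loops", {
  # identical central regions, different endings
  expect_equal(central_similarity("CAVAGGGGAKLIW", "CTTAGGGGAQQQF"),
               cdr3_similarity("AGGGGA", "AGGGGA"))
})

test_that("reference tables parse per chain with duplicates retained", {
  d <- withr::local_tempdir()
  f <- file.path(d, "ref.csv")
  writeLines(c("CDR3_alpha,CDR3_beta,Epitope,Pathology",
               "CAVMDSNYQLIW,CASSEGGLGEQYF,5-OP-RU,Mtb",
               ",CASSVGGGTDTQYF,Gliadin,Celiac"), f)
  ref <- read_reference(f)
  expect_identical(nrow(ref), 3L)
  expect_identical(sum(ref$chain == "alpha"), 1L)
  writeLines("CDR3_alpha,CDR3_beta,Epitope,Pathology", f)
  expect_identical(nrow(read_reference(f)), 0L)
  writeLines(c("CDR3_alpha,Epitope", "CAV,5-OP-RU"), f)
  expect_error(read_reference(f), "CDR3_beta")
  # packaged fixture
  fixture <- system.file("extdata", "mcpas_synthetic_reference.csv", package = "maitcr")
  ref <- read_reference(fixture)
  expect_gte(nrow(ref), 12L)
  expect_true(all(ref$chain %in% c("alpha", "beta")))
})

test_that("perturbed matching finds exact matches through single indels", {
  refs <- data.frame(cdr3_aa = "CASSGF", chain = "beta", epitope = "E1",
                     pathology = "P1", source_id = "s", stringsAsFactors = FALSE)
  hit <- perturbed_match("CASSLGF", refs, max_insertions = 0L, max_deletions = 1L)
  expect_equal(hit$similarity_pct, 100)
  expect_identical(hit$indel_budget_used, 1L)
  expect_identical(hit$edit_operations, "del@5:L")
  refs$cdr3_aa <- "CAWSF"
  hit <- perturbed_match("CASF", refs, max_insertions = 1L, max_deletions = 0L)
  expect_equal(hit$similarity_pct, 100)
  expect_identical(hit$edit_operations, "ins@3:W")
  # identical query at zero budget stays at budget 0
  refs$cdr3_aa <- "CASF"
  hit <- perturbed_match("CASF", refs, max_insertions = 2L, max_deletions = 2L)
  expect_equal(hit$similarity_pct, 100)
  expect_identical(hit$indel_budget_used, 0L)
  expect_error(perturbed_match("CASF", refs[0, ]), "empty")
})

test_that("perturbed similarity is monotone nondecreasing in both budgets", {
  set.seed(23)
  refs <- data.frame(cdr3_aa = c("CASSEGGLGEQYF", "CAVMDSNYQLIW", "CASSVGGGTDTQYF"),
                     chain = "beta", epitope = c("E1", "E2", "E3"),
                     pathology = "P", source_id = "s", stringsAsFactors = FALSE)
  for (i in 1:10) {
    q <- random_aa(sample(6:10, 1))
    sims <- sapply(0:2, function(k)
      perturbed_match(q, refs, max_insertions = k, max_deletions = k)$similarity_pct)
    expect_true(all(diff(sims) >= -1e-9))
  }
})

test_that("perturbed matching equals exhaustive full-alphabet enumeration (length <= 8, budgets <= 2)", {
  all_deletions <- function(q, d) {
    if (d == 0) return(q)
    ch <- strsplit(q, "")[[1]]
    combos <- combn(length(ch), d, simplify = FALSE)
    vapply(combos, function(p) paste(ch[-p], collapse = ""), "")
  }
  all_insertions1 <- function(q) {
    L <- nchar(q)
    if (L < 2) return(character())
    out <- character()
    for (p in 2:L) for (r in AA20)
      out <- c(out, paste0(substr(q, 1, p - 1), r, substr(q, p, L)))
    out
  }
  brute_best <- function(q, refs, max_ins, max_del) {
    vars <- q
    if (max_del >= 1) vars <- c(vars, all_deletions(q, 1))
    if (max_del >= 2) vars <- c(vars, all_deletions(q, 2))
    if (max_ins >= 1) {
      one <- all_insertions1(q)
      vars <- c(vars, one)
      if (max_ins >= 2) vars <- c(vars, unlist(lapply(one, all_insertions1)))
    }
    vars <- unique(vars)
    best <- 0
    for (r in refs$cdr3_aa) best <- max(best, max(cdr3_similarity(vars, r)))
    best
  }
  refs <- data.frame(cdr3_aa = c("CASSGWF", "CAVNYQW", "CGGGAF"), chain = "beta",
                     epitope = c("E1", "E2", "E3"), pathology = "P",
                     source_id = "s", stringsAsFactors = FALSE)
  set.seed(24)
  cases <- c("CASF", "CAWSGF", replicate(6, random_aa(sample(5:8, 1))))
  for (q in cases) {
    for (budget in list(c(1L, 0L), c(0L, 1L), c(2L, 2L))) {
      got <- perturbed_match(q, refs, budget[1], budget[2])$similarity_pct
      want <- brute_best(q, refs, budget[1], budget[2])
      expect_equal(got, want, info = paste(q, budget[1], budget[2]))
    }
  }
})

test_that("deletion-only matching reaches 100 when the reference is a subsequence deficit away", {
  # if the query equals the reference plus k extra residues (k <= budget),
  # deleting them recovers an exact match
  set.seed(25)
  for (i in 1:10) {
    ref <- random_aa(sample(6:9, 1))
    pos <- sample(2:(nchar(ref)), 1)
    q <- paste0(substr(ref, 1, pos - 1), sample(AA20, 1), substr(ref, pos, nchar(ref)))
    refs <- data.frame(cdr3_aa = ref, chain = "alpha", epitope = "E",
                       pathology = "P", source_id = "s", stringsAsFactors = FALSE)
    hit <- perturbed_match(q, refs, max_insertions = 0L, max_deletions = 1L)
    expect_equal(hit$similarity_pct, 100)
  }
})
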