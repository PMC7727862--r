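aligned_pair <- function(n = 6, seed = 2) {
  set.seed(seed)
  x <- rnorm(n)
  small <- rbind(anti = 2^(8 + x), pos = 2^(8 + x), null = 2^rnorm(n, 8))
  mrna <- rbind(t_anti = 2^(8 - x), t_pos = 2^(8 + x),
                t_null = 2^rnorm(n, 8))
  colnames(small) <- colnames(mrna) <- paste0("s", seq_len(n))
  list(small = small, mrna = mrna)
}

test_that("negative correlation screen keeps only anti-correlated pairs", {
  d <- aligned_pair()
  hits <- negative_correlation_screen(d$small, d$mrna)
  expect_true(any(hits$small_rna == "anti" & hits$mrna == "t_anti"))
  expect_equal(hits$r[hits$small_rna == "anti" & hits$mrna == "t_anti"],
               -1, tolerance = 1e-4)
  expect_false(any(hits$small_rna == "pos" & hits$mrna == "t_pos"))
})

test_that("misaligned samples are an error", {
  d <- aligned_pair()
  m2 <- d$mrna[, rev(colnames(d$mrna))]
  expect_error(negative_correlation_screen(d$small, m2), "identical")
})

test_that("screen results match brute-force recomputation on a fixture", {
  cfg <- scenario_config(seed = 5)
  pe <- generate_paired_expression(cfg)
  hits <- negative_correlation_screen(pe$small_rna, pe$mrna)
  # every planted pair is recovered
  planted <- paste(pe$truth$pairs$small_rna, pe$truth$pairs$mrna)
  expect_true(all(planted %in% paste(hits$small_rna, hits$mrna)))
  # the full below-threshold set matches a direct double loop
  ls <- log2(pe$small_rna + 1); lm <- log2(pe$mrna + 1)
  brute <- 0
  for (i in seq_len(nrow(ls)))
    brute <- brute + sum(cor(ls[i, ], t(lm)) < -0.5)
  expect_equal(nrow(hits), brute)
})

test_that("spearman-mode screen is monotone-transform invariant", {
  d <- aligned_pair(seed = 6)
  h1 <- negative_correlation_screen(d$small, d$mrna, method = "spearman")
  h2 <- negative_correlation_screen(d$small^3, exp(d$mrna / 100),
                                    method = "spearman")
  expect_equal(h1[c("small_rna", "mrna", "r")],
               h2[c("small_rna", "mrna", "r")])
})

toy_db <- function() {
  data.frame(
    source = c("db1", "db2", "db3", "db1", "db2", "db1"),
    small_rna = c("mir-a", "mir-a", "mir-a", "mir-b", "mir-b", "mir-c"),
    mrna = c("G1", "G1", "G1", "G2", "G2", "G3"),
    stringsAsFactors = FALSE)
}

test_that("database consensus keeps pairs with enough support", {
  cand <- data.frame(small_rna = c("mir-a", "mir-b", "mir-c"),
                     mrna = c("G1", "G2", "G3"),
                     r = c(-0.9, -0.8, -0.7), stringsAsFactors = FALSE)
  out <- db_consensus_filter(cand, toy_db(), min_support = 3)
  expect_equal(out$small_rna, "mir-a")
  expect_equal(out$db_support, 3L)
  out2 <- db_consensus_filter(cand, toy_db(), min_support = 2)
  expect_setequal(out2$small_rna, c("mir-a", "mir-b"))
  expect_error(db_consensus_filter(cand, toy_db()[0, ]), "empty database")
})

test_that("raising min_support never adds pairs", {
  cfg <- scenario_config(seed = 3)
  pe <- generate_paired_expression(cfg)
  cand <- pe$truth$pairs
  prev <- Inf
  for (ms in 1:5) {
    n <- nrow(db_consensus_filter(cand, pe$db, min_support = ms))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("consensus on the synthetic fixture equals the planted half", {
  cfg <- scenario_config(seed = 8)
  pe <- generate_paired_expression(cfg)
  hits <- negative_correlation_screen(pe$small_rna, pe$mrna)
  cons <- db_consensus_filter(hits, pe$db, min_support = 3)
  expect_setequal(tolower(paste(cons$small_rna, cons$mrna)),
                  tolower(paste(pe$truth$consensus_pairs$small_rna,
                                pe$truth$consensus_pairs$mrna)))
})

test_that("seed-match join is a pure lookup", {
  tab <- data.frame(small_rna = c("piR-1", "piR-1", "piR-2"),
                    mrna = c("G1", "G2", "G3"), stringsAsFactors = FALSE)
  out <- seed_match_targets(c("piR-1", "piR-3"), tab)
  expect_equal(out$mrna, c("G1", "G2"))
  expect_equal(nrow(seed_match_targets(character(0), tab)), 0L)
  expect_error(seed_match_targets("x", NULL), "seed_table")
})

test_that("enrichment attains its floor when the query is the pathway", {
  universe <- sprintf("G%04d", 1:1000)
  sets <- list(hit = universe[1:5], other = universe[900:950])
  res <- enrich(universe[1:5], sets, universe, n_perm = 200, seed = 4)
  expect_equal(res$empirical_p[res$pathway == "hit"], 1 / 201)
  expect_gt(res$empirical_p[res$pathway == "other"], 0.5)
})

test_that("enrichment is reproducible for a fixed seed", {
  universe <- sprintf("G%04d", 1:300)
  sets <- list(a = universe[1:30], b = universe[31:90])
  q <- universe[c(1:12, 200:240)]
  r1 <- enrich(q, sets, universe, n_perm = 300, seed = 77)
  r2 <- enrich(q, sets, universe, n_perm = 300, seed = 77)
  expect_identical(r1, r2)
})

test_that("query genes outside the universe are flagged and intersected", {
  universe <- sprintf("G%04d", 1:100)
  sets <- list(a = universe[1:10])
  expect_warning(res <- enrich(c(universe[1:5], "NOT_A_GENE"), sets,
                               universe, n_perm = 100, seed = 1),
                 "outside the universe")
  expect_equal(res$overlap, 5L)
  expect_warning(
    expect_warning(res0 <- enrich("NOT_A_GENE", sets, universe,
                                  n_perm = 100, seed = 1),
                   "outside the universe"),
    "empty query")
  expect_equal(res0$empirical_p, 1)
})

test_that("GMT files round-trip through the reader", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tG1\tG2\tG3", "setB\tdesc\tG4"), f)
  sets <- read_gmt(f)
  expect_equal(sets$setA, c("G1", "G2", "G3"))
  expect_equal(sets$setB, "G4")
})
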