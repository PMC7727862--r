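test_that("generators are pure functions of the scenario config", {
  cfg <- scenario_config(seed = 13)
  a <- generate_survival_profiles(cfg)
  b <- generate_survival_profiles(cfg)
  expect_identical(a, b)
  expect_identical(generate_ct_matrix(cfg, a$sf_true),
                   generate_ct_matrix(cfg, a$sf_true))
  expect_identical(generate_serum_counts(cfg), generate_serum_counts(cfg))
  expect_identical(generate_paired_expression(cfg),
                   generate_paired_expression(cfg))
})

test_that("survival profiles have the configured shape and spread", {
  cfg <- scenario_config(seed = 2, n_cell_lines = 7)
  sp <- generate_survival_profiles(cfg)
  expect_equal(nrow(sp$profiles), 7 * 3)
  expect_equal(dim(sp$sf_true), c(7L, 3L))
  expect_true(all(sp$sf_true >= 0.2 & sp$sf_true <= 0.9))
  # every treatment spans the same SF levels in a different line order
  expect_equal(apply(sp$sf_true, 2, sort),
               matrix(rep(seq(0.2, 0.9, length.out = 7), 3), ncol = 3,
                      dimnames = list(NULL, cfg$treatments)))
})

test_that("the planted inconsistent line is flagged by aggregation", {
  cfg <- scenario_config(seed = 2, inconsistent_line = TRUE)
  sp <- generate_survival_profiles(cfg)
  flagged <- sp$profiles[!sp$profiles$consistent, ]
  expect_equal(nrow(flagged), 1L)
  expect_equal(flagged$treatment, "radiation")
})

test_that("Ct matrix carries the planted structure", {
  cfg <- scenario_config(seed = 6)
  sp <- generate_survival_profiles(cfg)
  cm <- generate_ct_matrix(cfg, sp$sf_true)
  expect_equal(dim(cm$ct), c(112L, 8L))
  undet <- apply(cm$ct, 1, function(r) all(is.na(r)))
  expect_setequal(rownames(cm$ct)[undet], cm$truth$undetected)
  rng <- range(cm$ct, na.rm = TRUE)
  expect_gt(rng[1], 15)
  expect_lte(rng[2], 40)
  # planted resistance miRNAs correlate positively with their SF axis
  for (tr in cfg$treatments) {
    rho <- sapply(cm$truth$resistance[[tr]], function(id)
      cor(rank(-cm$ct[id, ]), rank(sp$sf_true[, tr])))
    expect_true(all(rho > 0))
  }
})

test_that("planted HKGs are recovered by housekeeping selection", {
  for (s in c(4, 9)) {
    cfg <- scenario_config(seed = s)
    sp <- generate_survival_profiles(cfg)
    cm <- generate_ct_matrix(cfg, sp$sf_true)
    sel <- select_housekeeping(cm$ct)
    expect_setequal(sel$selected, cm$truth$hkg)
  }
})

test_that("serum counts have planted DE recoverable by the serum screen", {
  cfg <- scenario_config(seed = 5)
  sc <- generate_serum_counts(cfg)
  expect_true(all(sc$counts >= 0))
  expect_equal(dim(sc$counts), c(187L, 39L))
  counts <- filter_low_counts(sc$counts)
  de <- mwu_de(normalize_counts(counts, tmm_factors(counts)), sc$labels)
  sens <- mean(sc$truth$planted_de %in% de$mirna[de$p < 0.05])
  expect_gte(sens, 0.8)
})

test_that("a null serum scenario has calibrated type-I error", {
  cfg <- scenario_config(seed = 19, lfc_serum = 0)
  sc <- generate_serum_counts(cfg)
  counts <- filter_low_counts(sc$counts)
  de <- mwu_de(normalize_counts(counts, tmm_factors(counts)), sc$labels)
  expect_lt(mean(de$p < 0.05), 0.12)
})

test_that("noise-free anti-correlated pairs are exactly the planted set", {
  cfg <- scenario_config(seed = 3, r_target = -1)
  pe <- generate_paired_expression(cfg)
  # in the zero-noise limit the planted pairs are exactly affine, so on
  # the log2 scale their correlation is -1 to machine precision, while no
  # null pair comes anywhere near
  hits <- negative_correlation_screen(log2(pe$small_rna), log2(pe$mrna),
                                      r_threshold = -1 + 1e-9,
                                      log2_transform = FALSE)
  expect_setequal(paste(hits$small_rna, hits$mrna),
                  paste(pe$truth$pairs$small_rna, pe$truth$pairs$mrna))
})

test_that("the planted pathway attains the minimal empirical p", {
  cfg <- scenario_config(seed = 10)
  pe <- generate_paired_expression(cfg)
  hits <- negative_correlation_screen(pe$small_rna, pe$mrna)
  cons <- db_consensus_filter(hits, pe$db, min_support = 3)
  enr <- enrich(unique(cons$mrna), pe$gene_sets,
                universe = toupper(rownames(pe$mrna)), n_perm = 500,
                seed = 1)
  expect_equal(enr$pathway[which.min(enr$empirical_p)],
               pe$truth$enriched_pathway)
  expect_equal(min(enr$empirical_p), 1 / 501)
})

test_that("scenario directories are written complete and reproducible", {
  cfg <- scenario_config(seed = 21)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_scenario(cfg, d1)
  simulate_scenario(cfg, d2)
  files <- c("survival_profiles.tsv", "ct_matrix.tsv", "serum_counts.tsv",
             "serum_labels.tsv", "small_rna_expression.tsv",
             "mrna_expression.tsv", "target_db.tsv", "gene_sets.gmt",
             "ground_truth.json")
  expect_setequal(list.files(d1), files)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
})
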