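toy_design <- function() {
  prof <- do.call(rbind, lapply(1:6, function(i)
    aggregate_profile(rep(i / 10, 3), cell_line = paste0("L", i),
                      treatment = "radiation")))
  treatment_design(prof, "radiation")
}

test_that("treatment design ranks extremes pairs by mean SF", {
  des <- toy_design()
  expect_setequal(des$resistant_pair, c("L6", "L5"))
  expect_setequal(des$sensitive_pair, c("L1", "L2"))
  expect_error(treatment_design(data.frame(), "x"), ">= 4 cell lines")
})

test_that("extremes t-test reports linear fold and Welch p on log2 levels", {
  des <- toy_design()
  m <- rbind(flat = rep(2, 6),
             quad = c(2, 2, 5, 5, 8, 8),
             mixed = 2^c(1.0, 1.1, 5, 5, 4.1, 3.9))
  colnames(m) <- paste0("L", 1:6)
  res <- extremes_ttest(m, des)
  expect_equal(res$fold_change[res$mirna == "flat"], 1)
  expect_equal(res$t_p[res$mirna == "flat"], 1)
  expect_equal(res$fold_change[res$mirna == "quad"], 4)
  # hand Welch t on log2 values: resistant {4.1, 3.9} vs sensitive {1.0, 1.1}
  a <- c(4.1, 3.9); b <- c(1.0, 1.1)
  tstat <- (mean(a) - mean(b)) / sqrt(var(a) / 2 + var(b) / 2)
  df <- (var(a) / 2 + var(b) / 2)^2 /
    ((var(a) / 2)^2 / 1 + (var(b) / 2)^2 / 1)
  p_hand <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  expect_equal(res$t_p[res$mirna == "mixed"], p_hand)
  expect_equal(res$fold_change[res$mirna == "mixed"],
               mean(2^a) / mean(2^b))
})

test_that("Spearman correlation is exact by enumeration for small n", {
  r1 <- resistance_correlation(1:7, (1:7)^3)
  expect_equal(r1$rho, 1)
  expect_true(r1$exact)
  expect_equal(r1$p, 2 / factorial(7))

  r2 <- resistance_correlation(1:7, rev(1:7))
  expect_equal(r2$rho, -1)
  expect_equal(r2$p, 2 / factorial(7))
})

test_that("exact Spearman p matches an independent enumeration oracle", {
  set.seed(11)
  for (n in c(5, 6)) {
    for (rep in 1:3) {
      x <- rnorm(n); y <- rnorm(n)
      got <- resistance_correlation(x, y)
      expect_equal(got$p, oracle_spearman_p(x, y), tolerance = 1e-12)
      # and cor.test agrees on tie-free data
      expect_equal(got$p,
                   cor.test(x, y, method = "spearman")$p.value,
                   tolerance = 1e-9)
    }
  }
})

test_that("Spearman screen is invariant under strictly monotone transforms", {
  set.seed(3)
  x <- rnorm(8); y <- rnorm(8)
  base <- resistance_correlation(x, y)
  tr <- resistance_correlation(exp(x), y^3 + 5 * y)
  expect_equal(tr$rho, base$rho)
  expect_equal(tr$p, base$p)
})

test_that("constant inputs are flagged, small n rejected", {
  expect_error(resistance_correlation(1:4, 1:4), ">= 5")
  r <- resistance_correlation(rep(1, 6), 1:6)
  expect_true(is.na(r$rho))
  expect_true(r$constant)
})

test_that("Storey estimator behaves at the extremes", {
  # everything tiny and significant: pi0 and FDR collapse to zero
  res <- storey_fdr(rep(1e-6, 50))
  expect_equal(res$pi0, 0)
  expect_equal(res$fdr_at_alpha, 0)
  # empty post-filter set
  expect_warning(res2 <- storey_fdr(runif(10), prefilter = rep(FALSE, 10)),
                 "pre-filter")
  expect_true(is.na(res2$pi0))
})

test_that("q-values are monotone non-decreasing in p", {
  set.seed(21)
  p <- c(runif(80), rbeta(20, 0.2, 5))
  q <- storey_fdr(p)$qvalues
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-12))
  expect_true(all(q >= p * storey_fdr(p)$pi0 * 0 - 1e-12))  # in [0,1]
  expect_true(all(q <= 1))
})

test_that("prefilter restricts estimation but not the table", {
  set.seed(4)
  p <- runif(40)
  mask <- rep(c(TRUE, FALSE), 20)
  res <- storey_fdr(p, prefilter = mask)
  expect_equal(res$m, 20L)
  expect_true(all(is.na(res$qvalues[!mask])))
  expect_true(all(!is.na(res$qvalues[mask])))
})

grid_results <- function(sp, tp, dr) {
  trs <- c("radiation", "cisplatin", "fluorouracil")
  lapply(setNames(trs, trs), function(tr) {
    i <- match(tr, trs)
    data.frame(mirna = "m1", t_p = tp[i], spearman_p = sp[i],
               direction = dr[i], stringsAsFactors = FALSE)
  })
}

test_that("uniqueness rule handles the canonical worked cases", {
  # clean radiation-unique call
  r <- classify_uniqueness(grid_results(c(0.03, 0.5, 0.2),
                                        c(0.02, 0.6, 0.9),
                                        c("up", "up", "up")))
  expect_equal(r$call, "unique:radiation")
  # two concordant significant treatments are shared
  r2 <- classify_uniqueness(grid_results(c(0.03, 0.04, 0.3),
                                         c(0.01, 0.01, 0.5),
                                         c("up", "up", "up")))
  expect_equal(r2$call, "shared:cisplatin+radiation")
  # opposite direction preserves uniqueness; smaller p wins the call
  r3 <- classify_uniqueness(grid_results(c(0.03, 0.04, 0.3),
                                         c(0.01, 0.01, 0.5),
                                         c("up", "down", "up")))
  expect_equal(r3$call, "unique:radiation")
})

test_that("uniqueness classification matches the brute-force evaluator", {
  trs <- c("radiation", "cisplatin", "fluorouracil")
  sp_grid <- c(0.01, 0.07, 0.2)
  tp_grid <- c(0.05, 0.2)
  dir_grid <- c("up_in_resistant", "down_in_resistant")
  cases <- expand.grid(sp1 = sp_grid, sp2 = sp_grid, sp3 = sp_grid,
                       tp1 = tp_grid, tp2 = tp_grid, tp3 = tp_grid,
                       d1 = dir_grid, d2 = dir_grid, d3 = dir_grid,
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    sp <- setNames(c(cs$sp1, cs$sp2, cs$sp3), trs)
    tp <- setNames(c(cs$tp1, cs$tp2, cs$tp3), trs)
    dr <- setNames(c(cs$d1, cs$d2, cs$d3), trs)
    got <- classify_uniqueness(grid_results(sp, tp, dr))$call
    want <- oracle_uniqueness(sp, tp, dr)
    if (!identical(got, want))
      fail(sprintf("case %d: got %s, want %s", i, got, want))
  }
  succeed()
})

test_that("outlier diagnostic flags a planted permuted line", {
  set.seed(8)
  sf <- setNames(seq(0.2, 0.9, length.out = 7), paste0("L", 1:7))
  m <- t(sapply(1:40, function(i) 2^(5 + 4 * sf + rnorm(7, 0, 0.3))))
  colnames(m) <- names(sf)
  clean <- outlier_diagnostic(m, sf)
  expect_false(any(clean$flagged))
  # plant a line whose expression sits where a much more resistant line
  # would: every miRNA becomes discordant at that line, and removing it
  # restores the correlation
  m2 <- m
  m2[, "L2"] <- 2^(5 + 4 * (1.1 - sf[["L2"]]) + rnorm(40, 0, 0.3))
  diag2 <- outlier_diagnostic(m2, sf)
  expect_equal(diag2$cell_line[which.max(diag2$influence)], "L2")
  expect_true(diag2$flagged[diag2$cell_line == "L2"])
})

test_that("resistance screen ties the stages together", {
  set.seed(12)
  prof <- do.call(rbind, lapply(1:8, function(i)
    aggregate_profile(rep(0.15 + i / 10, 3), cell_line = paste0("L", i),
                      treatment = "radiation")))
  des <- treatment_design(prof, "radiation")
  sf <- des$sf
  m <- rbind(
    planted = 2^(3 + 4 * sf + rnorm(8, 0, 0.2)),
    t(sapply(1:30, function(i) 2^(5 + rnorm(8, 0, 1)))))
  rownames(m) <- c("planted", sprintf("null%02d", 1:30))
  colnames(m) <- names(sf)
  scr <- resistance_screen(m, des)
  tab <- scr$table
  expect_lt(tab$spearman_p[tab$mirna == "planted"], 0.05)
  expect_gt(tab$fold_change[tab$mirna == "planted"], 1.5)
  expect_equal(tab$direction[tab$mirna == "planted"], "up_in_resistant")
  expect_true(is.finite(scr$pi0))
})
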