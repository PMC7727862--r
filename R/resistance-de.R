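# Association of normalized miRNA levels with treatment resistance.
#
# Two-stage screen: a Welch t-test between the two most resistant and two
# most sensitive cell lines finds candidate differences, then a Spearman
# correlation of level against survival fraction across the full panel
# checks that the difference is consistent rather than driven by the
# extremes.  FDR of the Spearman-significant set is estimated by Storey's
# pi0 method after a >1.5-fold pre-filter.

#' Build a treatment design from survival profiles
#'
#' Ranks cell lines by mean survival fraction for one treatment and picks
#' the two most resistant (highest SF) and the two most sensitive (lowest)
#' as the extremes pairs; both can be overridden when the analyst has named
#' the pairs explicitly.
#'
#' @param profiles Survival-profile data frame (see [survival_profiles()])
#'   restricted to one treatment, or with a `treatment` column to subset by.
#' @param treatment Treatment label to subset on (optional when `profiles`
#'   already holds one treatment).
#' @param resistant_pair,sensitive_pair Optional explicit cell-line pairs.
#' @return List of class `treatment_design` with `treatment`, `cell_lines`,
#'   `sf` (named vector of mean SFs), `resistant_pair`, `sensitive_pair`.
#' @export
treatment_design <- function(profiles, treatment = NULL,
                             resistant_pair = NULL, sensitive_pair = NULL) {
  if (!is.null(treatment))
    profiles <- profiles[profiles$treatment == treatment, , drop = FALSE]
  if (nrow(profiles) < 4L)
    stop_input("need >= 4 cell lines to define extremes pairs")
  if (is.null(treatment)) treatment <- profiles$treatment[1L]
  sf <- setNames(profiles$sf_mean, profiles$cell_line)
  ord <- names(sort(sf, decreasing = TRUE))
  if (is.null(resistant_pair)) resistant_pair <- ord[1:2]
  if (is.null(sensitive_pair)) sensitive_pair <- rev(ord)[1:2]
  if (length(intersect(resistant_pair, sensitive_pair)) > 0L)
    stop_input("resistant and sensitive pairs must be disjoint")
  structure(list(treatment = treatment, cell_lines = names(sf), sf = sf,
                 resistant_pair = resistant_pair,
                 sensitive_pair = sensitive_pair),
            class = "treatment_design")
}

#' @export
print.treatment_design <- function(x, ...) {
  cat("Treatment design:", x$treatment, "\n")
  cat("  resistant pair:", paste(x$resistant_pair, collapse = ", "),
      " sensitive pair:", paste(x$sensitive_pair, collapse = ", "), "\n")
  invisible(x)
}

#' Extremes t-test per miRNA
#'
#' Two-sided Welch (default) or pooled-variance t-test on log2 normalized
#' levels between the resistant and sensitive pairs. Fold change is
#' reported on the linear scale as mean(resistant)/mean(sensitive). When
#' both groups are constant with equal means the test is degenerate and
#' p = 1; constant groups with different means give p = 0.
#'
#' @param norm Normalized level matrix (miRNA x sample, samples = cell
#'   lines).
#' @param design A [treatment_design()] object.
#' @param var.equal Pooled-variance t-test instead of Welch? Default
#'   `FALSE`.
#' @return Data frame: `mirna`, `fold_change`, `t_p`, `direction`.
#' @export
extremes_ttest <- function(norm, design, var.equal = FALSE) {
  rp <- design$resistant_pair; sp <- design$sensitive_pair
  missing_cols <- setdiff(c(rp, sp), colnames(norm))
  if (length(missing_cols) > 0L)
    stop_input("cell lines absent from matrix: ",
               paste(missing_cols, collapse = ", "))
  res <- t(apply(norm, 1L, function(r) {
    a <- r[rp]; b <- r[sp]
    if (any(is.na(c(a, b))) || any(c(a, b) <= 0))
      return(c(NA_real_, NA_real_))
    fold <- mean(a) / mean(b)
    la <- log2(a); lb <- log2(b)
    p <- tryCatch(t.test(la, lb, var.equal = var.equal)$p.value,
                  error = function(e) {
                    if (isTRUE(all.equal(mean(la), mean(lb)))) 1 else 0
                  })
    c(fold, p)
  }))
  data.frame(mirna = rownames(norm), fold_change = res[, 1L], t_p = res[, 2L],
             direction = ifelse(res[, 1L] >= 1, "up_in_resistant",
                                "down_in_resistant"),
             stringsAsFactors = FALSE, row.names = NULL)
}

# All permutations of 1..n as an n!-row matrix (n <= 9); memoized, the
# matrix is reused across the whole screen.
perm_cache <- new.env(parent = emptyenv())

all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(perm_cache[[key]])) return(perm_cache[[key]])
  out <- all_permutations_impl(n)
  if (n <= 9L) perm_cache[[key]] <- out
  out
}

all_permutations_impl <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations_impl(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- k
    adj <- sub
    adj[adj >= k] <- adj[adj >= k] + 1L
    out[rows, -1L] <- adj
  }
  out
}

#' Spearman correlation of a miRNA's levels with the resistance axis
#'
#' Spearman rho with mid-ranks for ties. The two-sided p-value is exact by
#' full enumeration of rank permutations for n <= `exact_max` tie-free
#' observations, and uses the t approximation otherwise.
#'
#' @param levels Numeric vector of (normalized) levels across cell lines.
#' @param sf Survival fractions, same order and length.
#' @param exact_max Largest n for exact enumeration (default 9).
#' @return List `rho`, `p`, `n`, `exact`; `rho` is `NA` (flagged) when
#'   either vector is constant.
#' @export
resistance_correlation <- function(levels, sf, exact_max = 9) {
  keep <- is.finite(levels) & is.finite(sf)
  x <- levels[keep]; y <- sf[keep]
  n <- length(x)
  if (n < 5L) stop_input("need >= 5 paired observations, got ", n)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(rho = NA_real_, p = NA_real_, n = n, exact = FALSE,
                constant = TRUE))
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (!ties && n <= exact_max) {
    perms <- all_permutations(n)
    # rho for every permutation of the y-ranks against the fixed x-ranks;
    # with centred x-ranks the cross-term with the (constant) rank mean
    # vanishes, so each permuted rho is a plain dot product
    rc <- rx - mean(rx)
    denom <- sqrt(sum(rc^2) * sum((ry - mean(ry))^2))
    rho_perm <- (perms %*% rc)[, 1L] / denom
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    exact <- TRUE
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    exact <- FALSE
  }
  list(rho = rho, p = min(p, 1), n = n, exact = exact, constant = FALSE)
}

#' Storey false-discovery-rate estimation
#'
#' Estimates the null proportion pi0 = min(1, #\{p > lambda\} / (m (1 -
#' lambda))) from the p-values surviving an optional pre-filter, the FDR of
#' the significant set \{p <= alpha\} as pi0 * m * alpha / #\{p <= alpha\},
#' and per-p q-values (monotonized so q is non-decreasing in p).
#'
#' @param pvalues Numeric p-values in `[0, 1]`.
#' @param prefilter Optional logical mask (e.g. fold change beyond 1.5-fold
#'   in either direction); estimation uses only masked-in p-values, and
#'   q-values are `NA` for masked-out entries.
#' @param lambda Tuning parameter (default 0.5).
#' @param alpha Significance threshold defining the reported set (default
#'   0.05).
#' @return List `pi0`, `fdr_at_alpha`, `n_significant`, `qvalues`, `m`.
#' @export
storey_fdr <- function(pvalues, prefilter = NULL, lambda = 0.5,
                       alpha = 0.05) {
  check_number(lambda, "lambda", 0, 1)
  if (any(!is.na(pvalues) & (pvalues < 0 | pvalues > 1)))
    stop_input("p-values must lie in [0, 1]")
  if (is.null(prefilter)) prefilter <- rep(TRUE, length(pvalues))
  use <- prefilter & !is.na(pvalues)
  p <- pvalues[use]
  m <- length(p)
  if (m == 0L) {
    warning("no p-values survive the pre-filter; FDR undefined",
            call. = FALSE)
    return(list(pi0 = NA_real_, fdr_at_alpha = NA_real_,
                n_significant = 0L,
                qvalues = rep(NA_real_, length(pvalues)), m = 0L))
  }
  pi0 <- min(1, sum(p > lambda) / (m * (1 - lambda)))
  nsig <- sum(p <= alpha)
  fdr <- if (nsig > 0L) min(1, pi0 * m * alpha / nsig) else NA_real_
  ord <- order(p, decreasing = TRUE)
  q <- numeric(m)
  running <- Inf
  for (i in ord) {
    running <- min(running, pi0 * m * p[i] / sum(p <= p[i]))
    q[i] <- min(running, 1)
  }
  qv <- rep(NA_real_, length(pvalues))
  qv[use] <- q
  list(pi0 = pi0, fdr_at_alpha = fdr, n_significant = nsig, qvalues = qv,
       m = m)
}

#' Full resistance screen for one treatment
#'
#' Runs the extremes t-test and the cross-line Spearman screen on a
#' normalized level matrix, then attaches Storey FDR estimates (pi0, the
#' set-level FDR of the Spearman-significant set, and q-values) computed
#' after the fold-change pre-filter.
#'
#' @param norm Normalized level matrix (miRNA x cell line).
#' @param design A [treatment_design()] object.
#' @param fold_threshold Pre-filter: keep miRNAs with fold change >
#'   `fold_threshold` or < `1/fold_threshold` before FDR estimation
#'   (default 1.5). The DE table itself is never filtered.
#' @param alpha Significance threshold on Spearman p (default 0.05).
#' @param lambda Storey tuning parameter (default 0.5).
#' @param var.equal Passed to [extremes_ttest()].
#' @return List of class `resistance_screen`: `table` (per-miRNA DE table),
#'   `pi0`, `fdr_at_alpha`, `design`, `params`.
#' @export
resistance_screen <- function(norm, design, fold_threshold = 1.5,
                              alpha = 0.05, lambda = 0.5,
                              var.equal = FALSE) {
  tt <- extremes_ttest(norm, design, var.equal = var.equal)
  lines <- design$cell_lines
  missing_cols <- setdiff(lines, colnames(norm))
  if (length(missing_cols) > 0L)
    stop_input("cell lines absent from matrix: ",
               paste(missing_cols, collapse = ", "))
  sf <- design$sf[lines]
  sp <- lapply(rownames(norm), function(id) {
    lv <- log2(norm[id, lines])
    resistance_correlation(lv, sf)
  })
  tt$spearman_rho <- vapply(sp, `[[`, numeric(1), "rho")
  tt$spearman_p <- vapply(sp, `[[`, numeric(1), "p")
  mask <- !is.na(tt$fold_change) &
    (tt$fold_change > fold_threshold | tt$fold_change < 1 / fold_threshold)
  fdr <- storey_fdr(tt$spearman_p, prefilter = mask, lambda = lambda,
                    alpha = alpha)
  tt$q <- fdr$qvalues
  structure(list(table = tt, pi0 = fdr$pi0, fdr_at_alpha = fdr$fdr_at_alpha,
                 n_significant = fdr$n_significant, design = design,
                 params = list(fold_threshold = fold_threshold,
                               alpha = alpha, lambda = lambda)),
            class = "resistance_screen")
}

#' @export
print.resistance_screen <- function(x, ...) {
  cat("Resistance screen:", x$design$treatment, "\n")
  n_t <- sum(x$table$t_p <= x$params$alpha, na.rm = TRUE)
  n_sp <- sum(x$table$spearman_p <= x$params$alpha, na.rm = TRUE)
  cat("  ", n_t, "miRNAs differential between extremes pairs (t-test p <=",
      x$params$alpha, ")\n")
  cat("  ", n_sp, "consistent across the panel (Spearman p <=",
      x$params$alpha, ")\n")
  cat("   estimated pi0:", round(x$pi0, 3),
      " set-level FDR:", round(100 * x$fdr_at_alpha, 1), "%\n")
  invisible(x)
}

#' Classify treatment uniqueness of resistance-associated miRNAs
#'
#' A miRNA is uniquely associated with treatment T when its Spearman p for
#' T is below `alpha` and, for each other treatment, either both the
#' Spearman and the t-test p are at or above `relaxed` or the direction of
#' change is opposite. When opposite directions let several treatments
#' qualify, the one with the smallest Spearman p is assigned. A miRNA is
#' shared across the treatments where Spearman p < `alpha` with concordant
#' direction (two or more). Everything else is `none` — including
#' ambiguous-evidence miRNAs with a single significant treatment whose
#' independence conditions fail.
#'
#' @param results Named list (one element per treatment) of DE tables with
#'   columns `mirna`, `t_p`, `spearman_p`, `direction`.
#' @param alpha Association threshold on Spearman p (default 0.05).
#' @param relaxed Independence threshold for the other treatments (default
#'   0.1).
#' @return Data frame: `mirna`, `call` (`"unique:<T>"`, `"shared:<T1+T2>"`,
#'   or `"none"`), plus per-treatment evidence columns.
#' @export
classify_uniqueness <- function(results, alpha = 0.05, relaxed = 0.1) {
  treatments <- names(results)
  if (length(treatments) < 2L)
    stop_input("need results for at least two treatments")
  ids <- sort(unique(unlist(lapply(results, `[[`, "mirna"))))
  get <- function(tr, id, col) {
    tab <- results[[tr]]
    i <- match(id, tab$mirna)
    if (is.na(i)) NA else tab[[col]][i]
  }
  rows <- lapply(ids, function(id) {
    sp <- vapply(treatments, get, numeric(1), id = id, col = "spearman_p")
    tp <- vapply(treatments, get, numeric(1), id = id, col = "t_p")
    dr <- vapply(treatments, get, character(1), id = id, col = "direction")
    assoc <- !is.na(sp) & sp < alpha
    unique_ok <- vapply(treatments, function(tr) {
      if (is.na(sp[tr]) || sp[tr] >= alpha) return(FALSE)
      others <- setdiff(treatments, tr)
      all(vapply(others, function(o) {
        # missing results for another treatment: treated as non-associated
        if (is.na(sp[o]) || is.na(tp[o])) return(TRUE)
        indep <- sp[o] >= relaxed && tp[o] >= relaxed
        opposite <- !is.na(dr[o]) && !is.na(dr[tr]) && dr[o] != dr[tr]
        indep || opposite
      }, logical(1)))
    }, logical(1))
    call <- "none"
    if (any(unique_ok)) {
      cand <- treatments[unique_ok]
      call <- paste0("unique:", cand[which.min(sp[cand])])
    } else {
      conc <- treatments[assoc]
      if (length(conc) >= 2L) {
        # shared requires concordant direction among the associated set
        dirs <- dr[conc]
        if (length(unique(dirs[!is.na(dirs)])) == 1L) {
          call <- paste0("shared:", paste(sort(conc), collapse = "+"))
        } else {
          # split by direction; a concordant sub-set of >= 2 is shared
          for (d in unique(dirs)) {
            sub <- conc[!is.na(dirs) & dirs == d]
            if (length(sub) >= 2L)
              call <- paste0("shared:", paste(sort(sub), collapse = "+"))
          }
        }
      }
    }
    out <- data.frame(mirna = id, call = call, stringsAsFactors = FALSE)
    for (tr in treatments) {
      out[[paste0(tr, "_spearman_p")]] <- sp[tr]
      out[[paste0(tr, "_t_p")]] <- tp[tr]
      out[[paste0(tr, "_direction")]] <- dr[tr]
    }
    out
  })
  do.call(rbind, rows)
}

#' Leave-one-out influence of each cell line on the resistance correlation
#'
#' For each cell line, recomputes the Spearman rho of every miRNA against
#' the survival fractions without that line and reports the change in the
#' median absolute rho. A line whose removal raises the median |rho| by
#' more than `influence_threshold` is flagged as a candidate outlier
#' (advisory only; nothing is excluded automatically).
#'
#' @param norm Normalized level matrix (miRNA x cell line).
#' @param sf Named survival-fraction vector over the matrix's columns.
#' @param influence_threshold Flagging threshold on the influence score
#'   (default 0.1).
#' @return Data frame `cell_line`, `influence`, `flagged`.
#' @export
outlier_diagnostic <- function(norm, sf, influence_threshold = 0.1) {
  lines <- colnames(norm)
  if (length(lines) < 6L) stop_input("need >= 6 cell lines")
  sf <- sf[lines]
  med_abs_rho <- function(cols) {
    rhos <- apply(norm[, cols, drop = FALSE], 1L, function(r) {
      if (length(unique(r)) == 1L) return(NA_real_)
      cor(rank(r), rank(sf[cols]))
    })
    median(abs(rhos), na.rm = TRUE)
  }
  base <- med_abs_rho(lines)
  infl <- vapply(lines, function(l) med_abs_rho(setdiff(lines, l)) - base,
                 numeric(1))
  data.frame(cell_line = lines, influence = infl,
             flagged = infl > influence_threshold &
               infl >= max(infl) - 1e-12,
             stringsAsFactors = FALSE, row.names = NULL)
}
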