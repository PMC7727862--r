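# Serum small-EV miRNA count analysis: TMM between-sample normalization,
# Mann-Whitney differential expression between nCRT response classes, and
# cross-referencing against the cell-line resistance screen.

#' Trimmed-mean-of-M-values (TMM) normalization factors
#'
#' Implements the canonical TMM algorithm: the reference sample is the one
#' whose upper-quartile count/library-size ratio is closest to the mean of
#' that ratio; for every sample the factor is 2 to the doubly-trimmed
#' (30% on M, 5% on A), precision-weighted mean of gene-wise log2 ratios
#' against the reference, with genes at zero in either sample excluded;
#' factors are rescaled to geometric mean 1.
#'
#' @param counts Integer count matrix (features x samples).
#' @param lib_size Optional library sizes (default: column sums).
#' @param trim_m Two-sided trim fraction on the log-ratios M (default 0.30).
#' @param trim_a Two-sided trim fraction on the average abundances A
#'   (default 0.05).
#' @param do_weighting Use inverse asymptotic-variance weights (default
#'   `TRUE`).
#' @param ref_column Optional explicit reference sample index.
#' @return List of class `tmm_factors`: `factors` (named, geometric mean 1),
#'   `reference_sample`, `lib_size`.
#' @export
tmm_factors <- function(counts, lib_size = NULL, trim_m = 0.30,
                        trim_a = 0.05, do_weighting = TRUE,
                        ref_column = NULL) {
  x <- as.matrix(counts)
  if (anyNA(x) || any(x < 0)) stop_input("counts must be non-negative")
  if (ncol(x) < 2L) stop_input("need >= 2 samples")
  if (is.null(lib_size)) lib_size <- colSums(x)
  keep <- rowSums(x > 0) > 0L
  x <- x[keep, , drop = FALSE]
  if (nrow(x) == 0L) stop_input("no nonzero features")
  if (is.null(ref_column)) {
    f75 <- apply(x, 2L, quantile, probs = 0.75) / lib_size
    ref_column <- if (median(f75) < 1e-20) which.max(colSums(sqrt(x)))
                  else which.min(abs(f75 - mean(f75)))
  }
  ref <- x[, ref_column]
  n_ref <- lib_size[ref_column]
  f <- vapply(seq_len(ncol(x)), function(j) {
    obs <- x[, j]; n_obs <- lib_size[j]
    m <- log2((obs / n_obs) / (ref / n_ref))
    a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
    v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
    fin <- is.finite(m) & is.finite(a)
    if (!any(fin)) stop_input("sample ", j, " shares no nonzero feature ",
                              "with the reference")
    m <- m[fin]; a <- a[fin]; v <- v[fin]
    if (max(abs(m)) < 1e-6) return(1)
    n <- length(m)
    lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
    keep_g <- rank(m) >= lo_m & rank(m) <= hi_m &
      rank(a) >= lo_a & rank(a) <= hi_a
    fj <- if (do_weighting)
      sum(m[keep_g] / v[keep_g], na.rm = TRUE) /
        sum(1 / v[keep_g], na.rm = TRUE)
    else mean(m[keep_g], na.rm = TRUE)
    if (is.na(fj)) fj <- 0
    2^fj
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  structure(list(factors = f,
                 reference_sample = colnames(counts)[ref_column] %||%
                   ref_column,
                 lib_size = lib_size),
            class = "tmm_factors")
}

#' @export
print.tmm_factors <- function(x, ...) {
  cat("TMM factors (reference:", x$reference_sample, ")\n")
  print(round(x$factors, 4))
  invisible(x)
}

#' Normalize counts to TMM-adjusted counts per million
#'
#' Effective library size = library size x TMM factor; value =
#' count / effective size x 1e6.
#'
#' @param counts Count matrix (features x samples).
#' @param factors A [tmm_factors()] object, or a numeric vector of factors.
#' @return Normalized expression matrix.
#' @export
normalize_counts <- function(counts, factors) {
  if (inherits(factors, "tmm_factors")) {
    eff <- factors$lib_size * factors$factors
  } else {
    eff <- colSums(counts) * factors
  }
  if (any(eff <= 0)) stop_input("zero effective library size")
  sweep(as.matrix(counts), 2L, eff, "/") * 1e6
}

#' Filter low-abundance features before TMM
#'
#' Keeps features with at least `min_count` reads in at least
#' `min_prop` of the samples. TMM is undefined on all-zero rows, and
#' near-zero rows only add noise to the trimmed mean.
#'
#' @param counts Count matrix.
#' @param min_count Minimum count (default 5).
#' @param min_prop Minimum fraction of samples (default 0.25).
#' @return Filtered matrix.
#' @export
filter_low_counts <- function(counts, min_count = 5, min_prop = 0.25) {
  keep <- rowMeans(counts >= min_count) >= min_prop
  counts[keep, , drop = FALSE]
}

#' Mann-Whitney differential expression between two response classes
#'
#' Two-sided Mann-Whitney U test per feature with mid-ranks for ties:
#' exact when the smaller class has at most `exact_max` samples and the
#' feature has no ties, normal approximation with tie correction
#' otherwise. Direction is the sign of the median difference
#' (first class minus second).
#'
#' @param norm Normalized expression matrix (features x samples).
#' @param labels Factor/character vector over samples with exactly two
#'   classes; the first level is the reference for direction.
#' @param exact_max Largest min-class size for the exact distribution
#'   (default 8).
#' @return Data frame: `mirna`, `U`, `p`, `direction`, `q` (BH, for
#'   information only — the screen operates on raw p).
#' @export
mwu_de <- function(norm, labels, exact_max = 8) {
  g <- as.factor(labels)
  if (nlevels(g) != 2L) stop_input("labels must define exactly two classes")
  if (any(table(g) < 2L)) stop_input("both classes need >= 2 samples")
  a_idx <- g == levels(g)[1L]; b_idx <- g == levels(g)[2L]
  res <- t(apply(norm, 1L, function(r) {
    a <- r[a_idx]; b <- r[b_idx]
    if (length(unique(c(a, b))) == 1L) return(c(NA_real_, 1, 0))
    exact <- min(length(a), length(b)) <= exact_max &&
      anyDuplicated(c(a, b)) == 0L
    wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = !exact))
    c(unname(wt$statistic), wt$p.value, median(a) - median(b))
  }))
  data.frame(mirna = rownames(norm), U = res[, 1L], p = res[, 2L],
             direction = ifelse(res[, 3L] >= 0,
                                paste0("up_in_", levels(g)[1L]),
                                paste0("down_in_", levels(g)[1L])),
             q = p.adjust(res[, 2L], "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-reference cell-line resistance hits with serum differential
#' expression
#'
#' Cell-line candidates (resistance-screen p below `cell_p_max`) are looked
#' up in the serum DE results. The candidate tier reflects the strength of
#' the cell-line evidence — `"strict"` for cell p below `cell_strict`,
#' `"relaxed"` for the widened band up to `cell_p_max` — and a serum hit
#' requires serum p below `serum_alpha` (a suggestive flag is set below
#' `serum_suggestive`). Direction concordance is annotated but never used
#' as a filter — cell-line and circulating-vesicle levels of the same
#' miRNA can legitimately move in opposite directions. miRNA names are
#' case-normalized before matching and unmatched candidates are reported
#' in the result, not dropped silently.
#'
#' @param cell_hits Data frame with columns `mirna`, `spearman_p` (or `p`),
#'   `direction`.
#' @param serum Data frame from [mwu_de()].
#' @param cell_strict,cell_p_max Cell-line evidence tiers (defaults 0.05
#'   and 0.1); candidates need cell p below `cell_p_max`.
#' @param serum_alpha Serum significance threshold for a hit (default
#'   0.05).
#' @param serum_suggestive Wider serum threshold for the suggestive flag
#'   (default 0.1).
#' @return Data frame: `mirna`, `cell_line_p`, `cell_tier` (`"strict"`,
#'   `"relaxed"`, or `"unmatched"` when absent from the serum table),
#'   `serum_p`, `serum_hit`, `serum_suggestive`, `direction_concordant`.
#' @export
crossref_serum <- function(cell_hits, serum, cell_strict = 0.05,
                           cell_p_max = 0.1, serum_alpha = 0.05,
                           serum_suggestive = 0.1) {
  cp <- cell_hits$spearman_p %||% cell_hits$p
  if (is.null(cp)) stop_input("cell_hits needs a 'spearman_p' or 'p' column")
  cand <- !is.na(cp) & cp < cell_p_max
  ids <- cell_hits$mirna[cand]
  cp <- cp[cand]
  cdir <- (cell_hits$direction %||% rep(NA_character_, nrow(cell_hits)))[cand]
  key <- tolower(serum$mirna)
  rows <- lapply(seq_along(ids), function(i) {
    tier <- if (cp[i] < cell_strict) "strict" else "relaxed"
    j <- match(tolower(ids[i]), key)
    if (is.na(j))
      return(data.frame(mirna = ids[i], cell_line_p = cp[i],
                        cell_tier = "unmatched", serum_p = NA_real_,
                        serum_hit = NA, serum_suggestive = NA,
                        direction_concordant = NA, stringsAsFactors = FALSE))
    sp <- serum$p[j]
    conc <- if (is.na(cdir[i]) || is.na(serum$direction[j])) NA
            else grepl("^up", cdir[i]) == grepl("^up", serum$direction[j])
    data.frame(mirna = ids[i], cell_line_p = cp[i], cell_tier = tier,
               serum_p = sp,
               serum_hit = !is.na(sp) && sp < serum_alpha,
               serum_suggestive = !is.na(sp) && sp < serum_suggestive,
               direction_concordant = conc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
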