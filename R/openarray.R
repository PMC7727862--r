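# qPCR Ct -> relative level conversion, housekeeping-miRNA selection, and
# geometric-mean normalization for OpenArray-style panels.
#
# A Ct matrix has miRNAs in rows and samples in columns; NA encodes
# "undetected after max_cycles cycles of amplification".  Relative levels
# are 2^(max_cycles - Ct), so one extra cycle to threshold means half the
# template.

#' Convert Ct values to relative expression levels
#'
#' `2^(max_cycles - ct)`: a Ct equal to the cycle ceiling maps to level 1,
#' each cycle earlier doubles the level.
#'
#' @param ct Numeric Ct values (vector or matrix); `NA` = undetected.
#' @param max_cycles PCR cycle ceiling (default 40).
#' @param undetected How to treat `NA` Ct: `"floor"` maps it to level 1
#'   (i.e. Ct = `max_cycles`), `"na"` propagates `NA`.
#' @return Relative levels, same shape as `ct`.
#' @examples
#' relative_level(c(40, 39, 30))  # 1, 2, 1024
#' @export
relative_level <- function(ct, max_cycles = 40, undetected = c("floor", "na")) {
  undetected <- match.arg(undetected)
  check_number(max_cycles, "max_cycles", lower = 1)
  bad <- !is.na(ct) & (ct <= 0 | ct > max_cycles)
  if (any(bad))
    stop_input("Ct values must lie in (0, max_cycles]; offending value: ",
               ct[bad][1L])
  lev <- 2^(max_cycles - ct)
  if (undetected == "floor") lev[is.na(ct)] <- 1
  lev
}

#' Geometric mean
#'
#' `exp(mean(log(x)))` for strictly positive values.
#'
#' @param x Positive numeric vector.
#' @param na.rm Drop `NA`s first?
#' @return The geometric mean.
#' @examples
#' geometric_mean(c(4, 16))  # 8
#' @export
geometric_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0L) stop_input("geometric_mean of an empty vector")
  if (any(is.na(x)) || any(x <= 0))
    stop_input("geometric_mean requires strictly positive values")
  exp(mean(log(x)))
}

#' Read a Ct matrix from TSV
#'
#' First column: miRNA identifier; remaining columns: samples; `NA` encodes
#' undetected assays.
#'
#' @param path Path to a tab-separated file.
#' @param max_cycles Cycle ceiling used for validation (default 40).
#' @return Numeric matrix of Ct values with miRNA rownames.
#' @export
read_ct_matrix <- function(path, max_cycles = 40) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_input("Ct matrix needs an id column and >=1 sample")
  raw <- as.matrix(df[, -1L, drop = FALSE])
  m <- suppressWarnings(structure(as.numeric(raw), dim = dim(raw),
                                  dimnames = dimnames(raw)))
  corrupt <- which(is.na(m) & !(is.na(raw) | raw %in% c("NA", "")),
                   arr.ind = TRUE)
  if (nrow(corrupt) > 0L)
    stop_input("non-numeric Ct value '", raw[corrupt[1L, , drop = FALSE]],
               "' at row ", corrupt[1L, 1L] + 1L, " of ", path)
  rownames(m) <- df[[1L]]
  if (any(duplicated(rownames(m))))
    stop_input("duplicated miRNA identifiers in ", path)
  bad <- !is.na(m) & (m <= 0 | m > max_cycles)
  if (any(bad))
    stop_input("Ct values outside (0, ", max_cycles, "] in ", path)
  m
}

#' Select housekeeping miRNAs from a Ct matrix
#'
#' Candidates must satisfy four criteria: (i) detected in all samples at
#' high levels (median Ct below `median_ct_max`); (ii) no group difference
#' (two-sided Mann-Whitney U, p above `group_p_min`) when a two-group sample
#' partition is supplied; (iii) low variability — SD of the candidate's log2
#' relative levels below twice the SD of that statistic over all candidates
#' — and no outlier sample (level outside `fold_window`-fold of the
#' candidate's mean); (iv) Pearson correlation above `corr_min` between the
#' candidate's log2 level and the geometric-mean reference of the current
#' candidate set, iterated to a fixed point by backward elimination (the
#' worst-correlated candidate is dropped and the reference recomputed until
#' every remaining candidate passes).
#'
#' @param ct Ct matrix (miRNA x sample, `NA` = undetected).
#' @param groups Optional factor/vector over samples with exactly two levels
#'   for criterion (ii); with `NULL` or one group the criterion is skipped
#'   with a warning.
#' @param median_ct_max Criterion (i) threshold, cycles (default 30).
#' @param group_p_min Criterion (ii) threshold (default 0.1).
#' @param fold_window Criterion (iii) outlier window, fold of the mean
#'   (default 5).
#' @param corr_min Criterion (iv) threshold (default 0.7).
#' @param max_cycles Cycle ceiling (default 40).
#' @param iterate Iterate criterion (iv) to a fixed point (default `TRUE`);
#'   `FALSE` applies it once against the initial reference.
#' @return A list of class `hkg_selection`: `report` (one row per candidate
#'   with per-criterion outcomes), `selected` (ids passing all four).
#' @export
select_housekeeping <- function(ct, groups = NULL, median_ct_max = 30,
                                group_p_min = 0.1, fold_window = 5,
                                corr_min = 0.7, max_cycles = 40,
                                iterate = TRUE) {
  if (!is.matrix(ct) || is.null(rownames(ct)))
    stop_input("ct must be a matrix with miRNA rownames")
  if (ncol(ct) < 2L) stop_input("need at least two samples")
  ids <- rownames(ct)
  lev <- relative_level(ct, max_cycles, undetected = "na")

  detected_all <- apply(ct, 1L, function(r) all(!is.na(r)))
  median_ct <- apply(ct, 1L, median, na.rm = TRUE)
  crit1 <- detected_all & median_ct < median_ct_max

  two_groups <- !is.null(groups) && length(unique(stats::na.omit(groups))) == 2L
  if (!two_groups) {
    if (!is.null(groups))
      warning("groups does not define two classes; criterion (ii) skipped",
              call. = FALSE)
    group_p <- rep(NA_real_, nrow(ct))
    crit2 <- rep(TRUE, nrow(ct))
  } else {
    g <- as.factor(groups)
    group_p <- apply(lev, 1L, function(r) {
      a <- r[g == levels(g)[1L]]; b <- r[g == levels(g)[2L]]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < 1L || length(b) < 1L) return(NA_real_)
      suppressWarnings(wilcox.test(a, b, exact = NULL)$p.value)
    })
    crit2 <- !is.na(group_p) & group_p > group_p_min
    crit2[is.na(group_p)] <- FALSE
  }

  # variability is measured as the SD of log2 relative levels (the scale
  # on which qPCR noise is additive); the linear-scale CV saturates for
  # highly variable assays and blurs the stable/variable boundary
  cv <- apply(lev, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r) < 2L) return(NA_real_)
    sd(log2(r))
  })
  variability_cut <- 2 * sd(cv, na.rm = TRUE)
  outlier <- apply(lev, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0L) return(TRUE)
    m <- mean(r)
    any(r < m / fold_window | r > m * fold_window)
  })
  crit3 <- !is.na(cv) & cv < variability_cut & !outlier

  candidates <- ids[crit1 & crit2 & crit3]
  corr <- rep(NA_real_, nrow(ct)); names(corr) <- ids
  dropped_iv <- character(0)
  if (length(candidates) > 0L) {
    log_lev <- log2(lev)
    current <- candidates
    # backward elimination: drop the worst-correlated candidate, refresh
    # the reference, repeat; the candidate set shrinks monotonically so
    # the fixed point is reached in < length(candidates) rounds
    for (round in seq_len(length(candidates) + 1L)) {
      ref <- apply(log_lev[current, , drop = FALSE], 2L, mean, na.rm = TRUE)
      r_now <- vapply(current, function(id) {
        v <- log_lev[id, ]
        # a zero-variance candidate is perfectly stable; its correlation
        # with any reference is undefined, not disqualifying
        if (sd(v, na.rm = TRUE) == 0) return(1)
        suppressWarnings(cor(v, ref, use = "pairwise.complete.obs",
                             method = "pearson"))
      }, numeric(1))
      corr[current] <- r_now
      fail <- current[is.na(r_now) | r_now <= corr_min]
      if (length(fail) == 0L) break
      if (!iterate) {
        dropped_iv <- union(dropped_iv, fail)
        current <- setdiff(current, fail)
        break
      }
      worst <- current[which.min(replace(r_now, is.na(r_now), -Inf))]
      dropped_iv <- union(dropped_iv, worst)
      current <- setdiff(current, worst)
      if (length(current) == 0L) break
    }
    selected <- current
  } else selected <- character(0)

  crit4 <- ids %in% selected | (ids %in% candidates & !(ids %in% dropped_iv))
  passed <- ids %in% selected
  criteria_failed <- vapply(seq_along(ids), function(i) {
    f <- c(if (!crit1[i]) "median_ct",
           if (!crit2[i]) "group_test",
           if (!crit3[i]) "variability",
           if (ids[i] %in% dropped_iv) "geomean_corr")
    paste(f, collapse = ";")
  }, character(1))

  report <- data.frame(
    mirna = ids, median_ct = median_ct, detected_all = detected_all,
    group_test_p = group_p, log2_sd = cv, outlier_found = outlier,
    corr_with_geomean = corr, passed = passed,
    criteria_failed = criteria_failed, stringsAsFactors = FALSE,
    row.names = NULL)

  if (length(selected) == 0L) {
    message_report <- paste(utils::capture.output(print(head(report))),
                            collapse = "\n")
    stop("no housekeeping candidate survives all four criteria\n",
         message_report)
  }
  structure(list(report = report, selected = selected,
                 variability_cut = variability_cut), class = "hkg_selection")
}

#' @export
print.hkg_selection <- function(x, ...) {
  cat("Housekeeping selection:", length(x$selected), "of",
      nrow(x$report), "candidates pass all four criteria\n")
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Normalize relative levels by the geometric mean of housekeeping miRNAs
#'
#' Every value in a sample is divided by that sample's geometric mean over
#' the housekeeping rows, cancelling sample-level scale (loading, input
#' amount, global efficiency).
#'
#' @param levels Relative-level matrix (miRNA x sample).
#' @param hkg Character vector of housekeeping miRNA ids; all must be
#'   present and detected (non-`NA`, positive) in every sample.
#' @return Normalized matrix with attribute `hkg`.
#' @export
normalize_levels <- function(levels, hkg) {
  if (!is.matrix(levels) || is.null(rownames(levels)))
    stop_input("levels must be a matrix with miRNA rownames")
  missing_ids <- setdiff(hkg, rownames(levels))
  if (length(missing_ids) > 0L)
    stop_input("housekeeping ids absent from matrix: ",
               paste(missing_ids, collapse = ", "))
  sub <- levels[hkg, , drop = FALSE]
  bad <- which(is.na(sub) | sub <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop_input("housekeeping miRNA ", hkg[bad[1L, 1L]],
               " undetected in sample ", colnames(levels)[bad[1L, 2L]])
  divisors <- apply(sub, 2L, geometric_mean)
  out <- sweep(levels, 2L, divisors, "/")
  attr(out, "hkg") <- hkg
  out
}
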