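# Small-RNA -> mRNA interaction screening after perturbation: negative
# correlation across paired expression profiles, multi-database consensus
# filtering, seed-table joins for piRNAs, and permutation gene-set
# enrichment.

#' Screen paired small-RNA / mRNA profiles for negative correlations
#'
#' Computes the correlation of every small RNA against every mRNA across
#' the aligned samples (log2 of the supplied expression values for the
#' Pearson default) and keeps pairs with r strictly below `r_threshold`.
#' With a handful of samples this is a filter, not a test: no p-values are
#' attached.
#'
#' @param small_rna,mrna Expression matrices (feature x sample) with
#'   identical sample columns in identical order.
#' @param r_threshold Correlation ceiling (default -0.5).
#' @param method `"pearson"` (on log2 values; default) or `"spearman"`.
#' @param log2_transform Log2-transform before Pearson correlation?
#'   Default `TRUE`; a pseudocount of 1 guards zeros.
#' @return Data frame of class `interaction_candidates`: `small_rna`,
#'   `mrna`, `r`. Constant features are skipped and listed in the
#'   `skipped` attribute.
#' @export
negative_correlation_screen <- function(small_rna, mrna, r_threshold = -0.5,
                                        method = c("pearson", "spearman"),
                                        log2_transform = TRUE) {
  method <- match.arg(method)
  if (ncol(small_rna) != ncol(mrna) ||
      !identical(colnames(small_rna), colnames(mrna)))
    stop_input("small_rna and mrna matrices must share identical, ",
               "identically ordered sample columns")
  if (ncol(small_rna) < 4L) stop_input("need >= 4 aligned samples")
  xs <- as.matrix(small_rna); xm <- as.matrix(mrna)
  if (method == "pearson" && log2_transform) {
    xs <- log2(xs + 1); xm <- log2(xm + 1)
  }
  const_s <- apply(xs, 1L, function(r) length(unique(r)) == 1L)
  const_m <- apply(xm, 1L, function(r) length(unique(r)) == 1L)
  skipped <- c(rownames(xs)[const_s], rownames(xm)[const_m])
  xs <- xs[!const_s, , drop = FALSE]; xm <- xm[!const_m, , drop = FALSE]
  rmat <- if (method == "pearson") cor(t(xs), t(xm))
          else cor(t(apply(xs, 1L, rank)), t(apply(xm, 1L, rank)))
  hits <- which(rmat < r_threshold, arr.ind = TRUE)
  out <- data.frame(small_rna = rownames(xs)[hits[, 1L]],
                    mrna = rownames(xm)[hits[, 2L]],
                    r = rmat[hits], stringsAsFactors = FALSE)
  out <- out[order(out$r), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("interaction_candidates", "data.frame")
  out
}

#' Read a local target-interaction database table
#'
#' TSV with columns `source`, `small_rna`, `mrna`: one row per (database,
#' interaction) record. Identifiers are case-normalized on load.
#'
#' @param path Path to the TSV file.
#' @return Data frame `source`, `small_rna`, `mrna`.
#' @export
read_target_db <- function(path) {
  db <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("source", "small_rna", "mrna")
  if (!all(need %in% names(db)))
    stop_input("target database needs columns: ",
               paste(need, collapse = ", "))
  db$small_rna <- tolower(db$small_rna)
  db$mrna <- toupper(db$mrna)
  db
}

#' Filter interaction candidates by multi-database consensus
#'
#' Retains candidate pairs recorded in at least `min_support` of the
#' supplied databases, annotating the support count and the database
#' names. Raising `min_support` can only shrink the result.
#'
#' @param candidates Data frame with `small_rna`, `mrna` columns (e.g. from
#'   [negative_correlation_screen()]).
#' @param db Data frame `source`, `small_rna`, `mrna` (see
#'   [read_target_db()]); multiple tables can be `rbind`-ed.
#' @param min_support Minimum number of distinct databases (default 3).
#' @return Candidates subset with `db_support` and `db_names` columns.
#' @export
db_consensus_filter <- function(candidates, db, min_support = 3) {
  if (nrow(db) == 0L || length(unique(db$source)) == 0L)
    stop_input("empty database catalogue")
  key <- paste(tolower(candidates$small_rna), toupper(candidates$mrna),
               sep = "\r")
  dbkey <- paste(tolower(db$small_rna), toupper(db$mrna), sep = "\r")
  support <- lapply(key, function(k) sort(unique(db$source[dbkey == k])))
  candidates$db_support <- vapply(support, length, integer(1))
  candidates$db_names <- vapply(support, paste, character(1), collapse = ";")
  out <- candidates[candidates$db_support >= min_support, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Join piRNA seed-match candidates from a precomputed target table
#'
#' No de-novo prediction happens here: the table holds precomputed
#' seed-to-target rows (e.g. exported from an external prediction tool)
#' and this function only joins the input piRNAs against it.
#'
#' @param pirnas Character vector of piRNA identifiers.
#' @param seed_table Data frame with columns `small_rna` (piRNA id) and
#'   `mrna` (target gene).
#' @return Data frame of matched `small_rna`, `mrna` pairs.
#' @export
seed_match_targets <- function(pirnas, seed_table) {
  if (is.null(seed_table) || !all(c("small_rna", "mrna") %in%
                                  names(seed_table)))
    stop_input("seed_table with columns small_rna, mrna required")
  out <- seed_table[tolower(seed_table$small_rna) %in% tolower(pirnas),
                    c("small_rna", "mrna"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a GMT gene-set collection
#'
#' @param path Path to a GMT file (set name, description, member genes).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Permutation gene-set enrichment with hypergeometric scoring
#'
#' For each pathway the score is the hypergeometric upper-tail probability
#' of the observed overlap between the query set and the pathway within
#' the universe. The empirical p-value compares that score against scores
#' of `n_perm` random query sets of the same size drawn from the universe:
#' `(1 + #\{permuted score <= observed\}) / (n_perm + 1)`, so the smallest
#' attainable value is `1/(n_perm + 1)`. Benjamini-Hochberg q-values
#' across pathways are attached for information.
#'
#' @param query Character vector of query genes. Genes outside the
#'   universe are flagged and dropped.
#' @param collection Named list of gene sets (see [read_gmt()]).
#' @param universe Character vector of background genes (default: union of
#'   the collection and the query).
#' @param n_perm Number of permutations (default 5000).
#' @param seed Integer seed for the permutations.
#' @return Data frame of class `enrichment_result`: `pathway`, `overlap`,
#'   `pathway_size`, `score` (hypergeometric tail), `empirical_p`, `q`,
#'   `n_perm`.
#' @export
enrich <- function(query, collection, universe = NULL, n_perm = 5000,
                   seed = 1) {
  if (length(collection) == 0L || any(lengths(collection) == 0L))
    stop_input("collection must be a non-empty list of non-empty sets")
  if (is.null(universe)) universe <- union(unlist(collection), query)
  universe <- unique(universe)
  outside <- setdiff(query, universe)
  if (length(outside) > 0L)
    warning(length(outside), " query genes outside the universe dropped",
            call. = FALSE)
  query <- intersect(unique(query), universe)
  n_u <- length(universe); n_q <- length(query)
  sets <- lapply(collection, function(s) intersect(unique(s), universe))
  if (n_q == 0L) {
    warning("empty query after intersection with universe; all p = 1",
            call. = FALSE)
    return(structure(data.frame(pathway = names(collection),
                                overlap = 0L,
                                pathway_size = lengths(sets),
                                score = 1, empirical_p = 1, q = 1,
                                n_perm = n_perm, stringsAsFactors = FALSE),
                     class = c("enrichment_result", "data.frame")))
  }
  member <- lapply(sets, function(s) universe %in% s)
  q_idx <- match(query, universe)
  obs_overlap <- vapply(member, function(m) sum(m[q_idx]), integer(1))
  sizes <- lengths(sets)
  score <- phyper(obs_overlap - 1L, sizes, n_u - sizes, n_q,
                  lower.tail = FALSE)
  # permute query membership over the universe with fixed query size; the
  # hypergeometric score is monotone decreasing in overlap, so
  # "permuted score <= observed" is "permuted overlap >= observed"
  set.seed(seed)
  perm_overlaps <- matrix(0L, n_perm, length(sets))
  member_mat <- do.call(cbind, member)
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n_u, n_q)
    perm_overlaps[b, ] <- colSums(member_mat[idx, , drop = FALSE])
  }
  emp_p <- vapply(seq_along(sets), function(k)
    (1 + sum(perm_overlaps[, k] >= obs_overlap[k])) / (n_perm + 1),
    numeric(1))
  structure(data.frame(pathway = names(collection), overlap = obs_overlap,
                       pathway_size = sizes, score = score,
                       empirical_p = emp_p,
                       q = p.adjust(emp_p, "BH"), n_perm = n_perm,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("enrichment_result", "data.frame"))
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Permutation gene-set enrichment (", x$n_perm[1L], " permutations)\n",
      sep = "")
  print.data.frame(x[order(x$empirical_p), ], ...)
  invisible(x)
}
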