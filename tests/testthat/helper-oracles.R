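# Independent oracles used to check package statistics by brute force.
# These deliberately avoid the package's own code paths.

# Recursive list-based permutation generator (independent of the
# package's iterative matrix construction).
oracle_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in oracle_perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# Exact two-sided Spearman p by full enumeration of y orderings.
oracle_spearman_p <- function(x, y) {
  obs <- abs(cor(rank(x), rank(y)))
  rhos <- vapply(oracle_perms(y), function(yy) cor(rank(x), rank(yy)),
                 numeric(1))
  mean(abs(rhos) >= obs - 1e-12)
}

# Exact two-sided Mann-Whitney p by enumeration of group assignments.
oracle_mwu_p <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  u_stat <- function(g1) {
    r <- rank(pool)
    sum(r[g1]) - n1 * (n1 + 1) / 2
  }
  obs <- u_stat(seq_len(n1))
  mu <- n1 * (length(b)) / 2
  combos <- combn(length(pool), n1)
  us <- apply(combos, 2L, u_stat)
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# Literal rule evaluator for treatment uniqueness: re-derived from the
# rule text, structured differently from the package implementation.
oracle_uniqueness <- function(sp, tp, dr, alpha = 0.05, relaxed = 0.1) {
  trs <- names(sp)
  ok <- logical(length(trs)); names(ok) <- trs
  for (tr in trs) {
    if (sp[tr] >= alpha) next
    others_ok <- TRUE
    for (o in setdiff(trs, tr)) {
      independent <- (sp[o] >= relaxed) && (tp[o] >= relaxed)
      opposite <- dr[o] != dr[tr]
      if (!independent && !opposite) others_ok <- FALSE
    }
    ok[tr] <- others_ok
  }
  if (any(ok)) {
    winners <- trs[ok]
    return(paste0("unique:", winners[order(sp[winners])][1L]))
  }
  assoc <- trs[sp < alpha]
  if (length(assoc) >= 2L) {
    for (d in unique(dr[assoc])) {
      grp <- assoc[dr[assoc] == d]
      if (length(grp) >= 2L)
        return(paste0("shared:", paste(sort(grp), collapse = "+")))
    }
  }
  "none"
}

# Small random count matrix for TMM checks.
random_count_matrix <- function(seed) {
  set.seed(seed)
  ng <- sample(20:80, 1)
  ns <- sample(2:6, 1)
  mu <- 2^runif(ng, 1, 10)
  m <- sapply(seq_len(ns), function(j)
    rnbinom(ng, mu = mu * runif(1, 0.5, 2), size = 3))
  rownames(m) <- sprintf("g%03d", seq_len(ng))
  colnames(m) <- sprintf("s%d", seq_len(ns))
  m
}
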