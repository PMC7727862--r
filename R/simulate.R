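# Synthetic-data generators with planted ground truth.  Every input the
# pipeline consumes can be generated here, so all stages are testable
# end-to-end with no external downloads.
#
# The default scenario mirrors the study design the pipeline is built for:
# a 112-miRNA qPCR panel over 8 cell lines and 3 treatments, ~187 serum
# small-EV miRNAs over 39 patients in two response classes, and a
# 100 x 500 paired small-RNA/mRNA matrix over 3 control + 3 inhibitor
# samples.

#' Scenario configuration for the synthetic generators
#'
#' All dimensions, effect sizes and noise levels of the planted-truth
#' generators, reproducible from a single integer seed.
#'
#' @param seed Master seed; each generator derives its own stream from it.
#' @param n_mirna Panel size of the qPCR Ct matrix (default 112).
#' @param n_cell_lines Number of cell lines (default 8).
#' @param n_hkg Planted stable housekeeping candidates (default 10).
#' @param n_undetected miRNAs undetected in every line (default 5).
#' @param n_resistance_mirna Planted resistance-correlated miRNAs per
#'   treatment (default 12).
#' @param effect_size Ct shift per unit survival fraction for planted
#'   resistance miRNAs, cycles (default 6; expression up in resistant
#'   lines).
#' @param noise_sd Assay noise on the Ct scale, cycles (default 0.5).
#' @param hkg_noise_sd Residual noise of housekeeping candidates, cycles
#'   (default 0.15).
#' @param background_sd Biological variability of non-planted miRNAs,
#'   cycles (default 2).
#' @param sample_offset_sd Per-sample global Ct offset (RNA input /
#'   loading variation), cycles (default 0.5).
#' @param sf_range Range spanned by per-line mean survival fractions
#'   (default `c(0.2, 0.9)`).
#' @param sf_rep_sd Replicate SD of survival fractions (default 0.05).
#' @param inconsistent_line Plant one cell line with a wildly variable
#'   radiation response? Default `FALSE`.
#' @param treatments Treatment labels (default radiation, cisplatin,
#'   fluorouracil).
#' @param n_serum_mirna Serum panel size (default 187).
#' @param n_good,n_poor Patients per response class (defaults 20 and 19).
#' @param nb_dispersion Negative-binomial dispersion of serum counts
#'   (default 0.3).
#' @param n_planted_serum_de Planted serum DE miRNAs (default 15).
#' @param lfc_serum Planted serum log2 fold change (default 2).
#' @param lib_size_base Median library size (default 1e6 reads).
#' @param lib_size_fold Approximate fold range of library sizes (default 3).
#' @param n_small_rna,n_mrna Paired-expression dimensions (defaults 100
#'   and 500).
#' @param n_pairs Planted anti-correlated small-RNA/mRNA pairs (default
#'   10).
#' @param r_target Target correlation of planted pairs (default -0.9).
#' @param n_per_group Samples per perturbation arm (default 3).
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1, n_mirna = 112, n_cell_lines = 8,
                            n_hkg = 10, n_undetected = 5,
                            n_resistance_mirna = 12, effect_size = 6,
                            noise_sd = 0.5, hkg_noise_sd = 0.15,
                            background_sd = 2, sample_offset_sd = 0.5,
                            sf_range = c(0.2, 0.9), sf_rep_sd = 0.05,
                            inconsistent_line = FALSE,
                            treatments = c("radiation", "cisplatin",
                                           "fluorouracil"),
                            n_serum_mirna = 187, n_good = 20, n_poor = 19,
                            nb_dispersion = 0.3, n_planted_serum_de = 15,
                            lfc_serum = 2, lib_size_base = 1e6,
                            lib_size_fold = 3,
                            n_small_rna = 100, n_mrna = 500, n_pairs = 10,
                            r_target = -0.9, n_per_group = 3) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_mirna >= cfg$n_hkg + cfg$n_undetected +
              length(treatments) * n_resistance_mirna,
            cfg$noise_sd > 0, cfg$n_cell_lines >= 5,
            r_target < 0, r_target >= -1)
  class(cfg) <- "scenario_config"
  cfg
}

# Deterministic sub-seed per generator, kept well below 2^31.
sub_seed <- function(cfg, offset) (cfg$seed * 1000L + offset) %% 2147483647L

#' Generate survival profiles with known per-line resistance
#'
#' Per-line mean survival fractions are evenly spread over `sf_range`, in
#' an independently shuffled line order per treatment, with three
#' replicate experiments (Normal noise, `sf_rep_sd`). With
#' `inconsistent_line = TRUE` one line's radiation replicates are spread
#' wide enough to trip the consistency flag.
#'
#' @param cfg A [scenario_config()].
#' @return List: `profiles` (a `mirres_profiles` data frame over all
#'   treatments), `sf_true` (matrix line x treatment of true mean SFs).
#' @export
generate_survival_profiles <- function(cfg) {
  set.seed(sub_seed(cfg, 1L))
  lines <- sprintf("CL%02d", seq_len(cfg$n_cell_lines))
  sf_levels <- seq(cfg$sf_range[1L], cfg$sf_range[2L],
                   length.out = cfg$n_cell_lines)
  sf_true <- sapply(cfg$treatments, function(tr) sf_levels[sample.int(
    cfg$n_cell_lines)])
  rownames(sf_true) <- lines
  rows <- list()
  for (tr in cfg$treatments) {
    for (i in seq_along(lines)) {
      reps <- pmax(0.01, rnorm(3L, sf_true[i, tr], cfg$sf_rep_sd))
      if (cfg$inconsistent_line && tr == cfg$treatments[1L] && i == 1L)
        reps <- pmin(sf_true[i, tr] * c(0.2, 1, 1.8), 1.4)
      rows[[length(rows) + 1L]] <-
        aggregate_profile(reps, cell_line = lines[i], treatment = tr)
    }
  }
  profiles <- do.call(rbind, rows)
  class(profiles) <- c("mirres_profiles", "data.frame")
  list(profiles = profiles, sf_true = sf_true)
}

#' Generate a Ct matrix with planted housekeepers and resistance miRNAs
#'
#' Housekeeping candidates are constant apart from a shared per-sample
#' offset (input/loading variation) and small residual noise; planted
#' resistance miRNAs have Ct decreasing linearly with the true survival
#' fraction of their treatment (expression up in resistant lines);
#' background miRNAs carry independent cycle-scale noise; a configurable
#' subset is undetected (`NA`) in every line.
#'
#' @param cfg A [scenario_config()].
#' @param sf_true Line x treatment matrix of true mean survival fractions
#'   (from [generate_survival_profiles()]).
#' @return List: `ct` (miRNA x line Ct matrix), `truth` (list with
#'   `hkg`, `resistance` per treatment, `undetected`).
#' @export
generate_ct_matrix <- function(cfg, sf_true) {
  set.seed(sub_seed(cfg, 2L))
  lines <- rownames(sf_true)
  n <- cfg$n_mirna
  ids <- sprintf("miR-%03d", seq_len(n))
  hkg_ids <- ids[seq_len(cfg$n_hkg)]
  res_ids <- list(); used <- cfg$n_hkg
  for (tr in cfg$treatments) {
    res_ids[[tr]] <- ids[used + seq_len(cfg$n_resistance_mirna)]
    used <- used + cfg$n_resistance_mirna
  }
  undet_ids <- ids[used + seq_len(cfg$n_undetected)]
  # the loading offset and the per-miRNA background variation are
  # calibrated to their stated spreads in every realization, and the
  # offset is made orthogonal to the resistance axes, so the planted
  # stable/variable/resistance labels are true of the emitted matrix
  # itself, not just in expectation
  offset <- rnorm(length(lines))
  offset <- stats::resid(stats::lm(offset ~ sf_true))
  offset <- (offset - mean(offset)) / sd(offset) * cfg$sample_offset_sd
  scaled_noise <- function(sd_target) {
    e <- rnorm(length(lines))
    (e - mean(e)) / sd(e) * sd_target
  }
  ct <- matrix(NA_real_, n, length(lines), dimnames = list(ids, lines))
  base <- runif(n, 20, 28)
  for (i in seq_len(n)) {
    id <- ids[i]
    if (id %in% undet_ids) next
    if (id %in% hkg_ids) {
      ct[i, ] <- 25 + offset + rnorm(length(lines), 0, cfg$hkg_noise_sd)
    } else {
      tr_hit <- names(res_ids)[vapply(res_ids, function(s) id %in% s,
                                      logical(1))]
      if (length(tr_hit) == 1L) {
        sfv <- sf_true[, tr_hit]
        ct[i, ] <- base[i] - cfg$effect_size * (sfv - mean(sfv)) + offset +
          rnorm(length(lines), 0, cfg$noise_sd)
      } else {
        ct[i, ] <- base[i] + offset + scaled_noise(cfg$background_sd)
      }
    }
  }
  ct[!is.na(ct)] <- pmin(pmax(ct[!is.na(ct)], 15.01), 40)
  list(ct = ct,
       truth = list(hkg = hkg_ids, resistance = res_ids,
                    undetected = undet_ids))
}

#' Generate serum small-EV miRNA counts with planted response effects
#'
#' Negative-binomial counts with shared dispersion, lognormal library-size
#' variation spanning roughly `lib_size_fold`-fold, and
#' `n_planted_serum_de` miRNAs shifted by `lfc_serum` log2 units between
#' response classes (alternating sign).
#'
#' @param cfg A [scenario_config()].
#' @return List: `counts` (miRNA x patient integer matrix), `labels`
#'   (named response-class vector), `truth` (planted DE ids and signs).
#' @export
generate_serum_counts <- function(cfg) {
  stopifnot(cfg$n_good >= 3, cfg$n_poor >= 3)
  set.seed(sub_seed(cfg, 3L))
  n <- cfg$n_serum_mirna
  ids <- sprintf("miR-%03d", seq_len(n))
  patients <- c(sprintf("good_%02d", seq_len(cfg$n_good)),
                sprintf("poor_%02d", seq_len(cfg$n_poor)))
  labels <- setNames(rep(c("good", "poor"), c(cfg$n_good, cfg$n_poor)),
                     patients)
  n_de <- cfg$n_planted_serum_de
  sign_de <- rep(c(1, -1), length.out = n_de)
  base_rel <- 2^runif(n, 2, 12)
  base_rel <- base_rel / sum(base_rel)
  lib <- cfg$lib_size_base *
    exp(rnorm(length(patients), 0, log(cfg$lib_size_fold) / 4))
  counts <- matrix(0L, n, length(patients),
                   dimnames = list(ids, patients))
  for (j in seq_along(patients)) {
    lfc <- numeric(n)
    if (labels[j] == "poor") lfc[seq_len(n_de)] <- sign_de * cfg$lfc_serum
    mu <- base_rel * 2^lfc
    mu <- mu / sum(mu) * lib[j]
    counts[, j] <- rnbinom(n, mu = mu, size = 1 / cfg$nb_dispersion)
  }
  list(counts = counts, labels = labels,
       truth = list(planted_de = ids[seq_len(n_de)],
                    sign = setNames(sign_de, ids[seq_len(n_de)])))
}

#' Generate paired small-RNA / mRNA expression with planted
#' anti-correlated pairs, database fixtures and gene sets
#'
#' Emulates a 3-control vs 3-inhibitor perturbation: each planted pair
#' shifts the small RNA down and its target mRNA up in the inhibitor arm,
#' with residual noise tuned so the expected sample correlation is
#' `r_target`. Five synthetic target databases cover the planted pairs so
#' that the first half reach consensus support of at least three and the
#' second half at most two; a synthetic GMT collection contains one
#' pathway holding exactly the planted target mRNAs.
#'
#' @param cfg A [scenario_config()].
#' @return List: `small_rna`, `mrna` (expression matrices), `db`
#'   (database table `source`, `small_rna`, `mrna`), `gene_sets` (named
#'   list), `truth` (planted pairs, consensus-supported pairs, enriched
#'   pathway).
#' @export
generate_paired_expression <- function(cfg) {
  stopifnot(cfg$n_per_group * 2 >= 4)
  set.seed(sub_seed(cfg, 4L))
  samples <- c(sprintf("ctrl_%d", seq_len(cfg$n_per_group)),
               sprintf("inhib_%d", seq_len(cfg$n_per_group)))
  arm <- rep(c(1, -1), each = cfg$n_per_group)  # +1 control, -1 inhibitor
  s_ids <- sprintf("sRNA_%03d", seq_len(cfg$n_small_rna))
  m_ids <- sprintf("GENE%03d", seq_len(cfg$n_mrna))
  ns <- length(samples)
  small <- matrix(8 + rnorm(cfg$n_small_rna * ns, 0, 0.5),
                  cfg$n_small_rna, ns, dimnames = list(s_ids, samples))
  mrna <- matrix(8 + rnorm(cfg$n_mrna * ns, 0, 0.5),
                 cfg$n_mrna, ns, dimnames = list(m_ids, samples))
  for (k in seq_len(cfg$n_pairs)) {
    # each pair shares a response profile: the perturbation-arm shift plus
    # a pair-specific component, so different pairs are strongly but not
    # perfectly collinear; residual noise is scaled so the expected
    # within-pair correlation magnitude is |r_target|
    delta <- rnorm(ns, 0, sqrt(0.2))
    profile <- arm + (delta - mean(delta))
    sigma <- sd(profile) *
      sqrt((1 - abs(cfg$r_target)) / abs(cfg$r_target))
    small[k, ] <- 8 + profile + rnorm(ns, 0, sigma)
    mrna[k, ] <- 8 - profile + rnorm(ns, 0, sigma)
  }
  pairs <- data.frame(small_rna = s_ids[seq_len(cfg$n_pairs)],
                      mrna = m_ids[seq_len(cfg$n_pairs)],
                      stringsAsFactors = FALSE)
  # database fixtures: planted pairs 1..ceil(n/2) get support 3, the rest 2;
  # decoy rows keep the tables from being pure answer keys
  half <- ceiling(cfg$n_pairs / 2)
  sources <- sprintf("db%d", 1:5)
  db_rows <- list()
  for (k in seq_len(cfg$n_pairs)) {
    in_dbs <- if (k <= half) sources[1:3] else sources[1:2]
    for (s in in_dbs)
      db_rows[[length(db_rows) + 1L]] <-
        data.frame(source = s, small_rna = pairs$small_rna[k],
                   mrna = pairs$mrna[k], stringsAsFactors = FALSE)
  }
  for (s in sources) {
    decoy <- data.frame(source = s,
                        small_rna = sample(s_ids, 20, replace = TRUE),
                        mrna = sample(m_ids, 20, replace = TRUE),
                        stringsAsFactors = FALSE)
    db_rows[[length(db_rows) + 1L]] <- decoy
  }
  db <- unique(do.call(rbind, db_rows))
  db$small_rna <- tolower(db$small_rna)
  db$mrna <- toupper(db$mrna)
  # gene sets: one pathway = the planted target mRNAs, plus random sets
  gene_sets <- c(list(planted_target_pathway = toupper(pairs$mrna)),
                 setNames(lapply(1:9, function(i)
                   toupper(sample(m_ids[-seq_len(cfg$n_pairs)], 25))),
                   sprintf("random_pathway_%02d", 1:9)))
  list(small_rna = 2^small, mrna = 2^mrna, db = db, gene_sets = gene_sets,
       truth = list(pairs = pairs,
                    consensus_pairs = pairs[seq_len(half), , drop = FALSE],
                    enriched_pathway = "planted_target_pathway"))
}

#' Write a full synthetic scenario to a fixture directory
#'
#' Emits every TSV the pipeline reads (well counts, Ct matrix, serum
#' counts, labels, paired expression, database tables), a GMT file, and a
#' ground-truth JSON.
#'
#' @param cfg A [scenario_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the list of generated objects.
#' @export
simulate_scenario <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- generate_survival_profiles(cfg)
  cm <- generate_ct_matrix(cfg, sp$sf_true)
  sc <- generate_serum_counts(cfg)
  pe <- generate_paired_expression(cfg)
  w <- function(df, name, rn = FALSE) {
    if (rn) df <- data.frame(id = rownames(df), df, check.names = FALSE)
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  w(as.data.frame(sp$profiles), "survival_profiles.tsv")
  w(as.data.frame(cm$ct), "ct_matrix.tsv", rn = TRUE)
  w(as.data.frame(sc$counts), "serum_counts.tsv", rn = TRUE)
  w(data.frame(patient_id = names(sc$labels), response_class = sc$labels),
    "serum_labels.tsv")
  w(as.data.frame(pe$small_rna), "small_rna_expression.tsv", rn = TRUE)
  w(as.data.frame(pe$mrna), "mrna_expression.tsv", rn = TRUE)
  w(pe$db, "target_db.tsv")
  gmt <- vapply(names(pe$gene_sets), function(nm)
    paste(c(nm, "synthetic", pe$gene_sets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(gmt, file.path(dir, "gene_sets.gmt"))
  truth <- list(hkg = cm$truth$hkg, resistance = cm$truth$resistance,
                undetected = cm$truth$undetected,
                serum_de = sc$truth$planted_de,
                pairs = pe$truth$pairs,
                consensus_pairs = pe$truth$consensus_pairs,
                enriched_pathway = pe$truth$enriched_pathway,
                sf_true = as.data.frame(sp$sf_true))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(list(profiles = sp, ct = cm, serum = sc, paired = pe))
}
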