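# End-to-end orchestration: read the stage inputs named in a config, run
# the toggled stages in order, write every intermediate table, and record
# a manifest with parameters, seeds and input checksums.

read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  m
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

default_params <- function() {
  list(alpha = 0.05, lambda = 0.5, fold_threshold = 1.5,
       cv_flag_threshold = 0.3, median_ct_max = 30, corr_min = 0.7,
       fold_window = 5, max_cycles = 40, cell_strict = 0.05,
       cell_p_max = 0.1, serum_alpha = 0.05, serum_suggestive = 0.1,
       r_threshold = -0.5, min_db_support = 3, n_perm = 5000,
       min_count = 5, min_prop = 0.25)
}

#' Run the full resistance-screening pipeline from a config
#'
#' Stages (each toggleable via `config$stages`): `phenotyping` (survival
#' profiles from a well table, or profiles read directly),
#' `normalize` (Ct matrix to housekeeping-normalized levels), `de`
#' (per-treatment resistance screen + uniqueness calls), `serum` (TMM +
#' Mann-Whitney + cross-referencing), `interactions` (negative-correlation
#' screen, database consensus, enrichment). Every output table is written
#' to `config$out_dir` and a `manifest.json` records parameters, the seed
#' and MD5 checksums of all inputs. Reruns with identical config and
#' inputs reproduce all outputs exactly.
#'
#' @param config Path to a YAML file or an equivalent named list. Keys:
#'   `seed`, `out_dir`, `inputs` (paths: `profiles`, `wells`, `ct_matrix`,
#'   `serum_counts`, `serum_labels`, `small_rna`, `mrna`, `target_db`,
#'   `gene_sets`), `stages` (logical toggles), `params` (overrides of
#'   [default_params()]), `treatments` (optional explicit labels),
#'   `hkg_groups` (optional sample partition for the housekeeping group
#'   test).
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop_input("config$out_dir is required")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- utils::modifyList(default_params(), config$params %||% list())
  stages <- utils::modifyList(
    list(phenotyping = TRUE, normalize = TRUE, de = TRUE, serum = TRUE,
         interactions = TRUE),
    config$stages %||% list())
  seed <- config$seed %||% 1L
  inputs <- config$inputs %||% list()
  present <- inputs[!vapply(inputs, is.null, logical(1))]
  checksums <- vapply(present, function(p)
    unname(tools::md5sum(p)), character(1))
  results <- list()
  outputs <- character(0)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  profiles <- NULL
  if (isTRUE(stages$phenotyping)) {
    profiles <- run_stage("phenotyping", {
      if (!is.null(inputs$wells)) {
        survival_profiles(read.delim(inputs$wells,
                                     stringsAsFactors = FALSE),
                          cv_flag_threshold = params$cv_flag_threshold)
      } else if (!is.null(inputs$profiles)) {
        p <- read.delim(inputs$profiles, stringsAsFactors = FALSE)
        class(p) <- c("mirres_profiles", "data.frame")
        p
      } else stop_input("phenotyping needs inputs$wells or inputs$profiles")
    })
    outputs <- c(outputs, write_tsv(as.data.frame(profiles),
                                    file.path(config$out_dir,
                                              "survival_profiles.tsv")))
    results$profiles <- profiles
  }

  norm <- NULL
  if (isTRUE(stages$normalize)) {
    normalized <- run_stage("normalize", {
      ct <- read_ct_matrix(inputs$ct_matrix, max_cycles = params$max_cycles)
      hkg <- select_housekeeping(
        ct, groups = config$hkg_groups,
        median_ct_max = params$median_ct_max,
        fold_window = params$fold_window, corr_min = params$corr_min,
        max_cycles = params$max_cycles)
      lev <- relative_level(ct, max_cycles = params$max_cycles,
                            undetected = "floor")
      list(hkg = hkg, norm = normalize_levels(lev, hkg$selected))
    })
    results$hkg <- normalized$hkg
    norm <- normalized$norm
    outputs <- c(outputs,
                 write_tsv(normalized$hkg$report,
                           file.path(config$out_dir, "hkg_report.tsv")))
    outputs <- c(outputs, write_tsv(
      data.frame(mirna = rownames(norm), norm, check.names = FALSE),
      file.path(config$out_dir, "normalized_levels.tsv")))
    results$normalized <- norm
  }

  if (isTRUE(stages$de)) {
    if (is.null(norm) || is.null(profiles))
      stop("stage 'de' needs the normalize and phenotyping stages",
           call. = FALSE)
    screens <- run_stage("de", {
      treatments <- config$treatments %||% unique(profiles$treatment)
      lapply(setNames(treatments, treatments), function(tr) {
        des <- treatment_design(profiles, treatment = tr)
        des$cell_lines <- intersect(des$cell_lines, colnames(norm))
        resistance_screen(norm[, des$cell_lines, drop = FALSE], des,
                          fold_threshold = params$fold_threshold,
                          alpha = params$alpha, lambda = params$lambda)
      })
    })
    for (tr in names(screens))
      outputs <- c(outputs, write_tsv(
        screens[[tr]]$table,
        file.path(config$out_dir, paste0("de_", tr, ".tsv"))))
    uniq <- classify_uniqueness(lapply(screens, `[[`, "table"),
                                alpha = params$alpha)
    outputs <- c(outputs, write_tsv(uniq, file.path(config$out_dir,
                                                    "uniqueness.tsv")))
    results$screens <- screens
    results$uniqueness <- uniq
  }

  if (isTRUE(stages$serum)) {
    serum <- run_stage("serum", {
      counts <- read_matrix_tsv(inputs$serum_counts)
      lab <- read.delim(inputs$serum_labels, stringsAsFactors = FALSE)
      labels <- setNames(lab$response_class, lab$patient_id)[
        colnames(counts)]
      counts <- filter_low_counts(counts, params$min_count,
                                  params$min_prop)
      fac <- tmm_factors(counts)
      de <- mwu_de(normalize_counts(counts, fac), labels)
      list(factors = fac, de = de)
    })
    outputs <- c(outputs, write_tsv(serum$de,
                                    file.path(config$out_dir,
                                              "serum_de.tsv")))
    results$serum <- serum
    if (!is.null(results$screens)) {
      for (tr in names(results$screens)) {
        xr <- crossref_serum(results$screens[[tr]]$table, serum$de,
                             cell_strict = params$cell_strict,
                             cell_p_max = params$cell_p_max,
                             serum_alpha = params$serum_alpha,
                             serum_suggestive = params$serum_suggestive)
        outputs <- c(outputs, write_tsv(
          xr, file.path(config$out_dir, paste0("crossref_", tr, ".tsv"))))
        results$crossref[[tr]] <- xr
      }
    }
  }

  if (isTRUE(stages$interactions)) {
    inter <- run_stage("interactions", {
      small <- read_matrix_tsv(inputs$small_rna)
      mrna <- read_matrix_tsv(inputs$mrna)
      cand <- negative_correlation_screen(small, mrna,
                                          r_threshold = params$r_threshold)
      db <- read_target_db(inputs$target_db)
      cons <- db_consensus_filter(cand, db,
                                  min_support = params$min_db_support)
      sets <- read_gmt(inputs$gene_sets)
      enr <- enrich(unique(cons$mrna), sets,
                    universe = toupper(rownames(mrna)),
                    n_perm = params$n_perm, seed = seed)
      list(candidates = cand, consensus = cons, enrichment = enr)
    })
    outputs <- c(outputs,
                 write_tsv(inter$candidates,
                           file.path(config$out_dir, "interactions.tsv")),
                 write_tsv(inter$consensus,
                           file.path(config$out_dir,
                                     "interactions_consensus.tsv")),
                 write_tsv(inter$enrichment,
                           file.path(config$out_dir, "enrichment.tsv")))
    results$interactions <- inter
  }

  manifest <- list(
    stages = names(Filter(isTRUE, stages)),
    seed = seed, params = params,
    inputs = lapply(seq_along(present), function(i)
      list(path = present[[i]], md5 = unname(checksums[i]))),
    outputs = basename(outputs))
  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
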