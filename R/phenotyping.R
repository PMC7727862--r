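# Clonogenic / soft-agar / apoptosis assay arithmetic.
#
# The resistance axis for the whole pipeline is the survival fraction (SF):
# the fraction of cells surviving a treatment relative to mock-treated or
# vehicle controls.  Clonogenic assays give SF via plating efficiencies;
# flow-cytometry apoptosis assays give SF via viable-cell percentages.

#' Plating efficiency of a clonogenic assay well
#'
#' PE = colonies counted / cells seeded. The universal clonogenic-assay
#' definition; colony calling (e.g. the ">50 cells" rule used for soft-agar
#' colonies) happens upstream at the microscope.
#'
#' @param colonies Non-negative integer colony count (vectorised).
#' @param cells_seeded Positive integer number of cells seeded (vectorised).
#' @return Plating efficiency in `[0, 1]`.
#' @examples
#' plating_efficiency(250, 1000)  # 0.25
#' @export
plating_efficiency <- function(colonies, cells_seeded) {
  if (any(!is.finite(cells_seeded)) || any(cells_seeded <= 0))
    stop_input("cells_seeded must be > 0")
  if (any(!is.finite(colonies)) || any(colonies < 0))
    stop_input("colonies must be >= 0")
  if (any(colonies > cells_seeded))
    stop_input("colonies cannot exceed cells_seeded")
  colonies / cells_seeded
}

#' Clonogenic survival fraction
#'
#' SF = mean plating efficiency of treated wells divided by mean plating
#' efficiency of mock-treated wells. Both arguments are data frames with
#' columns `colonies` and `cells_seeded`, one row per technical-replicate
#' well; rows are from the same cell line and the same independent
#' experiment.
#'
#' @param treated,mock Data frames of wells with columns `colonies`,
#'   `cells_seeded`.
#' @return Survival fraction (non-negative; can exceed 1 from counting noise).
#' @export
clonogenic_sf <- function(treated, mock) {
  for (df in list(treated, mock)) {
    if (!is.data.frame(df) || nrow(df) == 0L)
      stop_input("treated and mock must be non-empty data frames")
    if (!all(c("colonies", "cells_seeded") %in% names(df)))
      stop_input("well tables need 'colonies' and 'cells_seeded' columns")
  }
  pe_t <- mean(plating_efficiency(treated$colonies, treated$cells_seeded))
  pe_m <- mean(plating_efficiency(mock$colonies, mock$cells_seeded))
  if (pe_m <= 0)
    stop_input("degenerate control: mock mean plating efficiency is zero")
  pe_t / pe_m
}

#' Percent reduction of a count relative to a reference
#'
#' `100 * (b - a) / b`, reported to the nearest integer percent when
#' `round = TRUE` (the convention for reporting colony-count reductions).
#'
#' @param a Observed count (e.g. colonies after inhibitor transfection).
#' @param b Reference count (e.g. colonies after negative control).
#' @param round Round to nearest integer percent? Default `TRUE`.
#' @return Percentage reduction.
#' @examples
#' percent_reduction(69, 86)  # 20
#' @export
percent_reduction <- function(a, b, round = TRUE) {
  check_number(a, "a", lower = 0)
  check_number(b, "b")
  if (b <= 0) stop_input("reference count b must be > 0")
  pct <- 100 * (b - a) / b
  if (round) round(pct) else pct
}

#' Renormalize flow-cytometry event counts to apoptosis-assay percentages
#'
#' Viable, early-apoptotic and late-apoptotic events are rescaled to sum to
#' 100%; necrotic cells and detritus are excluded before renormalization, so
#' the resulting percentages are invariant to the necrotic fraction.
#'
#' @param viable,early,late,necrotic Non-negative event counts. `necrotic`
#'   is accepted (and ignored) to make the exclusion explicit at call sites.
#' @return Named numeric vector `viable_pct`, `early_apoptotic_pct`,
#'   `late_apoptotic_pct` summing to 100.
#' @export
flow_fractions <- function(viable, early, late, necrotic = 0) {
  for (x in list(viable, early, late, necrotic))
    check_number(x, "event count", lower = 0)
  tot <- viable + early + late
  if (tot <= 0) stop_input("no viable/early/late events to renormalize")
  c(viable_pct = 100 * viable / tot,
    early_apoptotic_pct = 100 * early / tot,
    late_apoptotic_pct = 100 * late / tot)
}

#' Apoptosis-assay survival fraction
#'
#' SF = viable percentage of the treated sample divided by the mean viable
#' percentage of the vehicle controls (percentages renormalized over
#' viable + early + late apoptotic events only).
#'
#' @param treated_viable_pct Viable percentage of the treated sample.
#' @param vehicle_viable_pct Numeric vector of vehicle-control viable
#'   percentages (non-empty).
#' @return Survival fraction.
#' @export
apoptosis_sf <- function(treated_viable_pct, vehicle_viable_pct) {
  check_number(treated_viable_pct, "treated_viable_pct", 0, 100)
  if (length(vehicle_viable_pct) == 0L || any(!is.finite(vehicle_viable_pct)))
    stop_input("vehicle_viable_pct must be a non-empty finite vector")
  vm <- mean(vehicle_viable_pct)
  if (vm <= 0) stop_input("degenerate control: vehicle mean viable % is zero")
  treated_viable_pct / vm
}

#' Aggregate per-experiment survival fractions into a survival profile
#'
#' One independent experiment contributes one SF value; technical replicates
#' are pooled upstream (within-experiment mean plating efficiency). The
#' profile records the mean, the sample SD, and a consistency flag based on
#' the coefficient of variation. Inconsistent profiles are flagged, never
#' dropped: exclusion of variable cell lines is the analyst's decision.
#'
#' @param sf_replicates Numeric vector of per-experiment survival fractions.
#' @param cell_line,treatment Labels carried into the profile.
#' @param cv_flag_threshold Flag the profile inconsistent when
#'   `sd/mean` exceeds this value. Default 0.3.
#' @return A one-row data frame with columns `cell_line`, `treatment`,
#'   `sf_mean`, `sf_sd`, `n_experiments`, `consistent`.
#' @export
aggregate_profile <- function(sf_replicates, cell_line = NA_character_,
                              treatment = NA_character_,
                              cv_flag_threshold = 0.3) {
  if (length(sf_replicates) == 0L || any(!is.finite(sf_replicates)))
    stop_input("sf_replicates must be non-empty and finite")
  if (any(sf_replicates < 0))
    stop_input("survival fractions cannot be negative")
  if (any(sf_replicates > 1.5))
    warning("survival fraction > 1.5: check colony counts", call. = FALSE)
  n <- length(sf_replicates)
  m <- mean(sf_replicates)
  if (n < 2L) {
    warning("single replicate: SD and consistency undefined", call. = FALSE)
    s <- NA_real_
    consistent <- NA
  } else {
    s <- sd(sf_replicates)
    consistent <- if (m > 0) (s / m) <= cv_flag_threshold else FALSE
  }
  data.frame(cell_line = cell_line, treatment = treatment,
             sf_mean = m, sf_sd = s, n_experiments = n,
             consistent = consistent, stringsAsFactors = FALSE)
}

#' Survival profiles from a clonogenic-assay well table
#'
#' Pools wells per the mean-PE-within-experiment convention: technical
#' replicates are averaged into one plating efficiency per experiment, SF is
#' formed per independent experiment against that experiment's mock wells,
#' and experiments are summarised as mean +/- SD.
#'
#' @param wells Data frame with columns `cell_line`, `treatment`,
#'   `experiment_id`, `well_id`, `cells_seeded`, `colonies` (one row per
#'   well); the `mock_label` level of `treatment` provides the controls.
#' @param mock_label Treatment label of the mock/control wells
#'   (default `"mock"`).
#' @param cv_flag_threshold Passed to [aggregate_profile()].
#' @return Data frame of survival profiles (class `mirres_profiles`), one
#'   row per cell line x non-mock treatment.
#' @export
survival_profiles <- function(wells, mock_label = "mock",
                              cv_flag_threshold = 0.3) {
  need <- c("cell_line", "treatment", "experiment_id", "cells_seeded",
            "colonies")
  if (!all(need %in% names(wells)))
    stop_input("wells table needs columns: ", paste(need, collapse = ", "))
  out <- list()
  for (cl in unique(wells$cell_line)) {
    w <- wells[wells$cell_line == cl, , drop = FALSE]
    mock <- w[w$treatment == mock_label, , drop = FALSE]
    if (nrow(mock) == 0L)
      stop_input("no '", mock_label, "' wells for cell line ", cl)
    for (tr in setdiff(unique(w$treatment), mock_label)) {
      wt <- w[w$treatment == tr, , drop = FALSE]
      sfs <- vapply(unique(wt$experiment_id), function(e) {
        te <- wt[wt$experiment_id == e, , drop = FALSE]
        me <- mock[mock$experiment_id == e, , drop = FALSE]
        if (nrow(me) == 0L)
          stop_input("experiment ", e, " of ", cl, " has no mock wells")
        clonogenic_sf(te, me)
      }, numeric(1))
      out[[length(out) + 1L]] <-
        aggregate_profile(sfs, cell_line = cl, treatment = tr,
                          cv_flag_threshold = cv_flag_threshold)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("mirres_profiles", "data.frame")
  res
}

#' Survival profiles from flow-cytometry apoptosis event counts
#'
#' @param events Data frame with columns `cell_line`, `treatment`,
#'   `experiment_id`, `viable`, `early`, `late`, `necrotic` (event counts,
#'   one row per sample).
#' @param vehicle_label Treatment label of the vehicle controls.
#' @param cv_flag_threshold Passed to [aggregate_profile()].
#' @return Data frame of survival profiles (class `mirres_profiles`).
#' @export
apoptosis_profiles <- function(events, vehicle_label = "vehicle",
                               cv_flag_threshold = 0.3) {
  need <- c("cell_line", "treatment", "experiment_id", "viable", "early",
            "late")
  if (!all(need %in% names(events)))
    stop_input("events table needs columns: ", paste(need, collapse = ", "))
  if (is.null(events$necrotic)) events$necrotic <- 0
  events$viable_pct <- apply(events[, c("viable", "early", "late",
                                        "necrotic")], 1L, function(r)
    flow_fractions(r[["viable"]], r[["early"]], r[["late"]],
                   r[["necrotic"]])[["viable_pct"]])
  out <- list()
  for (cl in unique(events$cell_line)) {
    ev <- events[events$cell_line == cl, , drop = FALSE]
    veh <- ev[ev$treatment == vehicle_label, , drop = FALSE]
    if (nrow(veh) == 0L)
      stop_input("no '", vehicle_label, "' samples for cell line ", cl)
    for (tr in setdiff(unique(ev$treatment), vehicle_label)) {
      et <- ev[ev$treatment == tr, , drop = FALSE]
      sfs <- vapply(unique(et$experiment_id), function(e) {
        te <- et[et$experiment_id == e, , drop = FALSE]
        ve <- veh[veh$experiment_id == e, , drop = FALSE]
        if (nrow(ve) == 0L)
          stop_input("experiment ", e, " of ", cl, " has no vehicle samples")
        mean(vapply(te$viable_pct, apoptosis_sf,
                    numeric(1), vehicle_viable_pct = ve$viable_pct))
      }, numeric(1))
      out[[length(out) + 1L]] <-
        aggregate_profile(sfs, cell_line = cl, treatment = tr,
                          cv_flag_threshold = cv_flag_threshold)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("mirres_profiles", "data.frame")
  res
}

#' @export
print.mirres_profiles <- function(x, ...) {
  cat("Survival profiles:", nrow(x), "cell line x treatment combinations\n")
  if (any(!is.na(x$consistent) & !x$consistent))
    cat("  flagged inconsistent:",
        paste(x$cell_line[!is.na(x$consistent) & !x$consistent],
              collapse = ", "), "\n")
  print.data.frame(x, ...)
  invisible(x)
}
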