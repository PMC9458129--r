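#' Run the full calcium/TRAIL apoptosis study
#'
#' End-to-end pipeline tying the stages together: single-cell hourly
#' trajectories for every calcium condition x TRAIL dose, heterogeneous
#' 1000-cell population runs per calcium condition at the in vitro dose, a
#' per-condition viability table, and the one-phase-decay fit of viability
#' against calcium. Every summary is stamped with the seed, solver tolerances
#' and package version so a run can be reproduced exactly.
#'
#' @param network Model network (default: the packaged [ca_trail_model()]).
#' @param panel Calcium panel (condition, calcium_um); default
#'   [default_calcium_panel()].
#' @param trail_doses TRAIL doses (ng/mL) for the single-cell sweep.
#' @param population_dose Dose used for the population runs (default 50, the
#'   in vitro dose).
#' @param n_cells Cells per population (default 1000).
#' @param seed Master seed.
#' @param momp_fraction Released-Smac fraction defining MOMP.
#' @param rtol,atol Solver tolerances.
#' @param out_dir If non-`NULL`, write `single_cell.csv`, `population.csv`,
#'   `condition_table.csv`, and `summary.json` (requires jsonlite) there.
#' @param keep_trajectories Keep the single-cell `cell_trajectory` objects in
#'   the returned bundle (default `TRUE`).
#' @return A list of class `apoptosis_study`: `single_cell_fates` (tibble),
#'   `trajectories` (nested list, unless dropped), `populations` (list of
#'   `population_result`), `condition_table`, `decay_fit`, `provenance`.
#' @export
run_apoptosis_study <- function(network = ca_trail_model(),
                                panel = default_calcium_panel(),
                                trail_doses = c(0.5, 50, 200),
                                population_dose = 50,
                                n_cells = 1000, seed = 1,
                                momp_fraction = 0.5,
                                rtol = 1e-6, atol = 1,
                                out_dir = NULL, keep_trajectories = TRUE) {
  provenance <- list(seed = seed, rtol = rtol, atol = atol,
                     momp_fraction = momp_fraction, n_cells = n_cells,
                     package_version = as.character(utils::packageVersion("camapop")))
  # stage 1: single-cell sweep
  trajectories <- list()
  fates <- list()
  for (dose in trail_doses) {
    for (i in seq_len(nrow(panel))) {
      cond <- make_condition(dose, panel$calcium_um[i], label = panel$condition[i])
      traj <- simulate_cell(network, cond, rtol = rtol, atol = atol)
      key <- sprintf("%s@%g", panel$condition[i], dose)
      if (keep_trajectories) trajectories[[key]] <- traj
      fates[[key]] <- dplyr::bind_cols(
        tibble::tibble(condition = panel$condition[i],
                       trail_ng_per_ml = dose,
                       calcium_um = panel$calcium_um[i]),
        fate_call(traj, momp_fraction = momp_fraction))
    }
  }
  single_cell_fates <- dplyr::bind_rows(fates)
  # stage 2: heterogeneous populations at the in vitro dose
  spec <- heterogeneity_spec(n_cells = n_cells, seed = seed)
  populations <- list()
  for (i in seq_len(nrow(panel))) {
    cond <- make_condition(population_dose, panel$calcium_um[i],
                           label = panel$condition[i])
    populations[[panel$condition[i]]] <-
      simulate_population(network, cond, spec, rtol = rtol, atol = atol,
                          momp_fraction = momp_fraction)
  }
  ctab <- condition_table(populations)
  # stage 3: one-phase decay of viability vs calcium
  fit <- fit_one_phase_decay(ctab, x = calcium_um, y = viability_percent)
  bundle <- structure(list(single_cell_fates = single_cell_fates,
                           trajectories = if (keep_trajectories) trajectories,
                           populations = populations,
                           condition_table = ctab,
                           decay_fit = fit,
                           provenance = provenance),
                      class = "apoptosis_study")
  if (!is.null(out_dir)) write_study(bundle, out_dir)
  bundle
}

#' @export
print.apoptosis_study <- function(x, ...) {
  cat("<apoptosis_study>\n")
  cat("Condition table:\n")
  print(as.data.frame(x$condition_table[, c("condition", "calcium_um",
                                            "viability_percent")]),
        row.names = FALSE)
  print(x$decay_fit)
  invisible(x)
}

write_study <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(bundle$single_cell_fates,
                   file.path(out_dir, "single_cell.csv"), progress = FALSE)
  percell <- purrr::map_dfr(names(bundle$populations), function(nm) {
    dplyr::mutate(tidy(bundle$populations[[nm]]), condition = nm, .before = 1)
  })
  readr::write_csv(percell, file.path(out_dir, "population.csv"),
                   progress = FALSE)
  readr::write_csv(bundle$condition_table,
                   file.path(out_dir, "condition_table.csv"), progress = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    summary <- c(bundle$provenance,
                 list(viability_percent = stats::setNames(
                        as.list(bundle$condition_table$viability_percent),
                        bundle$condition_table$condition),
                      decay_fit = as.list(bundle$decay_fit$coefficients)))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out_dir)
}
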