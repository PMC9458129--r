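#' Specify cell-to-cell heterogeneity
#'
#' Defines the random-normal distributions of the anti-apoptotic proteins that
#' vary across the simulated population. Defaults are the study's stated
#' parameters: cytosolic Bcl-2 mean 1.98e6, SD 9.91e5, and XIAP mean 1.01e5,
#' SD 9.91e4 molecules per cell. Non-positive draws are handled by the
#' truncation rule: `"redraw"` (rejection sampling, default; note this shifts
#' the realized XIAP mean upward since ~15% of its untruncated mass is <= 0)
#' or `"clamp"` (set to 0).
#'
#' @param n_cells Number of cells (default 1000).
#' @param seed Master seed; per-cell substreams are derived from it and the
#'   cell index, so changing `n_cells` does not reshuffle earlier cells.
#' @param species Named list of `c(mean, sd)` pairs keyed by species name.
#' @param truncation `"redraw"` or `"clamp"`.
#' @return An object of class `heterogeneity_spec`.
#' @export
heterogeneity_spec <- function(n_cells = 1000, seed = 1,
                               species = list(Bcl2 = c(mean = 1.98e6, sd = 9.91e5),
                                              XIAP = c(mean = 1.01e5, sd = 9.91e4)),
                               truncation = c("redraw", "clamp")) {
  truncation <- match.arg(truncation)
  stopifnot(n_cells >= 1)
  for (s in species) {
    stopifnot(length(s) == 2, s[[1]] > 0, s[[2]] >= 0)
  }
  structure(list(n_cells = as.integer(n_cells), seed = as.integer(seed),
                 species = species, truncation = truncation),
            class = "heterogeneity_spec")
}

#' @export
print.heterogeneity_spec <- function(x, ...) {
  cat(sprintf("<heterogeneity_spec: %d cells, seed %d, truncation '%s'>\n",
              x$n_cells, x$seed, x$truncation))
  for (nm in names(x$species))
    cat(sprintf("  %s ~ N(%.3g, %.3g)\n", nm, x$species[[nm]][[1]],
                x$species[[nm]][[2]]))
  invisible(x)
}

# deterministic per-cell substream seed; independent of n_cells
cell_seed <- function(master, i) {
  as.integer((abs(as.numeric(master)) + i * 48271) %% 2147483647)
}

#' Draw per-cell initial-amount overrides
#'
#' Reproducible Monte Carlo draws from the spec's normal distributions, one
#' independent substream per cell.
#'
#' @param spec A `heterogeneity_spec`.
#' @return Tibble with `cell_id` and one column per randomized species;
#'   attributes `seed` and `truncation` record provenance.
#' @export
draw_population <- function(spec) {
  stopifnot(inherits(spec, "heterogeneity_spec"))
  draws <- matrix(NA_real_, nrow = spec$n_cells, ncol = length(spec$species),
                  dimnames = list(NULL, names(spec$species)))
  for (i in seq_len(spec$n_cells)) {
    set.seed(cell_seed(spec$seed, i))
    for (nm in names(spec$species)) {
      p <- spec$species[[nm]]
      x <- stats::rnorm(1, p[[1]], p[[2]])
      if (spec$truncation == "redraw") {
        while (x <= 0) x <- stats::rnorm(1, p[[1]], p[[2]])
      } else {
        x <- max(x, 0)
      }
      draws[i, nm] <- x
    }
  }
  out <- tibble::as_tibble(draws)
  out <- dplyr::bind_cols(tibble::tibble(cell_id = seq_len(spec$n_cells)), out)
  attr(out, "seed") <- spec$seed
  attr(out, "truncation") <- spec$truncation
  out
}

#' Simulate a heterogeneous cell population
#'
#' Runs the single-cell model once per cell with that cell's drawn Bcl-2/XIAP
#' amounts substituted into the initial conditions, calls each fate, and
#' computes population viability (the percentage of cells whose cPARP never
#' exceeds the apoptosis threshold within the horizon). Per-cell results are
#' independent, so evaluation order cannot change the result.
#'
#' @param network A validated `reaction_network`.
#' @param condition A `cell_condition` (shared by all cells).
#' @param spec A `heterogeneity_spec`.
#' @param horizon_h,rtol,atol Passed to [simulate_cell()].
#' @param threshold,momp_fraction Passed to [fate_call()].
#' @param on_error `"abort"` (default) stops on any cell's integration failure,
#'   reporting its draws; `"skip"` flags the cell and continues.
#' @param mean_cell Also simulate the deterministic cell at the distribution
#'   means and store its fate (default `TRUE`).
#' @return An object of class `population_result`: the per-cell tibble
#'   (`cell_id`, draws, fate columns) with attributes `viability_percent`,
#'   `condition`, `spec`, `mean_cell_fate`.
#' @export
simulate_population <- function(network, condition, spec,
                                horizon_h = 24, rtol = 1e-6, atol = 1,
                                threshold = 5e5, momp_fraction = 0.5,
                                on_error = c("abort", "skip"),
                                mean_cell = TRUE) {
  on_error <- match.arg(on_error)
  draws <- draw_population(spec)
  sp_names <- names(spec$species)
  run_one <- function(i) {
    ov <- as.list(draws[i, sp_names, drop = FALSE])
    cond_i <- make_condition(condition$trail_ng_per_ml, condition$calcium_um,
                             overrides = utils::modifyList(condition$overrides, ov),
                             label = condition$label)
    tryCatch({
      traj <- simulate_cell(network, cond_i, horizon_h = horizon_h,
                            rtol = rtol, atol = atol)
      dplyr::mutate(fate_call(traj, threshold, momp_fraction), failed = FALSE)
    }, error = function(e) {
      if (on_error == "abort")
        stop(sprintf("cell %d failed (%s): %s", i,
                     paste(sprintf("%s=%.4g", sp_names, unlist(ov)),
                           collapse = ", "), conditionMessage(e)), call. = FALSE)
      tibble::tibble(apoptotic = NA, apoptosis_time_h = NA_real_,
                     momp_time_h = NA_real_, peak_smac_time_h = NA_real_,
                     failed = TRUE)
    })
  }
  fates <- purrr::map_dfr(seq_len(spec$n_cells), run_one)
  res <- dplyr::bind_cols(draws, fates)
  mean_fate <- NULL
  if (mean_cell) {
    ov <- lapply(spec$species, function(p) p[[1]])
    cond_m <- make_condition(condition$trail_ng_per_ml, condition$calcium_um,
                             overrides = utils::modifyList(condition$overrides, ov),
                             label = condition$label)
    mean_fate <- fate_call(simulate_cell(network, cond_m, horizon_h = horizon_h,
                                         rtol = rtol, atol = atol),
                           threshold, momp_fraction)
  }
  structure(res,
            class = c("population_result", class(res)),
            viability_percent = viability(res),
            condition = condition, spec = spec,
            mean_cell_fate = mean_fate)
}

#' Population viability
#'
#' The percentage of cells whose cPARP never exceeded the apoptosis threshold:
#' `100 * (non-apoptotic cells) / (all cells)`.
#'
#' @param fates A `population_result`, or any data frame with a logical
#'   `apoptotic` column, or a bare logical vector of apoptosis calls.
#' @return Percent in `[0, 100]`.
#' @export
viability <- function(fates) {
  apop <- if (is.data.frame(fates)) {
    stopifnot("apoptotic" %in% names(fates))
    fates$apoptotic
  } else {
    as.logical(fates)
  }
  apop <- apop[!is.na(apop)]
  if (length(apop) == 0) stop("no fate calls to summarise")
  100 * sum(!apop) / length(apop)
}

#' @export
print.population_result <- function(x, ...) {
  cat(sprintf("<population_result: %s; n = %d; viability %.1f%%>\n",
              attr(x, "condition")$label, nrow(x), attr(x, "viability_percent")))
  invisible(x)
}

#' Glance at a population result
#'
#' @param x A `population_result`.
#' @param ... Unused.
#' @return One-row tibble: condition label, TRAIL dose, calcium, n, viability,
#'   seed, truncation rule, and the mean cell's event hours when available.
#' @export
glance.population_result <- function(x, ...) {
  cond <- attr(x, "condition"); spec <- attr(x, "spec")
  mf <- attr(x, "mean_cell_fate")
  tibble::tibble(
    condition = cond$label,
    trail_ng_per_ml = cond$trail_ng_per_ml,
    calcium_um = cond$calcium_um,
    n_cells = nrow(x),
    viability_percent = attr(x, "viability_percent"),
    seed = spec$seed,
    truncation = spec$truncation,
    mean_cell_apoptosis_h = if (!is.null(mf)) mf$apoptosis_time_h else NA_real_,
    mean_cell_momp_h = if (!is.null(mf)) mf$momp_time_h else NA_real_
  )
}

#' Tidy a population result
#'
#' @param x A `population_result`.
#' @param ... Unused.
#' @return The per-cell tibble (one row per simulated cell).
#' @export
tidy.population_result <- function(x, ...) {
  tibble::as_tibble(x)
}
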