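#' Specify a synthetic flow-cytometry calcium panel
#'
#' The generator emulates per-event Fluo-4 / Fura Red intensities for a set of
#' conditions with known true calcium: Fura Red is log-normal around a base
#' intensity, and Fluo-4 is `gain * calcium * furared` times an independent
#' log-normal factor, so the per-event ratio distribution has median exactly
#' `gain * calcium` (the median of a log-normal noise factor is 1). This
#' reproduces the statistical structure the condition-mapping stage assumes --
#' ratio medians proportional to calcium with multiplicative measurement
#' noise -- without simulating instrument artefacts (doublets, spillover,
#' debris).
#'
#' @param conditions Data frame with `condition` and true `calcium_um`
#'   (default: [default_calcium_panel()]).
#' @param events_per_condition Events per condition (default 2000).
#' @param sigma Log-normal noise sigma on both channels (default 0.3).
#' @param gain Ratio units per uM calcium (default 1).
#' @param base_furared Median Fura Red intensity (default 1000).
#' @param window_s Acquisition window over which event times are spread.
#' @param seed Master seed.
#' @return An object of class `synth_panel_spec`.
#' @export
synth_panel_spec <- function(conditions = default_calcium_panel(),
                             events_per_condition = 2000, sigma = 0.3,
                             gain = 1, base_furared = 1000, window_s = 200,
                             seed = 1) {
  stopifnot(events_per_condition >= 1, sigma >= 0, gain > 0,
            all(conditions$calcium_um >= 0))
  structure(list(conditions = tibble::as_tibble(conditions),
                 events_per_condition = as.integer(events_per_condition),
                 sigma = sigma, gain = gain, base_furared = base_furared,
                 window_s = window_s, seed = as.integer(seed)),
            class = "synth_panel_spec")
}

#' Generate synthetic flow-cytometry events
#'
#' Pure function of its spec and seed: the same spec always produces the same
#' event table.
#'
#' @param spec A `synth_panel_spec`.
#' @return Tibble with `condition`, `time_s`, `fluo4`, `furared` -- the event
#'   dialect consumed by [ratiometric_median()] and, after summarising, by
#'   [normalize_calcium()].
#' @export
generate_flow_events <- function(spec) {
  stopifnot(inherits(spec, "synth_panel_spec"))
  set.seed(spec$seed)
  n <- spec$events_per_condition
  purrr::map2_dfr(spec$conditions$condition, spec$conditions$calcium_um,
                  function(cond, ca) {
    furared <- spec$base_furared * exp(spec$sigma * stats::rnorm(n))
    ratio <- spec$gain * ca * exp(spec$sigma * stats::rnorm(n))
    tibble::tibble(condition = cond,
                   time_s = stats::runif(n, 0, spec$window_s),
                   fluo4 = ratio * furared,
                   furared = furared)
  })
}

#' Prefilled population fixture for regression tests
#'
#' Returns a heterogeneity spec carrying the study's Bcl-2/XIAP distribution
#' parameters (overridable) together with a checksum of the first draws, so a
#' change in the sampling stream is caught immediately.
#'
#' @param n_cells Number of cells.
#' @param seed Master seed.
#' @param species Optional replacement distribution list (see
#'   [heterogeneity_spec()]).
#' @return List with `spec` (a `heterogeneity_spec`) and `checksum` (numeric).
#' @export
generate_population_fixture <- function(n_cells = 1000, seed = 1,
                                        species = NULL) {
  args <- list(n_cells = n_cells, seed = seed)
  if (!is.null(species)) args$species <- species
  spec <- do.call(heterogeneity_spec, args)
  head_draws <- draw_population(
    heterogeneity_spec(n_cells = min(n_cells, 10L), seed = seed,
                       species = spec$species, truncation = spec$truncation))
  checksum <- round(sum(vapply(names(spec$species),
                               function(nm) sum(head_draws[[nm]]), numeric(1))))
  list(spec = spec, checksum = checksum)
}

#' Toy networks with known dynamics
#'
#' Small fixtures with closed-form or brute-force-checkable behaviour, used to
#' validate the network machinery and the integrator:
#' * `"decay"`: `A -> 0` with k = 0.1/h, A(0) = 100; `A(t) = 100 exp(-0.1 t)`.
#' * `"conserved-pair"`: `A <-> B` (k = 0.3, 0.2), total A + B conserved.
#' * `"cascade"`: `A -> B -> C` (k = 0.5, 0.2), Bateman closed form.
#'
#' @param kind One of `"decay"`, `"cascade"`, `"conserved-pair"`.
#' @return A validated `reaction_network`.
#' @export
generate_toy_network <- function(kind = c("decay", "cascade", "conserved-pair")) {
  kind <- match.arg(kind)
  sp <- function(names, init) {
    tibble::tibble(name = names, compartment = "toy", initial_amount = init)
  }
  switch(kind,
    "decay" = reaction_network(
      sp("A", 100),
      tibble::tibble(label = "deg", reactants = "A", products = "",
                     rate_constant = 0.1)),
    "conserved-pair" = reaction_network(
      sp(c("A", "B"), c(100, 0)),
      tibble::tibble(label = c("fwd", "rev"),
                     reactants = c("A", "B"), products = c("B", "A"),
                     rate_constant = c(0.3, 0.2))),
    "cascade" = reaction_network(
      sp(c("A", "B", "C"), c(100, 0, 0)),
      tibble::tibble(label = c("ab", "bc"),
                     reactants = c("A", "B"), products = c("B", "C"),
                     rate_constant = c(0.5, 0.2)))
  )
}
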