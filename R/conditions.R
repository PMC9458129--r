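#' Define one simulated treatment condition
#'
#' A condition is a TRAIL dose (ng/mL), a clamped cytosolic free-calcium
#' concentration (uM), and optional per-cell initial-amount overrides. The
#' TRAIL dose is mapped to an initial ligand amount by linear scaling of the
#' model's reference ligand count, which represents 50 ng/mL; calcium is a
#' catalytic species expressed in uM, so `calcium_um` sets its amount directly.
#'
#' @param trail_ng_per_ml TRAIL dose in ng/mL (>= 0).
#' @param calcium_um Clamped cytosolic free calcium in uM (>= 0).
#' @param overrides Named list/vector of species initial-amount overrides
#'   (e.g. per-cell Bcl-2 and XIAP draws).
#' @param label Optional condition label.
#' @return An object of class `cell_condition`.
#' @examples
#' make_condition(50, 1.0)   # Yoda1-level calcium with the in vitro TRAIL dose
#' @export
make_condition <- function(trail_ng_per_ml, calcium_um, overrides = list(),
                           label = NULL) {
  if (!is.numeric(trail_ng_per_ml) || length(trail_ng_per_ml) != 1 ||
      is.na(trail_ng_per_ml) || trail_ng_per_ml < 0)
    stop("trail_ng_per_ml must be a single non-negative number")
  if (!is.numeric(calcium_um) || length(calcium_um) != 1 ||
      is.na(calcium_um) || calcium_um < 0)
    stop("calcium_um must be a single non-negative number")
  structure(list(trail_ng_per_ml = trail_ng_per_ml,
                 calcium_um = calcium_um,
                 overrides = as.list(overrides),
                 label = label %||%
                   sprintf("TRAIL %g ng/mL, Ca %g uM", trail_ng_per_ml, calcium_um)),
            class = "cell_condition")
}

#' @export
print.cell_condition <- function(x, ...) {
  cat(sprintf("<cell_condition: %s", x$label))
  if (length(x$overrides))
    cat(sprintf("; %d override(s)", length(x$overrides)))
  cat(">\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a condition to a network's initial state
#'
#' Sets the ligand amount to `reference_ligand * dose / reference_dose`
#' (linear dose mapping), the calcium species to `calcium_um`, and then any
#' per-cell overrides (overrides win over the dose/calcium mapping).
#'
#' @param network A `reaction_network` whose ligand species' tabulated initial
#'   amount corresponds to the reference dose.
#' @param condition A `cell_condition`.
#' @param ligand,calcium Species names for the TRAIL ligand and clamped calcium.
#' @param reference_dose Dose (ng/mL) the ligand's tabulated amount represents.
#' @return Named initial-state vector.
#' @export
condition_state <- function(network, condition, ligand = "TRAIL",
                            calcium = "Ca", reference_dose = 50) {
  y0 <- initial_state(network)
  if (!is.null(ligand) && ligand %in% names(y0)) {
    y0[ligand] <- y0[ligand] * condition$trail_ng_per_ml / reference_dose
  } else if (condition$trail_ng_per_ml > 0) {
    stop(sprintf("ligand species '%s' not in network but TRAIL dose > 0", ligand))
  }
  if (!is.null(calcium) && calcium %in% names(y0)) {
    y0[calcium] <- condition$calcium_um
  } else if (condition$calcium_um > 0) {
    stop(sprintf("calcium species '%s' not in network but calcium > 0", calcium))
  }
  if (length(condition$overrides)) {
    ov <- unlist(condition$overrides)
    unknown <- setdiff(names(ov), names(y0))
    if (length(unknown))
      stop("override for unknown species: ", paste(unknown, collapse = ", "))
    y0[names(ov)] <- as.numeric(ov)
  }
  y0
}

#' Normalize a ratiometric calcium panel to concentrations
#'
#' Converts per-condition median Fluo-4/Fura Red ratios to calcium
#' concentrations by scaling so the reference condition (Yoda1 by default)
#' equals the reference concentration (1 uM): `ca(c) = ref_um * m(c)/m(ref)`.
#' The designated blank condition maps to 0 by definition regardless of its
#' measured median. If the panel already carries a `calcium_um` column it is
#' passed through unchanged (and the source is recorded).
#'
#' @param panel Data frame with `condition` and either `median_ratio` or
#'   `calcium_um`.
#' @param reference Name of the reference condition (must be present with a
#'   positive median when normalising ratios).
#' @param reference_um Concentration assigned to the reference condition.
#' @param blank Condition name mapped to 0 uM by definition (`NULL` for none).
#' @return Tibble with `condition`, `calcium_um`; attribute `source` records
#'   whether ratios or concentrations were supplied.
#' @examples
#' normalize_calcium(data.frame(
#'   condition = c("calcium_free", "control", "yoda1"),
#'   median_ratio = c(0.02, 0.105, 1.0)))
#' @export
normalize_calcium <- function(panel, reference = "yoda1", reference_um = 1,
                              blank = "calcium_free") {
  panel <- tibble::as_tibble(panel)
  stopifnot("condition" %in% names(panel))
  if ("calcium_um" %in% names(panel)) {
    out <- dplyr::select(panel, "condition", "calcium_um")
    attr(out, "source") <- "calcium_um"
    return(out)
  }
  if (!"median_ratio" %in% names(panel))
    stop("panel needs a 'median_ratio' or 'calcium_um' column")
  if (any(panel$median_ratio < 0, na.rm = TRUE))
    stop("median ratios must be non-negative")
  ref <- panel$median_ratio[panel$condition == reference]
  if (length(ref) != 1 || is.na(ref) || ref <= 0)
    stop(sprintf("reference condition '%s' absent or non-positive", reference))
  out <- tibble::tibble(
    condition = panel$condition,
    calcium_um = reference_um * panel$median_ratio / ref
  )
  if (!is.null(blank)) out$calcium_um[out$condition == blank] <- 0
  attr(out, "source") <- "median_ratio"
  out
}

#' Default calcium panel
#'
#' The printed anchors of the study conditions: calcium-free 0 uM (blank by
#' definition), control 0.105 uM (resting cytosolic free calcium, just over
#' 100 nM), Yoda1 1.0 uM (normalisation reference), Yoda1 + resveratrol
#' 1.7 uM. The resveratrol-only value is not printed anywhere; the default of
#' 0.2 uM is a synthetic placeholder (flagged in the `source` column) and
#' should be replaced by a measured value when one is available.
#'
#' @return Tibble with `condition`, `calcium_um`, `source`.
#' @export
default_calcium_panel <- function() {
  tibble::tibble(
    condition = c("calcium_free", "control", "resveratrol", "yoda1", "yoda1_rsv"),
    calcium_um = c(0, 0.105, 0.2, 1.0, 1.7),
    source = c("definition", "printed", "synthetic_default", "printed", "printed")
  )
}

#' Read a calcium panel file
#'
#' Accepts CSV with columns `condition, median_ratio` or
#' `condition, calcium_um`; records which was given (attribute `source` after
#' [normalize_calcium()]).
#'
#' @param path CSV path.
#' @return Tibble as read.
#' @export
read_calcium_panel <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Expand a calcium map into per-condition treatment conditions
#'
#' @param map Data frame with `condition`, `calcium_um` (e.g. from
#'   [normalize_calcium()] or [default_calcium_panel()]).
#' @param trail_ng_per_ml TRAIL dose shared by all conditions.
#' @return Named list of `cell_condition` objects, one per row.
#' @export
panel_to_conditions <- function(map, trail_ng_per_ml) {
  stopifnot(nrow(map) > 0)
  conds <- purrr::map2(map$calcium_um, map$condition,
                       ~ make_condition(trail_ng_per_ml, .x, label = .y))
  stats::setNames(conds, map$condition)
}
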