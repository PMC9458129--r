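#' Yoda1 sensitization
#'
#' Percent decrease in viability caused by adding Yoda1:
#' `100 * (dmso - yoda) / dmso`. Negative values mean Yoda1 increased
#' viability. Scale-free (doubling both viabilities leaves it unchanged).
#'
#' @param dmso_viability Vehicle-control viability (%), must be > 0.
#' @param yoda_viability Yoda1-treated viability (%).
#' @return Sensitization in percent (vectorised).
#' @examples
#' yoda1_sensitization(80, 40)  # 50
#' @export
yoda1_sensitization <- function(dmso_viability, yoda_viability) {
  stopifnot(is.numeric(dmso_viability), is.numeric(yoda_viability))
  if (any(dmso_viability <= 0))
    stop("dmso_viability must be > 0")
  if (any(dmso_viability > 100 | yoda_viability < 0 | yoda_viability > 100))
    stop("viabilities must lie in [0, 100]")
  100 * (dmso_viability - yoda_viability) / dmso_viability
}

#' Donor-quenching FRET efficiency
#'
#' `E = 1 - (FI_double - FI_background) / (FI_donor - FI_background)`, where
#' the intensities are donor-channel means of the double-stained
#' (acceptor + donor), donor-only, and unstained samples. `E` lies in [0, 1]
#' when `background <= double <= donor`; out-of-range efficiencies are
#' returned as-is with `in_range = FALSE` so questionable stains are visible,
#' not silently clipped. Invariant to adding a constant offset to all three
#' intensities.
#'
#' @param fi_double Donor-channel mean fluorescence of the double stain.
#' @param fi_donor Donor-only stain.
#' @param fi_background Unstained background; `fi_donor` must exceed it.
#' @return Tibble with `efficiency` and `in_range` (vectorised).
#' @examples
#' fret_efficiency(600, 1000, 200)  # efficiency 0.5
#' @export
fret_efficiency <- function(fi_double, fi_donor, fi_background) {
  stopifnot(is.numeric(fi_double), is.numeric(fi_donor), is.numeric(fi_background))
  if (any(fi_double < 0 | fi_donor < 0 | fi_background < 0))
    stop("fluorescence intensities must be non-negative")
  if (any(fi_donor <= fi_background))
    stop("fi_donor must exceed fi_background (zero or negative denominator)")
  e <- 1 - (fi_double - fi_background) / (fi_donor - fi_background)
  tibble::tibble(efficiency = e, in_range = e >= 0 & e <= 1)
}

#' Median ratiometric calcium fluorescence
#'
#' Per-event Fluo-4 / Fura Red ratio summarised by the median over the first
#' `window_s` seconds (the standard 200 s acquisition window). Events with
#' zero Fura Red cannot form a ratio; they are excluded and counted. When the
#' trace carries a `condition` column, one row per condition is returned.
#'
#' @param trace Data frame with columns `time_s`, `fluo4`, `furared` and
#'   optionally `condition`.
#' @param window_s Acquisition window in seconds (default 200).
#' @return Tibble with `median_ratio`, `n_events`, `n_zero_furared`
#'   (per condition when present).
#' @export
ratiometric_median <- function(trace, window_s = 200) {
  trace <- tibble::as_tibble(trace)
  stopifnot(all(c("time_s", "fluo4", "furared") %in% names(trace)))
  if (any(trace$fluo4 < 0 | trace$furared < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  win <- dplyr::filter(trace, .data$time_s >= 0, .data$time_s <= window_s)
  if (nrow(win) == 0) stop("no events within the acquisition window")
  summarise_one <- function(d) {
    ok <- d$furared > 0
    tibble::tibble(
      median_ratio = stats::median(d$fluo4[ok] / d$furared[ok]),
      n_events = sum(ok),
      n_zero_furared = sum(!ok)
    )
  }
  if ("condition" %in% names(win)) {
    win |>
      dplyr::group_by(.data$condition) |>
      dplyr::group_modify(~ summarise_one(.x)) |>
      dplyr::ungroup()
  } else {
    summarise_one(win)
  }
}

#' Time-binned mean ratio trace (for plotting)
#'
#' Companion to [ratiometric_median()]: bins events into `bin_s`-second bins
#' and returns the mean ratio per bin, for trace plots of calcium influx over
#' time.
#'
#' @param trace As in [ratiometric_median()].
#' @param bin_s Bin width in seconds.
#' @return Tibble with `time_s` (bin midpoint), `mean_ratio`, `n_events`
#'   (and `condition` when present).
#' @export
ratiometric_trace <- function(trace, bin_s = 10) {
  trace <- tibble::as_tibble(trace)
  stopifnot(all(c("time_s", "fluo4", "furared") %in% names(trace)))
  d <- dplyr::filter(trace, .data$furared > 0)
  d$bin <- floor(d$time_s / bin_s)
  grp <- intersect(c("condition", "bin"), names(d))
  d |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(mean_ratio = mean(.data$fluo4 / .data$furared),
                     n_events = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(time_s = (.data$bin + 0.5) * bin_s, .keep = "unused",
                  .before = 1)
}
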