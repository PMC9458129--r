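#' Fit a one-phase-decay viability curve
#'
#' Nonlinear least squares for the one-phase exponential decay family
#' `y(x) = (y0 - plateau) * exp(-k * x) + plateau`, the standard model for
#' viability as a function of calcium influx. Ordinary (unweighted) least
#' squares via Levenberg-Marquardt; initial values `y0 = max(y)`,
#' `plateau = min(y)`, `k = 1/median(positive x)`, with bounds `k` in [0, 100]
#' and `plateau` in [0, 100].
#'
#' @param data Optional data frame containing the variables.
#' @param x,y Calcium concentrations (uM) and viabilities (%); bare column
#'   names when `data` is given (defaults `calcium_um`, `viability_percent`),
#'   numeric vectors otherwise.
#' @return An object of class `decay_fit` with elements `coefficients`
#'   (`y0`, `plateau`, `k`), `rss`, `residuals`, `fitted`, `data`,
#'   `converged`, `message`, and the underlying `nls` object.
#' @examples
#' x <- c(0, 0.1, 0.2, 1, 1.7)
#' y <- (70 - 46) * exp(-3 * x) + 46
#' coef(fit_one_phase_decay(x = x, y = y))
#' @export
fit_one_phase_decay <- function(data = NULL, x = calcium_um, y = viability_percent) {
  if (!is.null(data)) {
    x <- rlang::eval_tidy(rlang::enquo(x), data)
    y <- rlang::eval_tidy(rlang::enquo(y), data)
  }
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(unique(x)) < 3)
    stop("one-phase decay needs at least 3 distinct x values")
  d <- tibble::tibble(x = x, y = y)
  med <- stats::median(x[x > 0])
  start <- list(y0 = max(y), plateau = min(y),
                k = if (is.finite(med) && med > 0) 1 / med else 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ (y0 - plateau) * exp(-k * x) + plateau,
                      data = d, start = start,
                      lower = c(y0 = -Inf, plateau = 0, k = 0),
                      upper = c(y0 = Inf, plateau = 100, k = 100),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    # degenerate least-squares geometry (e.g. y taking very few distinct
    # values at small n): profile over k and solve the remaining linear
    # problem; reported as such, never silently
    prof <- profile_decay_fit(d)
    warning("one-phase decay: Levenberg-Marquardt failed (",
            conditionMessage(fit), "); used a profile-over-k fallback")
    return(prof)
  }
  cf <- stats::coef(fit)
  res <- stats::residuals(fit)
  structure(list(coefficients = cf,
                 rss = sum(res^2),
                 residuals = as.numeric(res),
                 fitted = as.numeric(stats::fitted(fit)),
                 data = d,
                 converged = fit$convInfo$isConv,
                 message = fit$convInfo$stopMessage,
                 nls = fit),
            class = "decay_fit")
}

# grid-profile the decay rate; for each k the model is linear in
# (y0, plateau), so ordinary least squares solves the rest
profile_decay_fit <- function(d) {
  ks <- c(0, exp(seq(log(1e-3), log(100), length.out = 400)))
  best <- NULL
  for (k in ks) {
    b <- exp(-k * d$x)
    co <- tryCatch(stats::lm.fit(cbind(plateau = 1 - b, y0 = b), d$y)$coefficients,
                   error = function(e) NULL)
    if (is.null(co) || anyNA(co)) next
    co["plateau"] <- min(max(co[["plateau"]], 0), 100)
    fitted <- (co[["y0"]] - co[["plateau"]]) * b + co[["plateau"]]
    rss <- sum((d$y - fitted)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(k = k, y0 = co[["y0"]], plateau = co[["plateau"]],
                   rss = rss, fitted = fitted)
  }
  if (is.null(best)) stop("one-phase decay fit failed to converge")
  structure(list(coefficients = c(y0 = best$y0, plateau = best$plateau,
                                  k = best$k),
                 rss = best$rss,
                 residuals = as.numeric(d$y - best$fitted),
                 fitted = as.numeric(best$fitted),
                 data = d,
                 converged = TRUE,
                 message = "profile-over-k fallback",
                 nls = NULL),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf("<decay_fit: y0 = %.3f, plateau = %.3f, k = %.4f per uM; RSS = %.4g>\n",
              cf[["y0"]], cf[["plateau"]], cf[["k"]], x$rss))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) object$coefficients

#' Predict from a one-phase-decay fit
#' @param object A `decay_fit`.
#' @param newdata Optional data frame with column `x` (or `calcium_um`), or a
#'   numeric vector of x values.
#' @param ... Unused.
#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  cf <- object$coefficients
  xv <- if (is.null(newdata)) object$data$x
        else if (is.numeric(newdata)) newdata
        else (newdata$x %||% newdata$calcium_um)
  (cf[["y0"]] - cf[["plateau"]]) * exp(-cf[["k"]] * xv) + cf[["plateau"]]
}

#' Tidy a one-phase-decay fit
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`term`, `estimate`, `std.error`).
#' @export
tidy.decay_fit <- function(x, ...) {
  s <- tryCatch(summary(x$nls)$coefficients, error = function(e) NULL)
  tibble::tibble(
    term = names(x$coefficients),
    estimate = as.numeric(x$coefficients),
    std.error = if (!is.null(s)) s[names(x$coefficients), "Std. Error"] else NA_real_
  )
}

#' Glance at a one-phase-decay fit
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @return One-row tibble with RSS, n, convergence diagnostics.
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = nrow(x$data),
                 sigma = sqrt(x$rss / max(1, nrow(x$data) - 3)),
                 converged = isTRUE(x$converged), message = x$message)
}

#' Summarise population results into a per-condition table
#'
#' One row per condition: calcium, viability, the mean cell's apoptosis and
#' MOMP hours, seed and n. Conditions sharing a label are kept (no silent
#' de-duplication) and flagged in `duplicated_label`. All results must share
#' the TRAIL dose.
#'
#' @param results A list of `population_result` objects.
#' @return Tibble sorted by calcium concentration.
#' @export
condition_table <- function(results) {
  if (inherits(results, "population_result")) results <- list(results)
  stopifnot(length(results) > 0)
  tab <- purrr::map_dfr(results, glance)
  if (dplyr::n_distinct(tab$trail_ng_per_ml) > 1)
    stop("condition_table expects results sharing a single TRAIL dose")
  tab$duplicated_label <- duplicated(tab$condition) |
    duplicated(tab$condition, fromLast = TRUE)
  dplyr::arrange(tab, .data$calcium_um)
}
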