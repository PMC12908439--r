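#' Classify Prony poles as stable or unstable
#'
#' A pole is stable when it lies on or inside the unit circle
#' (`|mu| <= 1`, equivalently damping `sigma = ln|mu| <= 0`): its component
#' does not grow in time. Poles outside the circle are unstable. Poles
#' exactly on the circle are undamped cosines and count as stable.
#'
#' @param model A [prony_model].
#' @param tol Nonnegative slack on the boundary: poles with
#'   `|mu| <= 1 + tol` are classified stable. The default 0 applies the
#'   definition exactly; a small positive value absorbs round-off for poles
#'   numerically on the circle.
#' @return Logical vector, `TRUE` for stable poles.
#' @export
classify_poles <- function(model, tol = 0) {
  stopifnot(inherits(model, "prony_model"))
  if (tol < 0) stop("'tol' must be >= 0")
  Mod(model$poles) <= 1 + tol
}

#' Refit a model keeping only its stable poles
#'
#' Drops unstable poles and re-solves the coefficients against the original
#' signal with the same scale factor. The resulting all-stable model cannot
#' diverge when used for forward-time extrapolation.
#'
#' @inheritParams solve_linear_prediction
#' @param model The [prony_model] previously fitted to `signal`.
#' @param tol Stability boundary slack passed to [classify_poles()].
#' @return A [prony_model] containing only the stable poles, with
#'   re-solved coefficients, updated `r_squared`, and attribute `n_removed`
#'   (number of unstable poles dropped).
#' @export
stable_refit <- function(signal, model, tol = 0) {
  signal <- as_prony_signal(signal)
  stopifnot(inherits(model, "prony_model"))
  stable <- classify_poles(model, tol)
  if (!any(stable))
    stop("cannot refit with stable poles only: the model has no stable poles")
  mu <- model$poles[stable]
  co <- fit_coefficients(signal, mu, model$scale_d)
  ord <- order(-Mod(co), Arg(co))
  out <- prony_model(mu[ord], co[ord], scale_d = model$scale_d,
                     sampling_rate = model$sampling_rate,
                     source_length = model$source_length,
                     label = model$label)
  fitted <- evaluate_model(out)
  out$r_squared <- r_squared(signal$samples, fitted)
  out$fitted <- fitted
  attr(out, "n_removed") <- sum(!stable)
  out
}

#' Pole-diagram metrics
#'
#' Summarizes the pole diagram of a model with the importance-weighted
#' metrics used to compare hemodynamic states:
#' \describe{
#'   \item{importance}{`alpha_i = |C_i| / max |C_i|`, in `[0, 1]`.}
#'   \item{mean angle}{weighted mean of the principal pole angles
#'     `theta_i = Arg(mu_i)` in degrees. The default weighting is
#'     `sum(alpha_i theta_i) / sum(alpha_i)`; `as_printed = TRUE` divides by
#'     `sum(theta_i)` instead (see Details).}
#'   \item{dispersion}{`1 / sd(|C_i|)` (n-1 denominator). Low when all poles
#'     carry equal weight; `+Inf` (flagged) when all `|C_i|` are equal.}
#'   \item{unit-circle deviation}{distances `| |mu_i| - 1 |` (inward and
#'     outward both count); reported as the mean of the 5 largest distances
#'     (all of them when fewer than 5 poles, flagged) and the count of poles
#'     at least `threshold` units off the circle.}
#' }
#'
#' @details The `sum(theta_i)` denominator fails the single-pole sanity check
#' (the "mean angle" of one pole would be its importance, not its angle) and
#' changes sign with the angle sum, so the importance-normalized weighted
#' mean is the default; the other form remains available for comparison.
#' Angles are principal values in `(-180, 180]` degrees, treated linearly
#' (no circular averaging).
#'
#' @param model A [prony_model].
#' @param subset `"all"` poles or `"stable"` only (the latter is the basis
#'   of the significant-damping analysis, where only inward deviations can
#'   occur).
#' @param threshold Off-circle distance threshold (default 0.2).
#' @param as_printed Use `sum(theta_i)` as the mean-angle denominator.
#' @param tol Stability boundary slack for `subset = "stable"`.
#' @return Object of class `pole_metrics`: list with `importance`,
#'   `mean_angle_deg`, `dispersion`, `dispersion_infinite`,
#'   `top5_mean_distance`, `top5_partial`, `n_off_unit_circle`, `n_stable`,
#'   `n_unstable`, `n_considered`, `subset`, `threshold`.
#' @export
pole_metrics <- function(model, subset = c("all", "stable"), threshold = 0.2,
                         as_printed = FALSE, tol = 0) {
  stopifnot(inherits(model, "prony_model"))
  subset <- match.arg(subset)
  if (!is.numeric(threshold) || threshold <= 0)
    stop("'threshold' must be positive")
  if (model$n_components < 1L) stop("the model has no components")
  stable <- classify_poles(model, tol)
  keep <- if (subset == "stable") stable else rep(TRUE, model$n_components)
  if (!any(keep)) stop("the '", subset, "' pole subset is empty")
  mu <- model$poles[keep]
  cmag <- Mod(model$coefficients[keep])

  alpha <- if (max(cmag) > 0) cmag / max(cmag) else rep(0, length(cmag))
  theta <- Arg(mu) * 180 / pi
  denom <- if (as_printed) sum(theta) else sum(alpha)
  mean_angle <- if (denom == 0) NA_real_ else sum(alpha * theta) / denom

  s <- stats::sd(cmag)
  disp_inf <- isTRUE(s == 0) || length(cmag) < 2L
  dispersion <- if (disp_inf) Inf else 1 / s

  dist <- abs(Mod(mu) - 1)
  k <- min(5L, length(dist))
  top5 <- mean(sort(dist, decreasing = TRUE)[seq_len(k)])

  structure(
    list(importance = alpha,
         mean_angle_deg = mean_angle,
         dispersion = dispersion,
         dispersion_infinite = disp_inf,
         top5_mean_distance = top5,
         top5_partial = length(dist) < 5L,
         n_off_unit_circle = sum(dist >= threshold),
         n_stable = sum(stable),
         n_unstable = sum(!stable),
         n_considered = length(mu),
         subset = subset,
         threshold = threshold),
    class = "pole_metrics")
}

#' @export
print.pole_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("<pole_metrics (%s, %d poles): mean angle %.2f deg, ",
           "dispersion %.4g%s, top-5 distance %.4g%s, ",
           "%d off circle (>= %.2g), %d stable / %d unstable>\n"),
    x$subset, x$n_considered, x$mean_angle_deg, x$dispersion,
    if (x$dispersion_infinite) " (infinite)" else "",
    x$top5_mean_distance, if (x$top5_partial) " (fewer than 5 poles)" else "",
    x$n_off_unit_circle, x$threshold, x$n_stable, x$n_unstable))
  invisible(x)
}

#' Pressure-to-volume ratio of unit-circle metrics
#'
#' Ratio of the pressure-model metric to the volume-model metric, for both
#' the top-5 mean distance from the unit circle and the off-circle pole
#' count. Used to compare the damping content of the two waveforms.
#'
#' @param metrics_pressure,metrics_volume [pole_metrics()] results for the
#'   pressure and volume models.
#' @return Named numeric vector with elements `top5_distance_ratio` and
#'   `off_circle_ratio`.
#' @export
pole_ratio <- function(metrics_pressure, metrics_volume) {
  stopifnot(inherits(metrics_pressure, "pole_metrics"),
            inherits(metrics_volume, "pole_metrics"))
  if (metrics_volume$top5_mean_distance == 0)
    stop("undefined ratio: volume top-5 mean distance is zero")
  if (metrics_volume$n_off_unit_circle == 0)
    stop("undefined ratio: volume off-circle pole count is zero")
  c(top5_distance_ratio =
      metrics_pressure$top5_mean_distance / metrics_volume$top5_mean_distance,
    off_circle_ratio =
      metrics_pressure$n_off_unit_circle / metrics_volume$n_off_unit_circle)
}
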