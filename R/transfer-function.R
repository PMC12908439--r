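#' Laplace transform of a sum of damped cosines
#'
#' Closed-form Laplace transform of `sum_i A_i e^(sigma_i t) cos(2 pi f_i t
#' + phi_i)` evaluated at complex `s`:
#' `sum_i A_i [cos(phi_i) (s - sigma_i) - 2 pi f_i sin(phi_i)] /
#'  [(s - sigma_i)^2 + 4 pi^2 f_i^2]`.
#' Parameters are in physical units (`sigma` in 1/s, `f` in Hz).
#'
#' @param components Data frame with columns `amplitude`, `damping`
#'   (or `damping_per_s`), `frequency` (or `frequency_hz`) and `phase`, as
#'   produced by the component folding of a fitted model.
#' @param s Complex vector of Laplace-domain evaluation points; none may
#'   coincide with a component pole `sigma_i +/- 2 pi f_i j`.
#' @param tol Absolute distance to a component pole below which evaluation
#'   is refused.
#' @return Complex vector, one value per element of `s`.
#' @examples
#' const <- data.frame(amplitude = 1, damping = 0, frequency = 0, phase = 0)
#' laplace_of_components(const, 2 + 0i)  # L{1} = 1/s = 0.5
#' @export
laplace_of_components <- function(components, s, tol = 1e-12) {
  comp <- .as_physical_components(components)
  s <- as.complex(s)
  if (nrow(comp) < 1L) stop("'components' must be nonempty")
  w <- 2 * pi * comp$frequency
  cpoles <- c(complex(real = comp$damping, imaginary = w),
              complex(real = comp$damping, imaginary = -w))
  for (k in seq_along(s)) {
    dmin <- min(Mod(s[k] - cpoles))
    if (dmin <= tol) {
      i <- ((which.min(Mod(s[k] - cpoles)) - 1L) %% nrow(comp)) + 1L
      stop(sprintf(
        "s = %g%+gi lies on the pole of component %d (sigma = %g, f = %g Hz)",
        Re(s[k]), Im(s[k]), i, comp$damping[i], comp$frequency[i]))
    }
  }
  .laplace_sum(comp, s)
}

## Closed-form sum without the singularity guard; yields Inf/NaN at
## component poles, which grid-based callers mask.
.laplace_sum <- function(comp, s) {
  w <- 2 * pi * comp$frequency
  out <- rep(0 + 0i, length(s))
  for (i in seq_len(nrow(comp))) {
    sm <- s - comp$damping[i]
    out <- out + comp$amplitude[i] *
      (cos(comp$phase[i]) * sm - w[i] * sin(comp$phase[i])) /
      (sm^2 + w[i]^2)
  }
  out
}

## Normalize a component table to physical-unit columns amplitude, damping,
## frequency, phase.
.as_physical_components <- function(components) {
  stopifnot(is.data.frame(components))
  damping <- if ("damping_per_s" %in% names(components))
    components$damping_per_s else components$damping
  frequency <- if ("frequency_hz" %in% names(components))
    components$frequency_hz else components$frequency
  if (is.null(damping) || is.null(frequency) ||
      is.null(components$amplitude) || is.null(components$phase))
    stop("'components' needs columns amplitude, damping, frequency, phase")
  data.frame(amplitude = components$amplitude, damping = damping,
             frequency = frequency, phase = components$phase)
}

#' Build the pressure-to-volume transfer function
#'
#' Forms the analytic transfer function `Z(s)` as the ratio of the
#' closed-form Laplace transforms of the pressure and volume Prony fits.
#' The poles of the pressure model are poles of `Z` and the poles of the
#' volume model are its zeros, so the two pole diagrams serve as
#' "pseudo-pole" diagrams of the transfer function and can be analyzed with
#' [pole_metrics()] directly.
#'
#' @param model_pressure,model_volume Fitted [prony_model]s of the pressure
#'   and volume waveforms; they must share a sampling rate.
#' @return Object of class `prony_tf`: list with `numerator_components` and
#'   `denominator_components` (folded real components in physical units),
#'   `pressure_poles` (poles of `Z`), `volume_poles` (zeros of `Z`), and
#'   `sampling_rate`.
#' @export
build_transfer_function <- function(model_pressure, model_volume) {
  stopifnot(inherits(model_pressure, "prony_model"),
            inherits(model_volume, "prony_model"))
  if (model_pressure$sampling_rate != model_volume$sampling_rate)
    stop("pressure and volume models have different sampling rates (",
         model_pressure$sampling_rate, " vs ", model_volume$sampling_rate, ")")
  if (model_pressure$n_components < 1L || model_volume$n_components < 1L)
    stop("both models must have at least one component")
  structure(
    list(numerator_components = .fold_model(model_pressure),
         denominator_components = .fold_model(model_volume),
         pressure_poles = model_pressure$poles,
         volume_poles = model_volume$poles,
         sampling_rate = model_pressure$sampling_rate),
    class = "prony_tf")
}

#' @export
print.prony_tf <- function(x, ...) {
  cat(sprintf(
    "<prony_tf: %d numerator x %d denominator components, SR = %g Hz>\n",
    nrow(x$numerator_components), nrow(x$denominator_components),
    x$sampling_rate))
  invisible(x)
}

#' Evaluate a transfer function at complex frequencies
#'
#' Ratio of the numerator (pressure) and denominator (volume) Laplace sums.
#'
#' @param tf A `prony_tf` from [build_transfer_function()].
#' @param s Complex vector of evaluation points.
#' @param tol Denominator magnitude below which the point is treated as a
#'   singularity.
#' @return Complex vector of `Z(s)` values.
#' @export
evaluate_tf <- function(tf, s, tol = 1e-12) {
  stopifnot(inherits(tf, "prony_tf"))
  num <- laplace_of_components(tf$numerator_components, s)
  den <- laplace_of_components(tf$denominator_components, s)
  bad <- Mod(den) <= tol
  if (any(bad))
    stop(sprintf(
      "transfer function singular at s = %g%+gi (|denominator| = %g)",
      Re(s[bad][1L]), Im(s[bad][1L]), Mod(den[bad][1L])))
  num / den
}

#' Bode curve of a transfer function
#'
#' Samples `Z(j 2 pi f)` on a regular frequency grid (default 1 to 100 Hz in
#' 1 Hz steps, covering the physiologically relevant range for rodents) and
#' reports magnitude in dB (20 log10 |Z|, with the linear magnitude kept
#' alongside) and phase in degrees, unwrapped along the grid. Grid points
#' falling on a singularity are masked (`NA`) and flagged rather than
#' aborting the curve.
#'
#' @param tf A `prony_tf`.
#' @param f_min_hz,f_max_hz,step_hz Frequency grid in Hz.
#' @param tol Singularity tolerance on the denominator magnitude.
#' @return Object of class `bode_curve`: data frame with `frequency_hz`,
#'   `magnitude_db`, `magnitude_linear`, `phase_deg`, `masked`.
#' @export
bode <- function(tf, f_min_hz = 1, f_max_hz = 100, step_hz = 1, tol = 1e-12) {
  stopifnot(inherits(tf, "prony_tf"))
  if (!(f_min_hz > 0 || f_min_hz == 0) || f_max_hz <= f_min_hz || step_hz <= 0)
    stop("invalid Bode frequency grid")
  f <- seq(f_min_hz, f_max_hz, by = step_hz)
  s <- complex(real = 0, imaginary = 2 * pi * f)
  num <- .laplace_sum(.as_physical_components(tf$numerator_components), s)
  den <- .laplace_sum(.as_physical_components(tf$denominator_components), s)
  masked <- !is.finite(Mod(num)) | !is.finite(Mod(den)) | Mod(den) <= tol
  z <- num / den
  z[masked] <- NA_complex_
  mag <- Mod(z)
  phase <- .unwrap_deg(Arg(z) * 180 / pi)
  structure(
    data.frame(frequency_hz = f,
               magnitude_db = 20 * log10(mag),
               magnitude_linear = mag,
               phase_deg = phase,
               masked = masked),
    class = c("bode_curve", "data.frame"))
}

## Unwrap a phase sequence in degrees; NA entries are carried through
## without breaking the accumulated offset.
.unwrap_deg <- function(p) {
  ok <- which(!is.na(p))
  if (length(ok) < 2L) return(p)
  v <- p[ok]
  jumps <- diff(v)
  corr <- cumsum(-360 * round(jumps / 360))
  v[-1L] <- v[-1L] + corr
  p[ok] <- v
  p
}

#' Average Bode curves into a composite
#'
#' Pointwise arithmetic mean of magnitude (dB) and phase (degrees) across
#' curves sharing a frequency grid; masked points are excluded from the mean
#' at their frequency.
#'
#' @param curves List of `bode_curve` objects with identical grids.
#' @return A `bode_curve` of the same grid.
#' @export
composite_bode <- function(curves) {
  if (!is.list(curves) || length(curves) < 1L ||
      !all(vapply(curves, inherits, logical(1), "bode_curve")))
    stop("'curves' must be a nonempty list of bode_curve objects")
  f <- curves[[1L]]$frequency_hz
  for (cv in curves)
    if (length(cv$frequency_hz) != length(f) ||
        any(cv$frequency_hz != f))
      stop("all Bode curves must share the same frequency grid")
  mag_db  <- rowMeans(sapply(curves, `[[`, "magnitude_db"), na.rm = TRUE)
  phase   <- rowMeans(sapply(curves, `[[`, "phase_deg"), na.rm = TRUE)
  mag_db[!is.finite(mag_db)] <- NA_real_
  phase[!is.finite(phase)] <- NA_real_
  structure(
    data.frame(frequency_hz = f,
               magnitude_db = mag_db,
               magnitude_linear = 10^(mag_db / 20),
               phase_deg = phase,
               masked = is.na(mag_db)),
    class = c("bode_curve", "data.frame"))
}
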