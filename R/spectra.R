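## Fold the complex components of a model fitted to a real signal into real
## damped cosines. Conjugate pole pairs are merged into one component at
## f >= 0 with the paired amplitudes combined (|C_i| + |C_j|, i.e. 2|C| for
## an exact pair), so a unit cosine reports amplitude 1. Unpaired components
## with negative frequency are mapped to their conjugate representative.
.fold_model <- function(model, pair_tol = 1e-6) {
  stopifnot(inherits(model, "prony_model"))
  mu <- model$poles; co <- model$coefficients
  n <- length(mu)
  used <- rep(FALSE, n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (used[i]) next
    used[i] <- TRUE
    partner <- NA_integer_
    if (abs(Im(mu[i])) > 0) {
      cand <- which(!used)
      if (length(cand)) {
        dist <- Mod(Conj(mu[i]) - mu[cand])
        j <- cand[which.min(dist)]
        if (length(dist) && min(dist) <= pair_tol * (1 + Mod(mu[i])))
          partner <- j
      }
    }
    if (!is.na(partner)) {
      used[partner] <- TRUE
      rep_i <- if (Arg(mu[i]) >= 0) i else partner
      amp <- Mod(co[i]) + Mod(co[partner])
    } else {
      rep_i <- i
      amp <- Mod(co[i])
    }
    m <- mu[rep_i]; cc <- co[rep_i]
    if (Arg(m) < 0) { m <- Conj(m); cc <- Conj(cc) }   # lone negative-f term
    rows[[i]] <- data.frame(
      amplitude = amp,
      damping   = log(Mod(m)),
      frequency = Arg(m) / (2 * pi),
      phase     = Arg(cc),
      paired    = !is.na(partner)
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  sr_d <- model$sampling_rate / model$scale_d
  out$damping_per_s <- out$damping * sr_d
  out$frequency_hz  <- out$frequency * sr_d
  rownames(out) <- NULL
  out
}

#' Prony amplitude, damping and phase spectra
#'
#' A Prony model yields, in addition to an amplitude and a phase spectrum,
#' a spectrum of the damping coefficient -- a spectral feature a Fourier
#' analysis does not provide. Each folded real component contributes one
#' point at its physical frequency (Hz, conjugate pairs merged at `f >= 0`
#' with combined amplitude).
#'
#' @param model A [prony_model].
#' @return Named list of three data frames (`amplitude`, `damping`, `phase`),
#'   each with columns `frequency_hz` and `value`, sorted by frequency, and a
#'   `kind` attribute. Damping values are in 1/s, phases in radians.
#' @export
prony_spectra <- function(model) {
  comp <- .fold_model(model)
  ord <- order(comp$frequency_hz)
  comp <- comp[ord, , drop = FALSE]
  mk <- function(values, kind) {
    structure(data.frame(frequency_hz = comp$frequency_hz, value = values),
              kind = kind)
  }
  list(amplitude = mk(comp$amplitude, "amplitude"),
       damping   = mk(comp$damping_per_s, "damping"),
       phase     = mk(comp$phase, "phase"))
}

#' Most significant Prony components with their time traces
#'
#' Selects the `k` components of largest coefficient magnitude `|C|` and
#' evaluates each one's time course `Re(C mu^(k/d))` over the source window,
#' e.g. to display the dominant damped sinusoids of a pressure waveform.
#'
#' @param model A [prony_model].
#' @param k Number of components, `1 <= k <= N`.
#' @return List with `components` (data frame of the selected components,
#'   scaled and physical units, in descending `|C|` order) and `traces`
#'   (numeric `M x k` matrix, one column per component). The column sums of
#'   `traces` over all `k = N` components equal the full reconstruction.
#' @export
top_components <- function(model, k) {
  stopifnot(inherits(model, "prony_model"))
  N <- model$n_components
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > N)
    stop("'k' must be an integer in [1, N] = [1, ", N, "]")
  ord <- order(-Mod(model$coefficients), Arg(model$coefficients))[seq_len(k)]
  comp <- components_from_poles(model$poles[ord], model$coefficients[ord],
                                model$sampling_rate, model$scale_d)
  comp <- cbind(index = ord, comp)
  tau <- (seq_len(model$source_length) - 1) / model$scale_d
  V <- .pole_powers(model$poles[ord], tau)
  traces <- Re(sweep(V, 2L, model$coefficients[ord], `*`))
  colnames(traces) <- paste0("component_", seq_len(k))
  list(components = comp, traces = traces)
}

#' One-sided Fourier power spectral density
#'
#' Discrete power spectrum on the Fourier grid `k/T`: `|DFT|^2 / M^2` with
#' one-sided doubling of all bins except DC and (for even `M`) Nyquist. With
#' this normalization the total one-sided power equals the mean squared
#' signal (Parseval).
#'
#' @inheritParams solve_linear_prediction
#' @return Data frame with `frequency_hz` and `power`, `kind` attribute
#'   `"power"`.
#' @examples
#' s <- prony_signal(cos(2 * pi * 7 * seq(0, 0.999, by = 0.001)), 1000)
#' ps <- fourier_power_spectrum(s)
#' ps$frequency_hz[which.max(ps$power)]  # 7
#' @export
fourier_power_spectrum <- function(signal) {
  signal <- as_prony_signal(signal)
  y <- signal$samples
  M <- length(y)
  X <- stats::fft(y)
  n_keep <- floor(M / 2) + 1L
  p <- Mod(X[seq_len(n_keep)])^2 / M^2
  dbl <- rep(2, n_keep); dbl[1L] <- 1
  if (M %% 2 == 0) dbl[n_keep] <- 1
  structure(
    data.frame(frequency_hz = (seq_len(n_keep) - 1) * signal$sampling_rate / M,
               power = p * dbl),
    kind = "power")
}

#' Frequency of the dominant spectral peak
#'
#' Frequency of the maximum-power (or maximum-value) bin of a spectrum. The
#' DC bin is excluded by default, since for baseline-offset physiological
#' signals the zero-frequency term reflects the mean level rather than
#' pulsatile content: for a pressure waveform the dominant peak then sits at
#' the heart-rate fundamental.
#'
#' @param spectrum Data frame with `frequency_hz` and a value column
#'   (`power` or `value`), as returned by [fourier_power_spectrum()].
#' @param exclude_dc Drop the `frequency_hz == 0` bin before locating the
#'   maximum.
#' @return Frequency in Hz of the maximum bin.
#' @examples
#' pv <- make_pv_waveforms(pv_sim_config())
#' dominant_frequency(fourier_power_spectrum(pv$pressure))  # 7 Hz
#' @export
dominant_frequency <- function(spectrum, exclude_dc = TRUE) {
  stopifnot(is.data.frame(spectrum), "frequency_hz" %in% names(spectrum))
  vals <- if ("power" %in% names(spectrum)) spectrum$power else spectrum$value
  keep <- if (exclude_dc) spectrum$frequency_hz > 0 else
    rep(TRUE, nrow(spectrum))
  if (!any(keep)) stop("no bins left after excluding DC")
  f <- spectrum$frequency_hz[keep]
  f[which.max(vals[keep])]
}

#' Truncated Fourier series fit
#'
#' Least-squares fit of a truncated Fourier series on the fundamental `1/T`
#' (T the record length): intercept plus `n_harmonics` cosine/sine pairs.
#' Fitting by least squares rather than coefficient integration keeps the fit
#' defined when the record holds a non-integer number of cycles, the regime
#' in which Fourier series fits show edge effects. Used as the classical
#' comparator for the Prony decomposition.
#'
#' @inheritParams solve_linear_prediction
#' @param n_harmonics Number of harmonics (>= 1). At `floor(M/2)` the basis
#'   is complete and the fit interpolates the signal.
#' @return List of class `fourier_fit`: `fitted` values, `r_squared`,
#'   `coefficients` (intercept, then cosine/sine pairs per harmonic), and
#'   `amplitude_spectrum` (data frame `frequency_hz`, `value`: `|a0|` at DC,
#'   `sqrt(a_j^2 + b_j^2)` per harmonic).
#' @export
fourier_series_fit <- function(signal, n_harmonics) {
  signal <- as_prony_signal(signal)
  y <- signal$samples
  M <- length(y)
  H <- as.integer(n_harmonics)
  if (length(H) != 1L || is.na(H) || H < 1L)
    stop("'n_harmonics' must be an integer >= 1")
  T_rec <- M / signal$sampling_rate
  t <- (seq_len(M) - 1) / signal$sampling_rate
  X <- matrix(1, nrow = M, ncol = 1L + 2L * H)
  for (j in seq_len(H)) {
    w <- 2 * pi * j * t / T_rec
    X[, 2L * j]      <- cos(w)
    X[, 2L * j + 1L] <- sin(w)
  }
  beta <- qr.coef(qr(X), y)      # pivoted QR: aliased columns come back NA
  beta[is.na(beta)] <- 0
  fitted <- drop(X %*% beta)
  amp <- c(abs(beta[1L]),
           sqrt(beta[2 * seq_len(H)]^2 + beta[2 * seq_len(H) + 1L]^2))
  structure(
    list(fitted = fitted,
         r_squared = r_squared(y, fitted),
         coefficients = beta,
         amplitude_spectrum = structure(
           data.frame(frequency_hz = (0:H) / T_rec, value = amp),
           kind = "amplitude")),
    class = "fourier_fit")
}
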