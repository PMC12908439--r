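#' Damped-sinusoid component (physical units)
#'
#' One real component `A e^(sigma t) cos(2 pi f t + phi)` of a generative
#' damped-sinusoid model, with damping in 1/s and frequency in Hz.
#'
#' @param amplitude Amplitude `A >= 0`, signal units.
#' @param damping Damping coefficient `sigma`, 1/s (negative decays).
#' @param frequency Frequency `f`, Hz.
#' @param phase Phase `phi`, radians; wrapped to `(-pi, pi]`.
#' @return One-row data frame with columns `amplitude`, `damping`,
#'   `frequency`, `phase`. Rows can be `rbind`-ed into a component table.
#' @export
prony_component <- function(amplitude, damping = 0, frequency = 0, phase = 0) {
  if (amplitude < 0) stop("'amplitude' must be >= 0")
  phase <- ((phase + pi) %% (2 * pi)) - pi
  if (phase == -pi) phase <- pi
  data.frame(amplitude = amplitude, damping = damping,
             frequency = frequency, phase = phase)
}

#' Generate an exact sum of damped sinusoids
#'
#' Samples `y(t_k) = sum_i A_i e^(sigma_i t_k) cos(2 pi f_i t_k + phi_i)` on
#' a uniform grid. The component table is attached as ground truth so
#' recovery tests can compare fitted against generating parameters.
#'
#' @param components Nonempty component table (rows of [prony_component()]).
#' @param sampling_rate Sampling rate, Hz.
#' @param duration Record length, s.
#' @param label Signal label.
#' @return A [prony_signal] with attribute `ground_truth` (the component
#'   table).
#' @examples
#' s <- make_damped_sinusoids(prony_component(1, -2, 5), 200, 1)
#' @export
make_damped_sinusoids <- function(components, sampling_rate, duration,
                                  label = "signal") {
  comp <- .as_physical_components(components)
  if (nrow(comp) < 1L) stop("'components' must be nonempty")
  t <- seq(0, duration - 1 / sampling_rate, by = 1 / sampling_rate)
  y <- rep(0, length(t))
  for (i in seq_len(nrow(comp)))
    y <- y + comp$amplitude[i] * exp(comp$damping[i] * t) *
      cos(2 * pi * comp$frequency[i] * t + comp$phase[i])
  out <- prony_signal(y, sampling_rate, label = label)
  attr(out, "ground_truth") <- comp
  out
}

#' Simulation configuration for pulsatile pressure-volume waveforms
#'
#' Defaults emulate a 1 s left-ventricular catheterization record from an
#' anesthetized rat: heart rate 420 bpm (7 Hz fundamental), 1000 Hz sampling,
#' pressure spanning 80-120 mmHg and volume 150-350 uL over the cardiac
#' cycle.
#'
#' @param heart_rate_bpm Heart rate, beats per minute (> 0).
#' @param sampling_rate Sampling rate, Hz.
#' @param duration Record length, s (`duration * sampling_rate >= 4`).
#' @param n_harmonics Number of harmonics of the fundamental used to shape
#'   the pulse (>= 2).
#' @param systolic_pressure,diastolic_pressure Pressure extremes, mmHg
#'   (systolic > diastolic).
#' @param end_diastolic_volume,end_systolic_volume Volume extremes, uL
#'   (EDV > ESV).
#' @param noise_sd Standard deviation of additive white Gaussian measurement
#'   noise, signal units (>= 0).
#' @param seed Integer seed governing all randomness of the generator.
#' @return Object of class `pv_sim_config`.
#' @export
pv_sim_config <- function(heart_rate_bpm = 420, sampling_rate = 1000,
                          duration = 1, n_harmonics = 8,
                          systolic_pressure = 120, diastolic_pressure = 80,
                          end_diastolic_volume = 350,
                          end_systolic_volume = 150,
                          noise_sd = 0, seed = 1L) {
  if (heart_rate_bpm <= 0) stop("'heart_rate_bpm' must be positive")
  if (sampling_rate <= 0) stop("'sampling_rate' must be positive")
  if (duration * sampling_rate < 4) stop("need at least 4 samples")
  if (n_harmonics < 2) stop("'n_harmonics' must be >= 2")
  if (systolic_pressure <= diastolic_pressure)
    stop("systolic pressure must exceed diastolic pressure")
  if (end_diastolic_volume <= end_systolic_volume)
    stop("end-diastolic volume must exceed end-systolic volume")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  structure(
    list(heart_rate_bpm = heart_rate_bpm, sampling_rate = sampling_rate,
         duration = duration, n_harmonics = as.integer(n_harmonics),
         systolic_pressure = systolic_pressure,
         diastolic_pressure = diastolic_pressure,
         end_diastolic_volume = end_diastolic_volume,
         end_systolic_volume = end_systolic_volume,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "pv_sim_config")
}

## Periodic pulse shape: decaying-amplitude harmonics 1/k with fixed
## per-harmonic phases. Returns samples plus the exact harmonic component
## table of the affinely rescaled signal spanning [lo, hi].
.harmonic_pulse <- function(t, f0, n_harmonics, phases, lo, hi) {
  s <- rep(0, length(t))
  for (k in seq_len(n_harmonics))
    s <- s + (1 / k) * cos(2 * pi * k * f0 * t + phases[k])
  rng <- range(s)
  gain <- (hi - lo) / (rng[2L] - rng[1L])
  offset <- lo - gain * rng[1L]
  comp <- rbind(
    prony_component(abs(offset), 0, 0, if (offset >= 0) 0 else pi),
    do.call(rbind, lapply(seq_len(n_harmonics), function(k)
      prony_component(gain / k, 0, k * f0, phases[k]))))
  list(samples = offset + gain * s, components = comp)
}

#' Generate synthetic pressure and volume waveforms
#'
#' Builds periodic pulsatile waveforms at the fundamental
#' `f0 = heart_rate_bpm / 60` from `n_harmonics` decaying-amplitude
#' harmonics (amplitude `1/k`, fixed per-harmonic phases), affinely rescaled
#' so the noiseless pressure spans `[diastolic, systolic]` and the volume
#' spans `[ESV, EDV]`. The volume harmonics are in counter-phase with the
#' pressure (filling while pressure falls). Optional additive white Gaussian
#' noise is drawn from the configured seed; equal seeds give identical
#' signals. Both noiseless waveforms are exact finite Prony models (DC plus
#' `n_harmonics` undamped cosines), recorded as ground truth.
#'
#' @param config A [pv_sim_config()].
#' @return List with `pressure` and `volume` ([prony_signal]s) and
#'   `ground_truth` (list of the two exact harmonic component tables).
#' @examples
#' pv <- make_pv_waveforms(pv_sim_config(duration = 0.25, sampling_rate = 500))
#' range(pv$pressure$samples)
#' @export
make_pv_waveforms <- function(config) {
  stopifnot(inherits(config, "pv_sim_config"))
  f0 <- config$heart_rate_bpm / 60
  sr <- config$sampling_rate
  t <- seq(0, config$duration - 1 / sr, by = 1 / sr)
  H <- config$n_harmonics
  ph_pressure <- -(seq_len(H)) * pi / 3
  ph_volume <- ph_pressure + seq_len(H) * pi    # counter-phase ejection/filling
  p <- .harmonic_pulse(t, f0, H, ph_pressure,
                       config$diastolic_pressure, config$systolic_pressure)
  v <- .harmonic_pulse(t, f0, H, ph_volume,
                       config$end_systolic_volume,
                       config$end_diastolic_volume)
  yp <- p$samples; yv <- v$samples
  if (config$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(config$seed)
    yp <- yp + stats::rnorm(length(t), 0, config$noise_sd)
    yv <- yv + stats::rnorm(length(t), 0, config$noise_sd)
  }
  list(pressure = prony_signal(yp, sr, label = "pressure"),
       volume = prony_signal(yv, sr, label = "volume"),
       ground_truth = list(pressure = p$components, volume = v$components))
}

#' Derive a perturbed hemodynamic-state configuration
#'
#' Returns a copy of `config` with the pulse pressure scaled by
#' `contractility_scale` (systolic pressure moved toward the diastolic
#' floor) and the stroke volume `EDV - ESV` scaled by `volume_scale` (EDV
#' moved toward ESV), so the pole-metric pipeline can be exercised on
#' distinguishable groups resembling baseline, shock and resuscitation
#' states.
#'
#' @param config A [pv_sim_config()].
#' @param contractility_scale,volume_scale Positive scale factors; `(1, 1)`
#'   leaves the configuration unchanged.
#' @return A [pv_sim_config()].
#' @export
perturb_to_shock <- function(config, contractility_scale = 1,
                             volume_scale = 1) {
  stopifnot(inherits(config, "pv_sim_config"))
  if (contractility_scale <= 0 || volume_scale <= 0)
    stop("scale factors must be positive")
  config$systolic_pressure <- config$diastolic_pressure +
    (config$systolic_pressure - config$diastolic_pressure) *
    contractility_scale
  config$end_diastolic_volume <- config$end_systolic_volume +
    (config$end_diastolic_volume - config$end_systolic_volume) * volume_scale
  config
}

#' Preset hemodynamic-state configurations
#'
#' Convenience presets for the three experimental states the pole-metric
#' pipeline is meant to distinguish: `"baseline"` (the defaults), `"shock"`
#' (halved stroke volume, reduced pulse pressure, faster heart rate) and
#' `"resuscitation"` (partial recovery of both).
#'
#' @param state One of `"baseline"`, `"shock"`, `"resuscitation"`.
#' @param seed Seed for the derived configuration.
#' @param ... Further arguments passed to [pv_sim_config()].
#' @return A [pv_sim_config()].
#' @export
pv_preset <- function(state = c("baseline", "shock", "resuscitation"),
                      seed = 1L, ...) {
  state <- match.arg(state)
  base <- pv_sim_config(seed = seed, ...)
  switch(state,
         baseline = base,
         shock = {
           cfg <- perturb_to_shock(base, contractility_scale = 0.6,
                                   volume_scale = 0.5)
           cfg$heart_rate_bpm <- base$heart_rate_bpm * 1.15
           cfg
         },
         resuscitation = perturb_to_shock(base, contractility_scale = 0.9,
                                          volume_scale = 0.85))
}
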