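# Shared fixtures and independent oracles used across the suite.

# Random damped-cosine component table with well-separated frequencies so
# noiseless recovery is well conditioned. Deterministic for a given seed.
random_components <- function(K, seed, f_range = c(2, 30),
                              damp_range = c(-3, 0), min_sep = 1.5) {
  set.seed(seed)
  repeat {
    freqs <- sort(stats::runif(K, f_range[1L], f_range[2L]))
    if (K == 1L || min(diff(freqs)) >= min_sep) break
  }
  do.call(rbind, lapply(seq_len(K), function(i)
    prony_component(stats::runif(1, 0.5, 3),
                    stats::runif(1, damp_range[1L], damp_range[2L]),
                    freqs[i],
                    stats::runif(1, -2.5, 2.5))))
}

# Numerical Laplace transform of a damped-cosine component table by
# quadrature of integral(f(t) exp(-s t), 0, T), truncated at T where the
# envelope exp((sigma_max - Re s) T) has fallen below 1e-10. Independent of
# the closed form it cross-checks.
laplace_quadrature <- function(components, s) {
  f_t <- function(t) {
    y <- rep(0, length(t))
    for (i in seq_len(nrow(components)))
      y <- y + components$amplitude[i] * exp(components$damping[i] * t) *
        cos(2 * pi * components$frequency[i] * t + components$phase[i])
    y
  }
  sigma_max <- max(components$damping)
  stopifnot(Re(s) > sigma_max)
  T_max <- log(1e10) / (Re(s) - sigma_max)
  re <- stats::integrate(function(t) f_t(t) * exp(-Re(s) * t) * cos(Im(s) * t),
                         0, T_max, rel.tol = 1e-10, subdivisions = 5000L)$value
  im <- stats::integrate(function(t) -f_t(t) * exp(-Re(s) * t) * sin(Im(s) * t),
                         0, T_max, rel.tol = 1e-10, subdivisions = 5000L)$value
  complex(real = re, imaginary = im)
}

# Plain-arithmetic pole metrics, written independently of pole_metrics().
metrics_oracle <- function(mu, C, threshold = 0.2) {
  a <- Mod(C) / max(Mod(C))
  th <- Arg(mu) * 180 / pi
  d <- abs(Mod(mu) - 1)
  d_sorted <- sort(d, decreasing = TRUE)
  list(mean_angle_deg = sum(a * th) / sum(a),
       dispersion = 1 / stats::sd(Mod(C)),
       top5_mean_distance = mean(d_sorted[seq_len(min(5L, length(d)))]),
       n_off_unit_circle = sum(d >= threshold))
}

# Align the rows of a folded fitted-component table with a ground-truth
# table by nearest frequency.
match_components <- function(fitted, truth) {
  idx <- vapply(truth$frequency,
                function(f) which.min(abs(fitted$frequency_hz - f)),
                integer(1))
  fitted[idx, , drop = FALSE]
}

# Conjugate-symmetric random pole/coefficient sets (optionally with a real
# pole) for model-construction tests.
random_pole_set <- function(n_pairs, seed, radius = c(0.7, 1.1),
                            real_pole = FALSE) {
  set.seed(seed)
  r <- stats::runif(n_pairs, radius[1L], radius[2L])
  ang <- sort(stats::runif(n_pairs, 0.15, pi - 0.15))
  mu <- complex(modulus = r, argument = ang)
  C <- complex(modulus = stats::runif(n_pairs, 0.2, 2),
               argument = stats::runif(n_pairs, -2.5, 2.5))
  mu <- c(mu, Conj(mu)); C <- c(C, Conj(C))
  if (real_pole) {
    mu <- c(mu, complex(real = stats::runif(1, 0.5, 0.95)))
    C <- c(C, complex(real = stats::runif(1, 0.2, 2)))
  }
  list(poles = mu, coefficients = C)
}
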