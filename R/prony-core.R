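## ---- internal numerical helpers ----------------------------------------

## Powers mu_i^tau_k as an M x N complex matrix. Zero poles get the
## convention 0^0 = 1, 0^tau = 0 (tau > 0). May contain Inf on overflow;
## callers decide whether that is an error.
.pole_powers <- function(poles, tau) {
  poles <- as.complex(poles)
  V <- matrix(0 + 0i, nrow = length(tau), ncol = length(poles))
  nz <- Mod(poles) > 0
  if (any(nz))
    V[, nz] <- exp(outer(as.numeric(tau), log(poles[nz])))
  if (any(!nz))
    V[tau == 0, !nz] <- 1 + 0i
  V
}

## Least-squares solve via SVD pseudoinverse with a relative singular-value
## cutoff (Moore-Penrose with truncation).
.pinv_solve <- function(A, b, sv_cutoff = 1e-13) {
  s <- svd(A)
  keep <- s$d > sv_cutoff * s$d[1L]
  if (!any(keep)) return(rep(0 + 0i, ncol(A)))
  ut_b <- Conj(t(s$u[, keep, drop = FALSE])) %*% b
  drop(s$v[, keep, drop = FALSE] %*% (ut_b / s$d[keep]))
}

## R^2 of the truncated-pseudoinverse fit of basis mu^(k/d) to y; -Inf when
## the basis overflows or the fit is non-finite. Uses the same solver as
## fit_coefficients so the scale search scores exactly the model it returns.
.fit_r2 <- function(y, poles, scale_d, sv_cutoff = 1e-13) {
  V <- .pole_powers(poles, (seq_along(y) - 1) / scale_d)
  if (any(!is.finite(Re(V))) || any(!is.finite(Im(V)))) return(-Inf)
  co <- .pinv_solve(V, y, sv_cutoff)
  fitted <- Re(V %*% co)
  if (any(!is.finite(fitted))) return(-Inf)
  r2 <- r_squared(y, fitted)
  if (!is.finite(r2)) -Inf else r2
}

## ---- linear prediction --------------------------------------------------

#' Solve the linear-prediction (Hankel) system of a signal
#'
#' Expresses each sample as a linear combination of the `n_poles` samples
#' preceding it and solves the resulting Hankel system for the prediction
#' coefficients `a` in the least-squares sense. All available prediction rows
#' (`l = N, ..., M-1`) are used, so the system is square when `M = 2N` and
#' overdetermined otherwise. The coefficients are those of the characteristic
#' polynomial whose roots are the Prony poles.
#'
#' @param signal A [prony_signal] (or numeric vector, taken at 1 Hz).
#' @param n_poles Number of prediction coefficients `N`; must satisfy
#'   `1 <= N <= floor(M/2)` where `M` is the signal length.
#'
#' @return An object of class `linear_prediction`: list with `coefficients`
#'   (numeric, length `N`), `n_poles`, and `residual_norm` (Euclidean norm of
#'   the least-squares residual).
#' @examples
#' lp <- solve_linear_prediction(0.5^(0:7), 1)
#' lp$coefficients  # 0.5: each sample is half the previous one
#' @export
solve_linear_prediction <- function(signal, n_poles) {
  signal <- as_prony_signal(signal)
  y <- signal$samples
  M <- length(y)
  n_poles <- as.integer(n_poles)
  if (length(n_poles) != 1L || is.na(n_poles) ||
      n_poles < 1L || n_poles > floor(M / 2))
    stop("'n_poles' must be an integer in [1, floor(M/2)] = [1, ",
         floor(M / 2), "], got ", n_poles)
  N <- n_poles
  rows <- (N + 1L):M                      # 1-based index of predicted samples
  D <- outer(rows, seq_len(N), function(l, m) y[l - m])
  d <- y[rows]
  # rank detection at a strict tolerance: Prony Hankel systems are routinely
  # ill-conditioned without being singular, and the scale search downstream
  # is the intended remedy
  qrD <- qr(D, tol = 1e-12)
  if (qrD$rank < N) {
    warning("Hankel system is numerically singular (rank ", qrD$rank,
            " < ", N, "); using the minimum-norm least-squares solution")
    a <- Re(.pinv_solve(D, d))
  } else {
    a <- qr.coef(qrD, d)
  }
  resid <- sqrt(sum((d - D %*% a)^2))
  structure(list(coefficients = as.numeric(a), n_poles = N,
                 residual_norm = resid),
            class = "linear_prediction")
}

#' Poles from linear-prediction coefficients
#'
#' Roots of the monic characteristic polynomial
#' `x^N - a_0 x^(N-1) - ... - a_(N-1)`, computed as the eigenvalues of its
#' companion matrix. The roots are the complex poles of the Prony model.
#'
#' @param lp A `linear_prediction` object (or bare numeric coefficient
#'   vector).
#' @return Complex vector of `N` poles, sorted by descending magnitude with
#'   ties broken by ascending phase.
#' @examples
#' poles_from_lp(c(sqrt(2), -1))  # conjugate pair exp(+-i*pi/4)
#' @export
poles_from_lp <- function(lp) {
  a <- if (inherits(lp, "linear_prediction")) lp$coefficients else as.numeric(lp)
  if (length(a) < 1L) stop("need at least one prediction coefficient")
  if (any(!is.finite(a))) stop("non-finite linear-prediction coefficients")
  N <- length(a)
  if (N == 1L) {
    roots <- as.complex(a)
  } else {
    comp <- rbind(a, cbind(diag(1, N - 1L, N - 1L), 0))
    dimnames(comp) <- NULL
    roots <- eigen(comp, only.values = TRUE)$values
  }
  roots <- as.complex(roots)
  # near-equal magnitudes count as ties so the phase tie-break is stable
  roots[order(-signif(Mod(roots), 10), Arg(roots))]
}

## ---- coefficient fit ----------------------------------------------------

#' Fit complex component coefficients against a signal
#'
#' Solves `Y = V^T C` in the least-squares sense, where `V^T` is the
#' Vandermonde-type matrix with entries `mu_i^(k/d)` at the scaled sample
#' times. The solve uses the Moore-Penrose pseudoinverse with relative
#' singular values below `sv_cutoff` truncated, so rank-deficient pole bases
#' (typical at high sampling rates) are handled without error.
#'
#' @inheritParams solve_linear_prediction
#' @param poles Nonempty complex vector of Prony poles.
#' @param scale_d Positive time-scaling factor `d`; sample `k` is raised to
#'   the power `k/d`.
#' @param sv_cutoff Relative singular-value truncation threshold.
#' @return Complex vector of coefficients `C`, one per pole.
#' @examples
#' fit_coefficients(0.5^(0:7), poles = 0.5 + 0i)  # C = 1
#' @export
fit_coefficients <- function(signal, poles, scale_d = 1, sv_cutoff = 1e-13) {
  signal <- as_prony_signal(signal)
  if (length(poles) < 1L) stop("'poles' must be a nonempty complex vector")
  if (!is.numeric(scale_d) || length(scale_d) != 1L || !is.finite(scale_d) ||
      scale_d <= 0)
    stop("'scale_d' must be a single positive number")
  y <- signal$samples
  V <- .pole_powers(poles, (seq_along(y) - 1) / scale_d)
  if (any(!is.finite(Re(V))) || any(!is.finite(Im(V))))
    stop("pole powers overflow at scale_d = ", scale_d,
         "; the largest pole magnitude is ", max(Mod(poles)))
  .pinv_solve(V, y, sv_cutoff)
}

#' Per-component parameters from poles and coefficients
#'
#' Converts pole/coefficient pairs to damped-cosine parameters: damping
#' `sigma = ln|mu|` and frequency `f = Arg(mu)/(2*pi)` per scaled time unit,
#' amplitude `A = |C|` and phase `phi = Arg(C)` (principal value in
#' `(-pi, pi]`). When `sampling_rate` and `scale_d` are supplied the physical
#' conversions `damping_per_s = sigma * SR/d` and `frequency_hz = f * SR/d`
#' are added.
#'
#' @param poles Complex vector of poles.
#' @param coefficients Complex vector of coefficients, same length.
#' @param sampling_rate Optional sampling rate in Hz for physical units.
#' @param scale_d Optional scale factor `d` for physical units.
#' @return A data frame with one row per component: `amplitude`, `damping`,
#'   `frequency`, `phase`, `zero_pole` (flags `|mu| = 0`, whose damping is
#'   `-Inf`), and physical-unit columns when requested.
#' @export
components_from_poles <- function(poles, coefficients,
                                  sampling_rate = NULL, scale_d = NULL) {
  poles <- as.complex(poles); coefficients <- as.complex(coefficients)
  if (length(poles) != length(coefficients))
    stop("'poles' and 'coefficients' must have equal length")
  zero <- Mod(poles) == 0
  out <- data.frame(
    amplitude = Mod(coefficients),
    damping   = log(Mod(poles)),        # -Inf for zero poles, kept and flagged
    frequency = Arg(poles) / (2 * pi),
    phase     = Arg(coefficients),
    zero_pole = zero
  )
  if (!is.null(sampling_rate) && !is.null(scale_d)) {
    out$damping_per_s <- out$damping * sampling_rate / scale_d
    out$frequency_hz  <- out$frequency * sampling_rate / scale_d
  }
  out
}

## ---- model object -------------------------------------------------------

#' Construct a Prony model
#'
#' A Prony model is the pole/coefficient representation
#' `y_k = Re( sum_i C_i mu_i^(k/d) )` of a signal of length `M` sampled at
#' `sampling_rate` Hz. Usually produced by [prony_fit()]; this constructor is
#' for building models directly (e.g. from known ground truth).
#'
#' @param poles Complex vector of poles `mu_i` (may be empty).
#' @param coefficients Complex vector of coefficients `C_i`, same length.
#' @param scale_d Time-scaling factor `d > 0`.
#' @param sampling_rate Sampling rate of the source signal, Hz.
#' @param source_length Length `M` of the source signal; the number of
#'   components must not exceed `floor(M/2)`.
#' @param label Signal label carried through from the source.
#' @param r_squared Optional goodness of fit against the source signal.
#' @return An object of class `prony_model`.
#' @export
prony_model <- function(poles, coefficients, scale_d = 1, sampling_rate = 1,
                        source_length, label = "signal", r_squared = NA_real_) {
  poles <- as.complex(poles); coefficients <- as.complex(coefficients)
  if (length(poles) != length(coefficients))
    stop("'poles' and 'coefficients' must have equal length")
  if (!is.finite(scale_d) || scale_d <= 0) stop("'scale_d' must be positive")
  source_length <- as.integer(source_length)
  if (length(poles) > floor(source_length / 2))
    stop("a model for a length-", source_length, " signal admits at most ",
         floor(source_length / 2), " components (floor(M/2))")
  structure(
    list(poles = poles, coefficients = coefficients,
         n_components = length(poles), scale_d = as.numeric(scale_d),
         sampling_rate = as.numeric(sampling_rate),
         source_length = source_length, label = as.character(label)[1L],
         r_squared = r_squared),
    class = "prony_model"
  )
}

#' @export
print.prony_model <- function(x, ...) {
  cat(sprintf(
    "<prony_model '%s': N = %d, d = %.6g, SR = %g Hz, M = %d%s>\n",
    x$label, x$n_components, x$scale_d, x$sampling_rate, x$source_length,
    if (is.finite(x$r_squared)) sprintf(", R^2 = %.6f", x$r_squared) else ""))
  invisible(x)
}

#' Evaluate a Prony model at sample indices
#'
#' Reconstructs `Re( sum_i C_i mu_i^(k/d) )` at the requested sample indices.
#' The magnitude of the largest discarded imaginary part is recorded in the
#' `"max_imag"` attribute; for models fitted to real signals it is at
#' numerical-noise level because poles occur in conjugate pairs.
#'
#' @param model A `prony_model`.
#' @param sample_indices Integer vector of 0-based sample indices `k`;
#'   defaults to the full source window `0:(M-1)`.
#' @return Numeric vector of reconstructed values with attribute `max_imag`.
#' @export
evaluate_model <- function(model, sample_indices = NULL) {
  stopifnot(inherits(model, "prony_model"))
  if (is.null(sample_indices))
    sample_indices <- seq_len(model$source_length) - 1L
  if (model$n_components == 0L)
    return(structure(rep(0, length(sample_indices)), max_imag = 0))
  V <- .pole_powers(model$poles, sample_indices / model$scale_d)
  z <- drop(V %*% model$coefficients)
  structure(Re(z), max_imag = max(abs(Im(z))))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` between an observed and a fitted series. Can
#' be negative when the fit is worse than the observed mean.
#'
#' @param observed Numeric vector (not constant, length >= 2).
#' @param fitted Numeric vector of the same length.
#' @return A single number.
#' @export
r_squared <- function(observed, fitted) {
  observed <- as.numeric(observed); fitted <- as.numeric(fitted)
  if (length(observed) != length(fitted))
    stop("'observed' and 'fitted' must have equal length")
  if (length(observed) < 2L) stop("need at least 2 points")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("R^2 is undefined for a constant observed signal")
  1 - sum((observed - fitted)^2) / ss_tot
}

## ---- scale optimization -------------------------------------------------

## Maximize R^2(d) over a logarithmic grid followed by golden-section
## refinement in log(d). Deterministic and derivative-free.
.optimize_d <- function(y, poles, d_max, n_grid = 25L, rel_tol = 1e-3,
                        sv_cutoff = 1e-13) {
  d_max <- max(1, d_max)
  grid <- if (d_max == 1) 1 else exp(seq(0, log(d_max), length.out = n_grid))
  r2s <- vapply(grid, function(d) .fit_r2(y, poles, d, sv_cutoff), numeric(1))
  if (all(!is.finite(r2s)))
    stop("scale optimization failed: R^2 non-finite for every candidate d ",
         "(best attempt d = ", grid[1L], ")")
  i <- which.max(r2s)
  lo <- log(grid[max(1L, i - 1L)]); hi <- log(grid[min(length(grid), i + 1L)])
  if (hi - lo > rel_tol) {
    gr <- (sqrt(5) - 1) / 2
    x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
    f1 <- .fit_r2(y, poles, exp(x1), sv_cutoff)
    f2 <- .fit_r2(y, poles, exp(x2), sv_cutoff)
    while (hi - lo > rel_tol) {
      if (f1 >= f2) {
        hi <- x2; x2 <- x1; f2 <- f1
        x1 <- hi - gr * (hi - lo); f1 <- .fit_r2(y, poles, exp(x1), sv_cutoff)
      } else {
        lo <- x1; x1 <- x2; f1 <- f2
        x2 <- lo + gr * (hi - lo); f2 <- .fit_r2(y, poles, exp(x2), sv_cutoff)
      }
    }
  }
  cand_d <- c(grid[i], exp((lo + hi) / 2))
  cand_r2 <- c(r2s[i], .fit_r2(y, poles, cand_d[2L], sv_cutoff))
  best <- which.max(cand_r2)
  structure(cand_d[best], r_squared = cand_r2[best],
            grid = data.frame(d = grid, r_squared = r2s))
}

#' Optimize the time-scaling factor d
#'
#' Finds the scaling factor `d` that maximizes the coefficient of
#' determination of the full Prony fit (linear prediction, pole extraction,
#' coefficient fit, reconstruction) for a given number of poles. The search
#' is a 25-point logarithmic grid over `[1, SR]` followed by golden-section
#' refinement around the grid maximum; it is deterministic for fixed inputs.
#'
#' @inheritParams solve_linear_prediction
#' @param n_grid Number of logarithmic grid points.
#' @param d_max Upper end of the search interval; defaults to the sampling
#'   rate.
#' @param sv_cutoff Relative singular-value cutoff for the coefficient solve.
#' @return The optimal `d` (numeric scalar) with attributes `r_squared` (the
#'   attained fit quality) and `grid` (the coarse-grid trace).
#' @export
optimize_scale <- function(signal, n_poles, n_grid = 25L, d_max = NULL,
                           sv_cutoff = 1e-13) {
  signal <- as_prony_signal(signal)
  poles <- poles_from_lp(solve_linear_prediction(signal, n_poles))
  if (is.null(d_max)) d_max <- signal$sampling_rate
  .optimize_d(signal$samples, poles, d_max, n_grid = n_grid,
              sv_cutoff = sv_cutoff)
}

## ---- end-to-end fit -----------------------------------------------------

#' Fit a Prony model to a signal
#'
#' Chains the linear-prediction solve, companion-matrix pole extraction and
#' pseudoinverse coefficient fit into a full Prony decomposition
#' `y_k ~ Re( sum_i C_i mu_i^(k/d) )`.
#'
#' With `n_poles = "auto"` the number of terms is treated as a hyperparameter
#' and chosen by maximizing R^2 over a candidate grid (by default the
#' multiples of `floor(M/20)` up to the Nyquist-style cap `floor(M/2)`).
#' With `scale_d = "auto"` the time-scaling factor is optimized per candidate
#' as in [optimize_scale()].
#'
#' @inheritParams solve_linear_prediction
#' @param n_poles Number of components, or `"auto"`.
#' @param scale_d Scaling factor `d`, or `"auto"`.
#' @param candidates Optional integer vector of candidate `N` values for the
#'   auto search (values above `floor(M/2)` are dropped).
#' @param n_grid Grid size for the scale search.
#' @param sv_cutoff Relative singular-value cutoff for the coefficient solve.
#' @return A [prony_model] with components ordered by descending importance
#'   `|C|` (ties by ascending phase), carrying `r_squared` and the attribute
#'   `max_imag` on its stored `fitted` values.
#' @examples
#' t <- seq(0, 1 - 1/200, by = 1/200)
#' s <- prony_signal(exp(-2 * t) * cos(2 * pi * 5 * t), 200)
#' m <- prony_fit(s, n_poles = 2)
#' m$r_squared
#' @export
prony_fit <- function(signal, n_poles = "auto", scale_d = "auto",
                      candidates = NULL, n_grid = 25L, sv_cutoff = 1e-13) {
  signal <- as_prony_signal(signal)
  y <- signal$samples
  M <- length(y)
  n_max <- floor(M / 2)

  if (identical(n_poles, "auto")) {
    if (is.null(candidates)) {
      base <- max(1L, floor(M / 20))
      candidates <- seq.int(base, n_max, by = base)
    }
    candidates <- sort(unique(as.integer(candidates)))
    candidates <- candidates[candidates >= 1L & candidates <= n_max]
    if (length(candidates) == 0L) stop("no admissible 'candidates'")
  } else {
    candidates <- as.integer(n_poles)
    if (length(candidates) != 1L || is.na(candidates) || candidates < 1L ||
        candidates > n_max)
      stop("'n_poles' must be \"auto\" or an integer in [1, floor(M/2)] = [1, ",
           n_max, "]")
  }
  auto_d <- identical(scale_d, "auto")
  if (!auto_d && (!is.numeric(scale_d) || scale_d <= 0))
    stop("'scale_d' must be \"auto\" or a positive number")

  best <- NULL
  for (N in candidates) {
    poles <- poles_from_lp(solve_linear_prediction(signal, N))
    if (auto_d) {
      d <- tryCatch(.optimize_d(y, poles, signal$sampling_rate,
                                n_grid = n_grid, sv_cutoff = sv_cutoff),
                    error = function(e) NULL)
      if (is.null(d)) next
      r2 <- attr(d, "r_squared")
      d <- as.numeric(d)
    } else {
      d <- as.numeric(scale_d)
      r2 <- .fit_r2(y, poles, d, sv_cutoff)
    }
    if (is.finite(r2) && (is.null(best) || r2 > best$r2))
      best <- list(N = N, poles = poles, d = d, r2 = r2)
  }
  if (is.null(best))
    stop("Prony fit failed: no candidate model achieved a finite R^2")

  co <- fit_coefficients(signal, best$poles, best$d, sv_cutoff)
  ord <- order(-Mod(co), Arg(co))
  model <- prony_model(best$poles[ord], co[ord], scale_d = best$d,
                       sampling_rate = signal$sampling_rate,
                       source_length = M, label = signal$label)
  fitted <- evaluate_model(model)
  model$r_squared <- r_squared(y, fitted)
  model$fitted <- fitted
  model
}
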