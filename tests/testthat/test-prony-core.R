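test_that("linear prediction recovers known recurrences", {
  # geometric sequence with ratio 0.5: y_l = 0.5 y_{l-1}
  lp <- solve_linear_prediction(c(1, 0.5, 0.25, 0.125), 1)
  expect_equal(lp$coefficients, 0.5, tolerance = 1e-12)
  expect_lt(lp$residual_norm, 1e-12)

  # sampled cosine cos(2 pi k / 8): a = (2 cos(pi/4), -1) = (sqrt(2), -1),
  # verified by solving the 2x2 system by hand
  lp2 <- solve_linear_prediction(cos(2 * pi * (0:7) / 8), 2)
  expect_equal(lp2$coefficients, c(sqrt(2), -1), tolerance = 1e-12)

  # constant signal: y_l = y_{l-1}
  lp3 <- solve_linear_prediction(rep(3.2, 4), 1)
  expect_equal(lp3$coefficients, 1, tolerance = 1e-12)
})

test_that("linear prediction validates its arguments", {
  expect_error(solve_linear_prediction(1:8, 0), "n_poles")
  expect_error(solve_linear_prediction(1:8, 5), "n_poles")   # > floor(M/2)
  expect_error(solve_linear_prediction(c(1, NA, 3, 4), 1), "finite")
  expect_warning(solve_linear_prediction(rep(0, 8), 2), "singular")
})

test_that("characteristic polynomial roots match known poles", {
  expect_equal(poles_from_lp(0.5), 0.5 + 0i)
  expect_equal(poles_from_lp(1), 1 + 0i)
  # x^2 - sqrt(2) x + 1 has roots exp(+-i pi/4) (quadratic formula)
  r <- poles_from_lp(c(sqrt(2), -1))
  expect_equal(sort(Arg(r)), c(-pi / 4, pi / 4), tolerance = 1e-12)
  expect_equal(Mod(r), c(1, 1), tolerance = 1e-12)
})

test_that("companion-matrix roots agree with an independent root finder", {
  for (seed in 1:10) {
    set.seed(seed)
    N <- sample(1:4, 1)
    a <- stats::runif(N, -1, 1)
    got <- poles_from_lp(a)
    # polyroot() (Jenkins-Traub) on x^N - a0 x^(N-1) - ... - a_(N-1)
    want <- polyroot(c(-rev(a), 1))
    expect_equal(sort(Re(got)) + 1i * sort(Im(got)),
                 sort(Re(want)) + 1i * sort(Im(want)),
                 tolerance = 1e-9)
  }
})

test_that("pole ordering is deterministic: descending magnitude, ties by phase", {
  r <- poles_from_lp(c(0, 0, 0.064))   # cube roots of 0.064: |mu| = 0.4
  expect_equal(Mod(r), rep(0.4, 3), tolerance = 1e-9)
  expect_true(all(diff(Arg(r)) > 0))
})

test_that("coefficient fit solves the Vandermonde system", {
  expect_equal(fit_coefficients(0.5^(0:7), 0.5 + 0i), 1 + 0i,
               tolerance = 1e-10)
  # cos(2 pi k/8) = 0.5 e^{i pi k/4} + 0.5 e^{-i pi k/4} (Euler)
  co <- fit_coefficients(cos(2 * pi * (0:7) / 8), exp(c(1i, -1i) * pi / 4))
  expect_equal(co, c(0.5 + 0i, 0.5 + 0i), tolerance = 1e-10)
  # cross-check Euler expansion against a brute-force normal-equations solve
  V <- outer(0:7, c(1i, -1i) * pi / 4, function(k, l) exp(k * l))
  brute <- solve(Conj(t(V)) %*% V, Conj(t(V)) %*% cos(2 * pi * (0:7) / 8))
  expect_equal(co, drop(brute), tolerance = 1e-10)

  expect_equal(fit_coefficients(rep(0, 6), c(0.5 + 0.1i, 0.5 - 0.1i)),
               c(0 + 0i, 0 + 0i), tolerance = 1e-12)
  expect_error(fit_coefficients(1:8, complex(0)), "nonempty")
  expect_error(fit_coefficients(1:8, 0.5 + 0i, scale_d = -1), "scale_d")
})

test_that("component parameters follow from pole and coefficient geometry", {
  c1 <- components_from_poles(exp(1i * pi / 2), 0.5 + 0i)
  expect_equal(c1$damping, 0)
  expect_equal(c1$frequency, 0.25)
  expect_equal(c1$amplitude, 0.5)
  expect_equal(c1$phase, 0)

  c2 <- components_from_poles(0.5 + 0i, 1 + 0i)
  expect_equal(c2$damping, log(0.5))
  expect_equal(c2$frequency, 0)

  c3 <- components_from_poles(1 + 0i, 1 + 1i)
  expect_equal(c3$amplitude, sqrt(2))
  expect_equal(c3$phase, pi / 4)

  # zero pole: damping -Inf, flagged but retained
  c4 <- components_from_poles(c(0 + 0i, 0.5 + 0i), c(1 + 0i, 1 + 0i))
  expect_equal(c4$damping[1], -Inf)
  expect_true(c4$zero_pole[1])
  expect_equal(nrow(c4), 2L)

  # physical units: damping and frequency scale by SR/d
  c5 <- components_from_poles(exp(1i * pi / 2), 1 + 0i,
                              sampling_rate = 1000, scale_d = 2)
  expect_equal(c5$frequency_hz, 0.25 * 500)
})

test_that("model evaluation reconstructs the defining sum", {
  m <- prony_model(exp(c(1i, -1i) * pi / 4), c(0.5 + 0i, 0.5 + 0i),
                   source_length = 8)
  y <- evaluate_model(m, 0:7)
  expect_equal(as.numeric(y), cos(2 * pi * (0:7) / 8), tolerance = 1e-12)
  expect_lt(attr(y, "max_imag"), 1e-12)

  m0 <- prony_model(complex(0), complex(0), source_length = 8)
  expect_equal(as.numeric(evaluate_model(m0, 0:7)), rep(0, 8))

  mc <- prony_model(1 + 0i, 2.5 + 0i, source_length = 8)
  expect_equal(as.numeric(evaluate_model(mc, 0:7)), rep(2.5, 8))
})

test_that("coefficient of determination matches its definition", {
  y <- c(0.3, 1.7, -0.2, 0.8)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  # SS_res = 2, SS_tot = 0.5 -> R^2 = -3
  expect_equal(r_squared(c(0, 1), c(1, 0)), -3)
  expect_error(r_squared(rep(1, 4), c(1, 2, 3, 4)), "constant")
  expect_error(r_squared(1:4, 1:5), "equal length")
})

test_that("scale optimization honors its maximization contract", {
  comp <- rbind(prony_component(2, -1.5, 5, 0.4),
                prony_component(1, -0.5, 11, -1.0))
  s <- make_damped_sinusoids(comp, 100, 1.5)
  d <- optimize_scale(s, 4)
  # the signal is exactly representable on index time (d = 1)
  poles <- poles_from_lp(solve_linear_prediction(s, 4))
  r2_at_1 <- pronypv:::.fit_r2(s$samples, poles, 1)
  expect_gte(attr(d, "r_squared") + 1e-12, r2_at_1)

  # R^2 is invariant under linear scaling of the samples, so is the search
  s2 <- prony_signal(2 * s$samples, s$sampling_rate)
  d2 <- optimize_scale(s2, 4)
  expect_equal(as.numeric(d), as.numeric(d2), tolerance = 1e-12)
})

test_that("scale optimization of a rich synthetic signal fits near-perfectly", {
  comp <- random_components(5, seed = 42, f_range = c(3, 45),
                            damp_range = c(-2, 0))
  s <- make_damped_sinusoids(comp, 1000, 1)
  d <- optimize_scale(s, 10)
  expect_gt(attr(d, "r_squared"), 0.99)
})

test_that("full fit recovers exact damped-sinusoid parameters", {
  comp <- rbind(prony_component(2.0, -1.5, 5, 0.4),
                prony_component(1.0, -0.5, 11, -1.0),
                prony_component(0.5, -2.5, 17, 2.0))
  s <- make_damped_sinusoids(comp, 100, 2)
  m <- prony_fit(s, n_poles = 6, scale_d = 1)
  expect_gte(m$r_squared, 1 - 1e-10)
  got <- match_components(pronypv:::.fold_model(m), comp)
  expect_equal(got$amplitude, comp$amplitude, tolerance = 1e-6)
  expect_equal(got$damping_per_s, comp$damping, tolerance = 1e-6)
  expect_equal(got$frequency_hz, comp$frequency, tolerance = 1e-6)
  expect_equal(got$phase, comp$phase, tolerance = 1e-6)
})

test_that("undamped cosines yield poles on the unit circle", {
  s <- prony_signal(cos(2 * pi * 6 * seq(0, 0.99, by = 0.01)), 100)
  m <- prony_fit(s, n_poles = 2, scale_d = 1)
  expect_lt(max(abs(Mod(m$poles) - 1)), 1e-8)
})

test_that("the component cap floor(M/2) is enforced", {
  s <- prony_signal(stats::rnorm(10), 10)
  expect_error(prony_fit(s, n_poles = 6, scale_d = 1), "floor")
  expect_error(prony_signal(1:3, 1), "at least 4")
  expect_error(prony_model(rep(0.5 + 0i, 6), rep(1 + 0i, 6),
                           source_length = 10), "floor")
})

test_that("round trip: model -> signal -> fit recovers the pole set", {
  for (seed in 1:5) {
    ps <- random_pole_set(2, seed, radius = c(0.85, 1.0), real_pole = TRUE)
    m <- prony_model(ps$poles, ps$coefficients, sampling_rate = 50,
                     source_length = 60)
    y <- evaluate_model(m, 0:59)
    refit <- prony_fit(prony_signal(y, 50), n_poles = 5, scale_d = 1)
    expect_equal(sort(Re(refit$poles)) + 1i * sort(Im(refit$poles)),
                 sort(Re(ps$poles)) + 1i * sort(Im(ps$poles)),
                 tolerance = 1e-6)
  }
})

test_that("real signals give conjugate-symmetric poles and real output", {
  for (seed in 1:5) {
    comp <- random_components(3, seed)
    s <- make_damped_sinusoids(comp, 100, 1.5)
    m <- prony_fit(s, n_poles = 6, scale_d = 1)
    # pole multiset closed under conjugation
    mu <- m$poles
    for (p in mu) expect_lt(min(Mod(Conj(p) - mu)), 1e-8)
    # discarded imaginary part at numerical-noise level
    y <- evaluate_model(m)
    expect_lt(attr(y, "max_imag"), 1e-8 * max(abs(s$samples)))
  }
})

test_that("auto pole-count search picks the R^2-maximizing candidate", {
  comp <- random_components(3, seed = 7)
  s <- make_damped_sinusoids(comp, 100, 1)
  m <- suppressWarnings(prony_fit(s, n_poles = "auto", scale_d = 1,
                                  candidates = c(2, 6, 10)))
  m_exact <- prony_fit(s, n_poles = 6, scale_d = 1)
  expect_gte(m$r_squared + 1e-12, m_exact$r_squared)
})
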