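test_that("stability splits on the unit circle, boundary counted stable", {
  mu <- c(0.9 * exp(1i * pi / 3), 1.1 + 0i, exp(1i * pi / 7))
  m <- prony_model(mu, rep(1 + 0i, 3), source_length = 10)
  expect_equal(classify_poles(m), c(TRUE, FALSE, TRUE))
  expect_error(classify_poles(m, tol = -1), "tol")
})

test_that("stable refit keeps all poles of an all-stable model", {
  comp <- rbind(prony_component(2, -1, 5, 0.2),
                prony_component(1, -2, 12, -0.5))
  s <- make_damped_sinusoids(comp, 100, 1.5)
  m <- prony_fit(s, n_poles = 4, scale_d = 1)
  refit <- stable_refit(s, m)
  expect_equal(sort(Mod(refit$poles)), sort(Mod(m$poles)), tolerance = 1e-12)
  expect_equal(refit$r_squared, m$r_squared, tolerance = 1e-8)
  expect_equal(attr(refit, "n_removed"), 0L)
})

test_that("stable refit drops a low-variance unstable component", {
  comp <- rbind(prony_component(5, -1, 4, 0.3),
                prony_component(0.05, 0.4, 13, -1.2))  # growing, < 1% variance
  s <- make_damped_sinusoids(comp, 100, 2)
  m <- prony_fit(s, n_poles = 4, scale_d = 1)
  expect_equal(sum(!classify_poles(m)), 2L)   # the growing conjugate pair
  refit <- stable_refit(s, m)
  expect_equal(refit$n_components, 2L)
  expect_gt(refit$r_squared, 0.99)
})

test_that("stable refit bookkeeping and degenerate cases", {
  set.seed(21)
  radii <- c(stats::runif(3, 0.7, 0.95), stats::runif(2, 1.05, 1.2))
  ang <- stats::runif(5, 0.2, 2.8)
  mu <- complex(modulus = rep(radii, 2), argument = c(ang, -ang))
  C <- complex(modulus = rep(stats::runif(5, 0.3, 1), 2),
               argument = c(ang / 2, -ang / 2))
  m <- prony_model(mu, C, sampling_rate = 50, source_length = 80)
  s <- prony_signal(evaluate_model(m, 0:79), 50)
  refit <- stable_refit(s, m)
  expect_equal(refit$n_components, 6L)                 # 10 poles, 4 unstable
  expect_equal(attr(refit, "n_removed"), 4L)
  # idempotent on the pole set, never increases N
  refit2 <- stable_refit(s, refit)
  expect_equal(sort(Mod(refit2$poles)), sort(Mod(refit$poles)),
               tolerance = 1e-12)

  all_unstable <- prony_model(1.2 + 0i, 1 + 0i, source_length = 10)
  expect_error(stable_refit(s, all_unstable), "no stable poles")
})

test_that("mean angle is the importance-weighted pole angle", {
  # single pole at 26 degrees: the weighted mean must be 26, not alpha
  m1 <- prony_model(complex(modulus = 0.9, argument = 26 * pi / 180),
                    0.37 + 0.2i, source_length = 10)
  mets <- pole_metrics(m1, subset = "all")
  expect_equal(mets$mean_angle_deg, 26, tolerance = 1e-10)
  # the as-printed denominator sum(theta) degenerates to alpha = 1 here
  expect_equal(pole_metrics(m1, subset = "all", as_printed = TRUE)$mean_angle_deg,
               1, tolerance = 1e-10)
})

test_that("unit-circle deviation metrics follow their definitions", {
  mu <- complex(modulus = c(0.7, 0.75, 0.85, 1.0), argument = c(1, 2, -1, 0.5))
  C <- c(1 + 0i, 0.5 + 0.5i, 2 - 1i, 0.3 + 0i)
  m <- prony_model(mu, C, source_length = 10)
  mets <- pole_metrics(m, subset = "all")
  expect_equal(mets$n_off_unit_circle, 2L)   # distances 0.3, 0.25, 0.15, 0
  expect_equal(mets$top5_mean_distance, mean(c(0.3, 0.25, 0.15, 0)))
  expect_true(mets$top5_partial)
  expect_equal(mets$n_stable + mets$n_unstable, 4L)
  expect_equal(max(mets$importance), 1)

  on_circle <- prony_model(exp(1i * c(0.3, -0.3, 1.2, -1.2)),
                           c(1, 1, 2i, -2i), source_length = 10)
  mets2 <- pole_metrics(on_circle, subset = "all")
  expect_equal(mets2$top5_mean_distance, 0)
  expect_equal(mets2$n_off_unit_circle, 0L)
})

test_that("equal weights flag an infinite dispersion", {
  m <- prony_model(c(0.8 + 0i, 0.5 + 0i), c(1 + 0i, 1i), source_length = 10)
  mets <- pole_metrics(m, subset = "all")
  expect_true(mets$dispersion_infinite)
  expect_equal(mets$dispersion, Inf)
})

test_that("metrics match a brute-force arithmetic oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    N <- sample(2:20, 1)
    mu <- complex(modulus = stats::runif(N, 0.3, 1.4),
                  argument = stats::runif(N, -pi, pi))
    C <- complex(modulus = stats::runif(N, 0.1, 3),
                 argument = stats::runif(N, -pi, pi))
    m <- prony_model(mu, C, source_length = 2 * N)
    mets <- pole_metrics(m, subset = "all")
    want <- metrics_oracle(mu, C)
    expect_equal(mets$mean_angle_deg, want$mean_angle_deg, tolerance = 1e-12)
    expect_equal(mets$dispersion, want$dispersion, tolerance = 1e-12)
    expect_equal(mets$top5_mean_distance, want$top5_mean_distance,
                 tolerance = 1e-12)
    expect_equal(mets$n_off_unit_circle, want$n_off_unit_circle)
  }
})

test_that("metrics are invariant to reordering and coefficient scaling", {
  ps <- random_pole_set(4, seed = 13)
  m <- prony_model(ps$poles, ps$coefficients, source_length = 20)
  perm <- sample(8)
  m_perm <- prony_model(ps$poles[perm], ps$coefficients[perm],
                        source_length = 20)
  m_scaled <- prony_model(ps$poles, 3.5 * ps$coefficients,
                          source_length = 20)
  a <- pole_metrics(m, "all"); b <- pole_metrics(m_perm, "all")
  d <- pole_metrics(m_scaled, "all")
  expect_equal(a$mean_angle_deg, b$mean_angle_deg, tolerance = 1e-12)
  expect_equal(a$top5_mean_distance, b$top5_mean_distance, tolerance = 1e-12)
  expect_equal(a$n_off_unit_circle, b$n_off_unit_circle)
  expect_equal(a$mean_angle_deg, d$mean_angle_deg, tolerance = 1e-12)
  expect_equal(sort(a$importance), sort(d$importance), tolerance = 1e-12)
  # dispersion scales inversely with a common coefficient factor
  expect_equal(d$dispersion, a$dispersion / 3.5, tolerance = 1e-12)
})

test_that("pure multi-tone signals keep every pole on the unit circle", {
  comp <- rbind(prony_component(2, 0, 5), prony_component(1, 0, 13),
                prony_component(0.5, 0, 21))
  s <- make_damped_sinusoids(comp, 100, 1.5)
  m <- prony_fit(s, n_poles = 6, scale_d = 1)
  mets <- pole_metrics(m, subset = "all", threshold = 1e-6)
  expect_equal(mets$n_off_unit_circle, 0L)
})

test_that("pressure/volume metric ratios divide pressure by volume", {
  mk <- function(radii) {
    n <- length(radii)
    pole_metrics(prony_model(complex(modulus = radii, argument = seq_len(n)),
                             rep(1 + 2i, n), source_length = 4 * n), "all")
  }
  mp <- mk(c(0.7, 0.7, 0.7, 0.7, 0.7, 0.7))   # six poles 0.3 off circle
  mv <- mk(c(0.7, 0.7, 0.7, 1, 1, 1))          # three off
  r <- pole_ratio(mp, mv)
  expect_equal(unname(r["off_circle_ratio"]), 2)
  expect_equal(unname(pole_ratio(mp, mp)["top5_distance_ratio"]), 1)

  on_circle <- mk(rep(1, 5))
  expect_error(pole_ratio(mp, on_circle), "undefined ratio")
})
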