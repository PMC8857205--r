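test_that("dipolar coupling follows the point-dipole formula", {
  # hand calculation from CODATA constants: 1e-7 * gH * gF * hbar / (2 pi r^3)
  expect_equal(dipolar_coupling(spin_pair(3.8)), 2060.568, tolerance = 1e-4)
  # exact r^-3 scaling and long-distance limit
  expect_equal(dipolar_coupling(spin_pair(2)) / dipolar_coupling(spin_pair(1)),
               1 / 8, tolerance = 1e-12)
  expect_lt(dipolar_coupling(spin_pair(1e4)), 1e-6)
  expect_error(spin_pair(-1), "positive")
  expect_error(spin_pair(0), "positive")
})

test_that("analytic universal curve matches brute-force propagation", {
  expect_identical(redor_universal_curve(0, 0.01), 0)
  expect_identical(redor_universal_curve(1000, 0), 0)
  # long-time asymptote is 1
  expect_equal(redor_universal_curve(5000, 0.01), 1, tolerance = 0.03)
  expect_error(redor_universal_curve(-1, 1), "non-negative")
  # mid-range lambdas against the independent time-sliced phase integral
  for (case in list(c(5.0, 32), c(5.0, 64), c(7.0, 96))) {
    d <- dipolar_coupling(spin_pair(case[1]))
    ana <- 1 - redor_universal_curve(d, case[2] / 38000)
    expect_equal(brute_redor(case[1], case[2]), ana, tolerance = 1e-3)
  }
})

test_that("ideal-pulse zero-CSA simulator reproduces the analytic curve", {
  p <- ideal_params(c(32, 64, 96) / 38000)
  for (r in c(5, 7, 9)) {
    sim <- simulate_redor(spin_pair(r), p)
    ana <- 1 - redor_universal_curve(dipolar_coupling(spin_pair(r)),
                                     p$mixing_times)
    expect_lt(max(abs(sim$s_ratio - ana)), 1e-3)
  }
})

test_that("simulated dephasing decreases with coupling and vanishes far away", {
  p <- light_params()
  far <- simulate_redor(spin_pair(40), p)
  expect_true(all(abs(far$s_ratio - 1) < 1e-3))
  # dephasing grows monotonically with coupling below the universal-curve
  # overshoot (coupling x time < ~1.2); beyond it the curve oscillates
  expect_lt(simulate_redor(spin_pair(3.8), p)$s_ratio[1],
            simulate_redor(spin_pair(9), p)$s_ratio[1])
  s <- vapply(c(6.5, 7.5, 9, 11, 14), function(r)
    simulate_redor(spin_pair(r), p)$s_ratio, numeric(3))
  expect_true(all(diff(s[1, ]) > 0))
  s_weak <- s[, -1, drop = FALSE]  # longer times: stay in the weak regime
  for (i in 2:3) expect_true(all(diff(s_weak[i, ]) > 0))
})

test_that("powder average is converged and flip weights normalize", {
  p1 <- redor_params(n_orient = 144, n_gamma = 16,
                     mixing_times = c(64, 144) / 38000)
  p2 <- redor_params(n_orient = 288, n_gamma = 16,
                     mixing_times = c(64, 144) / 38000)
  for (r in c(4, 6, 9)) {
    s1 <- simulate_redor(spin_pair(r), p1)$s_ratio
    s2 <- simulate_redor(spin_pair(r), p2)$s_ratio
    expect_lt(max(abs(s1 - s2)), 5e-3)
  }
  expect_equal(sum(p1$flip_angle_weights), 1, tolerance = 1e-12)
  expect_equal(sum(redor_params(flip_angle_grid = c(180, 170))$flip_angle_weights),
               1, tolerance = 1e-12)
})

test_that("sequence parameters are validated", {
  expect_error(redor_params(mixing_times = 1.7e-3), "integer multiples")
  expect_error(redor_params(mas_hz = -1), "positive")
  expect_error(redor_params(pulse_length_deph = 20e-6), "half a rotor period")
  expect_error(redor_params(csa_asymmetry = 1.5), "0, 1")
})

test_that("curve library covers the grid and is cache-stable", {
  lib <- test_library()
  expect_identical(length(lib$distances), 121L)
  expect_equal(lib$distances[1], 3.0)
  expect_equal(lib$distances[121], 15.0)
  # library row equals a direct simulation
  direct <- simulate_redor(spin_pair(5.0), light_params())
  expect_equal(unname(lib$s_matrix[match(5.0, lib$distances), ]),
               direct$s_ratio, tolerance = 1e-12)
  # caching round trip is bitwise identical
  p <- light_params()
  cache <- tempfile(fileext = ".rds")
  small <- build_curve_library(p, distances = c(4, 5, 6), cache_file = cache)
  reloaded <- build_curve_library(p, distances = c(4, 5, 6), cache_file = cache)
  expect_identical(small, reloaded)
  expect_error(build_curve_library(p, distances = numeric(0)), "empty")
})

test_that("distance fitting recovers noiseless truth and applies bound rules", {
  lib <- test_library()
  cv <- redor_curve("x", lib$mixing_times,
                    lib$s_matrix[match(5.0, lib$distances), ])
  fit <- fit_distance(cv, lib)
  expect_equal(fit$best_distance, 5.0)
  expect_false(fit$is_lower_bound_only)
  expect_true(fit$lower <= fit$best_distance && fit$best_distance <= fit$upper)
  expect_equal(min(fit$rmsd_profile),
               fit$rmsd_profile[[sprintf("%.4f", fit$best_distance)]])

  # no dephasing: at least 10 A away, upper uncertainty 40 A
  flat <- fit_distance(redor_curve("flat", lib$mixing_times, c(1, 1, 1)), lib)
  expect_true(flat$is_lower_bound_only)
  expect_equal(flat$lower, 10)
  expect_equal(flat$upper, 40)

  # overlapped sites get a widened lower uncertainty
  ov <- redor_curve("ov", lib$mixing_times,
                    lib$s_matrix[match(5.0, lib$distances), ],
                    overlapped = TRUE)
  fo <- fit_distance(ov, lib)
  expect_lte(fo$lower, fit$lower)
  expect_equal(fo$lower,
               max(lib$distances[1],
                   fit$best_distance - 2 * (fit$best_distance - fit$lower)),
               tolerance = 1e-9)

  expect_error(fit_distance(redor_curve("e", numeric(0), numeric(0)), lib),
               "empty")
})
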