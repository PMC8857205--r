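test_that("Henderson-Hasselbalch shift has the expected shape", {
  expect_equal(hh_shift(6.9, 6.9, 8, 7), 7.5)            # midpoint at pKa
  expect_equal(hh_shift(1, 6.9, 8, 7), 8, tolerance = 1e-4)
  expect_equal(hh_shift(13, 6.9, 8, 7), 7, tolerance = 1e-4)
  expect_equal(hh_shift(7.9, 6.9, 8, 7), 7.090909, tolerance = 1e-6)
  d <- hh_shift(seq(3, 11, 0.25), 6.9, 8, 7)
  expect_true(all(diff(d) < 0))                           # monotone
  expect_true(all(d >= 7 & d <= 8))                       # bounded
})

test_that("global pKa fit recovers generating parameters", {
  # single noiseless series: exact recovery
  one <- list(r1 = data.frame(pH = seq(5, 9, 0.5),
                              shift = hh_shift(seq(5, 9, 0.5), 7.2, 8.3, 7.6)))
  f1 <- global_fit_pka(one, n_mc = 0)
  expect_equal(f1$pka, 7.2, tolerance = 1e-4)
  expect_equal(f1$endpoints$delta_h, 8.3, tolerance = 1e-4)
  expect_equal(f1$endpoints$delta_d, 7.6, tolerance = 1e-4)

  # six-residue seeded set with realistic noise
  tt <- gen_titration(seed = 17)
  f6 <- global_fit_pka(tt$series, n_mc = 100, seed = 1)
  expect_lt(abs(f6$pka - tt$truth$pka), 0.1)

  # local optimality of the shared-pKa objective
  rss_at <- function(pka) {
    sum(vapply(tt$series, function(s) {
      w <- 10^(-s$pH) / (10^(-s$pH) + 10^(-pka))
      sum(stats::lm.fit(cbind(w, 1 - w), s$shift)$residuals^2)
    }, numeric(1)))
  }
  expect_lt(rss_at(f6$pka), rss_at(f6$pka + 0.2))
  expect_lt(rss_at(f6$pka), rss_at(f6$pka - 0.2))

  # flat series are excluded with a warning
  flat <- c(tt$series,
            list(flat = data.frame(pH = seq(5, 9, 0.5), shift = 8.1)))
  expect_warning(ff <- global_fit_pka(flat, n_mc = 0), "flat")
  expect_identical(ff$excluded, "flat")

  # inverse-variance combination sits between the inputs
  fa <- f6; fb <- f6
  fa$pka <- 6.8; fa$sigma_pka <- 0.1
  fb$pka <- 7.0; fb$sigma_pka <- 0.1
  cb <- combine_pka(fa, fb)
  expect_equal(cb$pka, 6.9, tolerance = 1e-9)
  expect_equal(cb$sigma_pka, 0.1 / sqrt(2), tolerance = 1e-9)
})

test_that("pKa recovery is unbiased over many seeded datasets", {
  err <- vapply(1:100, function(s) {
    tt <- gen_titration(seed = s, noise_sd = 0.01)
    global_fit_pka(tt$series, n_mc = 0)$pka - tt$truth$pka
  }, numeric(1))
  expect_lt(abs(mean(err)), 0.05)
})

test_that("composite shift difference behaves like a norm", {
  expect_equal(composite_shift_diff(0, 0), 0)
  expect_equal(composite_shift_diff(0.3, 0), 0.3 / sqrt(2))
  expect_equal(composite_shift_diff(0.2, 2.0), 0.2, tolerance = 1e-9)
  # carbon variant without the gyromagnetic scaling
  expect_equal(composite_shift_diff(0.2, 2.0, scale = 1),
               sqrt(0.5 * (0.04 + 4)), tolerance = 1e-9)
  # triangle inequality on component-wise sums
  expect_lte(composite_shift_diff(0.1 + 0.2, 1 + 0.5),
             composite_shift_diff(0.1, 1) + composite_shift_diff(0.2, 0.5))
})

test_that("effective temperature calibration is the stated line", {
  expect_equal(effective_temperature(4.89), 284.886, tolerance = 1e-9)
  expect_equal(round(effective_temperature(4.89)), 285)
  expect_equal(effective_temperature(4.83), 290.7, tolerance = 1e-9)
  expect_warning(t0 <- effective_temperature(7.83), "non-physical")
  expect_equal(t0, 0)
})

test_that("ITC buffer-ionization extrapolation recovers slope and intercept", {
  # two-buffer synthetic set with slope 0.8, intercept -20
  fit <- itc_extrapolate(c(3.6, 47.45), -20 + 0.8 * c(3.6, 47.45), dg = -41.1)
  expect_equal(fit$dh_binding, -20, tolerance = 1e-9)
  expect_equal(fit$n_protons, 0.8, tolerance = 1e-9)
  expect_equal(fit$minus_tds, -20 - (-41.1), tolerance = 1e-9)
  # zero slope: intercept equals the mean observed enthalpy
  f0 <- itc_extrapolate(c(5, 20, 40), c(-31.5, -31.5, -31.5), dg = -34.9)
  expect_equal(f0$dh_binding, -31.5, tolerance = 1e-9)
  expect_equal(f0$n_protons, 0, tolerance = 1e-9)
  expect_error(itc_extrapolate(4, -20, -30), "2 buffers")
  expect_error(itc_extrapolate(c(4, 4), c(-20, -21), -30), "singular")
})
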