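# Shared fixtures.  The REDOR curve library is expensive relative to the
# rest of the suite, so it is built once per session at a reduced powder
# quality (convergence-checked in test-spinsim.R) and memoized.

.test_cache <- new.env(parent = emptyenv())

# paper-condition pulse/CSA settings with a lighter powder set
light_params <- function(...) {
  redor_params(n_orient = 144, n_gamma = 8, ...)
}

test_library <- function() {
  if (is.null(.test_cache$lib)) {
    .test_cache$lib <- build_curve_library(light_params())
  }
  .test_cache$lib
}

# ideal-pulse sequence params for comparisons against the analytic curve
ideal_params <- function(mixing_times, n_orient = 233, n_gamma = 16) {
  redor_params(mixing_times = mixing_times, pulse_length_deph = 0,
               csa_span_ppm = 0, flip_angle_grid = 180,
               n_orient = n_orient, n_gamma = n_gamma)
}

# Brute-force time-sliced ideal-pulse REDOR oracle: S/S0 = <cos Phi> with
# Phi = integral of s(t) * wD(t), s toggling at the pulse positions.
# Independent of the propagator (direct phase integral + powder sum).
brute_redor <- function(distance, n_periods, mas_hz = 38000, nb = 120,
                        ng = 64, per_steps = 200) {
  d <- dipolar_coupling(spin_pair(distance))
  b <- 2 * pi * d
  tr <- 1 / mas_hz
  Tt <- n_periods * tr
  nt <- per_steps * n_periods
  tm <- acos(1 / sqrt(3))
  tt <- (seq_len(nt) - 0.5) / nt * Tt
  s <- ifelse(abs((tt %% tr) - tr / 2) > tr / 4, 1, -1)
  acc <- 0; wsum <- 0
  for (ib in seq_len(nb)) {
    be <- (ib - 0.5) / nb * pi
    ct0 <- cos(tm) * cos(be); amp <- sin(tm) * sin(be)
    for (ig in seq_len(ng)) {
      ga <- (ig - 0.5) / ng * 2 * pi
      ct <- ct0 - amp * cos(2 * pi * mas_hz * tt + ga)
      Phi <- sum(s * b * (3 * ct^2 - 1) / 2) * Tt / nt
      acc <- acc + sin(be) * cos(Phi)
      wsum <- wsum + sin(be)
    }
  }
  acc / wsum
}

# two-model ensemble where model 2 stretches one restraint by a known gap
toy_two_model <- function() {
  tc <- gen_toy_complex(n_models = 2, model_rms = 0, seed = 1)
  tc
}
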