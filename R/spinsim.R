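# Two-spin 1H-19F REDOR simulation and distance extraction.

# CODATA gyromagnetic ratios (rad s^-1 T^-1)
.GAMMA_1H <- 267.52218744e6
.GAMMA_19F <- 251.815e6
.HBAR <- 1.054571817e-34
.MU0_4PI <- 1e-7

#' Heteronuclear spin-pair geometry
#'
#' Describes a two-spin system by the internuclear distance and the
#' gyromagnetic ratios of the observed and dephasing nuclei.  Defaults are a
#' 1H (observed) - 19F (dephasing) pair, the geometry probed by
#' amide-proton-detected REDOR on fluorinated ligands.
#'
#' @param distance Internuclear distance in Angstrom (> 0).
#' @param gamma_obs,gamma_deph Gyromagnetic ratios in rad s^-1 T^-1.
#' @return An object of class `spin_pair`.
#' @export
#' @examples
#' dipolar_coupling(spin_pair(3.8))  # about 2.06 kHz
spin_pair <- function(distance, gamma_obs = .GAMMA_1H, gamma_deph = .GAMMA_19F) {
  if (!is.numeric(distance) || length(distance) != 1L || !is.finite(distance) ||
      distance <= 0) {
    stop("'distance' must be a single positive number (Angstrom)")
  }
  structure(list(distance = distance, gamma_obs = gamma_obs,
                 gamma_deph = gamma_deph),
            class = "spin_pair")
}

#' Point-dipole heteronuclear coupling constant
#'
#' Computes the dipolar coupling d = (mu0/4pi) * gamma1 * gamma2 * hbar /
#' (2 pi r^3) in Hz.  The coupling falls off as the inverse cube of the
#' distance, which is what makes REDOR dephasing a distance ruler.
#'
#' @param geom A [spin_pair()].
#' @return Dipolar coupling in Hz.
#' @export
dipolar_coupling <- function(geom) {
  stopifnot(inherits(geom, "spin_pair"))
  r_m <- geom$distance * 1e-10
  .MU0_4PI * geom$gamma_obs * geom$gamma_deph * .HBAR / (2 * pi * r_m^3)
}

#' Analytic powder-averaged REDOR dephasing (ideal pulses)
#'
#' The universal REDOR curve for an isolated spin pair with ideal
#' (delta-function) pulses, expressed through quarter-order Bessel
#' functions:
#' dS/S0(lambda) = 1 - (sqrt(2) pi / 4) J_{1/4}(sqrt(2) lambda)
#' J_{-1/4}(sqrt(2) lambda) with lambda = d * T.  Serves as the analytic
#' oracle for the numerical propagator in its ideal-pulse, zero-CSA limit.
#'
#' @param coupling Dipolar coupling in Hz (>= 0).
#' @param evolution_time Total dephasing time in seconds (>= 0).
#' @return dS/S0, the dephasing (0 at time zero, approaching 1 with a small
#'   overshoot at intermediate evolution).
#' @export
redor_universal_curve <- function(coupling, evolution_time) {
  if (any(coupling < 0) || any(evolution_time < 0)) {
    stop("'coupling' and 'evolution_time' must be non-negative")
  }
  lambda <- coupling * evolution_time
  out <- numeric(length(lambda))
  pos <- lambda > 0
  x <- sqrt(2) * lambda[pos]
  out[pos] <- 1 - (sqrt(2) * pi / 4) * besselJ(x, 0.25) * besselJ(x, -0.25)
  out
}

#' REDOR pulse-sequence and simulation parameters
#'
#' Bundles the experimental and numerical parameters of the rotor-
#' synchronized REDOR simulation: MAS rate, mixing times, the finite pi
#' pulse on the dephasing (19F) channel, the 19F CSA, the RF-inhomogeneity
#' flip-angle distribution, and the powder-averaging scheme.
#'
#' Defaults reflect the measurement conditions this package targets:
#' 38 kHz MAS with rotor-synchronized mixing times of 64, 96 and 144 rotor
#' periods (1.68, 2.53 and 3.79 ms), a 600 MHz
#' spectrometer (19F Larmor frequency 564.6 MHz), an aryl-fluorine CSA of
#' 60 ppm span with asymmetry 1 oriented along the internuclear vector, RF
#' inhomogeneity modelled as flip angles of 180 to 145 degrees in 5 degree
#' steps weighted by a half-Gaussian centred at 180 with sd 15 degrees, and
#' a 320-orientation repulsion powder set with 32 gamma angles.
#'
#' @param mas_hz MAS rate in Hz.
#' @param mixing_times REDOR mixing times in seconds; each must be an
#'   integer multiple of the rotor period to within `sync_tol` rotor
#'   periods (times are snapped to the nearest multiple).
#' @param pulse_length_deph Length of each pi pulse on the dephasing
#'   channel in seconds; 0 requests ideal (instantaneous) pulses.
#' @param csa_span_ppm Span (largest minus smallest principal value) of the
#'   dephasing-spin CSA in ppm; 0 disables the CSA.
#' @param csa_asymmetry Haeberlen asymmetry parameter eta in [0, 1].
#' @param larmor_deph_hz Larmor frequency of the dephasing nucleus in Hz,
#'   used to convert the CSA from ppm to Hz.
#' @param flip_angle_grid Pulse flip angles in degrees.
#' @param flip_angle_sigma Standard deviation (degrees) of the half-Gaussian
#'   flip-angle weighting centred on 180 degrees.
#' @param powder_scheme "repulsion" (electrostatically optimized quasi-
#'   uniform set) or "spiral" (deterministic golden-section spiral).
#' @param n_orient Number of (alpha, beta) crystallite orientations.
#' @param n_gamma Number of rotor-phase gamma angles per orientation.
#' @param n_steps Piecewise-constant propagation steps per rotor period.
#' @param sync_tol Rotor-synchronization tolerance in rotor periods.
#' @return An object of class `redor_params`.
#' @export
redor_params <- function(mas_hz = 38000,
                         mixing_times = c(64, 96, 144) / 38000,
                         pulse_length_deph = 6e-6,
                         csa_span_ppm = 60,
                         csa_asymmetry = 1,
                         larmor_deph_hz = 564.6e6,
                         flip_angle_grid = seq(180, 145, by = -5),
                         flip_angle_sigma = 15,
                         powder_scheme = c("repulsion", "spiral"),
                         n_orient = 320,
                         n_gamma = 32,
                         n_steps = 256,
                         sync_tol = 0.02) {
  powder_scheme <- match.arg(powder_scheme)
  if (mas_hz <= 0) stop("'mas_hz' must be positive")
  if (any(mixing_times <= 0)) stop("mixing times must be positive")
  if (pulse_length_deph < 0) stop("'pulse_length_deph' must be >= 0")
  if (pulse_length_deph >= 0.5 / mas_hz) {
    stop("pulse length must be shorter than half a rotor period")
  }
  if (csa_asymmetry < 0 || csa_asymmetry > 1) {
    stop("'csa_asymmetry' must lie in [0, 1]")
  }
  n_per <- mixing_times * mas_hz
  if (any(abs(n_per - round(n_per)) > sync_tol)) {
    stop("mixing times must be integer multiples of the rotor period")
  }
  if (any(round(n_per) < 1)) stop("mixing times must span >= 1 rotor period")
  w <- exp(-(180 - flip_angle_grid)^2 / (2 * flip_angle_sigma^2))
  structure(list(mas_hz = mas_hz,
                 mixing_times = mixing_times,
                 n_periods = as.integer(round(n_per)),
                 pulse_length_deph = pulse_length_deph,
                 csa_span_ppm = csa_span_ppm,
                 csa_asymmetry = csa_asymmetry,
                 larmor_deph_hz = larmor_deph_hz,
                 flip_angle_grid = flip_angle_grid,
                 flip_angle_weights = w / sum(w),
                 powder_scheme = powder_scheme,
                 n_orient = as.integer(n_orient),
                 n_gamma = as.integer(n_gamma),
                 n_steps = as.integer(n_steps)),
            class = "redor_params")
}

# cache of powder orientation sets
.powder_cache <- new.env(parent = emptyenv())

#' Quasi-uniform powder orientation sets
#'
#' Generates `n` crystallite orientations (alpha, beta) on the sphere.
#' `"spiral"` is a deterministic golden-section spiral; `"repulsion"`
#' refines the spiral by minimizing the inter-point Coulomb energy
#' (electrostatic repulsion), giving a quasi-uniform set in the spirit of
#' the REPULSION schemes used for MAS powder averaging.  Both constructions
#' are fully deterministic, so identical inputs give identical sets.
#'
#' @param n Number of orientations.
#' @param scheme "repulsion" or "spiral".
#' @param n_iter Repulsion refinement iterations.
#' @return An `n` x 2 matrix with columns alpha, beta in radians.
#' @export
powder_orientations <- function(n, scheme = c("repulsion", "spiral"),
                                n_iter = 200) {
  scheme <- match.arg(scheme)
  if (n < 2) stop("need at least 2 orientations")
  key <- paste(scheme, n, n_iter, sep = "_")
  if (!is.null(.powder_cache[[key]])) return(.powder_cache[[key]])

  # golden-section spiral start
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (1 + sqrt(5)) * i
  pts <- cbind(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)

  if (scheme == "repulsion") {
    step <- 2 / n
    for (it in seq_len(n_iter)) {
      dx <- outer(pts[, 1], pts[, 1], "-")
      dy <- outer(pts[, 2], pts[, 2], "-")
      dz <- outer(pts[, 3], pts[, 3], "-")
      r2 <- dx^2 + dy^2 + dz^2
      diag(r2) <- Inf
      inv3 <- r2^(-1.5)
      f <- cbind(rowSums(dx * inv3), rowSums(dy * inv3), rowSums(dz * inv3))
      pts <- pts + step * f / sqrt(rowSums(f^2) + 1e-12) *
        sqrt(rowSums(pts^2))
      pts <- pts / sqrt(rowSums(pts^2))
    }
  }
  ori <- cbind(alpha = atan2(pts[, 2], pts[, 1]),
               beta = acos(pmin(1, pmax(-1, pts[, 3]))))
  .powder_cache[[key]] <- ori
  ori
}

# traceless CSA principal values (rad/s) from span/asymmetry (Haeberlen)
.csa_principal <- function(span_ppm, eta, larmor_hz) {
  if (span_ppm == 0) return(c(0, 0, 0))
  d_aniso <- 2 * span_ppm / (3 + eta)          # ppm
  vals_ppm <- c(-d_aniso * (1 + eta) / 2, -d_aniso * (1 - eta) / 2, d_aniso)
  2 * pi * vals_ppm * larmor_hz / 1e6
}

#' REDOR dephasing curve container
#'
#' @param site_id Site label, e.g. `"W63B-NE1"`.
#' @param mixing_times Mixing times in seconds.
#' @param s_ratio S/S0 values.
#' @param s_ratio_err Optional uncertainties on S/S0.
#' @param overlapped Logical; TRUE for sites whose peaks overlap in the 2D
#'   spectrum (their fitted lower distance bound is widened).
#' @return An object of class `redor_curve`.
#' @export
redor_curve <- function(site_id, mixing_times, s_ratio, s_ratio_err = NULL,
                        overlapped = FALSE) {
  if (length(mixing_times) != length(s_ratio)) {
    stop("'mixing_times' and 's_ratio' lengths differ")
  }
  if (!all(is.finite(s_ratio))) stop("'s_ratio' values must be finite")
  if (!is.null(s_ratio_err) && length(s_ratio_err) != length(s_ratio)) {
    stop("'s_ratio_err' length must match 's_ratio'")
  }
  structure(list(site_id = site_id,
                 mixing_times = as.numeric(mixing_times),
                 s_ratio = as.numeric(s_ratio),
                 s_ratio_err = s_ratio_err,
                 overlapped = isTRUE(overlapped)),
            class = "redor_curve")
}

#' @export
print.redor_curve <- function(x, ...) {
  cat("REDOR curve", x$site_id,
      if (x$overlapped) "(overlapped)" else "", "\n")
  print(data.frame(mixing_time_s = x$mixing_times, s_ratio = x$s_ratio))
  invisible(x)
}

#' Simulate a two-spin REDOR dephasing curve
#'
#' Propagates the fluorine spin piecewise-constantly through one rotor
#' period under its CSA, the heteronuclear dipolar coupling and the rotor-
#' synchronized pi-pulse train (two pulses per rotor period), raises the
#' one-period propagators to the number of rotor cycles in each mixing
#' time, and powder-averages Re Tr[U+ U-^dagger]/2 over crystallite
#' orientations, rotor phases and the flip-angle distribution.  The
#' observed-spin coherence is treated as ideally refocused, so S0 = 1 and
#' the returned values are S/S0 directly.
#'
#' With `pulse_length_deph = 0` and `csa_span_ppm = 0` the result
#' reproduces the analytic universal curve [redor_universal_curve()].
#'
#' @param geom A [spin_pair()].
#' @param seq_params A [redor_params()].
#' @return A [redor_curve()] with simulated S/S0 values.
#' @export
simulate_redor <- function(geom, seq_params) {
  stopifnot(inherits(geom, "spin_pair"), inherits(seq_params, "redor_params"))
  lib <- .redor_simulate_grid(geom$distance, seq_params,
                              gamma_obs = geom$gamma_obs,
                              gamma_deph = geom$gamma_deph)
  redor_curve(site_id = sprintf("sim_%.2fA", geom$distance),
              mixing_times = seq_params$mixing_times,
              s_ratio = lib[1, ])
}

# core wrapper around the C++ kernel; returns matrix [n_dist x n_times]
.redor_simulate_grid <- function(distances, seq_params,
                                 gamma_obs = .GAMMA_1H,
                                 gamma_deph = .GAMMA_19F) {
  d_hz <- vapply(distances, function(r)
    dipolar_coupling(spin_pair(r, gamma_obs, gamma_deph)), numeric(1))
  ori <- powder_orientations(seq_params$n_orient, seq_params$powder_scheme)
  csa <- .csa_principal(seq_params$csa_span_ppm, seq_params$csa_asymmetry,
                        seq_params$larmor_deph_hz)
  ord <- order(seq_params$n_periods)
  res <- redor_kernel_cpp(d_hz, csa, ori, seq_params$n_gamma,
                          seq_params$flip_angle_grid * pi / 180,
                          seq_params$flip_angle_weights,
                          seq_params$mas_hz, seq_params$pulse_length_deph,
                          seq_params$n_periods[ord], seq_params$n_steps)
  out <- res
  out[, ord] <- res
  dimnames(out) <- list(sprintf("%.4f", distances),
                        sprintf("%.6g", seq_params$mixing_times))
  out
}

#' Build a library of simulated REDOR curves over a distance grid
#'
#' Simulates S/S0 curves for every distance on the grid (default 3.0 to
#' 15.0 Angstrom in 0.1 Angstrom steps) under the given sequence
#' parameters.  The library can be cached to disk; the cache embeds the
#' generating parameters and is only reused when they match exactly.
#'
#' @param seq_params A [redor_params()].
#' @param distances Distance grid in Angstrom.
#' @param cache_file Optional path to an RDS cache.
#' @return An object of class `redor_library` with elements `distances`,
#'   `mixing_times`, `s_matrix` (distances x mixing times) and `params`.
#' @export
build_curve_library <- function(seq_params,
                                distances = seq(3, 15, by = 0.1),
                                cache_file = NULL) {
  stopifnot(inherits(seq_params, "redor_params"))
  if (length(distances) == 0) stop("empty distance grid")
  if (any(diff(distances) <= 0)) stop("distance grid must be increasing")
  key <- list(params = unclass(seq_params), distances = distances)
  if (!is.null(cache_file) && file.exists(cache_file)) {
    cached <- readRDS(cache_file)
    if (identical(cached$key, key)) return(cached$library)
  }
  s_mat <- .redor_simulate_grid(distances, seq_params)
  lib <- structure(list(distances = distances,
                        mixing_times = seq_params$mixing_times,
                        s_matrix = s_mat,
                        params = seq_params),
                   class = "redor_library")
  if (!is.null(cache_file)) {
    saveRDS(list(key = key, library = lib), cache_file)
  }
  lib
}

#' @export
print.redor_library <- function(x, ...) {
  cat("REDOR curve library:", length(x$distances), "distances (",
      min(x$distances), "-", max(x$distances), "A ),",
      length(x$mixing_times), "mixing times\n")
  invisible(x)
}

#' Extract a distance from a measured REDOR curve
#'
#' Grid search: for every library distance, the root-mean-square deviation
#' between simulated and measured S/S0 values (over the curve's mixing
#' times) is computed; the best-fit distance minimizes this RMSD.  The
#' reported uncertainty interval is the contiguous grid interval around the
#' minimum over which RMSD <= `rmsd_threshold` (default 0.2).  Curves whose
#' dephasing is indistinguishable from none (RMSD to S/S0 = 1 within the
#' threshold and a sub-threshold interval reaching the top of the grid) are
#' reported as lower bounds: the site is at least `lb_lower` (10 A) from
#' the fluorines, with upper uncertainty `lb_upper` (40 A, the longest
#' plausible distance in the dimer).  For overlapped sites the lower
#' uncertainty interval is widened by `overlap_factor`.
#'
#' Equal-RMSD grid minima resolve to the shorter distance (the more
#' conservative restraint).  If several disjoint sub-threshold intervals
#' exist, the widest enclosing interval is reported with a warning.
#'
#' @param curve A [redor_curve()].
#' @param library A [build_curve_library()] result; the curve's mixing
#'   times must be a subset of the library's.
#' @param rmsd_threshold RMSD cutoff defining the uncertainty interval.
#' @param lb_lower,lb_upper Bounds (Angstrom) reported for no-dephasing sites.
#' @param overlap_factor Widening factor for the lower uncertainty of
#'   overlapped sites.
#' @return An object of class `distance_fit` with `best_distance`, `lower`,
#'   `upper`, `rmsd_profile`, `is_lower_bound_only`, `site_id`, `overlapped`.
#' @export
fit_distance <- function(curve, library, rmsd_threshold = 0.2,
                         lb_lower = 10, lb_upper = 40, overlap_factor = 2) {
  stopifnot(inherits(curve, "redor_curve"), inherits(library, "redor_library"))
  if (length(curve$s_ratio) == 0) stop("empty REDOR curve")
  idx <- match_times(curve$mixing_times, library$mixing_times)
  sim <- library$s_matrix[, idx, drop = FALSE]
  resid <- sweep(sim, 2, curve$s_ratio, "-")
  rmsd <- sqrt(rowMeans(resid^2))
  names(rmsd) <- sprintf("%.4f", library$distances)

  best_i <- which(rmsd == min(rmsd))[1]  # ties -> shorter distance
  below <- rmsd <= rmsd_threshold
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  sub <- which(runs$values)
  if (length(sub) > 1) {
    warning("multiple disjoint sub-threshold RMSD intervals; ",
            "reporting the widest enclosing interval")
    lo_i <- starts[sub[1]]
    hi_i <- ends[sub[length(sub)]]
  } else if (length(sub) == 1) {
    lo_i <- starts[sub]
    hi_i <- ends[sub]
  } else {
    lo_i <- hi_i <- best_i
  }

  n_grid <- length(library$distances)
  flat_rmsd <- sqrt(mean((curve$s_ratio - 1)^2))
  lb_only <- flat_rmsd <= rmsd_threshold && any(below) && hi_i == n_grid

  if (lb_only) {
    fit <- list(best_distance = NA_real_, lower = lb_lower, upper = lb_upper,
                is_lower_bound_only = TRUE)
  } else {
    best <- library$distances[best_i]
    lower <- library$distances[lo_i]
    upper <- library$distances[hi_i]
    if (curve$overlapped) lower <- max(library$distances[1],
                                       best - overlap_factor * (best - lower))
    fit <- list(best_distance = best, lower = lower, upper = upper,
                is_lower_bound_only = FALSE)
  }
  structure(c(fit, list(rmsd_profile = rmsd, site_id = curve$site_id,
                        overlapped = curve$overlapped)),
            class = "distance_fit")
}

#' @export
print.distance_fit <- function(x, ...) {
  if (x$is_lower_bound_only) {
    cat(sprintf("%s: no significant dephasing; distance >= %.1f A (upper %.1f A)\n",
                x$site_id, x$lower, x$upper))
  } else {
    cat(sprintf("%s: %.1f A [%.1f, %.1f]%s\n", x$site_id, x$best_distance,
                x$lower, x$upper, if (x$overlapped) " (overlapped)" else ""))
  }
  invisible(x)
}

# match requested times against available ones (relative tolerance)
match_times <- function(times, available, tol = 0.01) {
  idx <- vapply(times, function(t) {
    j <- which(abs(available - t) <= tol * max(t, 1e-12))
    if (length(j) == 0) {
      stop("mixing time ", t, " s not present in the curve library")
    }
    j[1]
  }, integer(1))
  idx
}
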