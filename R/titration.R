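# pH titration analysis: Henderson-Hasselbalch pKa fitting, composite
# chemical-shift asymmetry, sample-temperature calibration, and ITC
# buffer-ionization extrapolation.

#' Henderson-Hasselbalch chemical shift
#'
#' Fast-exchange-averaged chemical shift of a site titrating between a
#' protonated endpoint delta_h and a deprotonated endpoint delta_d with
#' midpoint pKa:
#' delta = (delta_h 10^-pH + delta_d 10^-pKa) / (10^-pH + 10^-pKa).
#'
#' @param pH pH value(s).
#' @param pka Acid dissociation midpoint.
#' @param delta_h,delta_d Protonated / deprotonated endpoint shifts (ppm).
#' @return Chemical shift(s) in ppm, bounded by the two endpoints and
#'   equal to their midpoint at pH = pKa.
#' @export
hh_shift <- function(pH, pka, delta_h, delta_d) {
  wh <- 10^(-pH)
  wd <- 10^(-pka)
  (delta_h * wh + delta_d * wd) / (wh + wd)
}

#' Global single-pKa fit of titration series
#'
#' Fits one shared pKa across all series while each series keeps its own
#' protonated/deprotonated endpoints.  Because the model is linear in the
#' endpoints at fixed pKa, the fit is a one-dimensional profile over pKa
#' with the endpoints solved by linear least squares -- no starting values
#' needed.  Series whose shift range is below `flat_tol` carry no pKa
#' information and are excluded with a warning.  The pKa uncertainty is
#' estimated by Monte Carlo: points are perturbed by the per-series
#' residual standard deviation and refit.
#'
#' @param series A list of data frames, each with columns `pH` and
#'   `shift` (ppm), optionally named by residue.
#' @param n_mc Monte Carlo replicates for the pKa uncertainty.
#' @param seed Optional RNG seed.
#' @param flat_tol Minimum shift range (ppm) for a series to contribute.
#' @param pka_range Search interval for the shared pKa.
#' @return An object of class `pka_fit`: `pka`, `sigma_pka`, `endpoints`
#'   (data frame of per-series delta_h, delta_d), `excluded`.
#' @export
global_fit_pka <- function(series, n_mc = 500, seed = NULL,
                           flat_tol = 1e-3, pka_range = c(2, 12)) {
  if (length(series) == 0) stop("no titration series supplied")
  if (is.null(names(series)) || any(names(series) == "")) {
    names(series) <- paste0("series", seq_along(series))
  }
  rng <- vapply(series, function(s) diff(range(s$shift)), numeric(1))
  excluded <- names(series)[rng < flat_tol]
  if (length(excluded) > 0) {
    warning("flat series excluded: ", paste(excluded, collapse = ", "))
    series <- series[rng >= flat_tol]
    if (length(series) == 0) stop("all series are flat")
  }

  fit_at <- function(pka, dat) {
    # linear endpoints at fixed pKa; returns rss and endpoint estimates
    res <- lapply(dat, function(s) {
      w <- 10^(-s$pH) / (10^(-s$pH) + 10^(-pka))
      X <- cbind(w, 1 - w)
      f <- stats::lm.fit(X, s$shift)
      list(rss = sum(f$residuals^2), cf = f$coefficients)
    })
    list(rss = sum(vapply(res, `[[`, numeric(1), "rss")),
         cf = t(vapply(res, `[[`, numeric(2), "cf")))
  }
  obj <- function(pka, dat) fit_at(pka, dat)$rss
  opt <- stats::optimize(obj, pka_range, dat = series)
  best <- fit_at(opt$minimum, series)

  sigma_pka <- NA_real_
  if (n_mc > 0) {
    if (!is.null(seed)) set.seed(seed)
    # per-series residual noise level at the optimum
    noise <- vapply(seq_along(series), function(i) {
      s <- series[[i]]
      w <- 10^(-s$pH) / (10^(-s$pH) + 10^(-opt$minimum))
      pred <- best$cf[i, 1] * w + best$cf[i, 2] * (1 - w)
      n <- length(s$pH)
      sqrt(sum((s$shift - pred)^2) / max(1, n - 2))
    }, numeric(1))
    reps <- vapply(seq_len(n_mc), function(b) {
      pert <- lapply(seq_along(series), function(i) {
        s <- series[[i]]
        s$shift <- s$shift + rnorm(length(s$shift), 0, noise[i])
        s
      })
      stats::optimize(obj, pka_range, dat = pert)$minimum
    }, numeric(1))
    sigma_pka <- sd(reps)
  }
  structure(list(pka = opt$minimum, sigma_pka = sigma_pka,
                 endpoints = data.frame(series = names(series),
                                        delta_h = best$cf[, 1],
                                        delta_d = best$cf[, 2],
                                        row.names = NULL),
                 excluded = excluded),
            class = "pka_fit")
}

#' @export
print.pka_fit <- function(x, ...) {
  cat(sprintf("Global pKa = %.2f +/- %.2f (%d series)\n", x$pka,
              x$sigma_pka, nrow(x$endpoints)))
  invisible(x)
}

#' Inverse-variance combination of two pKa fits
#'
#' Convenience combination of, e.g., the separate 1H and 15N global fits
#' into a single value, weighting each by its inverse variance.
#'
#' @param ... Two or more [global_fit_pka()] results.
#' @return List with combined `pka` and `sigma_pka`.
#' @export
combine_pka <- function(...) {
  fits <- list(...)
  pka <- vapply(fits, `[[`, numeric(1), "pka")
  s <- vapply(fits, `[[`, numeric(1), "sigma_pka")
  w <- 1 / s^2
  list(pka = sum(w * pka) / sum(w), sigma_pka = sqrt(1 / sum(w)))
}

#' Composite chemical-shift difference
#'
#' Combines proton and heteronucleus shift differences into one value:
#' sqrt(0.5 * (dH^2 + (scale * dX)^2)).  The default scale 0.10
#' compensates the 1H/15N gyromagnetic-ratio difference for amide N-H
#' pairs; use `scale = 1` for CA/CO carbon pairs.
#'
#' @param delta_h Proton shift difference (ppm).
#' @param delta_x Heteronucleus shift difference (ppm).
#' @param scale Heteronucleus scaling factor.
#' @return Composite shift difference (ppm).
#' @export
composite_shift_diff <- function(delta_h, delta_x, scale = 0.10) {
  sqrt(0.5 * (delta_h^2 + (scale * delta_x)^2))
}

#' Effective MAS sample temperature from the water 1H shift
#'
#' Linear calibration T_eff (K) = 96.9 * (7.83 - delta_H2O), where
#' delta_H2O is the observed water proton chemical shift in ppm.  Shifts
#' at or above 7.83 ppm give non-physical (<= 0 K) temperatures and are
#' returned with a warning.
#'
#' @param delta_h2o Water 1H chemical shift in ppm.
#' @return Effective sample temperature in kelvin.
#' @export
effective_temperature <- function(delta_h2o) {
  t_eff <- 96.9 * (7.83 - delta_h2o)
  if (any(t_eff <= 0)) warning("non-physical temperature (delta >= 7.83 ppm)")
  t_eff
}

#' ITC buffer-ionization extrapolation
#'
#' Isothermal-titration-calorimetry enthalpies measured in buffers with
#' different ionization enthalpies contain a contribution from the
#' protons the buffer absorbs or releases.  Linear regression of the
#' observed enthalpy on the buffer ionization enthalpy gives the
#' buffer-independent binding enthalpy (the intercept, i.e. the
#' extrapolation to Delta_H_ionization = 0) and the number of protons
#' released (the slope); the entropic term follows as -T Delta_S =
#' Delta_H - Delta_G.
#'
#' @param dh_ionization Buffer ionization enthalpies (kJ/mol), >= 2
#'   distinct values.
#' @param dh_observed Observed binding enthalpies (kJ/mol).
#' @param dg Binding free energy (kJ/mol) at this pH.
#' @return List with `dh_binding`, `n_protons`, `minus_tds` (all kJ/mol
#'   except the dimensionless proton count).
#' @export
itc_extrapolate <- function(dh_ionization, dh_observed, dg) {
  if (length(dh_ionization) < 2) stop("need at least 2 buffers")
  if (length(unique(dh_ionization)) < 2) {
    stop("singular design: all buffer ionization enthalpies equal")
  }
  fit <- lm(dh_observed ~ dh_ionization)
  dh <- unname(coef(fit)[1])
  list(dh_binding = dh, n_protons = unname(coef(fit)[2]),
       minus_tds = dh - dg)
}
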