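# Seeded synthetic-data generators.  Every generator emits both the data
# and a machine-readable truth table so parameter-recovery tests can close
# the loop.  Identical seeds give identical outputs.

#' Generate synthetic REDOR curves with known distances
#'
#' Draws true distances from the library grid, takes the simulated S/S0
#' values at the library's mixing times and adds Gaussian intensity noise.
#' Alongside the measurable sites, `n_weak` non-dephasing sites (S/S0
#' about 1) are generated to exercise the >= 10 Angstrom lower-bound rule.
#' The default composition mirrors a realistic measurement campaign on a
#' fluorinated-ligand complex: 92 weak and 24 measurable sites out of 116
#' resolved dephasing curves.
#'
#' @param library A [build_curve_library()] result.
#' @param n_weak Number of non-dephasing (weak-coupling) sites.
#' @param n_measured Number of measurable sites.
#' @param noise_sd Gaussian noise standard deviation on S/S0.
#' @param distance_range Range (Angstrom) from which measurable true
#'   distances are drawn (snapped to the library grid).
#' @param seed RNG seed.
#' @return List with `curves` (list of [redor_curve()]) and `truth`
#'   (data frame: site_id, distance, weak).
#' @export
gen_redor_curves <- function(library, n_weak = 92, n_measured = 24,
                             noise_sd = 0.05, distance_range = c(3.5, 8.5),
                             seed = 1) {
  stopifnot(inherits(library, "redor_library"))
  set.seed(seed)
  grid <- library$distances
  pool <- grid[grid >= distance_range[1] & grid <= distance_range[2]]
  truth <- data.frame(
    site_id = sprintf("site%03d", seq_len(n_measured + n_weak)),
    distance = c(sample(pool, n_measured, replace = TRUE),
                 rep(NA_real_, n_weak)),
    weak = c(rep(FALSE, n_measured), rep(TRUE, n_weak)),
    stringsAsFactors = FALSE)
  nt <- length(library$mixing_times)
  curves <- lapply(seq_len(nrow(truth)), function(i) {
    s <- if (truth$weak[i]) rep(1, nt)
         else library$s_matrix[match(truth$distance[i], grid), ]
    redor_curve(truth$site_id[i], library$mixing_times,
                s + rnorm(nt, 0, noise_sd),
                s_ratio_err = rep(noise_sd, nt))
  })
  list(curves = curves, truth = truth)
}

# ideal alpha-helix backbone: N, CA, C, O, H per residue, axis along +z
.helix_chain <- function(n_res, chain) {
  rise <- 1.5; twist <- 100 * pi / 180
  at <- list(); xyz <- list()
  place <- function(phase, radius, i) {
    a <- twist * (i + phase)
    c(radius * cos(a), radius * sin(a), rise * (i + phase))
  }
  for (i in seq_len(n_res)) {
    n_pos <- place(-0.35, 1.6, i)
    ca_pos <- place(0, 2.3, i)
    c_pos <- place(0.35, 1.7, i)
    o_dir <- c_pos * c(1, 1, 0)
    o_pos <- c_pos + 1.23 * o_dir / sqrt(sum(o_dir^2))
    h_dir <- n_pos * c(1, 1, 0)
    h_pos <- n_pos + 1.0 * h_dir / sqrt(sum(h_dir^2))
    at[[i]] <- data.frame(chain = chain, resno = i, resid = "ALA",
                          elety = c("N", "CA", "C", "O", "H"),
                          elesy = c("N", "C", "C", "O", "H"),
                          stringsAsFactors = FALSE)
    xyz[[i]] <- rbind(n_pos, ca_pos, c_pos, o_pos, h_pos)
  }
  list(atoms = do.call(rbind, at), xyz = do.call(rbind, xyz))
}

#' Generate a toy helix-dimer / tetrahedral-ligand complex
#'
#' Builds a minimal geometric stand-in for a fluorinated-ligand membrane
#' protein complex: two idealized antiparallel poly-alanine helices
#' (chains A and B) flanking a tetrahedral ligand (chain L, residue TPP:
#' central phosphorus, four bonded carbons at 1.8 Angstrom, four
#' fluorines at 5.7 Angstrom along the same tetrahedral directions), with
#' optional water oxygens (chain W) placed in known counts inside and
#' outside the binding-pocket criteria (within 15 Angstrom of any ligand
#' atom and inside the z window spanned by the helix termini).  Additional
#' models are Gaussian-perturbed copies of the first.  Realism is not a
#' goal; exact geometric ground truth is.
#'
#' @param n_res Residues per helix.
#' @param n_models Number of models in the ensemble.
#' @param model_rms Per-atom RMS displacement (Angstrom) of models 2..n
#'   relative to model 1.
#' @param ligand_center Ligand phosphorus position (length-3, Angstrom).
#' @param helix_sep Distance between the two helix axes (Angstrom).
#' @param n_waters_inside,n_waters_outside Water oxygens satisfying /
#'   violating both pocket criteria.
#' @param seed RNG seed.
#' @param path Optional path; when given the ensemble is written as a
#'   multi-model PDB file.
#' @return List with `ensemble` (a [structure_ensemble()]), and `truth`:
#'   `hf_distances` (per-residue minimum H-F distance in model 1),
#'   `fluorine_sites`, `z_bound_atoms`, `n_waters_inside`,
#'   `n_waters_outside`.
#' @export
gen_toy_complex <- function(n_res = 16, n_models = 1, model_rms = 0.5,
                            ligand_center = c(0, 0, 0), helix_sep = 16,
                            n_waters_inside = 0, n_waters_outside = 0,
                            seed = 1, path = NULL) {
  set.seed(seed)
  z_mid <- 1.5 * (n_res + 1) / 2
  a <- .helix_chain(n_res, "A")
  a$xyz <- sweep(a$xyz, 2, c(0, 0, z_mid), "-")
  a$xyz[, 1] <- a$xyz[, 1] - helix_sep / 2
  # chain B is chain A rotated 180 degrees about y: an antiparallel dimer
  # whose two-fold axis also maps the tetrahedral fluorine set onto itself
  b <- .helix_chain(n_res, "B")
  b$xyz <- sweep(b$xyz, 2, c(0, 0, z_mid), "-")
  b$xyz[, 1] <- -(b$xyz[, 1] - helix_sep / 2)
  b$xyz[, 3] <- -b$xyz[, 3]

  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  lig_at <- data.frame(chain = "L", resno = 1, resid = "TPP",
                       elety = c("P", paste0("C", 1:4), paste0("F", 1:4)),
                       elesy = c("P", rep("C", 4), rep("F", 4)),
                       stringsAsFactors = FALSE)
  lig_xyz <- rbind(c(0, 0, 0), 1.8 * tet, 5.7 * tet)
  lig_xyz <- sweep(lig_xyz, 2, ligand_center, "+")

  prot_xyz <- rbind(a$xyz, b$xyz)
  if (min(as.matrix(stats::dist(rbind(lig_xyz, prot_xyz)))[
        seq_len(nrow(lig_xyz)), -seq_len(nrow(lig_xyz))]) < 1.5) {
    stop("ligand placement clashes with the protein")
  }

  wat_at <- NULL; wat_xyz <- NULL
  z_top <- max(prot_xyz[, 3]); z_bot <- min(prot_xyz[, 3])
  if (n_waters_inside + n_waters_outside > 0) {
    inside <- t(vapply(seq_len(n_waters_inside), function(i) {
      repeat {
        p <- c(runif(2, -7, 7), runif(1, 0.7 * z_bot, 0.7 * z_top))
        d <- sqrt(colSums((t(lig_xyz) - p)^2))
        if (min(d) <= 14 && min(d) > 2) return(p)
      }
    }, numeric(3)))
    outside <- t(vapply(seq_len(n_waters_outside), function(i) {
      if (i %% 2 == 0) {             # violates the z window
        c(runif(2, -5, 5), z_top + runif(1, 5, 10))
      } else {                       # violates the distance cutoff
        c(25 + runif(1, 0, 5), runif(1, -5, 5), runif(1, 0.5 * z_bot, 0.5 * z_top))
      }
    }, numeric(3)))
    wat_xyz <- rbind(if (n_waters_inside) inside, if (n_waters_outside) outside)
    wat_at <- data.frame(chain = "W", resno = seq_len(nrow(wat_xyz)),
                         resid = "HOH", elety = "O", elesy = "O",
                         stringsAsFactors = FALSE)
  }

  atoms <- rbind(a$atoms, b$atoms, lig_at, wat_at)
  base <- rbind(a$xyz, b$xyz, lig_xyz, wat_xyz)
  coords <- array(NA_real_, c(nrow(base), 3, n_models))
  coords[, , 1] <- base
  if (n_models > 1) {
    for (m in 2:n_models) {
      coords[, , m] <- base + matrix(rnorm(length(base), 0,
                                           model_rms / sqrt(3)),
                                     ncol = 3)
    }
  }
  ens <- structure_ensemble(atoms, coords)

  # ground-truth minimum H-F distances in model 1
  hi <- which(atoms$elety == "H")
  fi <- which(atoms$elesy == "F")
  hf <- data.frame(chain = atoms$chain[hi], resno = atoms$resno[hi],
                   min_hf = vapply(hi, function(i) {
                     min(sqrt(colSums((t(base[fi, ]) - base[i, ])^2)))
                   }, numeric(1)))
  ca_a <- which(atoms$chain == "A" & atoms$elety == "CA")
  ca_b <- which(atoms$chain == "B" & atoms$elety == "CA")
  truth <- list(hf_distances = hf,
                fluorine_sites = paste0("L:1:F", 1:4),
                z_bound_atoms = c(
                  sprintf("A:%d:CA", atoms$resno[ca_a[which.min(base[ca_a, 3])]]),
                  sprintf("B:%d:CA", atoms$resno[ca_b[which.max(base[ca_b, 3])]])),
                n_waters_inside = n_waters_inside,
                n_waters_outside = n_waters_outside)

  if (!is.null(path)) write_pdb_ensemble(ens, path)
  list(ensemble = ens, truth = truth)
}

#' Generate a synthetic 4-site exchange dataset
#'
#' Builds normalized diagonal-decay and cross-peak-buildup intensities for
#' four exchanging sites from the single-exponential model (one rate per
#' originating site; all curves of a row share its rate and approach the
#' equilibrated plateau of 0.25), then adds Gaussian noise consistent with
#' the SNR error model: each point is shifted by N(0, eps/2) where eps is
#' its 2-sigma propagated error.  Default rates span 165 to 318 s^-1.
#'
#' @param rates Exchange rates (s^-1), one per site.
#' @param mixing_times Mixing times in seconds.
#' @param plateau Equilibrated intensity.
#' @param snr_peak,snr_norm SNR of each peak and of the row normalization.
#' @param noise Logical; FALSE returns noiseless model values.
#' @param seed RNG seed.
#' @return List with `mixing_times`, `intensities` (4 x 4 x n_times),
#'   `errors` (same shape, 2-sigma), and `truth` (rates, plateau).
#' @export
gen_exchange <- function(rates = c(165, 215, 265, 318),
                         mixing_times = c(0.1, 0.2, 0.5, 1, 2, 5, 10, 20,
                                          40, 60, 80) / 1000,
                         plateau = 0.25, snr_peak = 150, snr_norm = 300,
                         noise = TRUE, seed = 1) {
  stopifnot(length(rates) == 4, all(rates > 0))
  set.seed(seed)
  nt <- length(mixing_times)
  inten <- array(NA_real_, c(4, 4, nt))
  for (i in 1:4) {
    diag_i <- (1 - plateau) * exp(-rates[i] * mixing_times) + plateau
    cross_i <- plateau * (1 - exp(-rates[i] * mixing_times))
    for (k in seq_len(nt)) {
      inten[i, , k] <- cross_i[k]
      inten[i, i, k] <- diag_i[k]
    }
  }
  errors <- point_error(inten, snr_peak, snr_norm)
  if (noise) {
    inten <- inten + array(rnorm(length(inten), 0, 1), dim(inten)) * errors / 2
  }
  list(mixing_times = mixing_times, intensities = inten, errors = errors,
       truth = list(rates = rates, plateau = plateau))
}

#' Generate a synthetic saturation-recovery curve
#'
#' Single-exponential recovery I(t) = P (1 - exp(-R1 t)) with
#' SNR-consistent Gaussian noise, normalized to the per-site maximum as in
#' the measurement workflow.
#'
#' @param r1 True longitudinal relaxation rate (s^-1).
#' @param delays Relaxation delays in seconds.
#' @param plateau True plateau before normalization.
#' @param snr Signal-to-noise ratio of the detected peaks.
#' @param noise Logical; FALSE returns noiseless model values.
#' @param seed RNG seed.
#' @return List with `curve` (a [recovery_curve()]) and `truth`.
#' @export
gen_recovery <- function(r1 = 0.5, delays = c(0.05, 0.1, 0.25, 0.5, 1, 2, 4),
                         plateau = 1, snr = 100, noise = TRUE, seed = 1) {
  set.seed(seed)
  y <- plateau * (1 - exp(-r1 * delays))
  err <- 2 * y / snr
  if (noise) y <- y + rnorm(length(y), 0, 1) * err / 2
  m <- max(y)
  list(curve = recovery_curve(delays, y / m, errors = err / m),
       truth = list(r1 = r1, plateau = plateau))
}

#' Generate synthetic pH titration series
#'
#' Henderson-Hasselbalch shift curves for a set of residues sharing one
#' pKa (drawn uniformly from `pka_range` when `pka` is NULL), each with
#' its own endpoint shifts, plus Gaussian shift noise.  The default
#' emulates a titration of six residues near the protonation site read
#' out on the amide proton.
#'
#' @param n_series Number of residues.
#' @param pka Shared pKa; NULL draws one uniformly from `pka_range`.
#' @param pka_range Range for a drawn pKa.
#' @param nucleus "H" or "N"; sets realistic endpoint magnitudes (ppm).
#' @param pH Titration pH values.
#' @param noise_sd Gaussian shift noise (ppm).
#' @param seed RNG seed.
#' @return List with `series` (named list of data frames pH/shift) and
#'   `truth` (pka, endpoints).
#' @export
gen_titration <- function(n_series = 6, pka = NULL, pka_range = c(6, 8),
                          nucleus = c("H", "N"),
                          pH = c(5.0, 5.5, 6.0, 6.5, 7.0, 7.5, 8.0, 8.5),
                          noise_sd = 0.01, seed = 1) {
  nucleus <- match.arg(nucleus)
  set.seed(seed)
  if (is.null(pka)) pka <- runif(1, pka_range[1], pka_range[2])
  base <- if (nucleus == "H") runif(n_series, 7.5, 8.8)
          else runif(n_series, 110, 125)
  amp <- (if (nucleus == "H") runif(n_series, 0.15, 0.6)
          else runif(n_series, 0.8, 3)) * sample(c(-1, 1), n_series, TRUE)
  series <- lapply(seq_len(n_series), function(i) {
    data.frame(pH = pH,
               shift = hh_shift(pH, pka, base[i], base[i] + amp[i]) +
                 rnorm(length(pH), 0, noise_sd))
  })
  names(series) <- sprintf("res%02d", seq_len(n_series))
  list(series = series,
       truth = list(pka = pka,
                    endpoints = data.frame(series = names(series),
                                           delta_h = base,
                                           delta_d = base + amp)))
}
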