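# Shared readers/writers (TSV, PDB, JSON config) and the end-to-end
# pipeline driver.

#' Write REDOR curves to a TSV file
#'
#' Columns: site_id, mixing_time_s, s0, s, s_ratio, snr_s0, snr_s,
#' overlapped.  Curves carrying only S/S0 values leave s0/s/SNR as NA.
#'
#' @param curves List of [redor_curve()] objects.
#' @param path Output path.
#' @export
write_redor_curves <- function(curves, path) {
  rows <- lapply(curves, function(cv) {
    data.frame(site_id = cv$site_id, mixing_time_s = cv$mixing_times,
               s0 = NA_real_, s = NA_real_, s_ratio = cv$s_ratio,
               snr_s0 = NA_real_, snr_s = NA_real_,
               s_ratio_err = if (is.null(cv$s_ratio_err)) NA_real_
                             else cv$s_ratio_err,
               overlapped = cv$overlapped, stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read REDOR curves from a TSV file
#'
#' Accepts the format written by [write_redor_curves()].  When `s_ratio`
#' is absent it is computed as s/s0, and when SNR columns are present the
#' per-point error is propagated as
#' (S/S0) sqrt(SNR_S^-2 + SNR_S0^-2).
#'
#' @param path Input path.
#' @return List of [redor_curve()] objects.
#' @export
read_redor_curves <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!"s_ratio" %in% names(d) || all(is.na(d$s_ratio))) {
    d$s_ratio <- d$s / d$s0
  }
  if (!"s_ratio_err" %in% names(d)) d$s_ratio_err <- NA_real_
  need_err <- is.na(d$s_ratio_err)
  if ("snr_s" %in% names(d) && any(need_err & !is.na(d$snr_s))) {
    i <- need_err & !is.na(d$snr_s) & !is.na(d$snr_s0)
    d$s_ratio_err[i] <- d$s_ratio[i] * sqrt(1 / d$snr_s[i]^2 +
                                            1 / d$snr_s0[i]^2)
  }
  lapply(split(d, factor(d$site_id, levels = unique(d$site_id))),
         function(g) {
           err <- if (all(is.na(g$s_ratio_err))) NULL else g$s_ratio_err
           redor_curve(g$site_id[1], g$mixing_time_s, g$s_ratio,
                       s_ratio_err = err,
                       overlapped = isTRUE(as.logical(g$overlapped[1])))
         })
}

#' Write distance restraints to a TSV file
#'
#' @param restraints List of [ambiguous_restraint()] objects.
#' @param path Output path.
#' @export
write_restraints_tsv <- function(restraints, path) {
  rows <- lapply(restraints, function(r) {
    data.frame(proton = r$proton_site,
               f1 = r$fluorine_sites[1], f2 = r$fluorine_sites[2],
               f3 = r$fluorine_sites[3], f4 = r$fluorine_sites[4],
               kind = r$kind,
               target = if (is.null(r$target)) NA_real_ else r$target,
               lower = r$lower, upper = r$upper,
               assigned = if (is.null(r$assigned_fluorine)) NA_character_
                          else r$assigned_fluorine,
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read distance restraints from a TSV file
#'
#' @param path Input path (format of [write_restraints_tsv()]).
#' @return List of [ambiguous_restraint()] objects.
#' @export
read_restraints_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(d)), function(i) {
    ambiguous_restraint(
      d$proton[i], c(d$f1[i], d$f2[i], d$f3[i], d$f4[i]), kind = d$kind[i],
      target = if (is.na(d$target[i])) NULL else d$target[i],
      lower = d$lower[i], upper = d$upper[i],
      assigned_fluorine = if (is.na(d$assigned[i])) NULL else d$assigned[i])
  })
}

#' Export restraints as a piecewise-linear restraint table
#'
#' Generic distance-restraint table for MD refinement with time-averaged
#' restraints: one row per proton-fluorine pair (all four pairs for still-
#' ambiguous restraints) with r0 (lower bound), r1 (upper bound; the
#' restoring force is proportional to the excess distance between r1 and
#' r2) and r2 = r1 + `r2_pad`.
#'
#' @param restraints List of [ambiguous_restraint()] objects.
#' @param path Output path.
#' @param r2_pad Width (Angstrom) of the linear-force region beyond r1.
#' @export
export_restraint_table <- function(restraints, path, r2_pad = 1) {
  rows <- lapply(restraints, function(r) {
    fl <- if (is.null(r$assigned_fluorine)) r$fluorine_sites
          else r$assigned_fluorine
    data.frame(proton = r$proton_site, fluorine = fl, r0 = r$lower,
               r1 = r$upper, r2 = r$upper + r2_pad,
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a structure ensemble as a multi-model PDB file
#'
#' Emits MODEL/ENDMDL blocks with ATOM records for protein chains and
#' HETATM records for ligand and water residues.
#'
#' @param ens A [structure_ensemble()].
#' @param path Output path.
#' @export
write_pdb_ensemble <- function(ens, path) {
  stopifnot(inherits(ens, "structure_ensemble"))
  at <- ens$atoms
  het <- at$resid %in% c("TPP", "HOH", "WAT", "TIP3", "SOL") |
    !(at$chain %in% unique(at$chain[at$elety == "CA"]))
  rec <- ifelse(het, "HETATM", "ATOM  ")
  name4 <- ifelse(nchar(at$elety) < 4, sprintf(" %-3s", at$elety),
                  at$elety)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(ens$n_models)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- ens$coords[, , m]
    writeLines(sprintf("%s%5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       rec, seq_len(nrow(at)), name4, at$resid, at$chain,
                       at$resno, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
                       toupper(at$elesy)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write / read a long-format exchange TSV
#'
#' Columns: mixing_time_s, peak_from, peak_to, volume, snr.
#'
#' @param mixing_times Mixing times (s).
#' @param intensities 4 x 4 x n_times volume array.
#' @param snr Scalar or array of peak SNRs.
#' @param path File path.
#' @export
write_exchange_tsv <- function(mixing_times, intensities, snr, path) {
  nt <- length(mixing_times)
  if (length(snr) == 1) snr <- array(snr, dim(intensities))
  rows <- expand.grid(peak_from = 1:4, peak_to = 1:4, t = seq_len(nt))
  d <- data.frame(mixing_time_s = mixing_times[rows$t],
                  peak_from = rows$peak_from, peak_to = rows$peak_to,
                  volume = intensities[cbind(rows$peak_from, rows$peak_to,
                                             rows$t)],
                  snr = snr[cbind(rows$peak_from, rows$peak_to, rows$t)])
  d <- d[order(d$mixing_time_s, d$peak_from, d$peak_to), ]
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_exchange_tsv
#' @return `read_exchange_tsv`: list with `mixing_times`, `intensities`
#'   (4 x 4 x n_times) and `snr` (same shape).
#' @export
read_exchange_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  times <- sort(unique(d$mixing_time_s))
  nt <- length(times)
  vol <- array(NA_real_, c(4, 4, nt))
  snr <- array(NA_real_, c(4, 4, nt))
  k <- match(d$mixing_time_s, times)
  vol[cbind(d$peak_from, d$peak_to, k)] <- d$volume
  snr[cbind(d$peak_from, d$peak_to, k)] <- d$snr
  list(mixing_times = times, intensities = vol, snr = snr)
}

#' Read a pipeline configuration from JSON
#'
#' Validates the schema: known top-level keys are `seed`, `redor`,
#' `files`, `scoring`; unknown keys are rejected.  Quantities carry
#' explicit units in their key names (`_s`, `_hz`, `_ppm`, `_angstrom`).
#'
#' @param path Path to a JSON config.
#' @return Named list of configuration values.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("seed", "redor", "files", "scoring")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0) {
    stop("unknown config keys: ", paste(extra, collapse = ", "))
  }
  known_redor <- c("mas_hz", "mixing_times_s", "pulse_length_s",
                   "csa_span_ppm", "csa_asymmetry", "larmor_deph_hz",
                   "n_orient", "n_gamma", "n_steps",
                   "distance_grid_angstrom")
  extra <- setdiff(names(cfg$redor), known_redor)
  if (length(extra) > 0) {
    stop("unknown redor config keys: ", paste(extra, collapse = ", "))
  }
  cfg
}

.config_redor_params <- function(cfg) {
  rd <- cfg$redor
  get <- function(nm, def) if (is.null(rd[[nm]])) def else rd[[nm]]
  redor_params(
    mas_hz = get("mas_hz", 38000),
    mixing_times = get("mixing_times_s", c(64, 96, 144) / 38000),
    pulse_length_deph = get("pulse_length_s", 6e-6),
    csa_span_ppm = get("csa_span_ppm", 60),
    csa_asymmetry = get("csa_asymmetry", 1),
    larmor_deph_hz = get("larmor_deph_hz", 564.6e6),
    n_orient = get("n_orient", 320),
    n_gamma = get("n_gamma", 32),
    n_steps = get("n_steps", 256))
}

#' Run the full analysis pipeline
#'
#' Chains the stages: read measured REDOR curves, build (or load) the
#' simulated curve library, fit distances, build ambiguous restraints,
#' score the structural ensemble, disambiguate against the best-scoring
#' model, compute ensemble statistics, and write all result tables plus a
#' provenance record (package version, seed, input hashes).  The run is
#' deterministic given the config, so a rerun produces identical outputs.
#'
#' Curve `site_id`s must be valid single-atom selectors
#' (`chain:resno:atom`) resolving to the amide protons in the structure.
#'
#' @param config A config list from [read_pipeline_config()] or a path to
#'   a JSON config.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the fits, restraints, scoring report and
#'   ensemble statistics.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  for (f in c("curves_tsv", "structure_pdb")) {
    if (is.null(cfg$files[[f]])) stop("config is missing files$", f)
    if (!file.exists(cfg$files[[f]])) {
      stop("input file not found: ", cfg$files[[f]])
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  curves <- read_redor_curves(cfg$files$curves_tsv)
  if (length(curves) == 0) stop("no curves found in ", cfg$files$curves_tsv)
  params <- .config_redor_params(cfg)
  grid_spec <- cfg$redor$distance_grid_angstrom
  grid <- if (is.null(grid_spec)) seq(3, 15, by = 0.1)
          else seq(grid_spec[1], grid_spec[2], by = grid_spec[3])
  lib <- build_curve_library(params, grid,
                             cache_file = cfg$files$library_cache)

  thr <- if (is.null(cfg$scoring$rmsd_threshold)) 0.2
         else cfg$scoring$rmsd_threshold
  fits <- lapply(curves, fit_distance, library = lib, rmsd_threshold = thr)

  fl <- cfg$files$fluorine_sites
  if (is.null(fl)) stop("config is missing files$fluorine_sites")
  proton_sites <- setNames(vapply(fits, `[[`, character(1), "site_id"),
                           vapply(fits, `[[`, character(1), "site_id"))
  restraints <- build_restraints(fits, as.list(proton_sites), fl)

  ens <- read_structure_ensemble(cfg$files$structure_pdb)
  sc <- score_structures(ens, restraints)
  best <- get_model(ens, sc$ranking_sum[1])
  restraints <- disambiguate(restraints, best)

  stats <- list(
    backbone_rmsd = if (ens$n_models > 1) pairwise_rmsd(ens, "backbone")[c("mean", "sd")]
                    else NULL)

  fit_df <- do.call(rbind, lapply(fits, function(f) {
    data.frame(site_id = f$site_id, best_distance = f$best_distance,
               lower = f$lower, upper = f$upper,
               lower_bound_only = f$is_lower_bound_only)
  }))
  write.table(fit_df, file.path(out_dir, "fits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_restraints_tsv(restraints, file.path(out_dir, "restraints.tsv"))
  write.table(sc$reports, file.path(out_dir, "violations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  prov <- list(package = "redorlab",
               version = as.character(utils::packageVersion("redorlab")),
               seed = cfg$seed,
               inputs = as.list(tools::md5sum(c(cfg$files$curves_tsv,
                                                cfg$files$structure_pdb))))
  jsonlite::write_json(c(prov, list(ensemble = stats)),
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(fits = fits, restraints = restraints, scores = sc,
                 ensemble_stats = stats))
}
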