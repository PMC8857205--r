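# Four-fold-ambiguous proton-fluorine distance restraints, structure
# scoring by violation statistics, and restraint disambiguation.

#' Ambiguous proton-fluorine distance restraint
#'
#' A restraint between one amide (or indole) proton and the four
#' chemically equivalent fluorines of a tetrahedral fluorinated ligand.
#' `kind = "measured"` restraints carry a target distance with bounds from
#' the REDOR fit; `kind = "lower_bound"` restraints encode sites with no
#' observable dephasing, which must be at least `lower` (10 Angstrom by
#' default) from the fluorines.
#'
#' @param proton_site Single-atom selector string `chain:resno:atom`.
#' @param fluorine_sites Character vector of exactly four selectors.
#' @param kind "measured" or "lower_bound".
#' @param target Target distance (Angstrom) or NULL for lower bounds.
#' @param lower,upper Distance bounds in Angstrom.
#' @param assigned_fluorine Optional single selector once disambiguated.
#' @return An object of class `ambiguous_restraint`.
#' @export
ambiguous_restraint <- function(proton_site, fluorine_sites,
                                kind = c("measured", "lower_bound"),
                                target = NULL, lower, upper,
                                assigned_fluorine = NULL) {
  kind <- match.arg(kind)
  if (length(fluorine_sites) != 4) {
    stop("'fluorine_sites' must contain exactly four selectors")
  }
  if (lower > upper) stop("'lower' must be <= 'upper'")
  if (kind == "lower_bound" && !is.null(target)) {
    stop("lower-bound restraints carry no target distance")
  }
  if (!is.null(assigned_fluorine) &&
      !assigned_fluorine %in% fluorine_sites) {
    stop("'assigned_fluorine' must be one of 'fluorine_sites'")
  }
  structure(list(proton_site = proton_site,
                 fluorine_sites = fluorine_sites, kind = kind,
                 target = target, lower = lower, upper = upper,
                 assigned_fluorine = assigned_fluorine),
            class = "ambiguous_restraint")
}

#' @export
print.ambiguous_restraint <- function(x, ...) {
  cat(sprintf("%s restraint %s -> %s [%g, %g] A\n", x$kind, x$proton_site,
              if (is.null(x$assigned_fluorine)) "4F (ambiguous)"
              else x$assigned_fluorine,
              x$lower, x$upper))
  invisible(x)
}

.resolve_atom <- function(model, sel) {
  idx <- tryCatch(atom_select(model, sel),
                  error = function(e) stop("atom '", sel, "' not found in model",
                                           call. = FALSE))
  if (length(idx) != 1) stop("selector '", sel, "' is not a single atom")
  model$xyz[idx, ]
}

#' Effective distance of an ambiguous restraint in a model
#'
#' The minimum over the four proton-fluorine Euclidean distances, or the
#' single assigned pair's distance once disambiguated.
#'
#' @param model A model from [get_model()].
#' @param r An [ambiguous_restraint()].
#' @return Distance in Angstrom.
#' @export
effective_distance <- function(model, r) {
  stopifnot(inherits(r, "ambiguous_restraint"))
  h <- .resolve_atom(model, r$proton_site)
  if (!is.null(r$assigned_fluorine)) {
    f <- .resolve_atom(model, r$assigned_fluorine)
    return(sqrt(sum((h - f)^2)))
  }
  min(vapply(r$fluorine_sites,
             function(s) sqrt(sum((h - .resolve_atom(model, s))^2)),
             numeric(1)))
}

#' Restraint violation in a model
#'
#' Measured restraints: the shortfall of the effective (minimum or
#' assigned) distance outside the `[lower, upper]` interval.  Lower-bound
#' restraints: each fluorine must individually satisfy the bound; the
#' violation is the summed shortfall over the four fluorines (or the
#' single assigned pair).
#'
#' @param model A model from [get_model()].
#' @param r An [ambiguous_restraint()].
#' @return Non-negative violation in Angstrom (0 when satisfied).
#' @export
violation <- function(model, r) {
  stopifnot(inherits(r, "ambiguous_restraint"))
  if (r$kind == "measured") {
    d <- effective_distance(model, r)
    return(max(0, d - r$upper) + max(0, r$lower - d))
  }
  h <- .resolve_atom(model, r$proton_site)
  fl <- if (is.null(r$assigned_fluorine)) r$fluorine_sites
        else r$assigned_fluorine
  sum(vapply(fl, function(s) {
    d <- sqrt(sum((h - .resolve_atom(model, s))^2))
    max(0, r$lower - d)
  }, numeric(1)))
}

#' Score an ensemble of structures against a restraint set
#'
#' Evaluates every restraint in every model and produces per-model
#' violation reports plus two rankings: by the lowest sum-total of
#' violations and by the least number of violated restraints (ties broken
#' by the violation sum, then by input order).
#'
#' @param ens A [structure_ensemble()].
#' @param restraints List of [ambiguous_restraint()] objects.
#' @return List with `reports` (data frame: model, sum_violation,
#'   n_violations), `per_restraint` (models x restraints matrix),
#'   `ranking_sum` and `ranking_count` (model index orderings).
#' @export
score_structures <- function(ens, restraints) {
  stopifnot(inherits(ens, "structure_ensemble"))
  if (length(restraints) == 0) stop("no restraints supplied")
  n <- ens$n_models
  per <- matrix(0, n, length(restraints))
  for (m in seq_len(n)) {
    mod <- get_model(ens, m)
    per[m, ] <- vapply(restraints, function(r) violation(mod, r), numeric(1))
  }
  reports <- data.frame(model = seq_len(n),
                        sum_violation = rowSums(per),
                        n_violations = rowSums(per > 0))
  list(reports = reports,
       per_restraint = per,
       ranking_sum = order(reports$sum_violation),
       ranking_count = order(reports$n_violations, reports$sum_violation))
}

#' Build restraints from REDOR distance fits
#'
#' Measured fits yield one four-fold ambiguous restraint each with bounds
#' from the fit's RMSD-threshold interval.  Lower-bound fits (no
#' observable dephasing) expand to four single-pair restraints, one per
#' fluorine, each requiring that fluorine to be at least `lb_lower`
#' (10 Angstrom) from the proton -- so the restraint count follows
#' 4 x (number of weak fits) + (number of measured fits).
#'
#' @param fits List of [fit_distance()] results.
#' @param proton_sites Named character vector mapping each fit's `site_id`
#'   to a proton selector.
#' @param fluorine_sites Character vector of the four fluorine selectors.
#' @return List of [ambiguous_restraint()] objects.
#' @export
build_restraints <- function(fits, proton_sites, fluorine_sites) {
  out <- list()
  for (f in fits) {
    ps <- proton_sites[[f$site_id]]
    if (is.null(ps)) stop("no proton site mapped for '", f$site_id, "'")
    if (f$is_lower_bound_only) {
      for (fs in fluorine_sites) {
        out[[length(out) + 1]] <- ambiguous_restraint(
          ps, fluorine_sites, kind = "lower_bound",
          lower = f$lower, upper = f$upper, assigned_fluorine = fs)
      }
    } else {
      out[[length(out) + 1]] <- ambiguous_restraint(
        ps, fluorine_sites, kind = "measured", target = f$best_distance,
        lower = f$lower, upper = f$upper)
    }
  }
  out
}

#' Disambiguate measured restraints against a reference model
#'
#' Assigns each measured, still-ambiguous restraint to the fluorine
#' nearest its proton in the reference model.  An exact distance tie
#' (within `tol`) leaves the restraint ambiguous with a warning.
#' Assignment to the minimizing fluorine never increases a restraint's
#' violation in the reference model.
#'
#' @param restraints List of [ambiguous_restraint()] objects.
#' @param reference_model A model from [get_model()].
#' @param tol Distance tie tolerance in Angstrom.
#' @return The restraint list with `assigned_fluorine` filled in.
#' @export
disambiguate <- function(restraints, reference_model, tol = 1e-6) {
  lapply(restraints, function(r) {
    if (r$kind != "measured" || !is.null(r$assigned_fluorine)) return(r)
    h <- .resolve_atom(reference_model, r$proton_site)
    d <- vapply(r$fluorine_sites,
                function(s) sqrt(sum((h - .resolve_atom(reference_model, s))^2)),
                numeric(1))
    ds <- sort(d)
    if (ds[2] - ds[1] < tol) {
      warning("distance tie for ", r$proton_site, "; kept ambiguous")
      return(r)
    }
    r$assigned_fluorine <- r$fluorine_sites[which.min(d)]
    r
  })
}
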