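# Structural-ensemble statistics: pairwise RMSD, ensemble-averaged
# distances, binding-pocket water counts.

#' Average pairwise RMSD over an ensemble
#'
#' Superposes every pair of models and reports the mean and standard
#' deviation of the post-fit RMSD over all C(n, 2) pairs.  By default each
#' pair is superposed on the same selection that is being measured; pass
#' `superpose_on` to fit on one selection (e.g. the backbone) and measure
#' the RMSD on another.
#'
#' @param ens A [structure_ensemble()] with >= 2 models.
#' @param selection Selection measured (and, by default, fitted).
#' @param superpose_on Optional separate selection used for the fit.
#' @return List with `mean`, `sd`, and the per-pair `values`.
#' @export
pairwise_rmsd <- function(ens, selection = "backbone", superpose_on = NULL) {
  stopifnot(inherits(ens, "structure_ensemble"))
  n <- ens$n_models
  if (n < 2) stop("need at least 2 models")
  vals <- numeric(0)
  for (i in seq_len(n - 1)) {
    mi <- get_model(ens, i)
    for (j in seq(i + 1, n)) {
      mj <- get_model(ens, j)
      if (is.null(superpose_on)) {
        vals <- c(vals, superpose(mi, mj, selection)$rmsd)
      } else {
        fit <- superpose(mi, mj, superpose_on)
        idx <- atom_select(ens, selection)
        moved <- mj$xyz[idx, , drop = FALSE] %*% fit$rotation
        moved <- sweep(moved, 2, fit$translation, "+")
        vals <- c(vals, sqrt(mean(rowSums(
          (moved - mi$xyz[idx, , drop = FALSE])^2))))
      }
    }
  }
  list(mean = mean(vals), sd = sd(vals), values = vals)
}

#' Ensemble-averaged inter-atomic distance
#'
#' Computes a per-model distance and reports its mean and standard
#' deviation across models.  With `reducer = "pair"` both selections must
#' resolve to single atoms and the Euclidean distance is used; with
#' `reducer = "min_over_b"` the first selection is a single atom and the
#' minimum distance to any atom of the second selection is taken (e.g. the
#' nearest of four chemically equivalent fluorines).
#'
#' @param ens A [structure_ensemble()].
#' @param sel_a,sel_b Selection strings (see [atom_select()]).
#' @param reducer "pair" or "min_over_b".
#' @return List with `mean`, `sd` and per-model `values` (Angstrom).
#' @export
ensemble_distance <- function(ens, sel_a, sel_b,
                              reducer = c("pair", "min_over_b")) {
  stopifnot(inherits(ens, "structure_ensemble"))
  reducer <- match.arg(reducer)
  ia <- atom_select(ens, sel_a)
  ib <- atom_select(ens, sel_b)
  if (length(ia) != 1) stop("'sel_a' must resolve to a single atom")
  if (reducer == "pair" && length(ib) != 1) {
    stop("'sel_b' must resolve to a single atom for reducer = 'pair'")
  }
  vals <- vapply(seq_len(ens$n_models), function(m) {
    xyz <- ens$coords[, , m]
    d <- sqrt(colSums((t(xyz[ib, , drop = FALSE]) - xyz[ia, ])^2))
    min(d)
  }, numeric(1))
  list(mean = mean(vals), sd = if (length(vals) > 1) sd(vals) else 0,
       values = vals)
}

#' Count water molecules in the ligand-binding pocket
#'
#' A water molecule is counted when its oxygen atom lies within `cutoff`
#' of any ligand atom and its z coordinate lies between the z coordinates
#' of two boundary atoms (the top and bottom planes of the transmembrane
#' helical bundle; the pair is order-normalized).  The structure is
#' assumed already aligned with z along the membrane normal.
#'
#' @param model A single model from [get_model()].
#' @param ligand_sel Selection string for the ligand atoms.
#' @param cutoff Distance cutoff in Angstrom (default 15).
#' @param z_bound_atoms Character vector of two single-atom selections
#'   defining the z window.
#' @param water_resid Residue names recognized as water.
#' @return Integer count of pocket waters.
#' @export
count_pocket_waters <- function(model, ligand_sel, cutoff = 15,
                                z_bound_atoms,
                                water_resid = c("HOH", "WAT", "TIP3", "SOL")) {
  at <- model$atoms
  il <- atom_select(model, ligand_sel)
  zb <- vapply(z_bound_atoms, function(s) {
    i <- atom_select(model, s)
    if (length(i) != 1) stop("z-bound selection '", s, "' is not one atom")
    model$xyz[i, 3]
  }, numeric(1))
  zlo <- min(zb); zhi <- max(zb)
  iw <- which(at$resid %in% water_resid & toupper(at$elesy) == "O")
  if (length(iw) == 0) return(0L)
  lig <- model$xyz[il, , drop = FALSE]
  ok <- vapply(iw, function(i) {
    w <- model$xyz[i, ]
    if (w[3] < zlo || w[3] > zhi) return(FALSE)
    min(sqrt(colSums((t(lig) - w)^2))) <= cutoff
  }, logical(1))
  sum(ok)
}
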