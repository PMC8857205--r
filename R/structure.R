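# Multi-model structure handling: reading, atom selection, superposition.

#' Structural ensemble container
#'
#' An ordered set of atomic models sharing one atom table.  `atoms` is a
#' data frame with columns `chain`, `resno`, `resid`, `elety` (atom name)
#' and `elesy` (element symbol); `coords` is a numeric array of dimension
#' (n_atoms, 3, n_models) in Angstrom.
#'
#' @param atoms Atom table (see Details).
#' @param coords Coordinate array (n_atoms x 3 x n_models).
#' @return An object of class `structure_ensemble`.
#' @export
structure_ensemble <- function(atoms, coords) {
  req <- c("chain", "resno", "resid", "elety", "elesy")
  if (!all(req %in% names(atoms))) {
    stop("'atoms' must have columns ", paste(req, collapse = ", "))
  }
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1))
  if (dim(coords)[1] != nrow(atoms) || dim(coords)[2] != 3) {
    stop("'coords' must be (n_atoms x 3 x n_models)")
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  structure(list(atoms = atoms, coords = coords,
                 n_models = dim(coords)[3]),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat("Structure ensemble:", x$n_models, "models,", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chains\n")
  invisible(x)
}

#' Read a multi-model PDB file into a structure ensemble
#'
#' Parses MODEL/ENDMDL records via `bio3d::read.pdb`.  Alternate locations
#' other than blank or "A" are dropped (altloc A preferred); insertion
#' codes are rejected with an error.
#'
#' @param path Path to a PDB file.
#' @return A [structure_ensemble()].
#' @export
read_structure_ensemble <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  if (any(!is.na(at$insert) & at$insert != "")) {
    stop("insertion codes are not supported")
  }
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep, , drop = FALSE]
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)
  idx <- rep(which(keep), each = 3) * 3 + c(-2, -1, 0)
  coords <- array(NA_real_, c(nrow(at), 3, n_models))
  for (m in seq_len(n_models)) {
    coords[, , m] <- matrix(xyz[m, idx], ncol = 3, byrow = TRUE)
  }
  elesy <- at$elesy
  if (is.null(elesy) || all(is.na(elesy)) || all(elesy == "")) {
    elesy <- substr(gsub("[0-9]", "", at$elety), 1, 1)
  }
  structure_ensemble(
    atoms = data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                       elety = at$elety, elesy = elesy,
                       stringsAsFactors = FALSE),
    coords = coords)
}

#' Extract one model from an ensemble
#'
#' @param ens A [structure_ensemble()].
#' @param i Model index.
#' @return A list with `atoms` and an (n_atoms x 3) coordinate matrix `xyz`.
#' @export
get_model <- function(ens, i) {
  stopifnot(inherits(ens, "structure_ensemble"))
  if (i < 1 || i > ens$n_models) stop("model index out of range")
  list(atoms = ens$atoms, xyz = ens$coords[, , i, drop = TRUE])
}

#' Select atoms by preset or mini-grammar
#'
#' Resolves an atom selection to integer indices into the ensemble's atom
#' table.  `spec` is either a preset name -- `"backbone"` (N, CA, C, O),
#' `"heavy"` (all non-hydrogen), `"ligand_center"` (the ligand phosphorus
#' and the four carbons directly bonded to it) -- or a string in the
#' grammar `chain:resrange:atoms`, e.g. `"A:10-20:N,CA,C,O"`,
#' `"B:63:HE1"`, `"*:*:CA"`.  `*` matches anything; resrange may be a
#' single number, a `lo-hi` range, or a comma list.
#'
#' @param x A [structure_ensemble()] or a single model from [get_model()].
#' @param spec Selection string.
#' @return Integer vector of atom indices (error if empty).
#' @export
atom_select <- function(x, spec) {
  at <- x$atoms
  idx <- switch(spec,
    backbone = which(at$elety %in% c("N", "CA", "C", "O")),
    heavy = which(toupper(at$elesy) != "H"),
    ligand_center = .ligand_center_idx(x),
    .parse_selection(at, spec))
  if (length(idx) == 0) stop("selection '", spec, "' matches no atoms")
  idx
}

.parse_selection <- function(at, spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3) {
    stop("selection '", spec, "' is not 'chain:resrange:atoms'")
  }
  keep <- rep(TRUE, nrow(at))
  if (parts[1] != "*") {
    keep <- keep & at$chain %in% strsplit(parts[1], ",")[[1]]
  }
  if (parts[2] != "*") {
    res <- unlist(lapply(strsplit(parts[2], ",")[[1]], function(tok) {
      if (grepl("-", tok)) {
        rng <- as.integer(strsplit(tok, "-")[[1]])
        seq(rng[1], rng[2])
      } else as.integer(tok)
    }))
    keep <- keep & at$resno %in% res
  }
  if (parts[3] != "*") {
    keep <- keep & at$elety %in% strsplit(parts[3], ",")[[1]]
  }
  which(keep)
}

# ligand center: phosphorus plus its four directly bonded carbons
.ligand_center_idx <- function(x) {
  at <- x$atoms
  xyz <- if (inherits(x, "structure_ensemble")) x$coords[, , 1] else x$xyz
  p <- which(toupper(at$elesy) == "P")
  if (length(p) != 1) stop("ligand_center needs exactly one phosphorus atom")
  carb <- which(toupper(at$elesy) == "C")
  d <- sqrt(colSums((t(xyz[carb, , drop = FALSE]) - xyz[p, ])^2))
  bonded <- carb[d < 2.0]
  if (length(bonded) != 4) {
    stop("expected 4 carbons bonded to P, found ", length(bonded))
  }
  c(p, bonded)
}

#' Least-squares superposition of two models
#'
#' Kabsch algorithm: finds the rigid rotation and translation that
#' minimize the RMSD between the selected atoms of two models, via SVD of
#' the covariance matrix with a determinant correction that excludes
#' reflections.
#'
#' @param model_a,model_b Models from [get_model()] (b is fitted onto a).
#' @param selection Selection string (see [atom_select()]) defining the
#'   atoms used for the fit; needs >= 3 non-collinear atoms.
#' @return List with `rotation` (3 x 3), `translation` (length 3; the
#'   fitted coordinates are `xyz_b %*% rotation + translation`), and the
#'   post-fit `rmsd` in Angstrom.
#' @export
superpose <- function(model_a, model_b, selection = "backbone") {
  ia <- atom_select(model_a, selection)
  ib <- atom_select(model_b, selection)
  if (length(ia) != length(ib)) stop("selections differ in size")
  if (length(ia) < 3) stop("need at least 3 atoms to superpose")
  A <- model_a$xyz[ia, , drop = FALSE]
  B <- model_b$xyz[ib, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  if (any(svd(A0)$d < 1e-8 * max(svd(A0)$d))) {
    stop("degenerate (collinear) selection")
  }
  H <- t(B0) %*% A0
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- B0 %*% R
  rmsd <- sqrt(mean(rowSums((fitted - A0)^2)))
  list(rotation = R, translation = ca - as.numeric(cb %*% R), rmsd = rmsd)
}
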