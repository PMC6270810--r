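# CoMFA descriptors: steric and electrostatic probe energies on a lattice,
# truncation, excluded-point handling, column filtering and block scaling.

#' Lattice specification
#'
#' @param origin Numeric length-3, Angstrom.
#' @param spacing Positive lattice spacing, Angstrom.
#' @param dims Integer length-3 point counts (nx, ny, nz), each >= 1.
#' @return Object of class `grid_spec`.
#' @export
grid_spec <- function(origin, spacing, dims) {
  stopifnot(length(origin) == 3, length(dims) == 3)
  if (spacing <= 0) stop("spacing must be > 0")
  if (any(dims < 1)) stop("each grid dimension needs >= 1 point")
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dims = as.integer(dims)), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid %dx%dx%d, spacing %.2f A, origin (%.2f, %.2f, %.2f)>\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Lattice point coordinates
#'
#' Points are ordered with x varying fastest, then y, then z.
#'
#' @param grid A [grid_spec].
#' @return Matrix (n_points x 3) of coordinates, Angstrom.
#' @export
grid_points <- function(grid) {
  ax <- lapply(1:3, function(k)
    grid$origin[k] + grid$spacing * (seq_len(grid$dims[k]) - 1))
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                               KEEP.OUT.ATTRS = FALSE))
  dimnames(pts) <- NULL
  pts
}

#' Build a lattice enclosing a set of aligned molecules
#'
#' The union bounding box of all atoms is padded by `margin` on every side
#' and snapped outward to whole multiples of `spacing`, so the grid is
#' translation-equivariant with the molecule set.
#'
#' @param mols List of [molecule] objects (aligned).
#' @param spacing Lattice spacing, Angstrom (default 2).
#' @param margin Clearance beyond the bounding box, Angstrom (default 4).
#' @return A [grid_spec].
#' @export
make_grid <- function(mols, spacing = 2, margin = 4) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  if (!length(mols)) stop("need at least one molecule")
  all_xyz <- do.call(rbind, lapply(mols, coords))
  lo <- apply(all_xyz, 2, min) - margin
  hi <- apply(all_xyz, 2, max) + margin
  origin <- floor(lo / spacing) * spacing
  dims <- ceiling((hi - origin) / spacing) + 1L
  grid_spec(origin, spacing, dims)
}

#' Probe-atom specification
#'
#' Defaults are the CoMFA convention: an sp3-carbon probe carrying a +1
#' elementary charge.
#'
#' @param vdw_radius Probe van der Waals radius, Angstrom (default 1.70).
#' @param vdw_epsilon Probe well depth, kcal/mol (default 0.107).
#' @param charge Probe charge, e (default +1).
#' @return Object of class `probe_spec`.
#' @export
probe_spec <- function(vdw_radius = 1.70, vdw_epsilon = 0.107, charge = 1.0) {
  if (vdw_radius <= 0) stop("probe radius must be > 0")
  if (vdw_epsilon < 0) stop("probe epsilon must be >= 0")
  structure(list(vdw_radius = vdw_radius, vdw_epsilon = vdw_epsilon,
                 charge = charge), class = "probe_spec")
}

point_atom_dist <- function(points, mol) {
  xyz <- coords(mol)
  # n_points x n_atoms distance matrix
  px2 <- rowSums(points^2); ax2 <- rowSums(xyz^2)
  d2 <- outer(px2, ax2, `+`) - 2 * points %*% t(xyz)
  sqrt(pmax(d2, 1e-12))
}

#' Steric (Lennard-Jones) probe energy at lattice points
#'
#' Sum over atoms of eps_ij ((r*_ij/d)^12 - 2 (r*_ij/d)^6) with
#' eps_ij = sqrt(probe eps x atom eps) and r*_ij = probe radius + atom
#' radius, clamped from above at `cap`.
#'
#' @param points Matrix (n x 3) of probe positions, Angstrom.
#' @param mol A [molecule] with van der Waals parameters assigned.
#' @param probe A [probe_spec()].
#' @param cap Truncation, kcal/mol (default 30).
#' @return Numeric vector of energies, kcal/mol.
#' @export
steric_energy <- function(points, mol, probe = probe_spec(), cap = 30) {
  if (anyNA(mol$atoms$vdw_radius)) stop("assign van der Waals parameters first")
  points <- matrix(points, ncol = 3)
  d <- point_atom_dist(points, mol)
  rstar <- matrix(probe$vdw_radius + mol$atoms$vdw_radius,
                  nrow(points), nrow(mol$atoms), byrow = TRUE)
  eps <- matrix(sqrt(probe$vdw_epsilon * mol$atoms$vdw_epsilon),
                nrow(points), nrow(mol$atoms), byrow = TRUE)
  sr6 <- (rstar / d)^6
  pmin(rowSums(eps * (sr6^2 - 2 * sr6)), cap)
}

#' Electrostatic (Coulomb) probe energy at lattice points
#'
#' Sum over atoms of 332.0 q_i q_probe / (D d) with the distance-dependent
#' dielectric D = d, i.e. proportional to 1/d^2; clamped to [-cap, cap].
#'
#' @inheritParams steric_energy
#' @param coulomb_const Conversion constant, kcal A/(mol e^2) (default 332).
#' @return Numeric vector of energies, kcal/mol.
#' @export
electrostatic_energy <- function(points, mol, probe = probe_spec(), cap = 30,
                                 coulomb_const = 332.0) {
  points <- matrix(points, ncol = 3)
  d <- point_atom_dist(points, mol)
  e <- rowSums(coulomb_const * probe$charge *
               matrix(mol$atoms$charge, nrow(points), nrow(mol$atoms),
                      byrow = TRUE) / d^2)
  pmin(pmax(e, -cap), cap)
}

#' Build the molecules x lattice descriptor block
#'
#' Evaluates the steric and electrostatic field of every molecule at every
#' lattice point. Lattice points where a molecule's steric energy reaches
#' the cap are "excluded" for that molecule: the electrostatic value there
#' is replaced by the column mean over non-excluded molecules (0 when every
#' molecule is excluded). Columns whose standard deviation falls below
#' `filter_sigma` (kcal/mol) are masked out; block weights are the inverse
#' of each block's overall standard deviation over retained entries
#' (CoMFA-standard block scaling).
#'
#' @param mols List of aligned [molecule] objects.
#' @param grid A [grid_spec] (default [make_grid()] of `mols`).
#' @param probe A [probe_spec()].
#' @param cap Truncation, kcal/mol (default 30).
#' @param filter_sigma Minimum column standard deviation, kcal/mol
#'   (default 2, the conventional column filter).
#' @return Object of class `field_matrix`: list with `grid`,
#'   `molecule_ids`, `steric` and `electrostatic` (n_mol x n_points),
#'   `keep_steric`/`keep_electrostatic` (column masks), `excluded`
#'   (logical, capped steric points), `block_weights`, `cap`,
#'   `filter_sigma`.
#' @export
build_field_matrix <- function(mols, grid = make_grid(mols),
                               probe = probe_spec(), cap = 30,
                               filter_sigma = 2) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  if (!length(mols)) stop("need at least one molecule")
  pts <- grid_points(grid)
  n_mol <- length(mols); n_pts <- nrow(pts)
  ste <- matrix(0, n_mol, n_pts)
  ele <- matrix(0, n_mol, n_pts)
  for (m in seq_len(n_mol)) {
    ste[m, ] <- steric_energy(pts, mols[[m]], probe, cap)
    ele[m, ] <- electrostatic_energy(pts, mols[[m]], probe, cap)
  }
  excluded <- ste >= cap
  ele[excluded] <- NA_real_
  col_mean_ok <- colMeans(ele, na.rm = TRUE)
  col_mean_ok[!is.finite(col_mean_ok)] <- 0
  for (j in which(colSums(excluded) > 0))
    ele[excluded[, j], j] <- col_mean_ok[j]
  sd_ste <- apply(ste, 2, sd)
  sd_ele <- apply(ele, 2, sd)
  keep_s <- sd_ste >= filter_sigma
  keep_e <- sd_ele >= filter_sigma
  if (!any(keep_s) && !any(keep_e))
    stop("every column masked by the ", filter_sigma,
         " kcal/mol filter; lower filter_sigma")
  w <- c(steric = block_weight(ste[, keep_s, drop = FALSE]),
         electrostatic = block_weight(ele[, keep_e, drop = FALSE]))
  structure(list(grid = grid,
                 molecule_ids = vapply(mols, function(m) m$id, character(1)),
                 steric = ste, electrostatic = ele,
                 keep_steric = keep_s, keep_electrostatic = keep_e,
                 excluded = excluded, block_weights = w,
                 cap = cap, filter_sigma = filter_sigma),
            class = "field_matrix")
}

block_weight <- function(block) {
  if (!length(block)) return(NA_real_)
  s <- sd(as.vector(block))
  if (is.na(s) || s == 0) 1 else 1 / s
}

#' @export
print.field_matrix <- function(x, ...) {
  cat(sprintf(paste0("<field matrix: %d molecules x %d points; ",
                     "%d steric + %d electrostatic columns retained ",
                     "(filter %.2g kcal/mol)>\n"),
              nrow(x$steric), ncol(x$steric),
              sum(x$keep_steric), sum(x$keep_electrostatic), x$filter_sigma))
  invisible(x)
}

#' Assemble the PLS descriptor matrix from a field matrix
#'
#' Retained steric columns come first, then retained electrostatic columns;
#' block scaling multiplies each block by its weight when requested.
#'
#' @param fm A [field_matrix][build_field_matrix].
#' @param block_scaling `"inverse_stdev"` (CoMFA-standard, default) or
#'   `"none"`.
#' @return Numeric matrix with attributes `block` (per-column `"steric"`/
#'   `"electrostatic"`) and `point` (per-column lattice point index).
#' @export
descriptor_matrix <- function(fm, block_scaling = c("inverse_stdev", "none")) {
  block_scaling <- match.arg(block_scaling)
  ws <- if (block_scaling == "inverse_stdev") fm$block_weights
        else c(steric = 1, electrostatic = 1)
  Xs <- fm$steric[, fm$keep_steric, drop = FALSE] * ws[["steric"]]
  Xe <- fm$electrostatic[, fm$keep_electrostatic, drop = FALSE] *
    ws[["electrostatic"]]
  X <- cbind(Xs, Xe)
  colnames(X) <- c(paste0("s", which(fm$keep_steric)),
                   paste0("e", which(fm$keep_electrostatic)))
  attr(X, "block") <- rep(c("steric", "electrostatic"),
                          c(ncol(Xs), ncol(Xe)))
  attr(X, "point") <- c(which(fm$keep_steric), which(fm$keep_electrostatic))
  X
}
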