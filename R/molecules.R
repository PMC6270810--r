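# Molecule data model and file input/output.

#' Construct a molecule
#'
#' A molecule is an ordered set of atoms (element, 3D coordinates in
#' Angstrom, partial charge, optional van der Waals parameters) plus a bond
#' list. Reference bond lengths and angles are captured from the input
#' coordinates at construction; the force-field restraint terms in
#' [energy()] are measured against them.
#'
#' @param id Molecule identifier (string).
#' @param atoms Data frame with columns `element`, `x`, `y`, `z`; optional
#'   `charge` (partial charge, e), `fcharge` (integer formal charge),
#'   `vdw_radius`, `vdw_epsilon`, `type`.
#' @param bonds Data frame with columns `i`, `j`, `order` (1-based atom
#'   indices; order 1, 2, 3, or 4 for aromatic). May have zero rows.
#' @return Object of class `molecule`.
#' @export
molecule <- function(id, atoms, bonds = data.frame(i = integer(),
                                                   j = integer(),
                                                   order = integer())) {
  stopifnot(is.data.frame(atoms), is.data.frame(bonds))
  for (col in c("element", "x", "y", "z"))
    if (is.null(atoms[[col]])) stop("atoms need column '", col, "'")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  n <- nrow(atoms)
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (is.null(atoms$fcharge)) atoms$fcharge <- 0L
  if (is.null(atoms$vdw_radius)) atoms$vdw_radius <- NA_real_
  if (is.null(atoms$vdw_epsilon)) atoms$vdw_epsilon <- NA_real_
  if (is.null(atoms$type)) atoms$type <- atoms$element
  if (nrow(bonds)) {
    if (is.null(bonds$order)) bonds$order <- 1L
    if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n))
      stop("bond indices out of range")
    if (any(bonds$i == bonds$j)) stop("self-bonds are not allowed")
  }
  mol <- structure(list(id = as.character(id), atoms = atoms, bonds = bonds,
                        formal_charge = sum(atoms$fcharge)),
                   class = "molecule")
  mol$reference <- reference_geometry(mol)
  mol
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule '%s': %d atoms, %d bonds, formal charge %+d>\n",
              x$id, nrow(x$atoms), nrow(x$bonds), x$formal_charge))
  invisible(x)
}

#' Atom coordinates as an n x 3 matrix
#' @param mol A [molecule].
#' @return Numeric matrix with columns x, y, z.
#' @export
coords <- function(mol) {
  m <- as.matrix(mol$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Replace atom coordinates
#' @param mol A [molecule].
#' @param xyz n x 3 numeric matrix.
#' @param rereference Recapture reference bond lengths/angles from the new
#'   coordinates? Default `FALSE` (restraints keep pointing at the original
#'   geometry).
#' @return The updated molecule.
#' @export
set_coords <- function(mol, xyz, rereference = FALSE) {
  stopifnot(nrow(xyz) == nrow(mol$atoms), ncol(xyz) == 3)
  mol$atoms$x <- xyz[, 1]; mol$atoms$y <- xyz[, 2]; mol$atoms$z <- xyz[, 3]
  if (rereference) mol$reference <- reference_geometry(mol)
  mol
}

# ---- file input/output -----------------------------------------------------

#' Read molecules from SDF (V2000) or MOL2
#'
#' SDF parsing is delegated to ChemmineR; MOL2 parsing to bio3d. MOL2
#' partial charges are imported when present. SDF partial charges are read
#' from a property block named `ATOM_PARTIAL_CHARGES` (lines of
#' "index charge", 1-based), else zeroed.
#'
#' @param path Input file.
#' @param format `"sdf"` or `"mol2"` (default: guessed from the extension).
#' @return List of [molecule] objects.
#' @export
read_molecules <- function(path, format = c("auto", "sdf", "mol2")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mol2$", path, ignore.case = TRUE)) "mol2" else "sdf"
  if (format == "sdf") read_sdf_molecules(path) else read_mol2_molecules(path)
}

read_sdf_molecules <- function(path) {
  if (!length(readLines(path, n = 1L, warn = FALSE)))
    stop("empty SDF file: ", path)
  sdfset <- ChemmineR::read.SDFset(path)
  lapply(seq_along(sdfset), function(k) {
    sdf <- sdfset[[k]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    if (!nrow(ab)) stop("SDF record ", k, " has no atoms")
    elements <- sub("_.*$", "", rownames(ab))
    atoms <- data.frame(element = elements,
                        x = ab[, 1], y = ab[, 2], z = ab[, 3],
                        stringsAsFactors = FALSE)
    rownames(atoms) <- NULL
    bonds <- if (length(bb) && nrow(as.matrix(bb))) {
      bbm <- matrix(as.numeric(as.matrix(bb)), ncol = ncol(as.matrix(bb)))
      data.frame(i = as.integer(bbm[, 1]), j = as.integer(bbm[, 2]),
                 order = as.integer(bbm[, 3]))
    } else data.frame(i = integer(), j = integer(), order = integer())
    db <- ChemmineR::datablock(sdf)
    if (!is.null(db) && "ATOM_PARTIAL_CHARGES" %in% names(db)) {
      atoms$charge <- parse_charge_block(db[["ATOM_PARTIAL_CHARGES"]],
                                         nrow(atoms), path)
    }
    name <- ChemmineR::header(sdf)[["Molecule_Name"]]
    if (is.null(name) || !nzchar(trimws(name))) name <- paste0("mol_", k)
    molecule(trimws(name), atoms, bonds)
  })
}

# ChemmineR joins multi-line data fields with " __ ".
parse_charge_block <- function(txt, n_atoms, path) {
  entries <- strsplit(trimws(unlist(strsplit(txt, "__", fixed = TRUE))), "\\s+")
  entries <- entries[vapply(entries, length, 1L) > 0]
  charges <- rep(0, n_atoms)
  for (e in entries) {
    if (length(e) != 2L)
      stop("malformed ATOM_PARTIAL_CHARGES entry in ", path, ": ",
           paste(e, collapse = " "))
    idx <- as.integer(e[1])
    if (is.na(idx) || idx < 1L || idx > n_atoms)
      stop("charge index out of range in ", path, ": ", e[1])
    charges[idx] <- as.numeric(e[2])
  }
  charges
}

read_mol2_molecules <- function(path) {
  m2 <- bio3d::read.mol2(path)
  if (is.data.frame(m2$atom)) m2 <- list(m2)
  lapply(m2, function(rec) {
    at <- rec$atom
    elements <- sub("\\..*$", "", at$elety)
    atoms <- data.frame(element = elements, x = at$x, y = at$y, z = at$z,
                        charge = if (!is.null(at$charge) &&
                                     !all(is.na(at$charge))) at$charge else 0,
                        type = at$elety, stringsAsFactors = FALSE)
    bonds <- if (!is.null(rec$bond) && nrow(rec$bond)) {
      ord <- rec$bond$type
      ord_num <- suppressWarnings(as.integer(ord))
      ord_num[ord %in% c("ar", "Ar", "AR")] <- 4L
      ord_num[ord %in% c("am", "Am")] <- 1L
      if (anyNA(ord_num)) stop("unrecognized MOL2 bond type in ", path)
      data.frame(i = rec$bond$origin, j = rec$bond$target, order = ord_num)
    } else data.frame(i = integer(), j = integer(), order = integer())
    id <- if (!is.null(rec$name) && nzchar(rec$name[1])) rec$name[1]
          else "mol2"
    molecule(id, atoms, bonds)
  })
}

#' Write molecules to an SDF (V2000) file
#'
#' Partial charges are carried in a property block named
#' `ATOM_PARTIAL_CHARGES`.
#'
#' @param mols List of [molecule] objects (or a single molecule).
#' @param path Output file.
#' @param write_charges Include the charge property block? Default `TRUE`.
#' @export
write_molecules <- function(mols, path, write_charges = TRUE) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  blocks <- vapply(mols, function(mol) {
    a <- mol$atoms
    n <- nrow(a); nb <- nrow(mol$bonds)
    lines <- c(mol$id, "  comfar", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              a$x, a$y, a$z, a$element))
    if (nb)
      lines <- c(lines, sprintf("%3d%3d%3d  0", mol$bonds$i, mol$bonds$j,
                                mol$bonds$order))
    lines <- c(lines, "M  END")
    if (write_charges && any(a$charge != 0)) {
      lines <- c(lines, "> <ATOM_PARTIAL_CHARGES>",
                 sprintf("%d %.6f", seq_len(n), a$charge), "")
    }
    paste(c(lines, "$$$$"), collapse = "\n")
  }, character(1))
  writeLines(blocks, path)
  invisible(path)
}

# ---- van der Waals parameters ---------------------------------------------

#' Packaged Tripos-style van der Waals parameter table
#'
#' Per-element van der Waals radius (Angstrom) and well depth (kcal/mol)
#' transcribed from the published Tripos 5.2 force-field listing. The table
#' is configuration, not code: pass your own data frame with the same
#' columns to [assign_vdw_params()] to swap it.
#'
#' @return Data frame with columns `element`, `vdw_radius`, `vdw_epsilon`.
#' @export
tripos_vdw_params <- function() {
  read.csv(extdata_path("tripos_vdw.csv"), stringsAsFactors = FALSE)
}

#' Assign van der Waals parameters to every atom
#'
#' @param mol A [molecule].
#' @param params Parameter table (default [tripos_vdw_params()]).
#' @return The molecule with `vdw_radius`/`vdw_epsilon` filled in.
#' @export
assign_vdw_params <- function(mol, params = tripos_vdw_params()) {
  idx <- match(mol$atoms$element, params$element)
  if (anyNA(idx)) {
    missing <- unique(mol$atoms$element[is.na(idx)])
    stop("no van der Waals parameters for element(s): ",
         paste(missing, collapse = ", "))
  }
  mol$atoms$vdw_radius <- params$vdw_radius[idx]
  mol$atoms$vdw_epsilon <- params$vdw_epsilon[idx]
  mol
}
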