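# Conformer preparation: simplified force-field energy, Cartesian
# minimization, torsional simulated annealing, and rigid least-squares
# scaffold superposition.

KB_KCAL <- 0.0019872041  # Boltzmann constant, kcal/(mol K)

# Reference bond lengths and angles captured from the current coordinates;
# harmonic restraints in energy() keep covalent geometry near them while
# nonbonded terms relax clashes.
reference_geometry <- function(mol) {
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")])
  b <- mol$bonds
  bond_len <- if (nrow(b)) sqrt(rowSums((xyz[b$i, , drop = FALSE] -
                                         xyz[b$j, , drop = FALSE])^2))
              else numeric()
  angles <- list(i = integer(), j = integer(), k = integer(), theta0 = numeric())
  if (nrow(b)) {
    nbrs <- neighbor_list(mol)
    for (j in seq_len(nrow(mol$atoms))) {
      nb <- nbrs[[j]]
      if (length(nb) < 2L) next
      for (p in seq_len(length(nb) - 1L)) for (q in seq((p + 1L), length(nb))) {
        i <- nb[p]; k <- nb[q]
        angles$i <- c(angles$i, i); angles$j <- c(angles$j, j)
        angles$k <- c(angles$k, k)
        angles$theta0 <- c(angles$theta0, vector_angle(xyz[i, ] - xyz[j, ],
                                                       xyz[k, ] - xyz[j, ]))
      }
    }
  }
  list(bond_length = bond_len, angles = as.data.frame(angles))
}

neighbor_list <- function(mol) {
  n <- nrow(mol$atoms)
  nbrs <- vector("list", n)
  if (nrow(mol$bonds))
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
      nbrs[[i]] <- c(nbrs[[i]], j); nbrs[[j]] <- c(nbrs[[j]], i)
    }
  nbrs
}

vector_angle <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang)))
}

bond_graph <- function(mol) {
  g <- igraph::make_empty_graph(n = nrow(mol$atoms), directed = FALSE)
  if (nrow(mol$bonds))
    g <- igraph::add_edges(g, rbind(mol$bonds$i, mol$bonds$j))
  g
}

#' Rotatable bonds of a molecule
#'
#' A bond is rotatable when it is a single bond, does not lie in a ring
#' (graph bridge), and both end atoms have at least one further neighbor.
#'
#' @param mol A [molecule].
#' @return Data frame with columns `i`, `j` (one row per rotatable bond).
#' @export
rotatable_bonds <- function(mol) {
  empty <- data.frame(i = integer(), j = integer())
  if (!nrow(mol$bonds)) return(empty)
  g <- bond_graph(mol)
  bridge_ids <- igraph::bridges(g)
  deg <- igraph::degree(g)
  keep <- logical(nrow(mol$bonds))
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    eid <- igraph::get_edge_ids(g, c(i, j))
    keep[k] <- mol$bonds$order[k] == 1L && eid %in% bridge_ids &&
      deg[i] >= 2L && deg[j] >= 2L
  }
  mol$bonds[keep, c("i", "j"), drop = FALSE]
}

# Precomputed static terms so energy can be re-evaluated cheaply during
# minimization and annealing.
make_energy_cache <- function(mol) {
  if (anyNA(mol$atoms$vdw_radius) || anyNA(mol$atoms$vdw_epsilon))
    stop("assign van der Waals parameters before computing energies")
  n <- nrow(mol$atoms)
  excl <- matrix(FALSE, n, n)
  if (nrow(mol$bonds)) {
    g <- bond_graph(mol)
    topo <- igraph::distances(g)
    excl <- topo <= 2  # 1-2 and 1-3 pairs (and self)
  } else diag(excl) <- TRUE
  pairs <- which(upper.tri(matrix(0, n, n)) & !excl, arr.ind = TRUE)
  r <- mol$atoms$vdw_radius; e <- mol$atoms$vdw_epsilon; q <- mol$atoms$charge
  tors <- torsion_quadruples(mol)
  list(n = n,
       nb_i = pairs[, 1], nb_j = pairs[, 2],
       eps_ij = sqrt(e[pairs[, 1]] * e[pairs[, 2]]),
       rstar_ij = r[pairs[, 1]] + r[pairs[, 2]],
       qq_ij = q[pairs[, 1]] * q[pairs[, 2]],
       bonds = mol$bonds, bond_r0 = mol$reference$bond_length,
       angles = mol$reference$angles,
       torsions = tors)
}

# One representative dihedral a-b-c-d per rotatable bond b-c.
torsion_quadruples <- function(mol) {
  rb <- rotatable_bonds(mol)
  if (!nrow(rb)) return(data.frame(a = integer(), b = integer(),
                                   c = integer(), d = integer()))
  nbrs <- neighbor_list(mol)
  out <- lapply(seq_len(nrow(rb)), function(k) {
    b <- rb$i[k]; c_ <- rb$j[k]
    a <- min(setdiff(nbrs[[b]], c_)); d <- min(setdiff(nbrs[[c_]], b))
    data.frame(a = a, b = b, c = c_, d = d)
  })
  do.call(rbind, out)
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

energy_xyz <- function(xyz, cache, k_bond = 300, k_angle = 40,
                       v_torsion = 0.2, coulomb_const = 332.0,
                       lj_pair_cap = 1e4, warn_overlap = TRUE) {
  e_total <- 0
  if (length(cache$nb_i)) {
    d2 <- rowSums((xyz[cache$nb_i, , drop = FALSE] -
                   xyz[cache$nb_j, , drop = FALSE])^2)
    if (warn_overlap && any(d2 < 1e-12))
      warning("overlapping atoms: Lennard-Jones energy clamped")
    d2 <- pmax(d2, 1e-12)
    d <- sqrt(d2)
    sr6 <- (cache$rstar_ij / d)^6
    lj <- pmin(cache$eps_ij * (sr6^2 - 2 * sr6), lj_pair_cap)
    coul <- coulomb_const * cache$qq_ij / d2  # distance-dependent dielectric
    e_total <- e_total + sum(lj) + sum(coul)
  }
  b <- cache$bonds
  if (nrow(b)) {
    dl <- sqrt(rowSums((xyz[b$i, , drop = FALSE] -
                        xyz[b$j, , drop = FALSE])^2)) - cache$bond_r0
    e_total <- e_total + k_bond * sum(dl^2)
  }
  ang <- cache$angles
  if (nrow(ang)) {
    th <- vapply(seq_len(nrow(ang)), function(r) {
      vector_angle(xyz[ang$i[r], ] - xyz[ang$j[r], ],
                   xyz[ang$k[r], ] - xyz[ang$j[r], ])
    }, numeric(1))
    e_total <- e_total + k_angle * sum((th - ang$theta0)^2)
  }
  tq <- cache$torsions
  if (nrow(tq)) {
    phi <- vapply(seq_len(nrow(tq)), function(r) {
      dihedral_angle(xyz[tq$a[r], ], xyz[tq$b[r], ],
                     xyz[tq$c[r], ], xyz[tq$d[r], ])
    }, numeric(1))
    e_total <- e_total + sum(0.5 * v_torsion * (1 + cos(3 * phi)))
  }
  e_total
}

#' Force-field energy of a molecule
#'
#' Simplified Tripos-style energy: Lennard-Jones 6-12 plus Coulomb (with
#' distance-dependent dielectric, so proportional to 1/d^2) over all atom
#' pairs except 1-2 and 1-3 neighbors, a 3-fold torsional potential on
#' rotatable bonds, and harmonic bond/angle restraints toward the reference
#' geometry captured at molecule construction (zero at the input geometry).
#'
#' @param mol A [molecule] with van der Waals parameters assigned.
#' @param ... Force-field constants passed on (`k_bond`, `k_angle`,
#'   `v_torsion`, `coulomb_const`).
#' @return Energy in kcal/mol.
#' @export
energy <- function(mol, ...) {
  energy_xyz(coords(mol), make_energy_cache(mol), ...)
}

#' Minimization configuration
#' @param max_cycles Maximum optimizer cycles (default 1000).
#' @param gradient_tol Gradient convergence criterion, kcal/(mol A)
#'   (default 0.005).
#' @return Object of class `minimize_config`.
#' @export
minimize_config <- function(max_cycles = 1000L, gradient_tol = 0.005) {
  if (max_cycles < 1L) stop("max_cycles must be >= 1")
  if (gradient_tol <= 0) stop("gradient_tol must be > 0")
  structure(list(max_cycles = as.integer(max_cycles),
                 gradient_tol = gradient_tol), class = "minimize_config")
}

#' Energy minimization
#'
#' Quasi-Newton (L-BFGS-B) minimization of [energy()] over Cartesian
#' coordinates. Terminates at the gradient tolerance or the cycle budget;
#' the returned conformer never has higher energy than the input.
#'
#' @param mol A [molecule] with van der Waals parameters assigned.
#' @param cfg A [minimize_config()].
#' @return List with `molecule`, `energy_initial`, `energy_final`,
#'   `final_gradient_norm` (max absolute component, kcal/(mol A)).
#' @export
minimize <- function(mol, cfg = minimize_config()) {
  cache <- make_energy_cache(mol)
  xyz0 <- coords(mol)
  fn <- function(par) {
    v <- energy_xyz(matrix(par, ncol = 3), cache, warn_overlap = FALSE)
    if (!is.finite(v)) stop("non-finite energy during minimization")
    v
  }
  e0 <- fn(as.vector(xyz0))
  opt <- optim(as.vector(xyz0), fn, method = "L-BFGS-B",
               control = list(maxit = cfg$max_cycles,
                              pgtol = cfg$gradient_tol, factr = 1e4))
  if (opt$value <= e0) {
    xyz <- matrix(opt$par, ncol = 3)
    e_final <- opt$value
  } else {
    xyz <- xyz0
    e_final <- e0
  }
  g <- numeric(length(xyz))
  h <- 1e-5
  par <- as.vector(xyz)
  for (k in seq_along(par)) {
    up <- par; up[k] <- up[k] + h
    dn <- par; dn[k] <- dn[k] - h
    g[k] <- (fn(up) - fn(dn)) / (2 * h)
  }
  list(molecule = set_coords(mol, xyz), energy_initial = e0,
       energy_final = e_final, final_gradient_norm = max(abs(g)))
}

#' Simulated-annealing configuration
#'
#' Torsional Metropolis annealing standing in for short heating/cooling
#' molecular dynamics: the same temperature endpoints, with time steps
#' mapped to Monte-Carlo torsion moves.
#'
#' @param t_hot Hot-phase temperature, K (default 700).
#' @param t_cold Final temperature, K (default 200).
#' @param steps_hot Moves at `t_hot` (default 1000).
#' @param steps_cold Moves during the linear cooling ramp (default 1000).
#' @param max_angle Largest torsion perturbation per move, degrees
#'   (default 30).
#' @param seed Integer RNG seed (required for reproducibility).
#' @return Object of class `anneal_config`.
#' @export
anneal_config <- function(t_hot = 700, t_cold = 200, steps_hot = 1000L,
                          steps_cold = 1000L, max_angle = 30, seed = 1L) {
  if (!(t_hot > t_cold && t_cold > 0)) stop("need t_hot > t_cold > 0")
  if (steps_hot < 1L || steps_cold < 1L) stop("step counts must be >= 1")
  structure(list(t_hot = t_hot, t_cold = t_cold,
                 steps_hot = as.integer(steps_hot),
                 steps_cold = as.integer(steps_cold),
                 max_angle = max_angle, seed = seed),
            class = "anneal_config")
}

#' Torsional simulated annealing
#'
#' Metropolis sampling over single random torsion moves: `steps_hot` moves
#' at the hot temperature followed by `steps_cold` moves while the
#' temperature ramps linearly down to `t_cold`. Bond lengths and angles are
#' untouched (torsion-only move set). Deterministic for a fixed seed.
#'
#' @param mol A [molecule] with van der Waals parameters assigned.
#' @param cfg An [anneal_config()].
#' @return List with `molecule`, `energy_initial`, `energy_final`,
#'   `accepted` (move acceptance count). A molecule without rotatable bonds
#'   is returned unchanged with a message.
#' @export
simulated_anneal <- function(mol, cfg = anneal_config()) {
  rb <- rotatable_bonds(mol)
  if (!nrow(rb)) {
    message("no rotatable bonds: annealing leaves '", mol$id, "' unchanged")
    return(list(molecule = mol, energy_initial = energy(mol),
                energy_final = energy(mol), accepted = 0L))
  }
  cache <- make_energy_cache(mol)
  g <- bond_graph(mol)
  # atoms moved when rotating about bond i-j: the component containing j
  # once the bond is removed
  moving <- lapply(seq_len(nrow(rb)), function(k) {
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(rb$i[k], rb$j[k])))
    comp <- igraph::components(g2)
    which(comp$membership == comp$membership[rb$j[k]])
  })
  xyz <- coords(mol)
  e_cur <- energy_xyz(xyz, cache, warn_overlap = FALSE)
  e0 <- e_cur
  n_total <- cfg$steps_hot + cfg$steps_cold
  temps <- c(rep(cfg$t_hot, cfg$steps_hot),
             seq(cfg$t_hot, cfg$t_cold, length.out = cfg$steps_cold))
  accepted <- 0L
  with_seed(cfg$seed, {
    for (s in seq_len(n_total)) {
      k <- sample.int(nrow(rb), 1L)
      ang <- runif(1, -cfg$max_angle, cfg$max_angle) * pi / 180
      cand <- rotate_about_axis(xyz, xyz[rb$i[k], ], xyz[rb$j[k], ],
                                moving[[k]], ang)
      e_new <- energy_xyz(cand, cache, warn_overlap = FALSE)
      if (e_new <= e_cur ||
          runif(1) < exp(-(e_new - e_cur) / (KB_KCAL * temps[s]))) {
        xyz <- cand; e_cur <- e_new; accepted <- accepted + 1L
      }
    }
  })
  list(molecule = set_coords(mol, xyz), energy_initial = e0,
       energy_final = e_cur, accepted = accepted)
}

# Rotate the atoms in `idx` about the axis from `p_from` to `p_to`.
rotate_about_axis <- function(xyz, p_from, p_to, idx, angle) {
  axis <- p_to - p_from
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  moved <- sweep(xyz[idx, , drop = FALSE], 2, p_from)
  xyz[idx, ] <- moved %*% t(R) + matrix(p_from, length(idx), 3, byrow = TRUE)
  xyz
}

#' Rigid least-squares superposition onto a template (atom fit)
#'
#' Kabsch superposition over an explicit atom correspondence: the proper
#' rotation and translation minimizing the RMSD of mapped atom pairs is
#' found by singular value decomposition (reflections are rejected) and
#' applied to the whole molecule.
#'
#' @param mol A [molecule] to move.
#' @param template A [molecule] held fixed.
#' @param map Two-column matrix or data frame of 1-based atom indices
#'   (template, molecule); at least 3 non-collinear template atoms.
#' @return List with `molecule` (transformed), `rmsd` (Angstrom, over the
#'   mapped pairs), `rotation`, `translation`.
#' @export
atom_fit <- function(mol, template, map) {
  map <- as.matrix(map)
  if (ncol(map) != 2L || nrow(map) < 3L)
    stop("scaffold map needs >= 3 (template, molecule) index pairs")
  if (anyDuplicated(map[, 1]) || anyDuplicated(map[, 2]))
    stop("scaffold map indices must be unique")
  t_xyz <- coords(template)[map[, 1], , drop = FALSE]
  m_xyz <- coords(mol)[map[, 2], , drop = FALSE]
  t_cent <- colMeans(t_xyz); m_cent <- colMeans(m_xyz)
  T_c <- sweep(t_xyz, 2, t_cent); M_c <- sweep(m_xyz, 2, m_cent)
  if (svd(T_c)$d[2] < 1e-8)
    stop("degenerate fit: mapped template atoms are collinear")
  H <- crossprod(M_c, T_c)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  all_xyz <- sweep(coords(mol), 2, m_cent) %*% t(R)
  all_xyz <- sweep(all_xyz, 2, t_cent, `+`)
  fitted <- set_coords(mol, all_xyz)
  rmsd <- sqrt(mean(rowSums((coords(fitted)[map[, 2], , drop = FALSE] -
                             t_xyz)^2)))
  list(molecule = fitted, rmsd = rmsd, rotation = R,
       translation = t_cent - as.vector(m_cent %*% t(R)))
}

#' Read a scaffold atom-correspondence map
#'
#' Two whitespace-separated columns of 1-based indices (template atom,
#' molecule atom); `#` starts a comment.
#'
#' @param path Map file.
#' @return Two-column integer matrix.
#' @export
read_scaffold_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty scaffold map: ", path)
  parts <- strsplit(lines, "\\s+")
  if (any(vapply(parts, length, 1L) != 2L))
    stop("scaffold map lines must hold two indices: ", path)
  m <- matrix(as.integer(unlist(parts)), ncol = 2, byrow = TRUE)
  if (anyNA(m)) stop("non-integer entry in scaffold map: ", path)
  colnames(m) <- c("template", "molecule")
  m
}
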