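# Builders for small test molecules; all fixtures are constructed in code.

# Two atoms at distance d on the x axis, no bond.
make_dimer <- function(d, elements = c("C", "C"), charges = c(0, 0)) {
  assign_vdw_params(molecule("dimer", data.frame(
    element = elements, x = c(0, d), y = 0, z = 0, charge = charges)))
}

# Four-atom chain a-b-c-d with unit bonds and a controllable dihedral.
# Tetrahedral-ish internal angles; torsion set by `phi` (degrees).
make_torsion_chain <- function(elements = c("C", "C", "C", "C"),
                               bond = 1.54, angle = 111, phi = 60) {
  th <- angle * pi / 180
  p1 <- c(0, 0, 0)
  p2 <- c(bond, 0, 0)
  p3 <- p2 + bond * c(-cos(th), sin(th), 0)
  # place p4 at the requested dihedral about the p2->p3 axis
  phi_r <- phi * pi / 180
  u <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  # reference direction perpendicular to u in the p1-p2-p3 plane
  v0 <- (p1 - p2) - sum((p1 - p2) * u) * u
  v0 <- v0 / sqrt(sum(v0^2))
  w0 <- c(u[2] * v0[3] - u[3] * v0[2],
          u[3] * v0[1] - u[1] * v0[3],
          u[1] * v0[2] - u[2] * v0[1])
  dir <- cos(phi_r) * v0 + sin(phi_r) * w0
  ang_off <- (angle - 90) * pi / 180
  p4 <- p3 + bond * (cos(ang_off) * dir + sin(ang_off) * u)
  xyz <- rbind(p1, p2, p3, p4)
  assign_vdw_params(molecule("chain", data.frame(
    element = elements, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
    data.frame(i = 1:3, j = 2:4, order = 1L)))
}

# Random bonded molecule: a random spanning tree over n atoms with random
# elements and coordinates; used for conservation-law property tests.
random_bonded_molecule <- function(n, elements = c("C", "N", "O", "H", "S")) {
  el <- sample(elements, n, replace = TRUE)
  xyz <- matrix(rnorm(3 * n, sd = 2), n, 3)
  parent <- c(NA, vapply(2:n, function(k) sample.int(k - 1L, 1L), integer(1)))
  bonds <- data.frame(i = parent[-1], j = 2:n, order = 1L)
  molecule(paste0("rand", n), data.frame(
    element = el, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    fcharge = 0L), bonds)
}

random_rotation <- function() {
  q <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Topology-only molecule builder for charge tests (PEOE ignores geometry).
topo_molecule <- function(elements, bonds_i, bonds_j, orders = 1L) {
  n <- length(elements)
  molecule("topo", data.frame(element = elements,
                              x = seq_len(n), y = 0, z = 0),
           data.frame(i = bonds_i, j = bonds_j,
                      order = rep_len(orders, length(bonds_i))))
}
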