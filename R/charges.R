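# Iterative partial-charge assignment by partial equalization of orbital
# electronegativity (PEOE, Gasteiger-Marsili), with an optional uniform
# pi-charge spreading step standing in for the Hueckel component of
# "Gasteiger-Hueckel" charges.

#' Charge-calculation configuration
#'
#' @param damping Per-iteration damping factor in (0, 1); the charge
#'   transferred along a bond at iteration k is scaled by `damping^k`.
#' @param iterations Number of PEOE iterations (>= 1).
#' @param huckel_pi Spread the net formal charge of each conjugated
#'   subsystem uniformly over its atoms before the sigma iteration (a
#'   first-order stand-in for Hueckel pi charges)? Default `TRUE`; it is a
#'   no-op for molecules whose conjugated systems are neutral.
#' @param params Electronegativity coefficient table (columns `element`,
#'   `hybrid`, `a`, `b`, `c`); default the packaged Gasteiger-Marsili set.
#' @return Object of class `charge_config`.
#' @export
charge_config <- function(damping = 0.5, iterations = 6L, huckel_pi = TRUE,
                          params = peoe_params()) {
  if (damping <= 0 || damping >= 1) stop("damping must lie in (0, 1)")
  if (iterations < 1L) stop("iterations must be >= 1")
  structure(list(damping = damping, iterations = as.integer(iterations),
                 huckel_pi = isTRUE(huckel_pi), params = params),
            class = "charge_config")
}

#' Packaged PEOE electronegativity coefficients
#'
#' Per element and hybridization: chi(q) = a + b q + c q^2, in eV.
#' @return Data frame with columns `element`, `hybrid`, `a`, `b`, `c`.
#' @export
peoe_params <- function() {
  read.csv(extdata_path("peoe_params.csv"), stringsAsFactors = FALSE)
}

# Hybridization from bond orders: triple bond (or two doubles) -> sp,
# any double/aromatic bond -> sp2, else sp3.
atom_hybridizations <- function(mol) {
  n <- nrow(mol$atoms)
  hyb <- rep("sp3", n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]; o <- mol$bonds$order[k]
      if (o == 2L || o == 4L) {
        for (a in c(i, j))
          hyb[a] <- if (hyb[a] %in% c("sp2", "sp")) "sp" else "sp2"
      } else if (o == 3L) {
        hyb[c(i, j)] <- "sp"
      }
    }
    # a single double bond leaves sp2; two cumulated doubles promoted to sp
    # (handled above); aromatic atoms stay sp2
    arom <- unique(c(mol$bonds$i[mol$bonds$order == 4L],
                     mol$bonds$j[mol$bonds$order == 4L]))
    hyb[arom] <- "sp2"
  }
  hyb
}

peoe_coefficients <- function(mol, params) {
  hyb <- atom_hybridizations(mol)
  key_specific <- paste(mol$atoms$element, hyb)
  key_any <- paste(mol$atoms$element, "any")
  tab_key <- paste(params$element, params$hybrid)
  idx <- match(key_specific, tab_key)
  idx[is.na(idx)] <- match(key_any[is.na(idx)], tab_key)
  if (anyNA(idx)) {
    missing <- unique(mol$atoms$element[is.na(idx)])
    stop("no PEOE parameters for element(s): ", paste(missing, collapse = ", "))
  }
  params[idx, c("a", "b", "c")]
}

# Uniform spreading of each conjugated component's net formal charge.
spread_pi_charge <- function(mol, q0) {
  conj_bonds <- mol$bonds[mol$bonds$order >= 2L, , drop = FALSE]
  if (!nrow(conj_bonds)) return(q0)
  g <- igraph::graph_from_edgelist(cbind(conj_bonds$i, conj_bonds$j),
                                   directed = FALSE)
  comp <- igraph::components(g)
  present <- seq_len(igraph::vcount(g))
  for (c_id in seq_len(comp$no)) {
    members <- present[comp$membership == c_id]
    members <- members[members <= length(q0)]
    if (length(members) < 2L) next
    total <- sum(q0[members])
    q0[members] <- total / length(members)
  }
  q0
}

#' Gasteiger (PEOE) partial charges
#'
#' Iterative partial equalization of orbital electronegativity: each atom's
#' electronegativity is chi(q) = a + b q + c q^2; at iteration k an amount
#' of charge (chi_acceptor - chi_donor) / chi_plus_donor * damping^k flows
#' across each bond from the less to the more electronegative atom, where
#' chi_plus is the donor's cation electronegativity a + b + c (20.02 for
#' hydrogen). Total charge is conserved exactly; the result is
#' deterministic.
#'
#' @param mol A [molecule] with bonds; per-atom formal charges seed the
#'   iteration.
#' @param cfg A [charge_config()].
#' @return The molecule with `atoms$charge` set.
#' @examples
#' # methane-like toy: C bonded to 4 H
#' m <- molecule("ch4", data.frame(
#'   element = c("C", "H", "H", "H", "H"),
#'   x = c(0, 1.09, -0.36, -0.36, -0.36),
#'   y = c(0, 0, 1.03, -0.51, -0.51),
#'   z = c(0, 0, 0, 0.89, -0.89)),
#'   data.frame(i = 1, j = 2:5, order = 1))
#' gasteiger_charges(m)$atoms$charge
#' @export
gasteiger_charges <- function(mol, cfg = charge_config()) {
  n <- nrow(mol$atoms)
  q <- as.numeric(mol$atoms$fcharge)
  if (cfg$huckel_pi) q <- spread_pi_charge(mol, q)
  if (!nrow(mol$bonds)) {
    mol$atoms$charge <- q
    return(mol)
  }
  coefs <- peoe_coefficients(mol, cfg$params)
  a <- coefs$a; b <- coefs$b; cc <- coefs$c
  chi_plus <- a + b + cc
  chi_plus[mol$atoms$element == "H"] <- 20.02
  bi <- mol$bonds$i; bj <- mol$bonds$j
  damp <- cfg$damping
  for (k in seq_len(cfg$iterations)) {
    chi <- a + b * q + cc * q^2
    if (any(!is.finite(chi))) stop("PEOE diverged: non-finite electronegativity")
    scale <- damp^k
    dq <- numeric(n)
    for (e in seq_along(bi)) {
      i <- bi[e]; j <- bj[e]
      if (chi[i] == chi[j]) next
      donor <- if (chi[i] < chi[j]) i else j
      acceptor <- if (donor == i) j else i
      moved <- (chi[acceptor] - chi[donor]) / chi_plus[donor] * scale
      dq[donor] <- dq[donor] + moved
      dq[acceptor] <- dq[acceptor] - moved
    }
    q <- q + dq
  }
  if (abs(sum(q) - mol$formal_charge) > 1e-3)
    stop("PEOE failed to conserve total charge")
  mol$atoms$charge <- q
  mol
}
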