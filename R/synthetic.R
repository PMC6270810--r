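# Synthetic aligned molecule sets with a known sparse linear
# field-to-activity ground truth. Substituents are parameter bundles
# (radius, well depth, charge) rather than real chemistry: the goal is a
# data set whose field effects are exactly controllable, standing in for a
# compound series whose structures are not machine-readable.

#' Rigid bicyclic scaffold template
#'
#' Nine heavy atoms: a benzene-like hexagon fused to a five-membered ring
#' whose central atom is nitrogen (an indole-like core). All ring bonds are
#' aromatic, so the scaffold is rigid; every generated molecule carries it
#' with identical coordinates, giving an exact alignment ground truth.
#'
#' @return A [molecule] with 9 atoms.
#' @export
scaffold_molecule <- function() {
  s <- 1.40  # aromatic bond length, Angstrom
  hex_angles <- (c(90, 150, 210, 270, 330, 30)) * pi / 180
  hex <- cbind(s * cos(hex_angles), s * sin(hex_angles), 0)
  A <- hex[1, ]; B <- hex[6, ]                     # fusion edge
  mid <- (A + B) / 2
  u <- mid / sqrt(sum(mid^2))                      # outward, in plane
  rp <- s / (2 * sin(pi / 5))                      # pentagon circumradius
  centre <- mid[1:2] + u[1:2] * rp * cos(pi / 5)
  thB <- atan2(B[2] - centre[2], B[1] - centre[1])
  thA <- atan2(A[2] - centre[2], A[1] - centre[1])
  # step around the pentagon from B toward A the long way
  step <- 2 * pi / 5
  dir <- if (sin(thA - thB) > 0) -1 else 1
  penta <- t(vapply(1:3, function(k) {
    th <- thB + dir * step * k
    c(centre[1] + rp * cos(th), centre[2] + rp * sin(th), 0)
  }, numeric(3)))
  xyz <- rbind(hex, penta)
  atoms <- data.frame(element = c(rep("C", 7), "N", "C"),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      charge = c(rep(0, 7), -0.2, 0.1),
                      stringsAsFactors = FALSE)
  bonds <- data.frame(i = c(1, 2, 3, 4, 5, 6, 6, 7, 8, 9),
                      j = c(2, 3, 4, 5, 6, 1, 7, 8, 9, 1),
                      order = 4L)
  molecule("scaffold", atoms, bonds)
}

#' Synthetic-set generator configuration
#'
#' Defaults emulate the design of the study the packaged affinity tables
#' come from: 92 molecules on a shared rigid bicyclic scaffold with three
#' substitution regions, activities spanning about 4 log units, and
#' Gaussian activity noise.
#'
#' @param n_molecules Number of molecules (>= 10; default 92).
#' @param n_substituents Library size per region (default 8).
#' @param n_hotspots Number of causal lattice columns (default 4).
#' @param effect_weights Relative hotspot weights (recycled, alternating
#'   sign; default 1).
#' @param noise_sigma Gaussian activity noise, log units (default 0.2).
#' @param activity_span_target Noiseless activity span, log units
#'   (default 4).
#' @param activity_center Mean activity level, pKi units (default 7).
#' @param spacing,margin,cap,filter_sigma Field-lattice settings used to
#'   define the ground truth (defaults 2, 4, 30, 2).
#' @param seed Integer RNG seed.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_molecules = 92L, n_substituents = 8L,
                             n_hotspots = 4L, effect_weights = 1,
                             noise_sigma = 0.2, activity_span_target = 4,
                             activity_center = 7, spacing = 2, margin = 4,
                             cap = 30, filter_sigma = 2, seed = 1L) {
  if (n_molecules < 10L) stop("n_molecules must be >= 10")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (n_hotspots < 1L) stop("n_hotspots must be >= 1")
  structure(list(n_molecules = as.integer(n_molecules),
                 n_substituents = as.integer(n_substituents),
                 n_hotspots = as.integer(n_hotspots),
                 effect_weights = effect_weights,
                 noise_sigma = noise_sigma,
                 activity_span_target = activity_span_target,
                 activity_center = activity_center,
                 spacing = spacing, margin = margin, cap = cap,
                 filter_sigma = filter_sigma, seed = seed),
            class = "generator_config")
}

# Three attachment sites on the scaffold with in-plane outward unit
# vectors: the ring nitrogen (alkyl-chain region), the five-ring carbon
# next to it (aroyl region), and a benzene carbon (ring-substitution
# region).
scaffold_regions <- function(scaffold) {
  xyz <- coords(scaffold)
  centroid <- colMeans(xyz)
  sites <- c(8L, 9L, 3L)
  lapply(sites, function(a) {
    u <- xyz[a, ] - centroid
    u[3] <- 0
    list(atom = a, direction = u / sqrt(sum(u^2)))
  })
}

# Pseudo-substituent library: per region, chains of 1-6 element-typed
# atoms in a local frame whose +x axis is the attachment direction.
build_substituent_library <- function(cfg) {
  elements <- c("C", "C", "C", "N", "O", "F", "S", "Cl")
  lapply(1:3, function(region) {
    lapply(seq_len(cfg$n_substituents), function(s) {
      len <- sample(1:6, 1)
      data.frame(
        element = sample(elements, len, replace = TRUE),
        x = 1.5 + 1.3 * (seq_len(len) - 1),
        y = rep_len(c(0.45, -0.45), len) + runif(len, -0.2, 0.2),
        z = runif(len, -0.4, 0.4),
        charge = runif(len, -0.3, 0.3),
        stringsAsFactors = FALSE)
    })
  })
}

attach_substituent <- function(atoms, bonds, sub, site) {
  u <- site$direction
  w <- c(0, 0, 1)
  v <- cross3(w, u)
  B <- cbind(u, v, w)
  local <- as.matrix(sub[, c("x", "y", "z")])
  world <- local %*% t(B)
  base <- c(atoms$x[site$atom], atoms$y[site$atom], atoms$z[site$atom])
  world <- sweep(world, 2, base, `+`)
  start <- nrow(atoms) + 1L
  atoms <- rbind(atoms, data.frame(element = sub$element,
                                   x = world[, 1], y = world[, 2],
                                   z = world[, 3], charge = sub$charge,
                                   stringsAsFactors = FALSE))
  idx <- seq(start, length.out = nrow(sub))
  bonds <- rbind(bonds,
                 data.frame(i = c(site$atom, head(idx, -1)),
                            j = idx, order = 1L))
  list(atoms = atoms, bonds = bonds)
}

random_rotation_matrix <- function() {
  repeat {
    M <- matrix(rnorm(9), 3, 3)
    qr_d <- qr(M)
    Q <- qr.Q(qr_d)
    Q <- Q %*% diag(sign(diag(qr.R(qr_d))))
    if (det(Q) > 0) return(Q)
  }
}

#' Generate a synthetic molecule set with known ground truth
#'
#' Molecules share the rigid scaffold exactly (pre-aligned); each carries
#' one library substituent per region. Activities are a sparse linear
#' function of the molecules' field values at a few "hotspot" lattice
#' columns, scaled so the noiseless activities span the target range, plus
#' Gaussian noise. Randomly rotated and translated copies are emitted
#' alongside for alignment testing. Deterministic per seed.
#'
#' @param cfg A [generator_config()].
#' @return List with `molecules` (aligned), `molecules_posed` (random
#'   rigid copies), `scaffold`, `scaffold_map` (9 identity pairs),
#'   `activities` (data frame: `molecule_id`, `pki`, `pki_noiseless`),
#'   `truth` (hotspot columns as block/point/weight, the field matrix and
#'   raw descriptor columns behind them), and `config`.
#' @export
generate_synthetic_set <- function(cfg = generator_config()) {
  scaffold <- assign_vdw_params(scaffold_molecule())
  regions <- scaffold_regions(scaffold)
  with_seed(cfg$seed, {
    library_ <- build_substituent_library(cfg)
    choice <- matrix(0L, cfg$n_molecules, 3)
    for (r in 1:3)
      choice[, r] <- sample.int(cfg$n_substituents, cfg$n_molecules,
                                replace = TRUE)
    mols <- lapply(seq_len(cfg$n_molecules), function(m) {
      atoms <- scaffold$atoms[, c("element", "x", "y", "z", "charge")]
      bonds <- scaffold$bonds
      for (r in 1:3) {
        built <- attach_substituent(atoms, bonds, library_[[r]][[choice[m, r]]],
                                    regions[[r]])
        atoms <- built$atoms; bonds <- built$bonds
      }
      assign_vdw_params(molecule(sprintf("syn_%03d", m), atoms, bonds))
    })
    grid <- make_grid(mols, spacing = cfg$spacing, margin = cfg$margin)
    fm <- build_field_matrix(mols, grid, cap = cfg$cap,
                             filter_sigma = cfg$filter_sigma)
    X_raw <- descriptor_matrix(fm, block_scaling = "none")
    col_sd <- apply(X_raw, 2, sd)
    ord <- order(col_sd, decreasing = TRUE)
    # pick high-variance columns that are mutually weakly correlated:
    # adjacent lattice columns are nearly collinear, and collinear causal
    # columns with opposing weights would make the ground truth
    # unidentifiable for any regression method
    hot <- integer(0)
    for (j in ord) {
      if (length(hot) == cfg$n_hotspots) break
      if (!length(hot) ||
          max(abs(stats::cor(X_raw[, j], X_raw[, hot, drop = FALSE]))) < 0.5)
        hot <- c(hot, j)
    }
    if (length(hot) < cfg$n_hotspots)
      stop("could not find ", cfg$n_hotspots,
           " sufficiently decorrelated hotspot columns")
    w0 <- rep_len(cfg$effect_weights, cfg$n_hotspots) *
      rep_len(c(1, -1), cfg$n_hotspots)
    raw_act <- drop(X_raw[, hot, drop = FALSE] %*% w0)
    span <- diff(range(raw_act))
    if (span <= 0) {
      warning("hotspot fields carry no variation; activity span is 0")
      weights <- w0
    } else {
      weights <- w0 * cfg$activity_span_target / span
    }
    noiseless <- cfg$activity_center +
      drop(X_raw[, hot, drop = FALSE] %*% weights)
    noiseless <- noiseless - mean(noiseless) + cfg$activity_center
    noisy <- noiseless + rnorm(cfg$n_molecules, 0, cfg$noise_sigma)
    posed <- lapply(mols, function(mol) {
      R <- random_rotation_matrix()
      shift <- runif(3, -10, 10)
      set_coords(mol, sweep(coords(mol) %*% t(R), 2, shift, `+`))
    })
    list(molecules = mols, molecules_posed = posed, scaffold = scaffold,
         scaffold_map = cbind(template = 1:9, molecule = 1:9),
         activities = data.frame(molecule_id = seq_len(cfg$n_molecules),
                                 pki = noisy, pki_noiseless = noiseless),
         truth = list(block = attr(X_raw, "block")[hot],
                      point = attr(X_raw, "point")[hot],
                      weights = weights, noiseless = noiseless,
                      noisy = noisy, field_matrix = fm,
                      descriptor_columns = X_raw[, hot, drop = FALSE]),
         config = cfg)
  })
}

#' Stratified train/test split of an activity set
#'
#' Molecules are ranked by activity and divided into as many contiguous
#' strata as there are test molecules; one test molecule is drawn per
#' stratum, so the test set spans the activity range. Deterministic per
#' seed.
#'
#' @param activities Data frame with `molecule_id` and `pki`.
#' @param fraction_test Test fraction in (0, 0.5); the test count is the
#'   nearest integer (default 0.22).
#' @param seed Integer RNG seed.
#' @param receptor Label for the resulting table (default `"SYN"`).
#' @return An [affinity_table] (predictions absent).
#' @export
train_test_split <- function(activities, fraction_test = 0.22, seed = 1L,
                             receptor = "SYN") {
  if (fraction_test <= 0 || fraction_test >= 0.5)
    stop("fraction_test must lie in (0, 0.5)")
  n <- nrow(activities)
  n_test <- round(n * fraction_test)
  if (n_test < 1L) stop("too few molecules for a test stratum")
  ord <- order(activities$pki)
  strata <- split(ord, cut(seq_len(n), n_test, labels = FALSE))
  if (any(vapply(strata, length, 1L) < 1L))
    stop("too few molecules per activity stratum")
  test_idx <- with_seed(seed,
    vapply(strata, function(s) s[sample.int(length(s), 1L)], integer(1)))
  split_flag <- rep("train", n)
  split_flag[test_idx] <- "test"
  df <- data.frame(receptor = receptor,
                   molecule_id = activities$molecule_id,
                   ki_nM = 10^(9 - activities$pki),
                   pki = activities$pki,
                   predicted_pki = NA_real_, residual = NA_real_,
                   split = split_flag, stringsAsFactors = FALSE)
  affinity_table(df)
}
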