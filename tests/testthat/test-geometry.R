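test_that("energy matches Lennard-Jones closed forms", {
  # two neutral carbons at the pair minimum distance r* = 3.4 A
  expect_equal(energy(make_dimer(3.4)), -0.107, tolerance = 1e-9)
  # single atom has zero energy
  single <- assign_vdw_params(molecule("a", data.frame(element = "C",
                                                       x = 0, y = 0, z = 0)))
  expect_equal(energy(single), 0)
  # mixed pair: epsilon combines geometrically, radii add
  m <- make_dimer(1.70 + 1.52, elements = c("C", "O"))
  expect_equal(energy(m), -sqrt(0.107 * 0.116), tolerance = 1e-9)
})

test_that("energy equals a brute-force pairwise sum on unbonded toys", {
  set.seed(21)
  for (rep in 1:10) {
    n <- 5
    atoms <- data.frame(element = sample(c("C", "N", "O"), n, replace = TRUE),
                        x = runif(n, -4, 4), y = runif(n, -4, 4),
                        z = runif(n, -4, 4),
                        charge = round(runif(n, -0.5, 0.5), 3))
    m <- assign_vdw_params(molecule("toy", atoms))
    xyz <- coords(m)
    e_oracle <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      eps <- sqrt(m$atoms$vdw_epsilon[i] * m$atoms$vdw_epsilon[j])
      rs <- m$atoms$vdw_radius[i] + m$atoms$vdw_radius[j]
      e_oracle <- e_oracle + eps * ((rs / d)^12 - 2 * (rs / d)^6) +
        332.0 * m$atoms$charge[i] * m$atoms$charge[j] / d^2
    }
    expect_equal(energy(m), e_oracle, tolerance = 1e-8)
  }
})

test_that("energy is invariant under rigid rotation and translation", {
  set.seed(22)
  m <- random_bonded_molecule(8)
  m$atoms$charge <- rnorm(8, sd = 0.2)
  m <- assign_vdw_params(m)
  e0 <- energy(m)
  for (rep in 1:10) {
    R <- random_rotation()
    shift <- rnorm(3, sd = 5)
    moved <- m
    moved$atoms[, c("x", "y", "z")] <- sweep(coords(m) %*% t(R), 2, shift, `+`)
    expect_equal(energy(moved), e0, tolerance = 1e-8)
  }
})

test_that("minimization descends and finds the pair minimum", {
  # already at the minimum: unchanged within tolerance
  at_min <- minimize(make_dimer(3.4))
  expect_equal(coords(at_min$molecule), coords(make_dimer(3.4)),
               tolerance = 1e-3)
  # stretched dimer converges to the closed-form minimum separation r*
  stretched <- minimize(make_dimer(5.2))
  d <- diff(coords(stretched$molecule)[, 1])
  expect_equal(d, 3.4, tolerance = 1e-2)
  expect_lt(stretched$energy_final, stretched$energy_initial)
  expect_lt(stretched$final_gradient_norm, 0.05)
})

test_that("minimization never raises the energy of perturbed molecules", {
  set.seed(23)
  for (rep in 1:50) {
    m <- assign_vdw_params(random_bonded_molecule(sample(3:6, 1)))
    out <- minimize(m, minimize_config(max_cycles = 50))
    expect_lte(out$energy_final, out$energy_initial + 1e-9)
  }
})

test_that("annealing is deterministic per seed and skips rigid systems", {
  chain <- make_torsion_chain(phi = 60)
  cfg <- anneal_config(steps_hot = 150, steps_cold = 150, seed = 12)
  a1 <- simulated_anneal(chain, cfg)
  a2 <- simulated_anneal(chain, cfg)
  expect_identical(coords(a1$molecule), coords(a2$molecule))
  a3 <- simulated_anneal(chain, anneal_config(steps_hot = 150,
                                              steps_cold = 150, seed = 13))
  expect_false(identical(coords(a1$molecule), coords(a3$molecule)))
  # an aromatic ring system has no rotatable bonds: identity plus a notice
  rigid <- assign_vdw_params(scaffold_molecule())
  expect_message(out <- simulated_anneal(rigid, cfg), "no rotatable bonds")
  expect_identical(coords(out$molecule), coords(rigid))
})

test_that("torsion moves leave bond lengths and angles untouched", {
  chain <- make_torsion_chain(phi = 60)
  ref <- chain$reference
  out <- simulated_anneal(chain, anneal_config(steps_hot = 100,
                                               steps_cold = 100, seed = 3))
  post <- comfar:::reference_geometry(out$molecule)
  expect_equal(post$bond_length, ref$bond_length, tolerance = 1e-9)
  expect_equal(post$angles$theta0, ref$angles$theta0, tolerance = 1e-9)
})

test_that("annealing plus minimization reaches the global torsion basin", {
  # heavy-halide chain: a 1-D torsion scan (the oracle) shows a single
  # global basin at the anti conformation, separated by ~2 kcal/mol
  build <- function(phi) make_torsion_chain(c("I", "C", "C", "I"), phi = phi)
  scan_phi <- seq(0, 355, by = 5)
  scan_e <- vapply(scan_phi, function(p) energy(build(p)), numeric(1))
  phi_min <- scan_phi[which.min(scan_e)]
  expect_gt(abs(((phi_min + 180) %% 360) - 180), 120)  # oracle: anti
  start <- build(60)  # gauche start
  hits <- 0L
  for (s in 1:50) {
    a <- simulated_anneal(start, anneal_config(steps_hot = 300,
                                               steps_cold = 300, seed = s))
    m <- minimize(a$molecule, minimize_config(max_cycles = 200))$molecule
    xyz <- coords(m)
    phi <- abs(comfar:::dihedral_angle(xyz[1, ], xyz[2, ], xyz[3, ],
                                       xyz[4, ])) * 180 / pi
    if (phi > 120) hits <- hits + 1L
  }
  expect_gte(hits, 45L)  # >= 90% of seeds
})

test_that("atom fit recovers rigid transforms and rejects reflections", {
  sc <- scaffold_molecule()
  map <- cbind(1:9, 1:9)
  # identity fit
  fit0 <- atom_fit(sc, sc, map)
  expect_lt(fit0$rmsd, 1e-12)
  # random rigid copies are recovered essentially exactly
  set.seed(31)
  for (rep in 1:10) {
    R <- random_rotation()
    shift <- rnorm(3, sd = 8)
    posed <- set_coords(sc, sweep(coords(sc) %*% t(R), 2, shift, `+`))
    fit <- atom_fit(posed, sc, map)
    expect_lt(fit$rmsd, 1e-6)
    expect_equal(coords(fit$molecule), coords(sc), tolerance = 1e-6)
  }
  # a mirrored copy cannot be superposed by a proper rotation
  mirrored <- set_coords(sc, coords(sc) %*% diag(c(-1, 1, 1)))
  mirrored$atoms$z[1] <- 0.3  # break planarity so reflection is detectable
  ref <- sc
  ref$atoms$z[1] <- 0.3
  fit_m <- atom_fit(set_coords(ref, coords(ref) %*% diag(c(-1, 1, 1))),
                    ref, map)
  expect_gt(fit_m$rmsd, 1e-3)
})

test_that("atom fit never exceeds the unfitted RMSD and validates input", {
  sc <- scaffold_molecule()
  map <- cbind(1:9, 1:9)
  set.seed(32)
  for (rep in 1:10) {
    jitter <- set_coords(sc, coords(sc) + matrix(rnorm(27, sd = 0.4), 9, 3))
    rmsd_raw <- sqrt(mean(rowSums((coords(jitter) - coords(sc))^2)))
    fit <- atom_fit(jitter, sc, map)
    expect_lte(fit$rmsd, rmsd_raw + 1e-12)
  }
  expect_error(atom_fit(sc, sc, cbind(1:2, 1:2)), ">= 3")
  line <- molecule("line", data.frame(element = rep("C", 3),
                                      x = 0:2, y = 0, z = 0))
  expect_error(atom_fit(line, line, cbind(1:3, 1:3)), "collinear")
})

test_that("scaffold map files parse with comments and validation", {
  path <- tempfile()
  writeLines(c("# template  molecule", "1 1", "2 2", " 3   3 "), path)
  m <- read_scaffold_map(path)
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(m[, 1], c(1L, 2L, 3L), ignore_attr = TRUE)
  writeLines(c("1 2 3"), path)
  expect_error(read_scaffold_map(path), "two indices")
})
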