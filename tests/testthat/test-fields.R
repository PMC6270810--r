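single_atom <- function(el = "C", at = c(0, 0, 0), q = 0) {
  assign_vdw_params(molecule("one", data.frame(
    element = el, x = at[1], y = at[2], z = at[3], charge = q)))
}

test_that("grid construction snaps the padded bounding box outward", {
  g <- make_grid(single_atom(), spacing = 2, margin = 4)
  expect_equal(g$dims, c(5L, 5L, 5L))
  expect_equal(g$origin, c(-4, -4, -4))
  # translating the molecules translates the grid identically
  shifted <- single_atom(at = c(10, -6, 2))
  g2 <- make_grid(shifted, spacing = 2, margin = 4)
  expect_equal(g2$origin, c(6, -10, -2))
  expect_equal(g2$dims, g$dims)
  expect_error(make_grid(list()), "at least one")
})

test_that("every atom keeps at least the margin clearance inside the grid", {
  set.seed(41)
  mols <- lapply(1:2, function(k) assign_vdw_params(random_bonded_molecule(6)))
  g <- make_grid(mols, spacing = 2, margin = 4)
  lo <- g$origin
  hi <- g$origin + (g$dims - 1) * g$spacing
  for (m in mols) {
    xyz <- coords(m)
    expect_true(all(sweep(xyz, 2, lo) >= 4 - g$spacing - 1e-9))
    expect_true(all(sweep(-xyz, 2, -hi) >= 4 - g$spacing - 1e-9))
  }
})

test_that("steric energy follows the probe Lennard-Jones closed forms", {
  m <- single_atom()
  # at r* = probe radius + atom radius the energy is -sqrt(eps_probe eps_C)
  pt <- matrix(c(3.4, 0, 0), 1)
  expect_equal(steric_energy(pt, m), -0.107, tolerance = 1e-9)
  # at the atom center the cap applies
  expect_equal(steric_energy(matrix(0, 1, 3), m), 30)
  # decay: far away the energy vanishes
  expect_lt(abs(steric_energy(matrix(c(25, 0, 0), 1), m, cap = Inf)), 1e-4)
})

test_that("electrostatic energy is Coulomb with 1/d^2 and clamps", {
  m <- single_atom(q = 1)
  for (d in c(2, 3.5, 6))
    expect_equal(electrostatic_energy(matrix(c(d, 0, 0), 1), m, cap = Inf),
                 332.0 / d^2, tolerance = 1e-10)
  expect_equal(electrostatic_energy(matrix(c(0.5, 0, 0), 1), m), 30)
  neutral <- single_atom(q = 0)
  pts <- matrix(rnorm(30), 10)
  expect_equal(electrostatic_energy(pts, neutral), rep(0, 10))
})

test_that("lattice energies equal a naive double-loop oracle", {
  set.seed(42)
  n <- 10
  atoms <- data.frame(element = sample(c("C", "N", "O", "S"), n, TRUE),
                      x = runif(n, -3, 3), y = runif(n, -3, 3),
                      z = runif(n, -3, 3), charge = runif(n, -0.4, 0.4))
  m <- assign_vdw_params(molecule("toy", atoms))
  pts <- matrix(runif(60, -6, 6), 20)
  probe <- probe_spec()
  ste <- steric_energy(pts, m, probe, cap = Inf)
  ele <- electrostatic_energy(pts, m, probe, cap = Inf)
  for (p in 1:20) {
    es <- 0; ee <- 0
    for (i in 1:n) {
      d <- sqrt(sum((pts[p, ] - coords(m)[i, ])^2))
      rs <- probe$vdw_radius + m$atoms$vdw_radius[i]
      eps <- sqrt(probe$vdw_epsilon * m$atoms$vdw_epsilon[i])
      es <- es + eps * ((rs / d)^12 - 2 * (rs / d)^6)
      ee <- ee + 332.0 * m$atoms$charge[i] * probe$charge / d^2
    }
    expect_equal(ste[p], es, tolerance = 1e-10)
    expect_equal(ele[p], ee, tolerance = 1e-10)
  }
})

test_that("field matrices are equivariant under shared rigid transforms", {
  set.seed(43)
  mols <- lapply(1:3, function(k) {
    m <- assign_vdw_params(random_bonded_molecule(6))
    m$atoms$charge <- rnorm(6, sd = 0.3)
    m
  })
  g <- make_grid(mols, spacing = 2, margin = 3)
  fm <- build_field_matrix(mols, g, filter_sigma = 0)
  shift <- c(7, -3, 11)  # whole-spacing translation keeps lattice registry
  shift <- round(shift / g$spacing) * g$spacing
  moved <- lapply(mols, function(m)
    set_coords(m, sweep(coords(m), 2, shift, `+`)))
  g2 <- grid_spec(g$origin + shift, g$spacing, g$dims)
  fm2 <- build_field_matrix(moved, g2, filter_sigma = 0)
  expect_equal(fm2$steric, fm$steric, tolerance = 1e-9)
  expect_equal(fm2$electrostatic, fm$electrostatic, tolerance = 1e-9)
})

test_that("column filtering masks by standard deviation, monotonically", {
  set.seed(44)
  mols <- lapply(1:6, function(k) {
    m <- assign_vdw_params(random_bonded_molecule(5))
    m$atoms$charge <- rnorm(5, sd = 0.3)
    m
  })
  g <- make_grid(mols, spacing = 2.5, margin = 3)
  fm0 <- build_field_matrix(mols, g, filter_sigma = 0)
  # filter 0 masks nothing
  expect_true(all(fm0$keep_steric) && all(fm0$keep_electrostatic))
  # mask equals an independent recomputation of column deviations
  fm2 <- build_field_matrix(mols, g, filter_sigma = 2)
  expect_equal(fm2$keep_steric, apply(fm0$steric, 2, sd) >= 2)
  expect_equal(fm2$keep_electrostatic, apply(fm0$electrostatic, 2, sd) >= 2)
  # raising the filter never unmasks a column
  fm5 <- build_field_matrix(mols, g, filter_sigma = 5)
  expect_true(all(fm2$keep_steric | !fm5$keep_steric))
  expect_true(all(fm2$keep_electrostatic | !fm5$keep_electrostatic))
  # identical replicated molecules have zero deviation everywhere
  clones <- rep(mols[1], 4)
  expect_error(build_field_matrix(clones, g, filter_sigma = 2),
               "every column masked")
})

test_that("electrostatics at steric-excluded points use the column mean", {
  set.seed(45)
  mols <- lapply(1:4, function(k) {
    m <- assign_vdw_params(random_bonded_molecule(5))
    m$atoms$charge <- rnorm(5, sd = 0.4)
    m
  })
  g <- make_grid(mols, spacing = 2, margin = 2)
  fm <- build_field_matrix(mols, g, filter_sigma = 0)
  pts <- grid_points(g)
  excl <- fm$excluded
  expect_true(any(excl))  # points inside atoms exist
  for (j in which(colSums(excl) > 0 & colSums(excl) < nrow(excl))[1:5]) {
    raw <- vapply(which(!excl[, j]), function(mrow)
      electrostatic_energy(pts[j, , drop = FALSE], mols[[mrow]]), numeric(1))
    expect_equal(unique(fm$electrostatic[excl[, j], j]), mean(raw),
                 tolerance = 1e-9)
  }
})

test_that("descriptor assembly applies block weights and labels", {
  set.seed(46)
  mols <- lapply(1:5, function(k) {
    m <- assign_vdw_params(random_bonded_molecule(5))
    m$atoms$charge <- rnorm(5, sd = 0.3)
    m
  })
  fm <- build_field_matrix(mols, make_grid(mols, 2.5, 3), filter_sigma = 1)
  X_raw <- descriptor_matrix(fm, "none")
  X_sc <- descriptor_matrix(fm, "inverse_stdev")
  blk <- attr(X_raw, "block")
  expect_equal(sum(blk == "steric"), sum(fm$keep_steric))
  ws <- fm$block_weights
  expect_equal(X_sc[, blk == "steric"],
               X_raw[, blk == "steric"] * ws[["steric"]])
  expect_equal(X_sc[, blk == "electrostatic"],
               X_raw[, blk == "electrostatic"] * ws[["electrostatic"]])
})
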