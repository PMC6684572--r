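test_that("spring force matches hand-evaluated cases", {
  expect_equal(spring_force(c(0, 0), c(1, 0), 1, 0.9), c(0, 0))
  # stretched: pulled toward the partner, magnitude k * (|d| - L)
  expect_equal(spring_force(c(0, 0), c(2, 0), 1, 0.9), c(0.9, 0))
  # compressed: pushed away, positive magnitude under compression
  expect_equal(spring_force(c(0, 0), c(0.5, 0), 1, 0.9), c(-0.45, 0))
  # equal and opposite on the partner
  expect_equal(spring_force(c(2, 0), c(0, 0), 1, 0.9),
               -spring_force(c(0, 0), c(2, 0), 1, 0.9))
  expect_error(spring_force(c(1, 1), c(1, 1), 1, 0.9), "degenerate")
})

test_that("per-cell pressure forces act on outward normals and cancel over the cell", {
  tis <- build_lr_grid(2, 2, 1, 1)
  pf <- cell_pressure_forces(1, tis, 0.05)
  # cell 1 is the unit square (0,0)-(1,1); its left wall (0,1)->(0,0) has
  # outward normal (-1,0) and length 1: each endpoint gets (-0.025, 0)
  # from it; combined with the bottom/top wall the corners see both
  v00 <- which(rownames(pf) == "1")
  expect_equal(unname(pf[v00, ]), c(-0.025, -0.025))
  # closed-contour identity: contributions sum to zero
  expect_equal(colSums(pf), c(x = 0, y = 0))

  # linearity in wall length: doubling the cell doubles every magnitude
  tis2 <- build_lr_grid(2, 2, 2, 2)
  pf2 <- cell_pressure_forces(1, tis2, 0.05)
  expect_equal(unname(pf2), unname(pf) * 2)

  # degenerate polygon is refused
  bad <- tis
  bad$pos[2, ] <- bad$pos[1, ]
  expect_error(cell_pressure_forces(1, bad, 0.05), "degenerate")
})

test_that("total forces agree with a brute-force oracle on small meshes", {
  set.seed(42)
  for (rep in 1:5) {
    tis <- build_lr_grid(2, 2, 1, 1)
    tis$pos <- tis$pos + matrix(runif(18, -0.1, 0.1), 9, 2)
    tis$wall_rest <- tis$wall_rest * runif(length(tis$wall_rest), 0.8, 1.2)
    p <- mechanics_params()
    f <- total_forces(tis, p, zero_fixed = FALSE)
    expect_lt(max(abs(f - brute_force_forces(tis, p$p_const))), 1e-12)
  }
})

test_that("interior spring sums vanish on a rest grid; boundary pressure remains", {
  tis <- build_lr_grid(4, 3, 10, 10)
  p <- mechanics_params()
  f <- total_forces(tis, p, zero_fixed = FALSE)
  interior <- tis$v_col > 0 & tis$v_col < tis$n_cols &
    tis$v_row > 0 & tis$v_row < tis$n_rows
  # springs at rest and interior pressure cancels between flanking cells
  expect_lt(max(abs(f[interior, ])), 1e-12)
  expect_gt(max(abs(f[!interior, ])), 0.1)
})

test_that("Euler updates match hand-computed steps", {
  p <- mechanics_params(dt_mech = 0.01)
  tis <- make_raw_tissue(matrix(c(0, 0), 1, 2))
  # unit force from rest: Vel <- dt * F/m, position advances with new Vel
  out <- integrate_step(tis, p, forces = matrix(c(1, 0), 1, 2))
  expect_equal(out$vel[1, ], c(0.01, 0))
  expect_equal(out$pos[1, ], c(1e-4, 0))
  # damping-only update
  tis$vel[1, ] <- c(1, 0)
  out <- integrate_step(tis, p, forces = matrix(0, 1, 2))
  expect_equal(out$vel[1, 1], 0.998)
  # pure forward ordering advances with the old velocity
  pf <- mechanics_params(dt_mech = 0.01, euler = "forward")
  tis2 <- make_raw_tissue(matrix(c(0, 0), 1, 2))
  out2 <- integrate_step(tis2, pf, forces = matrix(c(1, 0), 1, 2))
  expect_equal(out2$pos[1, ], c(0, 0))
  expect_equal(out2$vel[1, ], c(0.01, 0))
})

test_that("fixed_x vertices never move in x under any force", {
  p <- mechanics_params(dt_mech = 0.01)
  tis <- make_raw_tissue(matrix(c(5, 1), 1, 2), fixed_x = TRUE)
  out <- integrate_step(tis, p, forces = matrix(c(100, 3), 1, 2))
  expect_identical(out$pos[1, 1], 5)
  expect_identical(out$vel[1, 1], 0)
  expect_gt(out$pos[1, 2], 1)

  tis <- build_lr_grid(4, 2, 10, 10)
  r <- relax_to_equilibrium(tis, mechanics_params())
  expect_equal(r$tissue$pos[tis$fixed_x, 1], tis$pos[tis$fixed_x, 1])
})

test_that("a single stretched spring relaxes to its resting length", {
  p <- mechanics_params()
  for (engine in c("cpp", "r")) {
    tis <- make_raw_tissue(matrix(c(0, 0, 2, 0), 2, 2, byrow = TRUE),
                           from = 1, to = 2, rest = 1)
    r <- relax_to_equilibrium(tis, p, engine = engine)
    len <- sqrt(sum((r$tissue$pos[2, ] - r$tissue$pos[1, ])^2))
    expect_equal(len, 1, tolerance = 10 * p$equilibrium_tol)
    expect_lt(r$residual_force, p$equilibrium_tol)
    expect_lt(r$residual_velocity, p$equilibrium_tol)
  }
})

test_that("an already-relaxed mesh needs no further iterations", {
  tis <- build_lr_grid(4, 2, 10, 10)
  p <- mechanics_params()
  relaxed <- relax_to_equilibrium(tis, p)$tissue
  again <- relax_to_equilibrium(relaxed, p)
  expect_identical(again$iterations, 0L)
  expect_identical(again$tissue$pos, relaxed$pos)
})

test_that("compiled and reference relaxation engines agree", {
  tis <- assign_zones(build_lr_grid(4, 2, 10, 10), 10)
  p <- mechanics_params(dt_mech = 0.1)
  rc <- relax_to_equilibrium(tis, p, engine = "cpp")
  rr <- relax_to_equilibrium(tis, p, engine = "r")
  # identical update rule; only float summation order differs
  expect_lte(abs(rc$iterations - rr$iterations), 1L)
  expect_lt(max(abs(rc$tissue$pos - rr$tissue$pos)),
            10 * p$equilibrium_tol)
})

test_that("the relaxed configuration does not depend on the damping constant", {
  tis <- build_lr_grid(5, 3, 10, 10)
  tol <- 1e-6
  ref <- NULL
  for (beta in c(0.05, 0.2, 0.5)) {
    p <- mechanics_params(beta = beta, dt_mech = 0.05,
                          equilibrium_tol = tol, max_relax_iters = 5e5)
    r <- relax_to_equilibrium(tis, p)
    if (is.null(ref)) ref <- r$tissue$pos
    else expect_lt(max(abs(r$tissue$pos - ref)), 10 * tol)
  }
})

test_that("forces are invariant under a rigid y-translation", {
  tis <- build_lr_grid(4, 3, 10, 10)
  set.seed(7)
  tis$pos <- tis$pos + matrix(runif(nrow(tis$pos) * 2, -1, 1),
                              ncol = 2)
  p <- mechanics_params()
  f0 <- total_forces(tis, p)
  tis$pos[, 2] <- tis$pos[, 2] + 13.7
  expect_equal(total_forces(tis, p), f0)
})

test_that("the force field is mirror-symmetric for a mirror-symmetric tissue", {
  tis <- build_lr_grid(6, 4, 10, 10)
  H <- tis$n_rows * tis$cell_height
  set.seed(11)
  # perturb the lower half and mirror the perturbation to the upper half;
  # the midline row gets no y-perturbation so the tissue stays symmetric
  pert <- matrix(runif(nrow(tis$pos) * 2, -0.5, 0.5), ncol = 2)
  mirror_of <- (tis$n_rows - tis$v_row) * (tis$n_cols + 1L) + tis$v_col + 1L
  pert[tis$v_row == tis$n_rows / 2, 2] <- 0
  lower <- tis$v_row < tis$n_rows / 2
  pert[mirror_of[lower], 1] <- pert[lower, 1]
  pert[mirror_of[lower], 2] <- -pert[lower, 2]
  tis$pos <- tis$pos + pert
  f <- total_forces(tis, mechanics_params(), zero_fixed = FALSE)
  expect_lt(max(abs(f[mirror_of, 1] - f[, 1])), 1e-10)
  expect_lt(max(abs(f[mirror_of, 2] + f[, 2])), 1e-10)
})

test_that("mechanical energy dissipates during relaxation", {
  tis <- build_lr_grid(3, 2, 10, 10)
  set.seed(3)
  tis$pos <- tis$pos + matrix(runif(nrow(tis$pos) * 2, -0.5, 0.5), ncol = 2)
  p <- mechanics_params(dt_mech = 0.05)
  energies <- numeric(2001)
  energies[1] <- rootbend:::mech_energy(tis, p)
  for (i in 1:2000) {
    tis <- integrate_step(tis, p)
    energies[i + 1] <- rootbend:::mech_energy(tis, p)
  }
  expect_true(all(diff(energies) <= 1e-6))  # first-order Euler slack
  r <- relax_to_equilibrium(tis, p)
  kinetic <- 0.5 * p$mass * sum(r$tissue$vel^2)
  expect_lt(kinetic, p$equilibrium_tol^2 * nrow(tis$pos))
})

test_that("unreachable tolerances raise non-convergence errors", {
  tis <- make_raw_tissue(matrix(c(0, 0, 2, 0), 2, 2, byrow = TRUE),
                         from = 1, to = 2, rest = 1)
  p0 <- mechanics_params(equilibrium_tol = 0, max_relax_iters = 2000)
  expect_error(relax_to_equilibrium(tis, p0), "did not converge")
  p1 <- mechanics_params(max_relax_iters = 3)
  expect_error(relax_to_equilibrium(tis, p1, engine = "r"), "residual")
})

test_that("parameter validation enforces positivity and the stability bound", {
  expect_error(mechanics_params(k_x = 0), "positive")
  expect_error(mechanics_params(beta = -0.1), "positive")
  expect_error(mechanics_params(dt_mech = 0.5), "stability")
  expect_silent(mechanics_params(dt_mech = 0.01))
})
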