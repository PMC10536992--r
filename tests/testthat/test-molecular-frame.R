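test_that("normal modes of a harmonic diatomic give the textbook frequency", {
  k <- 0.3; m <- 2000
  sys <- molecular_system(c("X", "X"), c(0, 0, 0, 2, 0, 0), masses = c(m, m))
  surf <- build_spring_network_surface(sys$equilibrium_geometry,
                                       matrix(c(0, k, k, 0), 2))
  nm <- compute_normal_modes(sys, surf)
  expect_equal(nm$n_projected, 5L)          # linear molecule
  expect_equal(nm$n_vibrational, 1L)
  expect_equal(nm$frequencies, sqrt(2 * k / m), tolerance = 1e-10)
  expect_false(any(nm$imaginary))
})

test_that("a nonlinear 16-atom system has 42 vibrational modes", {
  mol <- make_spring_molecule(16, seed = 3)
  nm <- compute_normal_modes(mol$system, mol$surface)
  expect_equal(nm$n_projected, 6L)
  expect_equal(nm$n_vibrational, 42L)
  expect_false(any(nm$imaginary))
  # mode matrix orthonormal
  g <- crossprod(nm$mode_matrix)
  expect_lt(max(abs(g - diag(42))), 1e-10)
  # Eckart projection: the 6 projected directions are zero modes of the
  # mass-weighted Hessian
  m3 <- nm$masses3
  hmw <- mol$surface$hessian_at(mol$system$equilibrium_geometry) / sqrt(m3 %o% m3)
  expect_lt(max(abs(hmw %*% nm$tr_matrix)), 1e-10)
})

test_that("frequencies are invariant under rigid rotation of the geometry", {
  mol <- make_spring_molecule(6, seed = 5)
  nm0 <- compute_normal_modes(mol$system, mol$surface)
  set.seed(42)
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])), c(0, sin(th[1]), cos(th[1])))
  Rz <- rbind(c(cos(th[2]), -sin(th[2]), 0), c(sin(th[2]), cos(th[2]), 0), c(0, 0, 1))
  R <- Rz %*% Rx
  geom_rot <- as.numeric(R %*% matrix(mol$system$equilibrium_geometry, nrow = 3))
  sys_rot <- molecular_system(mol$system$atom_labels, geom_rot,
                              masses = mol$system$masses)
  surf_rot <- build_spring_network_surface(geom_rot, mol$surface$spring_constants)
  nm_rot <- compute_normal_modes(sys_rot, surf_rot)
  expect_equal(nm_rot$frequencies, nm0$frequencies, tolerance = 1e-8)
})

test_that("2-DOF quadratic H = [[2,1],[1,2]] has frequencies {1, sqrt(3)}", {
  # no projection needed: diagonalize the surface Hessian directly
  s <- build_harmonic_surface(matrix(c(2, 1, 1, 2), 2))
  lam <- eigen(s$hessian_at(c(0, 0)), symmetric = TRUE)$values
  expect_equal(sort(sqrt(lam)), c(1, sqrt(3)))
})

test_that("coordinate transforms are exact and mode displacements map to unit vectors", {
  mol <- make_spring_molecule(5, seed = 9)
  nm <- compute_normal_modes(mol$system, mol$surface)
  x0 <- mol$system$equilibrium_geometry
  expect_equal(to_normal_coordinates(nm, x0), rep(0, nm$n_vibrational))

  set.seed(1)
  x <- x0 + rnorm(length(x0), 0, 0.02)
  q <- to_normal_coordinates(nm, x, include_tr = TRUE)
  expect_equal(to_cartesian_coordinates(nm, q, include_tr = TRUE), x,
               tolerance = 1e-10)

  # displacement along mode j scaled by c -> normal coordinates c * e_j
  j <- 4L; cmag <- 0.37
  xj <- x0 + cmag * nm$mode_matrix[, j] / sqrt(nm$masses3)
  qj <- to_normal_coordinates(nm, xj)
  expect_equal(qj, cmag * as.numeric(seq_len(nm$n_vibrational) == j),
               tolerance = 1e-10)

  expect_error(to_normal_coordinates(nm, x0[-1]), "length")
})

test_that("normal-mode surface view matches the Cartesian surface", {
  mol <- make_spring_molecule(4, seed = 8)
  nm <- compute_normal_modes(mol$system, mol$surface)
  s <- normal_mode_surface(nm, mol$surface)
  expect_equal(s$dof_count, nm$n_vibrational)
  expect_equal(s$energy_at(rep(0, s$dof_count)), 0, tolerance = 1e-12)
  # harmonic expansion: Hessian at equilibrium is diag(omega^2)
  h0 <- s$hessian_at(rep(0, s$dof_count))
  expect_equal(h0, diag(nm$frequencies^2), tolerance = 1e-10)
  set.seed(2)
  q <- rnorm(s$dof_count, 0, 0.1)
  expect_equal(s$energy_at(q),
               mol$surface$energy_at(to_cartesian_coordinates(nm, q)))
  expect_equal(finite_difference_hessian(s, q, 1e-5), s$hessian_at(q),
               tolerance = 1e-5)
})

test_that("ZPE initial conditions give kinetic energy omega/2 per mode and zero force", {
  st <- zpe_initial_state(1)
  expect_equal(st$p, 1)
  expect_equal(0.5 * st$p^2, 0.5)

  st2 <- zpe_initial_state(c(1, 4))
  expect_equal(0.5 * sum(st2$p^2), 2.5)
  expect_equal(st2$q, c(0, 0))
  expect_equal(st2$f_tilde, c(0, 0))

  st3 <- zpe_initial_state(c(1, 4), signs = c(-1, 1))
  expect_equal(st3$p, c(-1, 2))
  expect_error(zpe_initial_state(c(1, -1)), "positive")

  mol <- make_spring_molecule(4, seed = 1)
  nm <- compute_normal_modes(mol$system, mol$surface)
  st4 <- zpe_initial_state(nm)
  expect_equal(st4$p, sqrt(nm$frequencies))
})

test_that("XYZ files round-trip through the reader and writer", {
  sys <- molecular_system(c("O", "H", "H"),
                          c(0, 0, 0.22, 0, 1.43, -0.89, 0, -1.43, -0.89))
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(sys, sys$equilibrium_geometry, path, comments = "water")
  back <- read_xyz(path)
  expect_equal(back$atom_labels, sys$atom_labels)
  expect_equal(back$equilibrium_geometry, sys$equilibrium_geometry,
               tolerance = 1e-9)
  expect_equal(attr(back, "comment"), "water")

  # multi-frame: 10 frames x (2 + 3) lines
  frames <- t(vapply(1:10, function(i) sys$equilibrium_geometry + 0.01 * i,
                     numeric(9)))
  write_xyz(sys, frames, path)
  expect_length(readLines(path), 50L)
  multi <- read_xyz(path)
  expect_equal(nrow(multi$frames), 10L)
  expect_equal(multi$frames[10, ], sys$equilibrium_geometry + 0.1,
               tolerance = 1e-9)

  expect_error(write_xyz(sys, c(0, NA, rep(0, 7)), path), "non-finite")
})
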