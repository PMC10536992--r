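test_that("pair scaling matches the 3-DOF partially decoupled structure", {
  h <- matrix(c(4, 1, 2,
                1, 5, 3,
                2, 3, 6), 3, byrow = TRUE)
  alpha <- 0.3
  spec <- decoupling_spec(list(list(a = c(1, 2), b = 3, alpha = alpha)))
  ht <- scale_hessian_pairs(h, spec)
  expected <- matrix(c(4, 1, alpha * 2,
                       1, 5, alpha * 3,
                       alpha * 2, alpha * 3, 6), 3, byrow = TRUE)
  expect_equal(ht, expected)
})

test_that("alpha = 1 is the identity and alpha = 0 fully separates", {
  h <- matrix(c(4, 1, 1, 3), 2)
  s1 <- decoupling_spec(list(list(a = 1, b = 2, alpha = 1)))
  expect_equal(scale_hessian_pairs(h, s1), h)
  s0 <- decoupling_spec(list(list(a = 1, b = 2, alpha = 0)))
  expect_equal(scale_hessian_pairs(h, s0), diag(c(4, 3)))
})

test_that("scaling preserves symmetry and trace for arbitrary specs", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(3:8, 1)
    h <- matrix(rnorm(n * n), n); h <- h + t(h)
    ga <- sample(n, sample(1:(n - 1), 1))
    rest <- setdiff(seq_len(n), ga)
    gb <- rest[sample(length(rest), 1)]
    spec <- decoupling_spec(list(list(a = ga, b = gb, alpha = runif(1))))
    ht <- scale_hessian_pairs(h, spec)
    expect_identical(sum(diag(ht)), sum(diag(h)))
    expect_identical(ht, t(ht))
  }
})

test_that("spec validation rejects bad groups, alphas and overlaps", {
  expect_error(decoupling_spec(list(list(a = 1, b = 1, alpha = 0.5))), "disjoint")
  expect_error(decoupling_spec(list(list(a = 1, b = 2, alpha = 1.2))), "alpha")
  expect_error(decoupling_spec(list(list(a = 0, b = 2, alpha = 0.5))), "1-based")
  # contradictory alpha on the same element
  spec <- decoupling_spec(list(list(a = 1, b = 2, alpha = 0.2),
                               list(a = 1, b = 2, alpha = 0.7)))
  expect_error(scale_hessian_pairs(diag(2), spec), "contradictory")
  # same alpha twice is fine; disjoint pairs compose
  spec2 <- decoupling_spec(list(list(a = 1, b = 2, alpha = 0.5),
                                list(a = 3, b = 4, alpha = 0)))
  h <- matrix(1, 4, 4) + diag(4)
  ht <- scale_hessian_pairs(h, spec2)
  expect_equal(ht[1, 2], 0.5)
  expect_equal(ht[3, 4], 0)
  expect_equal(ht[1, 3], 1)
  expect_error(scale_hessian_pairs(diag(2),
                                   decoupling_spec(list(list(a = 1, b = 5, alpha = 0)))),
               "out of range")
})

test_that("Cartesian atom decoupling is the rotate-scale-rotate triple product", {
  mol <- make_spring_molecule(4, seed = 2)
  nm <- compute_normal_modes(mol$system, mol$surface)
  nvib <- nm$n_vibrational
  set.seed(17)
  h_nm <- matrix(rnorm(nvib^2), nvib); h_nm <- (h_nm + t(h_nm)) / 2

  spec1 <- decoupling_spec(list(list(a = 1, b = 2, alpha = 1)),
                           frame = "cartesian_atoms")
  expect_equal(cartesian_atom_decoupled_hessian(h_nm, nm, spec1), h_nm,
               tolerance = 1e-12)

  # explicit triple product oracle for alpha = 0.5 on one atom pair
  spec <- decoupling_spec(list(list(a = 2, b = 3, alpha = 0.5)),
                          frame = "cartesian_atoms")
  U <- nm$mode_matrix
  hc <- U %*% h_nm %*% t(U)
  ia <- 4:6; ib <- 7:9
  hc[ia, ib] <- 0.5 * hc[ia, ib]; hc[ib, ia] <- 0.5 * hc[ib, ia]
  oracle <- t(U) %*% hc %*% U
  expect_equal(cartesian_atom_decoupled_hessian(h_nm, nm, spec),
               (oracle + t(oracle)) / 2, tolerance = 1e-12)

  expect_error(cartesian_atom_decoupled_hessian(
    h_nm, nm, decoupling_spec(list(list(a = 1, b = 9, alpha = 0)),
                              frame = "cartesian_atoms")),
    "out of range")
})

test_that("alpha = 0 decoupling of all atom pairs of a 2-atom system zeroes the cross blocks", {
  k <- 0.2; m <- 1800
  sys <- molecular_system(c("X", "X"), c(0, 0, 0, 2.5, 0, 0), masses = c(m, m))
  surf <- build_spring_network_surface(sys$equilibrium_geometry,
                                       matrix(c(0, k, k, 0), 2))
  nm <- compute_normal_modes(sys, surf)
  h_nm <- diag(nm$frequencies^2, nm$n_vibrational)
  spec <- decoupling_spec(list(list(a = 1, b = 2, alpha = 0)),
                          frame = "cartesian_atoms")
  ht <- cartesian_atom_decoupled_hessian(h_nm, nm, spec)
  # oracle: scale in the Cartesian frame (cross blocks exactly zeroed
  # there), rotate back through the vibrational basis
  U <- nm$mode_matrix
  hc <- U %*% h_nm %*% t(U)
  hc[1:3, 4:6] <- 0; hc[4:6, 1:3] <- 0
  expect_equal(ht, (t(U) %*% hc %*% U + t(t(U) %*% hc %*% U)) / 2,
               tolerance = 1e-13)
})

test_that("mode freezing clamps exactly the frozen components", {
  st <- phase_state(q = c(0.1, 0.2, 0.3), p = c(1, 2, 3),
                    f_tilde = c(-1, -2, -3))
  spec0 <- decoupling_spec()
  expect_identical(apply_mode_freezing(st, spec0), st)

  spec <- decoupling_spec(frozen_modes = 2L)
  out <- apply_mode_freezing(st, spec)
  expect_identical(out$q, c(0.1, 0, 0.3))
  expect_identical(out$p, c(1, 0, 3))
  expect_identical(out$f_tilde, c(-1, 0, -3))

  # frozen throughout a propagation: mode stays at equilibrium, zero KE
  s <- soft_quadratic_2d()
  tr <- propagate(phase_state(c(0, 0), c(0.01, 0.02)), s, "SEF2", 200, 10,
                  spec = decoupling_spec(frozen_modes = 2L))
  expect_identical(max(abs(tr$q[, 2])), 0)
  expect_identical(max(abs(tr$p[, 2])), 0)
})
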