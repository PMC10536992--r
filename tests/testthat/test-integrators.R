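test_that("scheme registry returns the exact closed-form coefficients", {
  s2 <- get_scheme("SEF2")
  expect_equal(s2$a, c(1 / 2, 1 / 2))
  expect_equal(s2$b, c(0, 1))
  expect_equal(s2$c, s2$a)
  expect_true(s2$needs_hessian)

  s4 <- get_scheme("SEF4")
  x13 <- 2^(1 / 3); xm <- 2^(-1 / 3)
  expect_equal(s4$a[1], (x13 + xm + 2) / 6)
  expect_equal(s4$a[2], -(x13 + xm - 1) / 6)
  expect_equal(s4$a, rev(s4$a))                       # time-symmetric
  expect_equal(s4$b[1], 0)
  expect_equal(s4$b[2], (2^(4 / 3) + 2^(2 / 3) + 4) / 6)
  expect_equal(s4$b[3], -(2^(7 / 3) + 2^(5 / 3) + 2) / 6)
  expect_identical(s4$c, s4$a)

  for (nm in c("SE2", "SE4", "SEF2", "SEF4")) {
    s <- get_scheme(nm)
    expect_lt(abs(sum(s$a) - 1), 1e-14)
    expect_lt(abs(sum(s$b) - 1), 1e-14)
    expect_identical(s$b[1], 0)
  }
  expect_error(get_scheme("SEF6"), "available")
})

test_that("free particle: SEF propagates straight-line motion with zero force", {
  zero <- build_harmonic_surface(matrix(0, 2, 2))
  st <- phase_state(q = c(1, -1), p = c(0.3, 0.1))
  out <- sef_step(st, zero, get_scheme("SEF2"), dt = 10)
  expect_equal(out$q, c(1, -1) + 10 * c(0.3, 0.1))
  expect_equal(out$p, c(0.3, 0.1))
  expect_equal(out$f_tilde, c(0, 0))
  expect_equal(out$q_hat, out$q)
})

test_that("SEF2 on quadratics reproduces the leapfrog trajectory step for step", {
  s <- soft_quadratic_2d()
  init <- quadratic_initial(s, c(0.3, -0.2), c(0.01, 0.02))
  tr <- propagate(init, s, "SEF2", 3000, dt = 10)
  lf <- leapfrog_trajectory(function(q) -s$gradient_at(q),
                            init$q, init$p, 10, 3000)
  expect_lt(max(abs(tr$q - lf$q)), 1e-12)
  expect_lt(max(abs(tr$p - lf$p)), 1e-12)
})

test_that("the SEF force estimate is exact on quadratic surfaces at every step", {
  s <- soft_quadratic_2d()
  H <- s$hessian_at(c(0, 0))
  init <- quadratic_initial(s, c(0.3, -0.2), c(0.01, 0.02))
  for (nm in c("SEF2", "SEF4")) {
    st <- init
    scheme <- get_scheme(nm)
    for (i in 1:50) {
      st <- sef_step(st, s, scheme, 10)
      expect_lt(max(abs(st$f_tilde + H %*% st$q)), 1e-13)
      expect_equal(st$q_hat, st$q)                 # c = a schemes
    }
  }
})

test_that("alpha = 0 block decoupling equals independent per-block propagation", {
  H <- matrix(c(1.0e-4, 2.0e-5, 1.0e-5,
                2.0e-5, 2.0e-4, 1.5e-5,
                1.0e-5, 1.5e-5, 3.0e-4), 3, byrow = TRUE)
  s <- build_harmonic_surface(H)
  spec0 <- decoupling_spec(list(list(a = c(1, 2), b = 3, alpha = 0)))
  init <- phase_state(c(0, 0, 0), sqrt(sqrt(diag(H))))
  Hb <- H; Hb[1:2, 3] <- 0; Hb[3, 1:2] <- 0
  for (nm in c("SEF2", "SEF4")) {
    joint <- propagate(init, s, nm, 500, 10, spec = spec0)
    blocks <- propagate(init, build_harmonic_surface(Hb), nm, 500, 10)
    expect_lt(max(abs(joint$q - blocks$q)), 1e-12)
    expect_lt(max(abs(joint$p - blocks$p)), 1e-12)
  }
})

test_that("SE2 conserves energy over many periods on a harmonic oscillator", {
  w <- 0.01
  s <- build_harmonic_surface(matrix(w^2, 1, 1))
  period <- 2 * pi / w
  tr <- propagate(phase_state(1, 0), s, "SE2", 100 * 1000, dt = period / 1000,
                  record_energy = TRUE)
  e <- tr$energy
  # leapfrog: bounded oscillation of order (omega dt)^2 / 8 ~ 5e-6, no drift
  expect_lt(max(abs(e - e[1])) / e[1], 1e-5)
  expect_lt(abs(energy_series(tr)$drift_slope), 1e-12)
})

test_that("measured convergence orders match the nominal scheme orders", {
  morse <- build_morse_surface(0.1, 1.0)
  oc <- lapply(c(SE2 = "SE2", SE4 = "SE4", SEF2 = "SEF2", SEF4 = "SEF4"),
               check_order_conditions, surface = morse)
  expect_equal(oc$SE2$measured_order, 2.0, tolerance = 0.2)
  expect_equal(oc$SEF2$measured_order, 2.0, tolerance = 0.2)
  expect_equal(oc$SE4$measured_order, 4.0, tolerance = 0.3)
  expect_equal(oc$SEF4$measured_order, 4.0, tolerance = 0.3)
  for (r in oc) {
    expect_true(r$sum_a_ok)
    expect_true(r$sum_b_ok)
  }
  expect_true(oc$SEF2$second_order_unique)

  # perturbing a_1 breaks consistency: measured order collapses
  bad <- get_scheme("SE2")
  bad$a[1] <- bad$a[1] + 0.01
  expect_lt(check_order_conditions(bad, surface = morse)$measured_order, 1.5)
})

test_that("SE4 matches a high-accuracy ODE reference at fourth order", {
  morse <- build_morse_surface(0.1, 1.0)
  init <- phase_state(0.3, 0.1)
  tf <- 40
  ref <- ode_reference(morse, init$q, init$p, tf)
  err <- vapply(c(0.4, 0.2, 0.1), function(dt) {
    tr <- propagate(init, morse, "SE4", round(tf / dt), dt, record_energy = FALSE)
    max(abs(c(tr$final_state$q, tr$final_state$p) - ref))
  }, numeric(1))
  slope <- coef(lm(log(err) ~ log(c(0.4, 0.2, 0.1))))[[2]]
  expect_equal(slope, 4.0, tolerance = 0.3)
})

test_that("propagation is deterministic and counts its Hessian evaluations", {
  fx <- make_fixture("triatomic_morse_bend", 4)
  init <- phase_state(c(0, 0, 0), c(0.05, 0.04, 0.06))
  t1 <- propagate(init, fx$surface, "SEF2", 100, 10)
  t2 <- propagate(init, fx$surface, "SEF2", 100, 10)
  expect_identical(t1$q, t2$q)
  expect_identical(t1$p, t2$p)
  expect_identical(t1$hessian_calls, 200L)          # 2 per step
  expect_identical(t1$gradient_calls, 0L)           # never the gradient
  t4 <- propagate(init, fx$surface, "SEF4", 100, 10)
  expect_identical(t4$hessian_calls, 600L)          # 6 per step (3 SEF2 blocks)
  tse <- propagate(init, fx$surface, "SE2", 100, 10)
  expect_identical(tse$gradient_calls, 100L)
  expect_identical(tse$hessian_calls, 0L)
})

test_that("propagate validates inputs and aborts on non-finite states", {
  s <- soft_quadratic_2d()
  init <- phase_state(c(0, 0), c(0.01, 0.01))
  expect_error(propagate(init, s, "SEF2", 100, 10, discard_steps = 100),
               "discard")
  expect_error(propagate(phase_state(0, 0.1), s, "SEF2", 10, 10), "dimension")
  expect_error(propagate(init, s, "SEF2", 10, dt = -1), "positive")
  # 0 steps -> initial state only
  tr0 <- propagate(init, s, "SEF2", 0, 10)
  expect_equal(nrow(tr0$q), 1L)
  expect_equal(tr0$q[1, ], init$q)
  # unstable frequency at this dt blows up and is caught with a step index
  stiff <- build_harmonic_surface(matrix(1, 1, 1))  # omega = 1, dt = 10
  expect_error(propagate(phase_state(0.1, 0), stiff, "SE2", 1000, 10),
               "step")
  expect_error(sef_step(init, s, get_scheme("SE2"), 10), "gradient-based")
  expect_error(se_step(init, s, get_scheme("SEF2"), 10), "Hessian-driven")
})
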