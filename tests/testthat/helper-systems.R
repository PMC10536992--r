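# shared model systems, built in code at test time

# 2x2 coupled quadratic with molecular-range frequencies (~22-35 cm^-1
# coupling-split soft modes): stable at dt = 10 au
soft_quadratic_2d <- function() {
  H <- matrix(c(1e-4, 2e-5, 2e-5, 2.5e-4), 2)
  build_harmonic_surface(H)
}

# consistent SEF initial state on a quadratic surface
quadratic_initial <- function(surface, q0, p0) {
  phase_state(q = q0, p = p0, f_tilde = -surface$gradient_at(q0))
}

# independent position-Verlet (drift-kick-drift) oracle, written against
# the force function directly
leapfrog_trajectory <- function(force, q0, p0, dt, n_steps) {
  q <- q0; p <- p0
  Q <- matrix(NA_real_, n_steps + 1L, length(q0)); P <- Q
  Q[1L, ] <- q; P[1L, ] <- p
  for (i in seq_len(n_steps)) {
    qh <- q + dt / 2 * p
    p <- p + dt * force(qh)
    q <- qh + dt / 2 * p
    Q[i + 1L, ] <- q; P[i + 1L, ] <- p
  }
  list(q = Q, p = P)
}

# high-accuracy reference trajectory via deSolve (independent oracle)
ode_reference <- function(surface, q0, p0, t_final) {
  deriv <- function(t, y, parms) {
    n <- length(y) / 2
    q <- y[seq_len(n)]; p <- y[n + seq_len(n)]
    list(c(p, -surface$gradient_at(q)))
  }
  out <- deSolve::ode(c(q0, p0), c(0, t_final), deriv, NULL,
                      method = "lsoda", rtol = 1e-12, atol = 1e-13)
  unname(out[2, -1])
}
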