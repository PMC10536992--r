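#' Integrator coefficient sets
#'
#' Returns the named symplectic scheme as exact closed-form coefficient
#' vectors `a` (drifts), `b` (kicks) and, for SEF schemes, `c` (auxiliary
#' drifts feeding the force integration).  All schemes satisfy
#' `sum(a) = sum(b) = 1`.
#'
#' Available schemes:
#' \describe{
#'   \item{SE2}{second-order symplectic leapfrog (position Verlet),
#'     gradient-based: `a = (1/2, 1/2)`, `b = (0, 1)`.}
#'   \item{SE4}{fourth-order Forest-Ruth composition, gradient-based.}
#'   \item{SEF2}{second-order Symplectic Explicit with Force: leapfrog
#'     `a`, `b` with `c = a`; the unique second-order solution with
#'     `b[1] = 0` is `b = (0, 1)`, `a = c = (1/2, 1/2)`.}
#'   \item{SEF4}{fourth-order SEF, a symmetric product of three SEF2 maps
#'     with Forest-Ruth `a`, `b` and `c = a`.}
#' }
#'
#' @param name scheme name (case-insensitive).
#' @return object of class `integrator_scheme` with fields `name`, `order`,
#'   `a`, `b`, `c`, `needs_hessian`.
#' @examples
#' get_scheme("SEF2")$a  # 0.5 0.5
#' @export
get_scheme <- function(name) {
  key <- toupper(name)
  # Forest-Ruth coefficients, kick-then-drift arrangement with b[1] = 0
  x13 <- 2^(1 / 3); xm13 <- 2^(-1 / 3)
  fr_a <- c((x13 + xm13 + 2) / 6, -(x13 + xm13 - 1) / 6,
            -(x13 + xm13 - 1) / 6, (x13 + xm13 + 2) / 6)
  fr_b <- c(0, (2^(4 / 3) + 2^(2 / 3) + 4) / 6,
            -(2^(7 / 3) + 2^(5 / 3) + 2) / 6, (2^(4 / 3) + 2^(2 / 3) + 4) / 6)
  theta <- 1 / (2 - x13)
  # SEF stage programs: "d" = drift segment (with one midpoint Hessian
  # sample integrating the force), "k" = kick.  SEF4 is the symmetric
  # product of three SEF2 leapfrog blocks; its drift segments are kept
  # unmerged because the force quadrature must follow the composition
  # structure for the map to stay fourth order.
  sef2_stages <- list(list("d", 1 / 2), list("k", 1), list("d", 1 / 2))
  block <- function(g) list(list("d", g / 2), list("k", g), list("d", g / 2))
  sef4_stages <- c(block(theta), block(1 - 2 * theta), block(theta))
  schemes <- list(
    SE2  = list(order = 2L, a = c(1 / 2, 1 / 2), b = c(0, 1), c = NULL,
                needs_hessian = FALSE, stages = NULL),
    SE4  = list(order = 4L, a = fr_a, b = fr_b, c = NULL,
                needs_hessian = FALSE, stages = NULL),
    SEF2 = list(order = 2L, a = c(1 / 2, 1 / 2), b = c(0, 1),
                c = c(1 / 2, 1 / 2), needs_hessian = TRUE,
                stages = sef2_stages),
    SEF4 = list(order = 4L, a = fr_a, b = fr_b, c = fr_a,
                needs_hessian = TRUE, stages = sef4_stages))
  if (!key %in% names(schemes))
    stop("unknown scheme '", name, "'; available: ",
         paste(names(schemes), collapse = ", "), call. = FALSE)
  s <- schemes[[key]]
  structure(list(name = key, order = s$order, a = s$a, b = s$b, c = s$c,
                 needs_hessian = s$needs_hessian, stages = s$stages),
            class = "integrator_scheme")
}

#' @export
print.integrator_scheme <- function(x, ...) {
  cat(sprintf("<integrator_scheme> %s (order %d, %s)\n", x$name, x$order,
              if (x$needs_hessian) "Hessian-driven" else "gradient-based"))
  cat("  a:", format(x$a, digits = 15), "\n  b:", format(x$b, digits = 15), "\n")
  if (!is.null(x$c)) cat("  c:", format(x$c, digits = 15), "\n")
  invisible(x)
}

#' Phase-space state
#'
#' Holds the mass-scaled coordinates `q`, conjugate momenta `p` (unit
#' mass), the propagated force estimate `f_tilde` (SEF schemes; the force
#' is never evaluated from the gradient), the auxiliary position `q_hat`
#' at which the Hessian is sampled (it tracks the time argument of the
#' momentum, and coincides with `q` at full-step boundaries whenever
#' `c = a`), and the time `t` (au).
#'
#' @param q,p numeric vectors of equal length.
#' @param f_tilde propagated force estimate; defaults to zero, consistent
#'   with starting at an energy minimum.
#' @param q_hat auxiliary position; defaults to `q`.
#' @param t time, au.
#' @return object of class `phase_state`.
#' @export
phase_state <- function(q, p, f_tilde = NULL, q_hat = NULL, t = 0) {
  q <- as.numeric(q); p <- as.numeric(p)
  if (length(q) != length(p)) stop("q and p lengths differ", call. = FALSE)
  if (is.null(f_tilde)) f_tilde <- numeric(length(q))
  if (is.null(q_hat)) q_hat <- q
  stopifnot(length(f_tilde) == length(q), length(q_hat) == length(q))
  structure(list(q = q, p = p, f_tilde = as.numeric(f_tilde),
                 q_hat = as.numeric(q_hat), t = t),
            class = "phase_state")
}

#' @export
print.phase_state <- function(x, ...) {
  cat(sprintf("<phase_state> %d dof at t = %g au\n", length(x$q), x$t))
  invisible(x)
}

#' One SEF step: force propagation by Hessian time-integration
#'
#' Advances the state by one time step of the Symplectic Explicit with
#' Force map, a sequence of kicks and drift segments.  A kick advances the
#' momentum with the current force estimate, `p <- p + b dt f_tilde`; a
#' drift segment of span `s` advances the positions, `q <- q + s p` and
#' `q_hat <- q_hat + s p`, and integrates the force estimate with one
#' midpoint-sampled Hessian, `f_tilde <- f_tilde - s h(q_hat + s p / 2) p`
#' where `h` is the (pair-decoupled) Hessian.  The midpoint sampling makes
#' every segment self-adjoint, so the composed map keeps its full order.
#' SEF2 is one leapfrog block (2 Hessian evaluations per step); SEF4 is a
#' symmetric product of three SEF2 blocks (6 evaluations per step,
#' because the force quadrature must follow the composition structure).
#' The gradient is never evaluated.  On a quadratic surface with
#' `f_tilde` consistent (`-H (q - q_eq)`), the force estimate stays exact
#' and SEF2 coincides with leapfrog step for step.
#'
#' @param state a [phase_state()].
#' @param surface a [potential_surface()].
#' @param scheme an [integrator_scheme()] with `needs_hessian = TRUE`.
#' @param dt time step (au).
#' @param spec optional [decoupling_spec()]; `NULL` means fully coupled.
#' @param basis optional [compute_normal_modes()] result, required for
#'   `cartesian_atoms` decoupling.
#' @return the advanced [phase_state()].
#' @export
sef_step <- function(state, surface, scheme, dt, spec = NULL, basis = NULL) {
  if (!scheme$needs_hessian)
    stop("scheme ", scheme$name, " is gradient-based; use se_step()", call. = FALSE)
  hfun <- decoupled_hessian_fn(surface, spec, basis)
  st <- sef_step_raw(state, hfun, scheme, dt)
  st
}

# inner loop shared by sef_step() and propagate(); hfun(q_hat) -> Hessian.
# Drifts advance q and q_hat and integrate the force estimate with a
# midpoint-sampled Hessian (self-adjoint per segment, so each SEF2 block
# is time-symmetric and the composed map keeps its full order); kicks
# advance p with the current force estimate.
sef_step_raw <- function(state, hfun, scheme, dt) {
  q <- state$q; p <- state$p; f <- state$f_tilde; qh <- state$q_hat
  for (st in scheme$stages) {
    s <- st[[2]] * dt
    if (st[[1]] == "k") {
      p <- p + s * f
    } else {
      q <- q + s * p
      f <- f - s * as.numeric(hfun(qh + (0.5 * s) * p) %*% p)
      qh <- qh + s * p
    }
  }
  phase_state(q, p, f, qh, state$t + dt)
}

#' One gradient-based symplectic step (SE2 leapfrog / SE4 Forest-Ruth)
#'
#' Standard kick-drift composition using exact forces `-grad V`:
#' for `k = 1..n`, `p <- p - b_k dt grad V(q)`; `q <- q + a_k dt p`.
#'
#' @inheritParams sef_step
#' @param scheme an [integrator_scheme()] with `needs_hessian = FALSE`.
#' @return the advanced [phase_state()].
#' @export
se_step <- function(state, surface, scheme, dt) {
  if (scheme$needs_hessian)
    stop("scheme ", scheme$name, " is Hessian-driven; use sef_step()", call. = FALSE)
  q <- state$q; p <- state$p
  a <- scheme$a; b <- scheme$b
  for (k in seq_along(a)) {
    if (b[k] != 0) p <- p - (b[k] * dt) * surface$gradient_at(q)
    q <- q + (a[k] * dt) * p
  }
  phase_state(q, p, state$f_tilde, q, state$t + dt)
}

#' Propagate a trajectory
#'
#' Runs `n_steps` of the chosen scheme from `initial`, recording positions,
#' momenta and the total energy `E = |p|^2 / 2 + V(q)` of the *fully
#' coupled* surface at every step (this is the conserved quantity monitored
#' even when the dynamics runs on a pair-decoupled Hessian).  Mode freezing
#' from `spec$frozen_modes` is applied after every step.  Propagation
#' aborts with the offending step index if a non-finite state appears
#' (e.g. a surface evaluated far outside its fitted region).
#'
#' For surfaces declaring `hessian_constant`, the (decoupled) Hessian is
#' evaluated once and reused, which makes long quadratic benchmark runs
#' cheap without changing any result.
#'
#' @param initial a [phase_state()].
#' @param surface the fully coupled [potential_surface()] (propagation
#'   frame).
#' @param scheme an [integrator_scheme()] or scheme name.
#' @param n_steps number of steps.
#' @param dt time step, au (default 10).
#' @param spec optional [decoupling_spec()].
#' @param basis optional basis for `cartesian_atoms` decoupling.
#' @param discard_steps steps flagged for downstream discarding (stored in
#'   the trajectory, not applied here); must be `< n_steps`.
#' @param record_energy set `FALSE` to skip the potential evaluation per
#'   step (used by bulk monodromy runs).
#' @return object of class `sef_trajectory`: matrices `q`, `p`
#'   (`n_steps + 1` rows), vectors `times`, `energy`, the final
#'   [phase_state()], the scheme, `dt`, `discard_steps` and the
#'   Hessian/gradient evaluation counts.
#' @export
propagate <- function(initial, surface, scheme, n_steps, dt = 10,
                      spec = NULL, basis = NULL, discard_steps = 0L,
                      record_energy = TRUE) {
  if (is.character(scheme)) scheme <- get_scheme(scheme)
  n_steps <- as.integer(n_steps)
  if (n_steps < 0L) stop("n_steps must be >= 0", call. = FALSE)
  if (!(dt > 0)) stop("dt must be positive", call. = FALSE)
  if (discard_steps >= n_steps && n_steps > 0L)
    stop("discard_steps must be smaller than n_steps", call. = FALSE)
  ndof <- length(initial$q)
  if (ndof != surface$dof_count)
    stop("state dimension does not match the surface", call. = FALSE)

  hess_calls <- 0L; grad_calls <- 0L
  if (scheme$needs_hessian) {
    hfun0 <- decoupled_hessian_fn(surface, spec, basis)
    if (surface$hessian_constant) {
      hconst <- hfun0(initial$q)
      hfun <- function(q) { hess_calls <<- hess_calls + 1L; hconst }
    } else {
      hfun <- function(q) { hess_calls <<- hess_calls + 1L; hfun0(q) }
    }
    stepper <- function(st) sef_step_raw(st, hfun, scheme, dt)
  } else {
    gfun <- surface$gradient_at
    stepper <- function(st) {
      q <- st$q; p <- st$p
      a <- scheme$a; b <- scheme$b
      for (k in seq_along(a)) {
        if (b[k] != 0) { p <- p - (b[k] * dt) * gfun(q); grad_calls <<- grad_calls + 1L }
        q <- q + (a[k] * dt) * p
      }
      phase_state(q, p, st$f_tilde, q, st$t + dt)
    }
  }

  freeze <- !is.null(spec) && length(spec$frozen_modes) > 0L
  st <- if (freeze) apply_mode_freezing(initial, spec) else initial
  Q <- matrix(NA_real_, n_steps + 1L, ndof)
  P <- matrix(NA_real_, n_steps + 1L, ndof)
  E <- rep(NA_real_, n_steps + 1L)
  times <- st$t + dt * (0:n_steps)
  Q[1L, ] <- st$q; P[1L, ] <- st$p
  if (record_energy) E[1L] <- 0.5 * sum(st$p^2) + surface$energy_at(st$q)
  for (i in seq_len(n_steps)) {
    st <- stepper(st)
    if (freeze) st <- apply_mode_freezing(st, spec)
    if (!all(is.finite(st$q)) || !all(is.finite(st$p)))
      stop("non-finite state at step ", i,
           " (surface evaluated outside its valid region?)", call. = FALSE)
    Q[i + 1L, ] <- st$q; P[i + 1L, ] <- st$p
    if (record_energy) E[i + 1L] <- 0.5 * sum(st$p^2) + surface$energy_at(st$q)
  }
  structure(list(q = Q, p = P, times = times, energy = E,
                 final_state = st, scheme = scheme, dt = dt,
                 n_steps = n_steps, discard_steps = as.integer(discard_steps),
                 spec = spec, hessian_calls = hess_calls,
                 gradient_calls = grad_calls),
            class = "sef_trajectory")
}

#' @export
print.sef_trajectory <- function(x, ...) {
  cat(sprintf("<sef_trajectory> %s: %d steps of %g au (%d dof)\n",
              x$scheme$name, x$n_steps, x$dt, ncol(x$q)))
  cat(sprintf("  Hessian calls: %d, gradient calls: %d\n",
              x$hessian_calls, x$gradient_calls))
  if (!all(is.na(x$energy)))
    cat(sprintf("  energy: mean %.10g, span %.3g au\n",
                mean(x$energy), diff(range(x$energy))))
  invisible(x)
}

#' Numerical verification of a scheme's order of accuracy
#'
#' Checks the algebraic consistency conditions `sum(a) = sum(b) = 1` and
#' measures the empirical global-error order by a Richardson ladder on a
#' one-dimensional anharmonic oscillator: the trajectory error at fixed
#' final time against a fine-step gradient-based (Forest-Ruth) reference
#' is fit as `log(err) ~ order * log(dt)`.  Using an independent reference
#' rather than self-convergence also exposes inconsistent coefficient
#' sets, which converge to a distorted flow of their own.
#' For second-order schemes with `b[1] = 0`
#' the unique-solution structure (`b = (0, 1)`, `a[1] = 1/2`) is also
#' reported.
#'
#' @param scheme an [integrator_scheme()] or name.
#' @param surface 1-DOF test surface; default a Morse oscillator.
#' @param t_final fixed final time for the ladder (au).
#' @param dts time-step ladder; each must divide `t_final`.
#' @param initial optional initial [phase_state()].
#' @return list with `measured_order` (the fitted slope), `errors`, `dts`,
#'   `sum_a_ok`, `sum_b_ok`, `second_order_unique` (NA unless applicable).
#' @export
check_order_conditions <- function(scheme,
                                   surface = build_morse_surface(0.1, 1.0),
                                   t_final = 50,
                                   dts = t_final / c(200, 400, 800, 1600),
                                   initial = NULL) {
  if (is.character(scheme)) scheme <- get_scheme(scheme)
  sum_a_ok <- abs(sum(scheme$a) - 1) < 1e-14
  sum_b_ok <- abs(sum(scheme$b) - 1) < 1e-14
  if (is.null(initial)) {
    q0 <- surface$reference_geometry
    w <- sqrt(max(diag(as.matrix(surface$hessian_at(q0))), 1e-8))
    initial <- phase_state(q = q0, p = rep(sqrt(w), surface$dof_count),
                           f_tilde = -surface$gradient_at(q0))
  }
  run <- function(dt, sch) {
    n <- round(t_final / dt)
    tr <- propagate(initial, surface, sch, n, dt, record_energy = FALSE)
    c(tr$final_state$q, tr$final_state$p)
  }
  ref <- run(min(dts) / 20, get_scheme("SE4"))
  errors <- vapply(dts, function(dt) max(abs(run(dt, scheme) - ref)),
                   numeric(1))
  fit <- stats::lm(log(errors) ~ log(dts))
  slope <- unname(stats::coef(fit)[2])
  unique2 <- NA
  if (scheme$order == 2L && length(scheme$b) >= 2L && scheme$b[1] == 0)
    unique2 <- isTRUE(all.equal(scheme$b[1:2], c(0, 1))) &&
      isTRUE(all.equal(scheme$a[1], 0.5))
  list(measured_order = slope, errors = errors, dts = dts,
       sum_a_ok = sum_a_ok, sum_b_ok = sum_b_ok,
       second_order_unique = unique2)
}
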