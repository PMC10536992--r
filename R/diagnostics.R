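#' Canonical symplectic matrix
#'
#' `J = [[0, I], [-I, 0]]` acting on phase vectors ordered `(q, p)`.
#'
#' @param f number of degrees of freedom (matrix is `2f x 2f`).
#' @return numeric matrix.
#' @export
canonical_j <- function(f) {
  J <- matrix(0, 2 * f, 2 * f)
  J[seq_len(f), f + seq_len(f)] <- diag(f)
  J[f + seq_len(f), seq_len(f)] <- -diag(f)
  J
}

#' Symplecticity deviation of a monodromy matrix
#'
#' `Upsilon = max |M' J M - J|` (elementwise), the most stringent scalar
#' reading of the symplectic condition `M' J M = J`; exactly zero (up to
#' roundoff) for the Jacobian of any symplectic map.  A Frobenius-norm
#' variant is available via `norm = "frobenius"`.
#'
#' @param M square matrix of even dimension.
#' @param norm `"max"` (default) or `"frobenius"`.
#' @return non-negative scalar.
#' @export
symplectic_deviation <- function(M, norm = c("max", "frobenius")) {
  norm <- match.arg(norm)
  n <- nrow(M)
  if (is.null(n) || n != ncol(M) || n %% 2 != 0)
    stop("M must be square with even dimension", call. = FALSE)
  J <- canonical_j(n / 2)
  D <- t(M) %*% J %*% M - J
  if (norm == "max") max(abs(D)) else sqrt(sum(D * D))
}

#' Monodromy matrix by central finite differences
#'
#' Estimates `M(t) = d z(t) / d z(0)` (phase vector `z = (q, p)`) by
#' propagating `2F` pairs of trajectories displaced by `+/- eps` along each
#' initial coordinate and momentum, at every requested sample time.  For
#' SEF schemes a geometry displacement also displaces the initial force
#' estimate by `-eps h(q0)[, j]` (decoupled Hessian at the base point),
#' keeping `f_tilde` consistent with the displaced geometry so that all
#' displaced runs sample one and the same flow.
#'
#' Convergence is validated by halving `eps` once and requiring the final
#' monodromy matrix to change by less than `conv_tol` (max-abs); a warning
#' is raised otherwise.
#'
#' @param initial a [phase_state()].
#' @param surface,scheme,dt,spec,basis as in [propagate()].
#' @param n_steps number of steps.
#' @param sample_every record `M(t)` every this many steps (plus the final
#'   step).
#' @param eps displacement (mass-scaled au).
#' @param check_convergence logical; halve `eps` and compare.
#' @param conv_tol convergence threshold on the final `M`.
#' @return object of class `monodromy_trace`: `times`, list `matrices`,
#'   `upsilon` (deviation per sample), `eps`, `converged`.
#' @export
monodromy_by_finite_difference <- function(initial, surface, scheme, n_steps,
                                           dt = 10, spec = NULL, basis = NULL,
                                           sample_every = max(1L, n_steps %/% 30L),
                                           eps = 1e-6,
                                           check_convergence = TRUE,
                                           conv_tol = 1e-5) {
  if (is.character(scheme)) scheme <- get_scheme(scheme)
  if (!(eps > 0)) stop("eps must be positive", call. = FALSE)
  f <- length(initial$q)
  samples <- unique(c(seq(sample_every, n_steps, by = sample_every), n_steps))
  # Local decoupled Hessian at the base point: displacing the initial
  # geometry must displace the force estimate consistently
  # (d f_tilde / d q0 = -h), otherwise each displaced trajectory would see
  # a shifted effective potential and the Jacobian would not be the
  # monodromy of a single flow.
  h0 <- if (scheme$needs_hessian)
    decoupled_hessian_fn(surface, spec, basis)(initial$q) else NULL

  run_displaced <- function(j, sign, eps) {
    st <- initial
    if (j <= f) {
      st$q[j] <- st$q[j] + sign * eps
      st$q_hat[j] <- st$q_hat[j] + sign * eps
      if (!is.null(h0)) st$f_tilde <- st$f_tilde - sign * eps * h0[, j]
    } else st$p[j - f] <- st$p[j - f] + sign * eps
    tr <- tryCatch(
      propagate(st, surface, scheme, n_steps, dt, spec, basis,
                record_energy = FALSE),
      error = function(e)
        stop("displaced trajectory (coordinate ", j, ", sign ", sign,
             ") failed: ", conditionMessage(e), call. = FALSE))
    cbind(tr$q[samples + 1L, , drop = FALSE], tr$p[samples + 1L, , drop = FALSE])
  }

  build <- function(eps) {
    cols <- vector("list", 2L * f)
    for (j in seq_len(2L * f)) {
      zp <- run_displaced(j, +1, eps)
      zm <- run_displaced(j, -1, eps)
      cols[[j]] <- (zp - zm) / (2 * eps)   # rows: samples, cols: z components
    }
    lapply(seq_along(samples), function(s)
      vapply(cols, function(cj) cj[s, ], numeric(2L * f)))
  }

  mats <- build(eps)
  converged <- NA
  if (check_convergence) {
    mats_half <- build(eps / 2)
    dmax <- max(abs(mats[[length(mats)]] - mats_half[[length(mats_half)]]))
    converged <- dmax < conv_tol
    if (!converged)
      warning("monodromy finite differences not converged (change ",
              format(dmax, digits = 3), " on eps halving)")
    mats <- mats_half
  }
  ups <- vapply(mats, symplectic_deviation, numeric(1))
  structure(list(times = initial$t + dt * samples, matrices = mats,
                 upsilon = ups, eps = eps, converged = converged,
                 scheme = scheme$name),
            class = "monodromy_trace")
}

#' @export
print.monodromy_trace <- function(x, ...) {
  cat(sprintf("<monodromy_trace> %s: %d samples, max Upsilon = %.3g\n",
              x$scheme, length(x$times), max(x$upsilon)))
  invisible(x)
}

#' Round-trip time-reversibility deviation
#'
#' Propagates for time `T_half`, flips the sign of every momentum, and
#' propagates for another `T_half`.  Returns the root-mean-square over the
#' coordinate components of the difference between the final and initial
#' geometries.  The force estimate `f_tilde` is carried through the flip
#' unchanged (its propagation direction reverses through the flipped
#' momenta), which makes the round trip exact, up to roundoff, on
#' quadratic surfaces for time-symmetric schemes.
#'
#' @param initial a [phase_state()].
#' @param surface,scheme,dt,spec,basis as in [propagate()].
#' @param T_half half-trip duration (au); must be a multiple of `dt`.
#'   Default 6000 au.
#' @return non-negative scalar (rms displacement, mass-scaled au).
#' @export
reversibility_deviation <- function(initial, surface, scheme, dt = 10,
                                    T_half = 6000, spec = NULL, basis = NULL) {
  n <- T_half / dt
  if (abs(n - round(n)) > 1e-9)
    stop("T_half must be a multiple of dt", call. = FALSE)
  n <- as.integer(round(n))
  if (n == 0L) return(0)
  fwd <- propagate(initial, surface, scheme, n, dt, spec, basis,
                   record_energy = FALSE)
  turn <- fwd$final_state
  turn$p <- -turn$p
  back <- propagate(turn, surface, scheme, n, dt, spec, basis,
                    record_energy = FALSE)
  sqrt(mean((back$final_state$q - initial$q)^2))
}

#' Total-energy series and conservation summary
#'
#' Recomputes `E(t) = |p|^2 / 2 + V(q)` on the fully coupled surface from
#' a stored trajectory and summarizes conservation: the oscillation
#' amplitude (max - min) and the linear drift slope from an ordinary
#' least-squares fit of energy against step index.
#'
#' @param trajectory an [propagate()] result.
#' @param surface the fully coupled surface; defaults to reusing the
#'   energies recorded during propagation when available.
#' @return list with `energy` (vector), `amplitude` (au), `drift_slope`
#'   (au per step).
#' @export
energy_series <- function(trajectory, surface = NULL) {
  if (is.null(surface) && !all(is.na(trajectory$energy))) {
    e <- trajectory$energy
  } else {
    if (is.null(surface)) stop("trajectory has no stored energies; supply a surface",
                               call. = FALSE)
    e <- vapply(seq_len(nrow(trajectory$q)), function(i)
      0.5 * sum(trajectory$p[i, ]^2) + surface$energy_at(trajectory$q[i, ]),
      numeric(1))
  }
  step <- seq_along(e) - 1
  slope <- unname(stats::coef(stats::lm(e ~ step))[2])
  list(energy = e, amplitude = diff(range(e)), drift_slope = slope)
}
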