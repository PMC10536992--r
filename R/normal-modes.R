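#' Normal-mode analysis with Eckart projection
#'
#' Diagonalizes the mass-weighted Hessian at the equilibrium geometry after
#' projecting out rigid translations and rotations (Eckart conditions).
#' The projection basis is built explicitly: three translation vectors
#' `sqrt(m_a) e_alpha` and up to three rotation vectors
#' `sqrt(m_a) (r_a - R_com) x e_alpha`, orthonormalized; rotation vectors
#' with negligible norm (linear molecules) are dropped, so 5 modes are
#' projected for linear molecules and 6 otherwise.  The Hessian is then
#' diagonalized in an orthonormal basis of the complement, which yields
#' exactly `3 N_at - n_projected` vibrational modes with no zero-mode
#' bookkeeping.
#'
#' Negative curvatures beyond tolerance are flagged as imaginary
#' frequencies (the magnitude `sqrt(-lambda)` is stored and
#' `imaginary[j]` set), never silently dropped.
#'
#' @param system a [molecular_system()].
#' @param surface a Cartesian [potential_surface()] whose Hessian is
#'   available at `system$equilibrium_geometry` (hartree / bohr^2).
#' @param tol_linear moment-of-inertia eigenvalue threshold (mass-weighted
#'   au) below which the molecule is treated as linear.
#' @param tol_imaginary curvature below `-tol_imaginary` flags an imaginary
#'   mode.
#' @return object of class `normal_mode_basis` with fields `frequencies`
#'   (ascending, au), `imaginary` (logical), `mode_matrix` (3N x n_vib,
#'   orthonormal columns, mass-weighted Cartesian), `tr_matrix` (the
#'   projected translation/rotation basis), `n_projected`, plus the system
#'   and the mass vector expanded per coordinate.
#' @export
compute_normal_modes <- function(system, surface,
                                 tol_linear = 1e-8, tol_imaginary = 1e-10) {
  x0 <- system$equilibrium_geometry
  n3 <- length(x0)
  m3 <- rep(system$masses, each = 3L)
  h <- surface$hessian_at(x0)
  check_symmetric(h, tol = 1e-8)
  hmw <- h / sqrt(m3 %o% m3)

  tr <- eckart_tr_vectors(system, tol_linear)
  n_proj <- ncol(tr)
  # orthonormal complement of the translation/rotation space
  comp <- qr.Q(qr(cbind(tr, diag(n3))))[, (n_proj + 1L):n3, drop = FALSE]
  hred <- crossprod(comp, hmw %*% comp)
  hred <- (hred + t(hred)) / 2
  es <- eigen(hred, symmetric = TRUE)
  lambda <- rev(es$values)                       # ascending
  vecs <- comp %*% es$vectors[, rev(seq_along(es$values)), drop = FALSE]
  imaginary <- lambda < -tol_imaginary
  freq <- sqrt(abs(lambda))
  structure(list(frequencies = freq,
                 imaginary = imaginary,
                 lambda = lambda,
                 mode_matrix = vecs,
                 tr_matrix = tr,
                 n_projected = n_proj,
                 n_vibrational = n3 - n_proj,
                 masses3 = m3,
                 system = system),
            class = "normal_mode_basis")
}

#' @export
print.normal_mode_basis <- function(x, ...) {
  cat(sprintf("<normal_mode_basis> %d vibrational modes (%d projected)\n",
              x$n_vibrational, x$n_projected))
  f <- x$frequencies * sef_constants[["cm1_per_hartree"]]
  f[x$imaginary] <- -f[x$imaginary]
  cat("  frequencies (cm^-1, negative = imaginary):\n  ")
  cat(format(round(f, 1)), fill = 70)
  invisible(x)
}

# translation + rotation vectors in mass-weighted coordinates, orthonormal
eckart_tr_vectors <- function(system, tol_linear = 1e-8) {
  m <- system$masses
  n <- system$n_atoms
  r <- matrix(system$equilibrium_geometry, nrow = 3)
  com <- as.numeric(r %*% m) / sum(m)
  rc <- r - com
  vecs <- matrix(0, 3 * n, 6L)
  sm <- sqrt(rep(m, each = 3L))
  for (a in 1:3) {                       # translations
    v <- matrix(0, 3, n); v[a, ] <- 1
    vecs[, a] <- as.numeric(v) * sm
  }
  for (a in 1:3) {                       # rotations about com
    e <- numeric(3); e[a] <- 1
    v <- apply(rc, 2, function(ri) crossprod_3(e, ri))
    vecs[, 3L + a] <- as.numeric(v) * sm
  }
  # Gram-Schmidt, dropping near-null rotations (linear molecules)
  keep <- list()
  for (j in seq_len(ncol(vecs))) {
    v <- vecs[, j]
    for (u in keep) v <- v - sum(u * v) * u
    nv <- sqrt(sum(v * v))
    if (nv^2 > tol_linear * max(1, sum(m)))
      keep[[length(keep) + 1L]] <- v / nv
  }
  do.call(cbind, keep)
}

crossprod_3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Cartesian <-> normal-mode coordinate transforms
#'
#' Normal coordinates are mass-scaled: `Q = U' sqrt(m) (x - x_eq)` with `U`
#' the orthonormal vibrational mode matrix, so the kinetic energy is
#' `|P|^2 / 2` with unit mass.  The equilibrium geometry maps to the zero
#' vector.  With `include_tr = TRUE` the projected translation/rotation
#' coordinates are appended, making the transform a full rotation of the
#' mass-weighted displacement space and the round trip exact for arbitrary
#' displacements; with the default `FALSE`, `to_cartesian_coordinates()`
#' restores only the vibrational part of a displacement.
#'
#' @param basis a [compute_normal_modes()] result.
#' @param x Cartesian geometry (bohr), length 3 N_at.
#' @param include_tr append translation/rotation coordinates.
#' @return numeric vector of normal coordinates (length n_vib, or 3 N_at
#'   with `include_tr`).
#' @export
to_normal_coordinates <- function(basis, x, include_tr = FALSE) {
  if (length(x) != length(basis$masses3))
    stop("geometry length does not match the basis", call. = FALSE)
  d <- sqrt(basis$masses3) * (x - basis$system$equilibrium_geometry)
  q <- as.numeric(crossprod(basis$mode_matrix, d))
  if (include_tr) q <- c(q, as.numeric(crossprod(basis$tr_matrix, d)))
  q
}

#' @rdname to_normal_coordinates
#' @param q normal coordinates as produced by [to_normal_coordinates()].
#' @export
to_cartesian_coordinates <- function(basis, q, include_tr = FALSE) {
  nv <- basis$n_vibrational
  d <- basis$mode_matrix %*% q[seq_len(nv)]
  if (include_tr) {
    if (length(q) != nv + basis$n_projected)
      stop("expected ", nv + basis$n_projected, " coordinates", call. = FALSE)
    d <- d + basis$tr_matrix %*% q[(nv + 1L):length(q)]
  } else if (length(q) != nv) {
    stop("expected ", nv, " vibrational coordinates", call. = FALSE)
  }
  basis$system$equilibrium_geometry + as.numeric(d) / sqrt(basis$masses3)
}

#' Normal-mode-frame view of a Cartesian surface
#'
#' Wraps a Cartesian [potential_surface()] as a surface over the mass-scaled
#' vibrational normal coordinates: `V_nm(Q) = V(x(Q))`, gradient
#' `U' m^-1/2 grad V`, Hessian `U' m^-1/2 H m^-1/2 U`.  This is the frame
#' in which all propagation runs: translations and rotations are discarded
#' and the kinetic energy has unit mass.
#'
#' @param basis a [compute_normal_modes()] result.
#' @param surface the Cartesian surface.
#' @return a [potential_surface()] over `n_vibrational` coordinates.
#' @export
normal_mode_surface <- function(basis, surface) {
  U <- basis$mode_matrix
  sm <- sqrt(basis$masses3)
  potential_surface(
    dof_count = basis$n_vibrational,
    reference_geometry = rep(0, basis$n_vibrational),
    energy_at = function(q) surface$energy_at(to_cartesian_coordinates(basis, q)),
    gradient_at = function(q) {
      g <- surface$gradient_at(to_cartesian_coordinates(basis, q))
      as.numeric(crossprod(U, g / sm))
    },
    hessian_at = function(q) {
      h <- surface$hessian_at(to_cartesian_coordinates(basis, q))
      hm <- h / (sm %o% sm)
      hn <- crossprod(U, hm %*% U)
      (hn + t(hn)) / 2
    },
    hessian_constant = surface$hessian_constant,
    label = paste0(surface$label, " [normal-mode frame]"))
}

#' Zero-point-energy initial conditions
#'
#' The standard quasiclassical initialization: every vibrational mode
#' starts at its equilibrium position (`Q_j = 0`) with momentum
#' `P_j = sqrt(omega_j)`, so its initial kinetic energy equals the harmonic
#' zero-point energy `omega_j / 2`.  The propagated force estimate starts
#' at zero, consistent with starting from the equilibrium of the fully
#' coupled system.  The sign of each momentum is arbitrary; all-positive is
#' the deterministic default and can be overridden per mode.
#'
#' @param basis a [compute_normal_modes()] result, or a plain numeric
#'   vector of vibrational frequencies (au).
#' @param signs optional vector of +1/-1 momentum signs.
#' @return a [phase_state()] with `q = 0`, `p = signs * sqrt(omega)`,
#'   `f_tilde = 0`.
#' @export
zpe_initial_state <- function(basis, signs = NULL) {
  if (inherits(basis, "normal_mode_basis")) {
    if (any(basis$imaginary))
      stop("imaginary frequencies present: cannot assign zero-point momenta",
           call. = FALSE)
    omega <- basis$frequencies
  } else {
    omega <- as.numeric(basis)
  }
  if (any(omega <= 0))
    stop("all vibrational frequencies must be positive", call. = FALSE)
  n <- length(omega)
  if (is.null(signs)) signs <- rep(1, n)
  stopifnot(length(signs) == n, all(abs(signs) == 1))
  phase_state(q = rep(0, n), p = signs * sqrt(omega), f_tilde = rep(0, n))
}
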