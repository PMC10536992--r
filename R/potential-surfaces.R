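#' Potential-energy-surface contract
#'
#' A `potential_surface` bundles closures evaluating the potential energy,
#' its gradient and its Hessian at an arbitrary geometry, all in atomic
#' units (hartree; coordinates are mass-scaled unless the surface is a
#' Cartesian one used for normal-mode analysis).  Every integrator and
#' diagnostic in the package talks to surfaces only through this contract,
#' so analytic model surfaces and externally fitted potentials are
#' interchangeable.
#'
#' @param dof_count number of degrees of freedom.
#' @param reference_geometry numeric vector of length `dof_count`; the
#'   geometry the surface was built around (usually an energy minimum).
#' @param energy_at function(q) -> scalar energy (hartree).
#' @param gradient_at function(q) -> numeric vector of length `dof_count`.
#' @param hessian_at function(q) -> symmetric `dof_count` x `dof_count`
#'   matrix.  If `NULL`, a symmetrized central finite difference of
#'   `gradient_at` is installed (see [finite_difference_hessian()]).
#' @param hessian_constant logical; `TRUE` when the Hessian does not depend
#'   on `q` (quadratic surfaces).  Propagators use this to cache.
#' @param label short description used in printing.
#'
#' @return an object of class `potential_surface`.
#' @export
potential_surface <- function(dof_count, reference_geometry, energy_at,
                              gradient_at, hessian_at = NULL,
                              hessian_constant = FALSE, label = "potential surface") {
  stopifnot(dof_count >= 1L, length(reference_geometry) == dof_count,
            is.function(energy_at), is.function(gradient_at))
  if (is.null(hessian_at)) {
    grad <- gradient_at
    hessian_at <- function(q) finite_difference_hessian(
      list(gradient_at = grad), q, step = 1e-4)
  }
  structure(list(dof_count = as.integer(dof_count),
                 reference_geometry = as.numeric(reference_geometry),
                 energy_at = energy_at,
                 gradient_at = gradient_at,
                 hessian_at = hessian_at,
                 hessian_constant = isTRUE(hessian_constant),
                 label = label),
            class = "potential_surface")
}

#' @export
print.potential_surface <- function(x, ...) {
  cat(sprintf("<potential_surface> %s\n  dof: %d, constant Hessian: %s\n",
              x$label, x$dof_count, x$hessian_constant))
  invisible(x)
}

check_symmetric <- function(h, tol = 1e-10, what = "hessian") {
  if (!is.matrix(h) || nrow(h) != ncol(h))
    stop(what, " must be a square matrix", call. = FALSE)
  scale <- max(abs(h), 1)
  if (max(abs(h - t(h))) > tol * scale)
    stop(what, " is not symmetric (relative asymmetry > ", tol, ")", call. = FALSE)
  invisible(h)
}

#' Harmonic (quadratic) surface from a Hessian
#'
#' Builds the quadratic potential `V(q) = (q - q_eq)' H (q - q_eq) / 2`
#' with gradient `H (q - q_eq)` and constant Hessian `H`.  Quadratic
#' surfaces are the regime where SEF propagation of the force estimate is
#' exact, so they anchor most correctness tests.
#'
#' @param hessian symmetric force-constant matrix (mass-scaled atomic
#'   units, i.e. eigenvalues are squared angular frequencies).
#' @param q_eq equilibrium geometry; defaults to the origin.
#' @return a [potential_surface()].
#' @examples
#' s <- build_harmonic_surface(matrix(c(2, 1, 1, 2), 2), c(0, 0))
#' s$energy_at(c(1, 0))    # 1
#' s$gradient_at(c(1, 0))  # c(2, 1)
#' @export
build_harmonic_surface <- function(hessian, q_eq = rep(0, nrow(hessian))) {
  hessian <- as.matrix(hessian)
  check_symmetric(hessian)
  if (nrow(hessian) != length(q_eq))
    stop("dimensions of hessian and q_eq do not match", call. = FALSE)
  q_eq <- as.numeric(q_eq)
  H <- (hessian + t(hessian)) / 2   # enforce exact symmetry
  potential_surface(
    dof_count = nrow(H),
    reference_geometry = q_eq,
    energy_at = function(q) { d <- q - q_eq; 0.5 * sum(d * (H %*% d)) },
    gradient_at = function(q) as.numeric(H %*% (q - q_eq)),
    hessian_at = function(q) H,
    hessian_constant = TRUE,
    label = "harmonic")
}

#' One-dimensional Morse oscillator
#'
#' `V(r) = depth * (1 - exp(-width * (r - r_eq)))^2`, the standard
#' anharmonic bond-stretch model; at the minimum the curvature is
#' `2 * depth * width^2`, i.e. the harmonic frequency (unit mass) is
#' `width * sqrt(2 * depth)`.
#'
#' @param depth dissociation energy (hartree), > 0.
#' @param width range parameter (inverse mass-scaled length), > 0.
#' @param r_eq equilibrium position.
#' @return a [potential_surface()] with analytic gradient and Hessian.
#' @export
build_morse_surface <- function(depth, width, r_eq = 0) {
  if (!(depth > 0)) stop("depth must be positive", call. = FALSE)
  if (!(width > 0)) stop("width must be positive", call. = FALSE)
  potential_surface(
    dof_count = 1L,
    reference_geometry = r_eq,
    energy_at = function(q) {
      u <- 1 - exp(-width * (q[1] - r_eq)); depth * u * u
    },
    gradient_at = function(q) {
      e <- exp(-width * (q[1] - r_eq))
      2 * depth * width * (1 - e) * e
    },
    hessian_at = function(q) {
      e <- exp(-width * (q[1] - r_eq))
      matrix(2 * depth * width^2 * e * (2 * e - 1), 1, 1)
    },
    label = sprintf("Morse(D=%g, a=%g)", depth, width))
}

#' Symmetrized central-difference Hessian
#'
#' Fallback for surfaces that only expose a gradient (e.g. adapters around
#' externally fitted potentials).  The result is forced symmetric by
#' averaging with its transpose; the error is O(step^2) for smooth
#' potentials.
#'
#' @param surface any object with a `gradient_at` function.
#' @param q geometry at which to differentiate.
#' @param step finite-difference displacement (mass-scaled au), > 0.
#' @return symmetric numeric matrix.
#' @export
finite_difference_hessian <- function(surface, q, step = 1e-4) {
  if (!(step > 0)) stop("step must be positive", call. = FALSE)
  g <- surface$gradient_at
  n <- length(q)
  h <- matrix(0, n, n)
  for (j in seq_len(n)) {
    dq <- numeric(n); dq[j] <- step
    gp <- g(q + dq); gm <- g(q - dq)
    if (max(abs(gp - gm)) == 0 && max(abs(gp)) > 0) {
      warning("finite differences underflowed; retrying with 100x larger step")
      gp <- g(q + 100 * dq); gm <- g(q - 100 * dq)
      if (max(abs(gp - gm)) == 0)
        stop("finite-difference step too small: gradient differences vanish",
             call. = FALSE)
      h[, j] <- (gp - gm) / (200 * step)
      next
    }
    h[, j] <- (gp - gm) / (2 * step)
  }
  (h + t(h)) / 2
}

# ---- quartic force fields ---------------------------------------------------

qff_check_tensor <- function(coef, arity) {
  if (is.null(coef) || nrow(coef) == 0L) return(coef)
  idx <- as.matrix(coef[, seq_len(arity), drop = FALSE])
  if (any(idx != round(idx)) || any(idx < 1))
    stop("coefficient indices must be positive integers", call. = FALSE)
  coef
}

# Expand a sparse list of unique (sorted-index) coefficients into the fully
# permutation-symmetric set, so the nested-sum energy formula can be applied
# with plain loops over the stored records.
qff_symmetrize <- function(coef, arity) {
  if (is.null(coef) || nrow(coef) == 0L)
    return(matrix(numeric(0), 0, arity + 1L))
  out <- list()
  for (r in seq_len(nrow(coef))) {
    idx <- as.numeric(coef[r, seq_len(arity)])
    val <- coef[r, arity + 1L]
    perms <- unique(perms_of(idx))
    for (p in perms) out[[length(out) + 1L]] <- c(p, val)
  }
  do.call(rbind, out)
}

perms_of <- function(x) {
  if (length(x) == 1L) return(list(x))
  res <- list()
  for (i in seq_along(x))
    for (rest in perms_of(x[-i]))
      res[[length(res) + 1L]] <- c(x[i], rest)
  res
}

#' Quartic force field in mass-scaled normal coordinates
#'
#' `V(Q) = sum_j w_j^2 Q_j^2 / 2 + (1/6) sum c_ijk Q_i Q_j Q_k +
#' (1/24) sum d_ijkl Q_i Q_j Q_k Q_l`, the standard polynomial expansion of
#' a molecular potential about its minimum.  Cubic and quartic coefficients
#' are given sparsely as data frames with columns `i, j, (k, (l)), value`
#' (1-based mode indices); each unique index combination is listed once and
#' the evaluator applies full permutation symmetry.
#'
#' @param omega vector of harmonic angular frequencies (au), all > 0.
#' @param cubic data frame or matrix with columns i, j, k, value; may be
#'   `NULL` or empty.
#' @param quartic data frame or matrix with columns i, j, k, l, value.
#' @return a [potential_surface()]; `$qff` holds the coefficient tables.
#' @export
build_quartic_ff_surface <- function(omega, cubic = NULL, quartic = NULL) {
  omega <- as.numeric(omega)
  n <- length(omega)
  if (any(omega <= 0)) stop("harmonic frequencies must be positive", call. = FALSE)
  cub <- if (!is.null(cubic) && NROW(cubic) > 0)
    qff_symmetrize(qff_check_tensor(as.matrix(cubic), 3L), 3L) else NULL
  qua <- if (!is.null(quartic) && NROW(quartic) > 0)
    qff_symmetrize(qff_check_tensor(as.matrix(quartic), 4L), 4L) else NULL
  if (!is.null(cub) && max(cub[, 1:3]) > n) stop("cubic index out of range", call. = FALSE)
  if (!is.null(qua) && max(qua[, 1:4]) > n) stop("quartic index out of range", call. = FALSE)
  w2 <- omega^2

  energy_at <- function(q) {
    v <- 0.5 * sum(w2 * q * q)
    if (!is.null(cub))
      v <- v + sum(cub[, 4] * q[cub[, 1]] * q[cub[, 2]] * q[cub[, 3]]) / 6
    if (!is.null(qua))
      v <- v + sum(qua[, 5] * q[qua[, 1]] * q[qua[, 2]] * q[qua[, 3]] * q[qua[, 4]]) / 24
    v
  }
  gradient_at <- function(q) {
    g <- w2 * q
    if (!is.null(cub)) {
      for (r in seq_len(nrow(cub)))
        g[cub[r, 1]] <- g[cub[r, 1]] + cub[r, 4] * q[cub[r, 2]] * q[cub[r, 3]] / 2
    }
    if (!is.null(qua)) {
      for (r in seq_len(nrow(qua)))
        g[qua[r, 1]] <- g[qua[r, 1]] +
          qua[r, 5] * q[qua[r, 2]] * q[qua[r, 3]] * q[qua[r, 4]] / 6
    }
    g
  }
  hessian_at <- function(q) {
    h <- diag(w2, n, n)
    if (!is.null(cub)) {
      for (r in seq_len(nrow(cub)))
        h[cub[r, 1], cub[r, 2]] <- h[cub[r, 1], cub[r, 2]] + cub[r, 4] * q[cub[r, 3]]
    }
    if (!is.null(qua)) {
      for (r in seq_len(nrow(qua)))
        h[qua[r, 1], qua[r, 2]] <- h[qua[r, 1], qua[r, 2]] +
          qua[r, 5] * q[qua[r, 3]] * q[qua[r, 4]] / 2
    }
    (h + t(h)) / 2
  }
  s <- potential_surface(n, rep(0, n), energy_at, gradient_at, hessian_at,
                         hessian_constant = is.null(cub) && is.null(qua),
                         label = sprintf("quartic force field (%d modes)", n))
  s$qff <- list(omega = omega, cubic = cubic, quartic = quartic)
  s
}

#' Read quartic force-field coefficients from a plain-text file
#'
#' One record per line: `i j value` (harmonic, value = omega_i, requires
#' i == j), `i j k value` (cubic) or `i j k l value` (quartic), 1-based
#' indices, atomic units.  Lines starting with `#` are comments.
#'
#' @param path file path.
#' @return a [potential_surface()] built by [build_quartic_ff_surface()].
#' @export
read_quartic_ff <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- lapply(strsplit(lines, "[[:space:]]+"), as.numeric)
  nf <- lengths(toks)
  if (any(!nf %in% c(3L, 4L, 5L)))
    stop("malformed quartic force-field record (need 3, 4 or 5 fields)", call. = FALSE)
  harm <- do.call(rbind, toks[nf == 3L])
  if (is.null(harm) || any(harm[, 1] != harm[, 2]))
    stop("harmonic records must have i == j and at least one is required", call. = FALSE)
  n <- max(harm[, 1])
  omega <- numeric(n)
  omega[harm[, 1]] <- harm[, 3]
  cubic <- do.call(rbind, toks[nf == 4L])
  quartic <- do.call(rbind, toks[nf == 5L])
  build_quartic_ff_surface(omega, cubic, quartic)
}

#' Cartesian spring-network surface
#'
#' Pairwise central harmonic springs at their natural lengths:
#' `V = sum_(a<b) k_ab (|r_a - r_b| - d0_ab)^2 / 2` with `d0` taken from the
#' reference geometry, so the reference is an energy minimum and (all
#' springs being central and unstrained) rigid translations and rotations
#' are exact zero modes of the Hessian.  Used as a download-free stand-in
#' for molecular force fields in normal-mode tests.
#'
#' @param geometry Cartesian reference geometry, length 3 * n_atoms (bohr).
#' @param spring_constants symmetric n_atoms x n_atoms matrix of force
#'   constants (hartree / bohr^2); zero entries mean no spring.
#' @return a [potential_surface()] over the 3N Cartesian coordinates.
#' @export
build_spring_network_surface <- function(geometry, spring_constants) {
  x0 <- as.numeric(geometry)
  nat <- length(x0) / 3
  if (nat != round(nat)) stop("geometry length must be divisible by 3", call. = FALSE)
  nat <- as.integer(nat)
  K <- as.matrix(spring_constants)
  check_symmetric(K, what = "spring_constants")
  ref <- matrix(x0, nrow = 3)
  pairs <- which(upper.tri(K) & K != 0, arr.ind = TRUE)
  d0 <- apply(pairs, 1, function(ab) sqrt(sum((ref[, ab[1]] - ref[, ab[2]])^2)))
  if (any(d0 == 0)) stop("coincident atoms joined by a spring", call. = FALSE)

  energy_at <- function(q) {
    r <- matrix(q, nrow = 3)
    v <- 0
    for (e in seq_len(nrow(pairs))) {
      a <- pairs[e, 1]; b <- pairs[e, 2]
      d <- sqrt(sum((r[, a] - r[, b])^2))
      v <- v + 0.5 * K[a, b] * (d - d0[e])^2
    }
    v
  }
  gradient_at <- function(q) {
    r <- matrix(q, nrow = 3)
    g <- matrix(0, 3, nat)
    for (e in seq_len(nrow(pairs))) {
      a <- pairs[e, 1]; b <- pairs[e, 2]
      dv <- r[, a] - r[, b]
      d <- sqrt(sum(dv * dv))
      f <- K[a, b] * (d - d0[e]) / d
      g[, a] <- g[, a] + f * dv
      g[, b] <- g[, b] - f * dv
    }
    as.numeric(g)
  }
  hessian_at <- function(q) {
    r <- matrix(q, nrow = 3)
    h <- matrix(0, 3 * nat, 3 * nat)
    for (e in seq_len(nrow(pairs))) {
      a <- pairs[e, 1]; b <- pairs[e, 2]
      dv <- r[, a] - r[, b]
      d <- sqrt(sum(dv * dv))
      u <- dv / d
      blk <- K[a, b] * (u %o% u + (1 - d0[e] / d) * (diag(3) - u %o% u))
      ia <- (3 * a - 2):(3 * a); ib <- (3 * b - 2):(3 * b)
      h[ia, ia] <- h[ia, ia] + blk
      h[ib, ib] <- h[ib, ib] + blk
      h[ia, ib] <- h[ia, ib] - blk
      h[ib, ia] <- h[ib, ia] - blk
    }
    h
  }
  s <- potential_surface(3L * nat, x0, energy_at, gradient_at, hessian_at,
                         label = sprintf("spring network (%d atoms)", nat))
  s$spring_constants <- K
  s
}
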