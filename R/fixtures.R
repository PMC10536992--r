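#' Download-free test systems
#'
#' Deterministic model systems exercising every scenario class the
#' integrators face: coupled quadratic networks, anharmonic bonds, quartic
#' force fields and weakly coupled 2-D pairs.  All randomness (coefficient
#' jitter) flows from the `seed` argument through a private RNG stream, so
#' the same `(name, seed)` always yields bit-identical systems.  All
#' frequencies are in the molecular vibrational range (roughly 40-4000
#' cm^-1), so the package's default time step of 10 au resolves every
#' oscillation.
#'
#' Available fixtures (`k` in a name like `harmonic_chain_3` is parsed
#' from the name):
#' \describe{
#'   \item{harmonic_chain_k}{`k` unit-mass particles on a line, pinned at
#'     both ends: nearest-neighbour springs of 1e-4 au (jittered by up to
#'     10%) plus weak 2e-6 au springs between all non-adjacent pairs.  The
#'     spring matrix is returned in `$meta$spring_matrix`; frequencies are
#'     the square roots of its eigenvalues.}
#'   \item{triatomic_morse_bend}{3 mass-scaled DOF: two Morse stretches
#'     (depth 0.1 hartree, width jittered around 0.07) and a harmonic bend
#'     (omega = 0.004 au) with bilinear stretch-stretch coupling 1e-6 au.}
#'   \item{quartic_toy}{3-mode quartic force field, omega = (0.005, 0.010,
#'     0.017) au with small seeded cubic and quartic couplings.}
#'   \item{coupled_pair_2d}{two harmonic modes omega = (0.006, 0.010) au
#'     with bilinear coupling `coupling` (default 5e-6 au); set
#'     `coupling = 0` for a naturally uncoupled pair.}
#' }
#'
#' @param name fixture identifier.
#' @param seed integer seed for the coefficient jitter.
#' @param coupling bilinear coupling constant for `coupled_pair_2d`.
#' @return list with `name`, `surface` (a [potential_surface()]),
#'   `system` (a [molecular_system()] or `NULL` for abstract-DOF
#'   fixtures) and `meta` (documented parameters).
#' @export
make_fixture <- function(name, seed = 1L, coupling = 5e-6) {
  rng <- local_rng(seed)
  if (grepl("^harmonic_chain_[0-9]+$", name)) {
    k <- as.integer(sub("^harmonic_chain_", "", name))
    return(fixture_harmonic_chain(k, rng, name))
  }
  switch(name,
    triatomic_morse_bend = fixture_triatomic(rng),
    quartic_toy = fixture_quartic_toy(rng),
    coupled_pair_2d = fixture_coupled_pair(coupling),
    stop("unknown fixture '", name,
         "'; available: harmonic_chain_<k>, triatomic_morse_bend, ",
         "quartic_toy, coupled_pair_2d", call. = FALSE))
}

# private RNG stream: does not disturb the caller's .Random.seed
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  draws <- stats::runif(64)
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  i <- 0L
  function() { i <<- i + 1L; draws[i] }
}

fixture_harmonic_chain <- function(k, rng, name) {
  if (k < 2L) stop("harmonic chain needs at least 2 particles", call. = FALSE)
  k_nn <- vapply(seq_len(k + 1L), function(i) 1e-4 * (0.9 + 0.2 * rng()),
                 numeric(1))                      # k+1 bonds incl. walls
  k_lr <- 2e-6
  K <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) {                    # interior bonds
    kb <- k_nn[i + 1L]
    K[i, i] <- K[i, i] + kb; K[i + 1L, i + 1L] <- K[i + 1L, i + 1L] + kb
    K[i, i + 1L] <- K[i, i + 1L] - kb; K[i + 1L, i] <- K[i + 1L, i] - kb
  }
  K[1L, 1L] <- K[1L, 1L] + k_nn[1L]               # wall springs
  K[k, k] <- K[k, k] + k_nn[k + 1L]
  if (k > 2L) for (i in seq_len(k - 2L)) for (j in (i + 2L):k) {
    K[i, i] <- K[i, i] + k_lr; K[j, j] <- K[j, j] + k_lr
    K[i, j] <- K[i, j] - k_lr; K[j, i] <- K[j, i] - k_lr
  }
  list(name = name,
       surface = build_harmonic_surface(K),
       system = NULL,
       meta = list(spring_matrix = K, k_nn = k_nn, k_lr = k_lr))
}

fixture_triatomic <- function(rng) {
  depth <- 0.1
  width1 <- 0.07 * (0.95 + 0.1 * rng())
  width2 <- 0.07 * (0.95 + 0.1 * rng())
  w_bend <- 0.004
  c12 <- 1e-6
  m1 <- build_morse_surface(depth, width1)
  m2 <- build_morse_surface(depth, width2)
  surface <- potential_surface(
    dof_count = 3L, reference_geometry = c(0, 0, 0),
    energy_at = function(q)
      m1$energy_at(q[1]) + m2$energy_at(q[2]) +
      0.5 * w_bend^2 * q[3]^2 + c12 * q[1] * q[2],
    gradient_at = function(q)
      c(m1$gradient_at(q[1]) + c12 * q[2],
        m2$gradient_at(q[2]) + c12 * q[1],
        w_bend^2 * q[3]),
    hessian_at = function(q) {
      h <- diag(c(m1$hessian_at(q[1])[1, 1], m2$hessian_at(q[2])[1, 1],
                  w_bend^2))
      h[1, 2] <- h[2, 1] <- c12
      h
    },
    label = "triatomic: two Morse stretches + harmonic bend")
  list(name = "triatomic_morse_bend", surface = surface, system = NULL,
       meta = list(depth = depth, widths = c(width1, width2),
                   w_bend = w_bend, c12 = c12))
}

fixture_quartic_toy <- function(rng) {
  omega <- c(0.005, 0.010, 0.017)
  scale3 <- 2e-7; scale4 <- 2e-9
  cubic <- rbind(c(1, 1, 2, scale3 * (0.5 + rng())),
                 c(2, 2, 3, scale3 * (0.5 + rng())),
                 c(1, 2, 3, scale3 * (0.5 + rng())))
  quartic <- rbind(c(1, 1, 1, 1, scale4 * (0.5 + rng())),
                   c(2, 2, 2, 2, scale4 * (0.5 + rng())),
                   c(1, 1, 2, 2, scale4 * (0.5 + rng())))
  list(name = "quartic_toy",
       surface = build_quartic_ff_surface(omega, cubic, quartic),
       system = NULL,
       meta = list(omega = omega, cubic = cubic, quartic = quartic))
}

fixture_coupled_pair <- function(coupling) {
  w <- c(0.006, 0.010)
  H <- diag(w^2)
  H[1, 2] <- H[2, 1] <- coupling
  list(name = "coupled_pair_2d",
       surface = build_harmonic_surface(H),
       system = NULL,
       meta = list(omega = w, coupling = coupling, hessian = H))
}

#' Random spring-network molecule
#'
#' A deterministic pseudo-molecule for normal-mode tests: `n_atoms` atoms
#' placed on a jittered 3-D grid, joined by pairwise central springs
#' (full connectivity, force constants decaying with distance, ~0.1-0.4
#' hartree/bohr^2 for near neighbours).  Being an unstrained central-force
#' network at its reference geometry, its Hessian has exactly six zero
#' modes, so a nonlinear `n_atoms`-atom system has `3 n_atoms - 6`
#' vibrational modes.
#'
#' @param n_atoms number of atoms (>= 3).
#' @param seed integer seed.
#' @param elements element symbols to cycle through.
#' @return list with `system` ([molecular_system()]) and `surface`
#'   ([build_spring_network_surface()]).
#' @export
make_spring_molecule <- function(n_atoms, seed = 1L,
                                 elements = c("C", "H", "O")) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  side <- ceiling(n_atoms^(1 / 3))
  grid <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                                z = seq_len(side)))[seq_len(n_atoms), ] * 2.5
  geom <- t(grid + matrix(stats::runif(3 * n_atoms, -0.4, 0.4), n_atoms, 3))
  K <- matrix(0, n_atoms, n_atoms)
  for (i in seq_len(n_atoms - 1L)) for (j in (i + 1L):n_atoms) {
    d <- sqrt(sum((geom[, i] - geom[, j])^2))
    K[i, j] <- K[j, i] <- 0.4 * exp(-(d - 2.5) / 2) * (0.8 + 0.4 * stats::runif(1))
  }
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  labels <- rep_len(elements, n_atoms)
  sys <- molecular_system(labels, as.numeric(geom))
  list(system = sys,
       surface = build_spring_network_surface(sys$equilibrium_geometry, K))
}
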