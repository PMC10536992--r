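#' Pair-decoupling specification
#'
#' Describes which groups of degrees of freedom are artificially decoupled
#' and by how much.  For every listed pair of disjoint groups, the Hessian
#' elements `h[i, j]` with `i` in one group and `j` in the other are scaled
#' by `alpha` (1 = fully coupled physics, 0 = the groups evolve as
#' instantaneously independent systems).  Diagonal elements are never
#' touched, so the trace is preserved exactly.
#'
#' Two frames are supported: `"normal_mode"` (group indices are normal-mode
#' / surface DOF indices, scaling applied directly) and
#' `"cartesian_atoms"` (groups are atom indices; the normal-mode Hessian is
#' rotated to mass-weighted Cartesian coordinates, the whole 3x3 blocks of
#' every decoupled atom pair are scaled, and the result is rotated back).
#' All indices are 1-based.
#'
#' @param pairs list of `list(a =, b =, alpha =)` entries; `a`, `b` are
#'   integer index vectors (DOFs or atoms depending on `frame`), disjoint
#'   within each entry.
#' @param frame `"normal_mode"` or `"cartesian_atoms"`.
#' @param frozen_modes integer vector of normal-mode indices whose
#'   coordinate and momentum are clamped to zero after every step.
#' @return object of class `decoupling_spec`.
#' @export
decoupling_spec <- function(pairs = list(), frame = c("normal_mode", "cartesian_atoms"),
                            frozen_modes = integer()) {
  frame <- match.arg(frame)
  for (p in pairs) {
    if (!all(c("a", "b", "alpha") %in% names(p)))
      stop("each pair needs fields a, b, alpha", call. = FALSE)
    if (length(intersect(p$a, p$b)) > 0)
      stop("decoupled groups must be disjoint", call. = FALSE)
    if (!(p$alpha >= 0 && p$alpha <= 1))
      stop("alpha must lie in [0, 1]", call. = FALSE)
    if (any(c(p$a, p$b) < 1) || any(c(p$a, p$b) != round(c(p$a, p$b))))
      stop("group indices must be positive integers (1-based)", call. = FALSE)
  }
  structure(list(pairs = pairs, frame = frame,
                 frozen_modes = as.integer(frozen_modes)),
            class = "decoupling_spec")
}

#' @export
print.decoupling_spec <- function(x, ...) {
  cat(sprintf("<decoupling_spec> frame: %s, %d pair(s), %d frozen mode(s)\n",
              x$frame, length(x$pairs), length(x$frozen_modes)))
  for (p in x$pairs)
    cat(sprintf("  {%s} x {%s}: alpha = %g\n", paste(p$a, collapse = ","),
                paste(p$b, collapse = ","), p$alpha))
  invisible(x)
}

# Element-wise scaling mask for an n x n Hessian.  Contradictory alphas for
# the same element across pairs are an error, not a silent override.
decoupling_mask <- function(n, pairs) {
  mask <- matrix(1, n, n)
  set <- matrix(FALSE, n, n)
  for (p in pairs) {
    if (max(c(p$a, p$b)) > n)
      stop("group index out of range (Hessian is ", n, " x ", n, ")", call. = FALSE)
    for (i in p$a) for (j in p$b) {
      if ((set[i, j] && mask[i, j] != p$alpha))
        stop("contradictory alpha for element (", i, ",", j, ")", call. = FALSE)
      mask[i, j] <- mask[j, i] <- p$alpha
      set[i, j] <- set[j, i] <- TRUE
    }
  }
  mask
}

#' Scale Hessian elements across decoupled group pairs
#'
#' `h[i, j] <- alpha * h[i, j]` exactly when `i` and `j` fall on opposite
#' sides of a decoupled group pair; all other elements, including the whole
#' diagonal, pass through untouched.  Symmetry and trace are preserved
#' exactly.  With `alpha = 0` between groups that partition all DOFs the
#' result is block diagonal: the Hessian of independent subsystems.
#'
#' @param h symmetric Hessian matrix.
#' @param spec a [decoupling_spec()] (its `pairs` are interpreted as DOF
#'   indices in the frame of `h`).
#' @return scaled symmetric matrix.
#' @export
scale_hessian_pairs <- function(h, spec) {
  check_symmetric(h)
  if (length(spec$pairs) == 0L) return(h)
  h * decoupling_mask(nrow(h), spec$pairs)
}

#' Atom-pair decoupling of a normal-mode Hessian
#'
#' Implements the rotate-scale-rotate scheme for decoupling whole atoms:
#' the normal-mode Hessian is rotated to mass-weighted Cartesian
#' coordinates with the orthonormal mode matrix `U` (`h_cart = U h U'`),
#' the 3x3 blocks coupling each decoupled atom pair (the Cartesian product
#' of their x, y, z components) are scaled by `alpha`, and the result is
#' rotated back (`U' h_cart_scaled U`).  Because `U` has orthonormal
#' columns, `alpha = 1` returns the input to machine precision.
#'
#' @param h_nm Hessian in the vibrational normal-mode frame.
#' @param basis a [compute_normal_modes()] result.
#' @param spec a [decoupling_spec()] with `frame = "cartesian_atoms"`;
#'   group indices are atom numbers.
#' @return decoupled Hessian in the normal-mode frame.
#' @export
cartesian_atom_decoupled_hessian <- function(h_nm, basis, spec) {
  if (spec$frame != "cartesian_atoms")
    stop("spec frame must be 'cartesian_atoms'", call. = FALSE)
  nat <- basis$system$n_atoms
  dof_pairs <- lapply(spec$pairs, function(p) {
    if (max(c(p$a, p$b)) > nat) stop("atom index out of range", call. = FALSE)
    list(a = as.integer(outer(1:3, (p$a - 1L) * 3L, `+`)),
         b = as.integer(outer(1:3, (p$b - 1L) * 3L, `+`)),
         alpha = p$alpha)
  })
  U <- basis$mode_matrix
  h_cart <- U %*% h_nm %*% t(U)
  h_cart <- (h_cart + t(h_cart)) / 2
  h_scaled <- h_cart * decoupling_mask(nrow(h_cart), dof_pairs)
  hn <- crossprod(U, h_scaled %*% U)
  (hn + t(hn)) / 2
}

# Build the function(q_hat) -> decoupled Hessian used by the SEF inner loop.
decoupled_hessian_fn <- function(surface, spec = NULL, basis = NULL) {
  if (is.null(spec) || length(spec$pairs) == 0L) {
    fn <- function(q) surface$hessian_at(q)
  } else if (spec$frame == "normal_mode") {
    mask <- decoupling_mask(surface$dof_count, spec$pairs)
    fn <- function(q) surface$hessian_at(q) * mask
  } else {
    if (is.null(basis))
      stop("cartesian_atoms decoupling requires a normal_mode_basis", call. = FALSE)
    fn <- function(q) cartesian_atom_decoupled_hessian(surface$hessian_at(q), basis, spec)
  }
  fn
}

#' Clamp frozen normal modes to equilibrium
#'
#' Sets the coordinate, momentum, force-estimate and auxiliary-position
#' components of every frozen mode to exactly zero, leaving all other modes
#' untouched.  Applied after every integration step by [propagate()], this
#' keeps the listed modes at equilibrium throughout the run.
#'
#' @param state a [phase_state()].
#' @param spec a [decoupling_spec()]; an empty `frozen_modes` set is a
#'   no-op.
#' @return the clamped state.
#' @export
apply_mode_freezing <- function(state, spec) {
  fz <- spec$frozen_modes
  if (length(fz) == 0L) return(state)
  if (max(fz) > length(state$q))
    stop("frozen mode index out of range", call. = FALSE)
  state$q[fz] <- 0; state$p[fz] <- 0
  state$f_tilde[fz] <- 0; state$q_hat[fz] <- 0
  state
}
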