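#' Physical constants (atomic units)
#'
#' `bohr_per_angstrom` (1 A = 1.8897259886 bohr), `cm1_per_hartree`
#' (1 hartree = 219474.63 cm^-1), `fs_per_au_time` (1 au of time =
#' 0.02418884254 fs) and `amu_to_au` (electron masses per unified amu).
#'
#' @format named numeric vector.
#' @export
sef_constants <- c(bohr_per_angstrom = 1.8897259886,
                   cm1_per_hartree = 219474.63,
                   fs_per_au_time = 0.02418884254,
                   amu_to_au = 1822.888486)

# standard atomic weights (amu) for the elements the fixtures use
.atomic_weights <- c(H = 1.00783, C = 12.0, N = 14.00307, O = 15.99491,
                     F = 18.99840, S = 31.97207, Cl = 34.96885)

#' Molecular system: labels, masses and equilibrium geometry
#'
#' @param atom_labels character vector of element symbols.
#' @param equilibrium_geometry Cartesian coordinates, length `3 * n_atoms`,
#'   in bohr, ordered `x1, y1, z1, x2, ...`.
#' @param masses per-atom masses in electron-mass atomic units; by default
#'   looked up from the element symbols (standard atomic weights times
#'   1822.888486).
#' @return object of class `molecular_system`.
#' @export
molecular_system <- function(atom_labels, equilibrium_geometry, masses = NULL) {
  n <- length(atom_labels)
  x <- as.numeric(equilibrium_geometry)
  if (length(x) != 3L * n)
    stop("geometry length must be 3 * n_atoms", call. = FALSE)
  if (is.null(masses)) {
    w <- .atomic_weights[atom_labels]
    if (anyNA(w))
      stop("unknown element symbol(s): ",
           paste(unique(atom_labels[is.na(w)]), collapse = ", "), call. = FALSE)
    masses <- unname(w) * sef_constants[["amu_to_au"]]
  }
  masses <- as.numeric(masses)
  if (length(masses) != n || any(masses <= 0))
    stop("masses must be strictly positive, one per atom", call. = FALSE)
  structure(list(atom_labels = as.character(atom_labels),
                 masses = masses,
                 equilibrium_geometry = x,
                 n_atoms = n),
            class = "molecular_system")
}

#' @export
print.molecular_system <- function(x, ...) {
  cat(sprintf("<molecular_system> %d atoms: %s\n", x$n_atoms,
              paste(x$atom_labels, collapse = " ")))
  invisible(x)
}

#' Read an XYZ file
#'
#' Standard XYZ: atom-count line, comment line, then `element x y z` in
#' Angstrom.  Multi-frame files are supported; coordinates are converted to
#' bohr.
#'
#' @param path file path.
#' @return for a single frame, a [molecular_system()] (the comment is
#'   attached as attribute `"comment"`); for multiple frames, a list with
#'   `system` (from frame 1) and `frames`, a matrix of geometries (bohr,
#'   one row per frame).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); comments <- character(); labels <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop("malformed XYZ: expected atom count at line ", i, call. = FALSE)
    if (i + 1L + nat > length(lines))
      stop("malformed XYZ: truncated frame at line ", i, call. = FALSE)
    comments <- c(comments, lines[i + 1L])
    rec <- strsplit(trimws(lines[(i + 2L):(i + 1L + nat)]), "[[:space:]]+")
    lab <- vapply(rec, `[[`, "", 1L)
    xyz <- t(vapply(rec, function(r) as.numeric(r[2:4]), numeric(3)))
    if (anyNA(xyz)) stop("malformed XYZ coordinates near line ", i + 2L, call. = FALSE)
    if (is.null(labels)) labels <- lab
    frames[[length(frames) + 1L]] <- as.numeric(t(xyz)) * sef_constants[["bohr_per_angstrom"]]
    i <- i + 2L + nat
  }
  if (length(frames) == 0L) stop("empty XYZ file", call. = FALSE)
  sys <- molecular_system(labels, frames[[1L]])
  attr(sys, "comment") <- comments[1L]
  if (length(frames) == 1L) return(sys)
  list(system = sys, frames = do.call(rbind, frames), comments = comments)
}

#' Write geometries to an XYZ file
#'
#' @param system a [molecular_system()].
#' @param geometries numeric vector (one frame) or matrix with one row per
#'   frame, Cartesian bohr.
#' @param path output path.
#' @param comments character vector of per-frame comment lines.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(system, geometries, path, comments = NULL) {
  if (is.null(dim(geometries))) geometries <- matrix(geometries, nrow = 1)
  if (!all(is.finite(geometries)))
    stop("refusing to write non-finite coordinates", call. = FALSE)
  nfr <- nrow(geometries)
  if (is.null(comments)) comments <- rep("", nfr)
  out <- character(0)
  ang <- geometries / sef_constants[["bohr_per_angstrom"]]
  for (f in seq_len(nfr)) {
    r <- matrix(ang[f, ], nrow = 3)
    out <- c(out, as.character(system$n_atoms), comments[f],
             sprintf("%-2s %18.10f %18.10f %18.10f",
                     system$atom_labels, r[1, ], r[2, ], r[3, ]))
  }
  writeLines(out, path)
  invisible(path)
}
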