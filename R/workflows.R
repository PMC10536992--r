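#' Run a full simulation from a configuration
#'
#' Configuration-driven end-to-end run: build (or accept) the system,
#' propagate with the requested scheme and decoupling, and optionally
#' compute diagnostics and the power spectrum, writing each artifact to the
#' requested path.  Defaults mirror the package's standard protocol:
#' `dt = 10` au, 3000 steps, no discard (use 5000 steps with 2000
#' discarded when the decoupling effect is weak and the fragments need
#' about 0.5 ps to decorrelate).
#'
#' The configuration is a named list (or a YAML file via
#' [read_run_config()]) with fields:
#' \describe{
#'   \item{fixture}{fixture name for [make_fixture()] (with optional
#'     `seed`), or}
#'   \item{system/surface}{a [molecular_system()] + Cartesian surface pair
#'     (propagation then runs in the normal-mode frame), or `surface`
#'     alone for abstract-DOF surfaces.}
#'   \item{scheme}{integrator name, default `"SEF2"`.}
#'   \item{dt, n_steps, discard_steps}{protocol numbers, defaults 10 au /
#'     3000 / 0.}
#'   \item{decouple}{list of `list(frame =, groups = list(a, b),
#'     alpha =)` entries (all 1-based indices).}
#'   \item{freeze_modes}{integer vector of normal-mode indices.}
#'   \item{initial}{`"zpe"` (default) or a [phase_state()].}
#'   \item{outputs}{named paths: `trajectory` (XYZ, Cartesian systems
#'     only), `spectrum` (TSV), `diagnostics` (TSV of the energy
#'     series).}
#' }
#'
#' @param config named list as described above.
#' @return list with `trajectory`, `spectrum` (or `NULL`), `energy`
#'   (summary from [energy_series()]), `basis` (or `NULL`) and
#'   `hessian_calls`.
#' @export
run_from_config <- function(config) {
  scheme <- get_scheme(config$scheme %||% "SEF2")
  dt <- config$dt %||% 10
  n_steps <- as.integer(config$n_steps %||% 3000L)
  discard <- as.integer(config$discard_steps %||% 0L)
  if (discard >= n_steps)
    stop("config error: discard_steps must be smaller than n_steps", call. = FALSE)

  basis <- NULL
  if (!is.null(config$fixture)) {
    fx <- make_fixture(config$fixture, seed = config$seed %||% 1L)
    surface <- fx$surface
  } else if (!is.null(config$system)) {
    cart <- config$surface
    basis <- compute_normal_modes(config$system, cart)
    surface <- normal_mode_surface(basis, cart)
  } else if (!is.null(config$surface)) {
    surface <- config$surface
  } else stop("config needs a 'fixture', a 'system' + 'surface', or a 'surface'",
              call. = FALSE)

  spec <- NULL
  if (!is.null(config$decouple) || !is.null(config$freeze_modes)) {
    pairs <- lapply(config$decouple %||% list(), function(d)
      list(a = as.integer(d$groups[[1]]), b = as.integer(d$groups[[2]]),
           alpha = d$alpha))
    frame <- if (length(config$decouple %||% list()) > 0)
      config$decouple[[1]]$frame %||% "normal_mode" else "normal_mode"
    spec <- decoupling_spec(pairs, frame = frame,
                            frozen_modes = as.integer(config$freeze_modes %||% integer()))
  }

  init <- config$initial %||% "zpe"
  if (identical(init, "zpe")) {
    init <- if (!is.null(basis)) zpe_initial_state(basis) else {
      h0 <- surface$hessian_at(surface$reference_geometry)
      ev <- eigen((h0 + t(h0)) / 2, symmetric = TRUE)$values
      if (any(ev <= 0))
        stop("surface is not at a positive-definite minimum; supply 'initial'",
             call. = FALSE)
      zpe_initial_state(sqrt(rev(ev)))
    }
  }

  traj <- propagate(init, surface, scheme, n_steps, dt, spec, basis,
                    discard_steps = discard)
  en <- energy_series(traj)
  spec_res <- NULL
  if (isTRUE(config$compute_spectrum %||% TRUE))
    spec_res <- total_power_spectrum(traj)

  outputs <- config$outputs %||% list()
  written <- character()
  on_fail_cleanup <- function() for (p in written) if (file.exists(p)) unlink(p)
  tryCatch({
    if (!is.null(outputs$spectrum) && !is.null(spec_res)) {
      write_spectrum_tsv(spec_res, outputs$spectrum)
      written <- c(written, outputs$spectrum)
    }
    if (!is.null(outputs$diagnostics)) {
      utils::write.table(
        data.frame(t = traj$times, energy = en$energy),
        outputs$diagnostics, sep = "\t", row.names = FALSE, quote = FALSE)
      written <- c(written, outputs$diagnostics)
    }
    if (!is.null(outputs$trajectory)) {
      if (is.null(basis))
        stop("XYZ trajectory output needs a Cartesian system", call. = FALSE)
      write_xyz_trajectory(traj, basis, outputs$trajectory)
      written <- c(written, outputs$trajectory)
    }
  }, error = function(e) { on_fail_cleanup(); stop(e) })

  list(trajectory = traj, spectrum = spec_res, energy = en, basis = basis,
       hessian_calls = traj$hessian_calls)
}

#' Read a YAML run configuration
#'
#' @param path YAML file with the fields documented in
#'   [run_from_config()].
#' @return named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("configuration must be a YAML mapping", call. = FALSE)
  cfg
}

#' Write a normal-mode trajectory as multi-frame XYZ
#'
#' Transforms each stored frame back to Cartesian coordinates and writes a
#' standard multi-frame XYZ file (Angstrom); the comment line carries the
#' frame time in fs.
#'
#' @param trajectory a [propagate()] result in the normal-mode frame.
#' @param basis the [compute_normal_modes()] basis used for propagation.
#' @param path output path.
#' @param stride write every `stride`-th frame.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(trajectory, basis, path, stride = 1L) {
  idx <- seq(1L, nrow(trajectory$q), by = stride)
  geoms <- t(vapply(idx, function(i)
    to_cartesian_coordinates(basis, trajectory$q[i, ]),
    numeric(length(basis$masses3))))
  comments <- sprintf("t = %.4f fs",
                      trajectory$times[idx] * sef_constants[["fs_per_au_time"]])
  write_xyz(basis$system, geoms, path, comments)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
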