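#' Power spectrum of one normal-mode momentum series
#'
#' Classical vibrational power spectrum
#' `I_j(w) = |int_0^T p_j(t) exp(-i w t) dt|^2 / (2 pi T)`
#' over the retained simulation span `T`, discretized with a rectangular
#' window by FFT of the retained samples.  The frequency resolution is
#' `dw = 2 pi / T`; peak positions give the anharmonic vibrational
#' frequencies, while absolute intensities depend on the initial
#' conditions and are not comparable to IR or Raman intensities.
#'
#' The spectrum is folded one-sided (the negative-frequency half is added
#' onto the positive grid), which makes the discrete integral identity
#' `sum(I_j) * dw = mean(p_j^2) = 2 x` mean kinetic energy of the mode
#' hold exactly (discrete Parseval with a rectangular window).
#'
#' @param p_series numeric vector of momentum samples, spaced `dt` apart.
#' @param dt sampling interval (au of time).
#' @param discard number of leading samples to drop (decorrelation time).
#' @param zero_pad integer factor; > 1 pads the series with zeros to refine
#'   the frequency grid for peak readout (the integral identity above then
#'   refers to the padded span).
#' @return list with `omega_au`, `omega_cm1`, `intensity`, `domega_au`,
#'   `T_used` (au).
#' @export
mode_power_spectrum <- function(p_series, dt, discard = 0L, zero_pad = 1L) {
  p <- as.numeric(p_series)
  if (discard >= length(p)) stop("discard exceeds series length", call. = FALSE)
  if (discard > 0L) p <- p[-seq_len(discard)]
  if (length(p) < 64L)
    stop("fewer than 64 retained samples: spectrum would be meaningless",
         call. = FALSE)
  zero_pad <- max(1L, as.integer(zero_pad))
  n_raw <- length(p)
  if (zero_pad > 1L) p <- c(p, numeric((zero_pad - 1L) * n_raw))
  n <- length(p)
  T_used <- n * dt
  ft <- stats::fft(p) * dt                    # approx int p exp(-iwt) dt
  I_full <- Mod(ft)^2 / (2 * pi * T_used)
  half <- floor(n / 2)
  I <- I_full[seq_len(half + 1L)]             # bins 0..half
  if (half >= 1L) {
    interior <- 2:(if (n %% 2 == 0) half else half + 1L)
    I[interior] <- I[interior] + I_full[n + 2L - interior]
  }
  domega <- 2 * pi / T_used
  omega <- domega * (0:half)
  list(omega_au = omega,
       omega_cm1 = omega * sef_constants[["cm1_per_hartree"]],
       intensity = I,
       domega_au = domega,
       T_used = T_used)
}

#' Total and per-mode power spectra of a trajectory
#'
#' Computes the power spectrum of every (non-frozen) mode's momentum series
#' and their pointwise sum.  Frozen modes are excluded from the sum and
#' reported in `frozen_modes`.
#'
#' @param trajectory a [propagate()] result whose momenta are in the
#'   normal-mode frame.
#' @param discard leading steps to drop; defaults to the trajectory's
#'   `discard_steps`.
#' @param zero_pad passed to [mode_power_spectrum()].
#' @return object of class `spectrum_result`: `omega_au`, `omega_cm1`,
#'   `mode_intensities` (modes in columns), `total_intensity`,
#'   `domega_au`, `T_used`, `discarded_steps`, `frozen_modes`.
#' @export
total_power_spectrum <- function(trajectory, discard = NULL, zero_pad = 1L) {
  if (is.null(discard)) discard <- trajectory$discard_steps
  nmodes <- ncol(trajectory$p)
  frozen <- integer()
  if (!is.null(trajectory$spec)) frozen <- trajectory$spec$frozen_modes
  active <- setdiff(seq_len(nmodes), frozen)
  spectra <- lapply(active, function(j)
    mode_power_spectrum(trajectory$p[, j], trajectory$dt, discard, zero_pad))
  grid <- spectra[[1L]]
  mode_I <- matrix(0, length(grid$omega_au), nmodes)
  for (k in seq_along(active)) mode_I[, active[k]] <- spectra[[k]]$intensity
  structure(list(omega_au = grid$omega_au,
                 omega_cm1 = grid$omega_cm1,
                 mode_intensities = mode_I,
                 total_intensity = rowSums(mode_I),
                 domega_au = grid$domega_au,
                 T_used = grid$T_used,
                 discarded_steps = as.integer(discard),
                 frozen_modes = frozen),
            class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf(
    "<spectrum_result> %d modes, %d grid points, resolution %.1f cm^-1\n",
    ncol(x$mode_intensities), length(x$omega_au),
    x$domega_au * sef_constants[["cm1_per_hartree"]]))
  pk <- peak_frequencies(x, prominence = 0.1)
  if (nrow(pk) > 0) {
    cat("  peaks (>= 10% of max):\n")
    print(utils::head(pk, 12), row.names = FALSE)
  }
  invisible(x)
}

#' Locate spectral peaks
#'
#' Local maxima of each mode's spectrum (and of the total) above
#' `prominence` times the global maximum, ordered by frequency.
#'
#' @param result a [total_power_spectrum()] result.
#' @param prominence fraction of the global maximum below which maxima are
#'   ignored; > 0.
#' @param total_only report only peaks of the summed spectrum.
#' @return data frame with columns `mode` (0 = total), `omega_au`,
#'   `omega_cm1`, `intensity`.
#' @export
peak_frequencies <- function(result, prominence = 0.1, total_only = FALSE) {
  if (!(prominence > 0)) stop("prominence must be positive", call. = FALSE)
  gmax <- max(result$total_intensity)
  find1 <- function(y) {
    n <- length(y)
    if (n < 3L) return(integer())
    idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
    idx[y[idx] >= prominence * gmax]
  }
  rows <- list()
  add <- function(mode, idx) {
    if (length(idx) == 0L) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      mode = mode,
      omega_au = result$omega_au[idx],
      omega_cm1 = result$omega_cm1[idx],
      intensity = if (mode == 0L) result$total_intensity[idx]
                  else result$mode_intensities[idx, mode])
  }
  add(0L, find1(result$total_intensity))
  if (!total_only)
    for (j in seq_len(ncol(result$mode_intensities)))
      add(j, find1(result$mode_intensities[, j]))
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(mode = integer(), omega_au = numeric(),
                         omega_cm1 = numeric(), intensity = numeric())
  out[order(out$mode, out$omega_au), , drop = FALSE]
}

#' Write a spectrum to TSV
#'
#' Columns: `omega_au`, `omega_cm1`, `I_total`, then one `I_mode_<j>`
#' column per mode.
#'
#' @param result a [total_power_spectrum()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(result, path) {
  df <- data.frame(omega_au = result$omega_au,
                   omega_cm1 = result$omega_cm1,
                   I_total = result$total_intensity)
  mi <- as.data.frame(result$mode_intensities)
  names(mi) <- paste0("I_mode_", seq_len(ncol(mi)))
  utils::write.table(cbind(df, mi), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
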