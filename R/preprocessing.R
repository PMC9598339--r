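# Pre-processing chain for urine Raman spectra:
# despike -> polynomial baseline removal -> water-band area normalization,
# followed by SNR-based quality filtering. The order matters and is fixed.

#' Pre-processing configuration
#'
#' Bundles every tunable of the spectral clean-up chain.
#'
#' @param despike_window Odd window (channels) for the running median used
#'   to locate cosmic-ray spikes.
#' @param despike_z Spike threshold in robust standard deviations of the
#'   residual from the running median.
#' @param baseline_order Polynomial order of the fluorescence baseline fit.
#' @param baseline_max_iter Maximum clipping iterations of the baseline fit.
#' @param baseline_tol Relative change of the fitted baseline below which
#'   iteration stops.
#' @param water_band_center,water_band_halfwidth Integration window
#'   (cm^-1) of the water/amide band used for area normalization.
#' @param snr_threshold Spectra with estimated SNR below this are excluded.
#' @param snr_signal_window Interval (cm^-1) whose maximum intensity is
#'   taken as signal (default covers the dominant urea band near 1002).
#' @param snr_noise_window Analyte-free interval (cm^-1) whose detrended
#'   standard deviation is taken as noise.
#' @return A list of class `"preprocess_config"`.
#' @export
preprocess_config <- function(despike_window = 5L,
                              despike_z = 8,
                              baseline_order = 5L,
                              baseline_max_iter = 100L,
                              baseline_tol = 1e-6,
                              water_band_center = 1660,
                              water_band_halfwidth = 50,
                              snr_threshold = 10,
                              snr_signal_window = c(950, 1050),
                              snr_noise_window = c(1750, 1800)) {
  despike_window <- as.integer(despike_window)
  if (despike_window < 3L || despike_window %% 2L == 0L) {
    stop("despike_window must be an odd integer >= 3", call. = FALSE)
  }
  if (despike_z <= 0) stop("despike_z must be > 0", call. = FALSE)
  if (baseline_order < 0) stop("baseline_order must be >= 0", call. = FALSE)
  if (snr_threshold <= 0) stop("snr_threshold must be > 0", call. = FALSE)
  stopifnot(length(snr_signal_window) == 2, length(snr_noise_window) == 2,
            snr_signal_window[1] < snr_signal_window[2],
            snr_noise_window[1] < snr_noise_window[2])
  structure(list(despike_window = despike_window,
                 despike_z = despike_z,
                 baseline_order = as.integer(baseline_order),
                 baseline_max_iter = as.integer(baseline_max_iter),
                 baseline_tol = baseline_tol,
                 water_band_center = water_band_center,
                 water_band_halfwidth = water_band_halfwidth,
                 snr_threshold = snr_threshold,
                 snr_signal_window = as.numeric(snr_signal_window),
                 snr_noise_window = as.numeric(snr_noise_window)),
            class = "preprocess_config")
}

.window_idx <- function(wavenumber, lo, hi) {
  idx <- which(wavenumber >= lo & wavenumber <= hi)
  if (!length(idx)) {
    stop("window [", lo, ", ", hi, "] cm^-1 lies outside the spectral axis",
         call. = FALSE)
  }
  idx
}

.trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# ---- despiking ---------------------------------------------------------

#' Remove cosmic-ray spikes
#'
#' Flags channels whose deviation from a running median exceeds
#' `despike_z` robust standard deviations and replaces them by linear
#' interpolation across the neighbouring unflagged channels. The robust
#' scale is the successive-difference estimator
#' `1.4826 x median(|diff(y)|) / sqrt(2)`, which is consistent for white
#' noise and insensitive to both spikes and band structure. Unflagged
#' channels pass through bit-identically. Refuses when more than 20% of
#' channels are flagged: that is a sign of real structure, not cosmic
#' rays.
#'
#' @param s A `raman_spectrum`.
#' @param cfg A [preprocess_config()].
#' @return A `raman_spectrum` with `meta$n_spikes_removed` set.
#' @export
despike <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "raman_spectrum"))
  y <- s$intensity
  n <- length(y)
  if (cfg$despike_window >= n) stop("despike window >= spectrum length", call. = FALSE)
  med <- stats::runmed(y, k = cfg$despike_window, endrule = "median")
  resid <- y - med
  sigma <- 1.4826 * stats::median(abs(diff(y))) / sqrt(2)
  sigma <- max(sigma, .Machine$double.eps * max(abs(y), 1))
  flagged <- which(abs(resid) > cfg$despike_z * sigma)
  if (length(flagged) > 0.2 * n) {
    stop("excessive spikes: ", length(flagged), " of ", n,
         " channels flagged (> 20%); refusing to despike", call. = FALSE)
  }
  out <- y
  if (length(flagged)) {
    keep <- setdiff(seq_len(n), flagged)
    out[flagged] <- stats::approx(s$wavenumber[keep], y[keep],
                                  xout = s$wavenumber[flagged],
                                  method = "linear", rule = 2)$y
  }
  meta <- s$meta
  meta$n_spikes_removed <- length(flagged)
  raman_spectrum(s$wavenumber, out, meta)
}

# ---- fluorescence baseline ---------------------------------------------

#' Iterative polynomial baseline removal
#'
#' Fits a polynomial of order `baseline_order` by least squares, clips the
#' working spectrum to the fit wherever it lies above it (so Raman peaks
#' are progressively excluded from the fit), and repeats until the fitted
#' baseline changes by less than `baseline_tol` in relative norm or
#' `baseline_max_iter` is reached. The corrected spectrum plus the
#' baseline reconstructs the input exactly.
#'
#' @param s A `raman_spectrum`.
#' @param cfg A [preprocess_config()].
#' @return List with elements `corrected` and `baseline`, both
#'   `raman_spectrum`; `corrected$meta$baseline_converged` records whether
#'   the iteration converged before the cap.
#' @export
remove_baseline <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "raman_spectrum"))
  y <- s$intensity
  n <- length(y)
  if (n <= cfg$baseline_order + 1L) {
    stop("spectrum length must exceed baseline_order + 1", call. = FALSE)
  }
  # scaled abscissa in [-1, 1] keeps the Vandermonde basis well conditioned
  u <- 2 * (s$wavenumber - s$wavenumber[1]) /
    (s$wavenumber[n] - s$wavenumber[1]) - 1
  basis <- outer(u, 0:cfg$baseline_order, `^`)
  w <- y
  fit_prev <- rep(0, n)
  converged <- FALSE
  for (it in seq_len(cfg$baseline_max_iter)) {
    fit <- drop(basis %*% qr.coef(qr(basis), w))
    delta <- sqrt(sum((fit - fit_prev)^2))
    if (delta <= cfg$baseline_tol * max(sqrt(sum(fit_prev^2)), 1e-12)) {
      converged <- TRUE
      break
    }
    fit_prev <- fit
    w <- pmin(w, fit)
  }
  meta <- s$meta
  meta$baseline_converged <- converged
  list(corrected = raman_spectrum(s$wavenumber, y - fit, meta),
       baseline = raman_spectrum(s$wavenumber, fit, s$meta))
}

# ---- water-band normalization ------------------------------------------

#' Normalize by the area of the water band
#'
#' Divides every intensity by the trapezoidal integral of the
#' (baseline-corrected) spectrum over the window
#' `water_band_center +/- water_band_halfwidth`. After normalization the
#' band area is exactly 1, which removes the collection-geometry and
#' laser-power scale between spectra. Applying the operation twice is a
#' no-op.
#'
#' @param s A baseline-corrected `raman_spectrum`.
#' @param cfg A [preprocess_config()].
#' @return The normalized `raman_spectrum`.
#' @export
normalize_water_band <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "raman_spectrum"))
  idx <- .window_idx(s$wavenumber,
                     cfg$water_band_center - cfg$water_band_halfwidth,
                     cfg$water_band_center + cfg$water_band_halfwidth)
  area <- .trapz(s$wavenumber[idx], s$intensity[idx])
  if (!is.finite(area) || area <= 0) {
    stop("normalization error: nonpositive water-band area (", format(area),
         "); baseline removal may have failed or the band is empty",
         call. = FALSE)
  }
  raman_spectrum(s$wavenumber, s$intensity / area, s$meta)
}

# ---- signal-to-noise ----------------------------------------------------

#' Estimate the signal-to-noise ratio of a corrected spectrum
#'
#' SNR is defined as the maximum intensity inside the signal window
#' (default 950--1050 cm^-1, containing the dominant urea band) divided by
#' the standard deviation of the linearly detrended intensity inside the
#' analyte-free noise window (default 1750--1800 cm^-1). A zero noise
#' standard deviation returns `Inf`.
#'
#' @param s A baseline-corrected `raman_spectrum`.
#' @param cfg A [preprocess_config()].
#' @return Non-negative scalar (possibly `Inf`).
#' @export
estimate_snr <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "raman_spectrum"))
  sig_idx <- .window_idx(s$wavenumber, cfg$snr_signal_window[1],
                         cfg$snr_signal_window[2])
  noi_idx <- .window_idx(s$wavenumber, cfg$snr_noise_window[1],
                         cfg$snr_noise_window[2])
  signal <- max(s$intensity[sig_idx])
  x <- s$wavenumber[noi_idx]
  yv <- s$intensity[noi_idx]
  res <- stats::lm.fit(cbind(1, x), yv)$residuals
  noise <- stats::sd(res)
  # a numerically flat noise window means a noiseless spectrum
  if (!is.finite(noise) || noise <= 1e-12 * max(diff(range(s$intensity)), 1)) {
    return(Inf)
  }
  max(signal, 0) / noise
}

# ---- set-level chain ----------------------------------------------------

#' Run the full pre-processing chain on every spectrum of a set
#'
#' Applies, in order, [despike()], [remove_baseline()] and
#' [normalize_water_band()] to each spectrum and records per-spectrum
#' quality fields in the metadata: `n_spikes_removed`,
#' `baseline_converged`, and `snr` (estimated on the baseline-corrected
#' spectrum, before normalization; the ratio is scale invariant so the
#' value is unchanged by normalization).
#'
#' @param set A raw `spectra_set`.
#' @param cfg A [preprocess_config()].
#' @return The pre-processed `spectra_set` (all spectra retained; use
#'   [qc_filter()] to drop low-SNR spectra).
#' @export
preprocess_spectra <- function(set, cfg = preprocess_config()) {
  stopifnot(inherits(set, "spectra_set"))
  n <- n_spectra(set)
  out <- set$intensities
  n_spikes <- integer(n)
  conv <- logical(n)
  snr <- numeric(n)
  for (i in seq_len(n)) {
    s <- raman_spectrum(set$wavenumber, set$intensities[i, ])
    s <- despike(s, cfg)
    n_spikes[i] <- s$meta$n_spikes_removed
    bl <- remove_baseline(s, cfg)
    conv[i] <- bl$corrected$meta$baseline_converged
    snr[i] <- estimate_snr(bl$corrected, cfg)
    out[i, ] <- normalize_water_band(bl$corrected, cfg)$intensity
  }
  meta <- set$meta
  meta$n_spikes_removed <- n_spikes
  meta$baseline_converged <- conv
  meta$snr <- snr
  spectra_set(set$wavenumber, out, meta)
}

#' Exclude low-SNR spectra
#'
#' Drops spectra whose `snr` falls below `cfg$snr_threshold` and records
#' `qc_pass` for every input spectrum in the returned attribute
#' `"qc_table"`. The retained set is invariant under permutation of the
#' input order.
#'
#' @param set A pre-processed `spectra_set` whose metadata carries `snr`
#'   (as produced by [preprocess_spectra()]); if absent, SNR is estimated
#'   on the spectra as given.
#' @param cfg A [preprocess_config()].
#' @return The filtered `spectra_set`; its metadata has `qc_pass = TRUE`
#'   for every retained spectrum, and the attribute `"qc_table"` holds the
#'   full per-spectrum QC report (spectrum_id, snr, qc_pass,
#'   n_spikes_removed).
#' @export
qc_filter <- function(set, cfg = preprocess_config()) {
  stopifnot(inherits(set, "spectra_set"))
  meta <- set$meta
  if (is.null(meta$snr)) {
    meta$snr <- vapply(seq_len(n_spectra(set)), function(i) {
      estimate_snr(raman_spectrum(set$wavenumber, set$intensities[i, ]), cfg)
    }, numeric(1))
  }
  pass <- meta$snr >= cfg$snr_threshold
  if (!any(pass)) {
    stop("empty set: all ", length(pass), " spectra fall below SNR threshold ",
         cfg$snr_threshold, call. = FALSE)
  }
  meta$qc_pass <- pass
  qc_table <- data.frame(
    spectrum_id = meta$spectrum_id,
    snr = meta$snr,
    qc_pass = pass,
    n_spikes_removed = if (is.null(meta$n_spikes_removed)) NA_integer_ else
      meta$n_spikes_removed,
    stringsAsFactors = FALSE)
  out <- spectra_set(set$wavenumber,
                     set$intensities[pass, , drop = FALSE],
                     meta[pass, , drop = FALSE])
  attr(out, "qc_table") <- qc_table
  out
}

#' Group mean spectra and their difference
#'
#' Channel-wise mean spectrum of each clinical group and the difference
#' DMHBP - CT, the standard display for locating the bands that separate
#' patients from controls.
#'
#' @param set A pre-processed `spectra_set` containing both groups.
#' @return List with `raman_spectrum` elements `mean_ct`, `mean_dm` and
#'   `difference`.
#' @export
group_mean_and_difference <- function(set) {
  stopifnot(inherits(set, "spectra_set"))
  for (g in .valid_groups) {
    if (!any(set$meta$group == g)) {
      stop("group ", g, " is missing from the set", call. = FALSE)
    }
  }
  m_ct <- colMeans(set$intensities[set$meta$group == "CT", , drop = FALSE])
  m_dm <- colMeans(set$intensities[set$meta$group == "DMHBP", , drop = FALSE])
  list(mean_ct = raman_spectrum(set$wavenumber, m_ct, list(group = "CT")),
       mean_dm = raman_spectrum(set$wavenumber, m_dm, list(group = "DMHBP")),
       difference = raman_spectrum(set$wavenumber, m_dm - m_ct,
                                   list(group = "DMHBP-CT")))
}
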