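# Seeded synthetic urine-Raman cohorts. Biomarker concentrations are
# drawn from group-specific distributions matched to published clinical
# urine panels; spectra are built as a linear Beer-Lambert-style mixture
# of per-analyte component spectra plus a water band, a smooth
# fluorescence baseline, Gaussian noise and occasional cosmic-ray spikes.
# Every spectrum carries its ground-truth panel, so recovery of the
# simulated concentrations can be tested with no external data.

# ---- component peak tables ---------------------------------------------

#' Default Raman peak table of the five urine analytes
#'
#' Peak centers follow the band positions observed in dispersive Raman
#' spectra of urine: urea at 516 (overlapping glucose), 587, 1002
#' (dominant) and 1157 cm^-1; creatinine at 678, 846 and 910 cm^-1
#' (overlapping glucose); phosphate at 880, 979 and 1080 cm^-1; glucose
#' at 446, 516, 910, 1080 and 1127 cm^-1; and broad protein bands across
#' 1250--1700 cm^-1. Narrow analyte bands are Lorentzian with 12 cm^-1
#' FWHM; protein bands are Gaussian with 40 cm^-1 FWHM. Relative heights
#' within an analyte reflect the qualitative prominence of the bands
#' (e.g. urea 1002 strongest).
#'
#' @return `data.frame` with columns `analyte`, `center` (cm^-1),
#'   `relative_height`, `fwhm` (cm^-1), `shape`
#'   (`lorentzian`/`gaussian`).
#' @export
default_peak_table <- function() {
  pk <- function(analyte, center, height, fwhm = 12, shape = "lorentzian") {
    data.frame(analyte = analyte, center = center, relative_height = height,
               fwhm = fwhm, shape = shape, stringsAsFactors = FALSE)
  }
  rbind(
    pk("urea", c(516, 587, 1002, 1157), c(0.35, 0.45, 1.00, 0.35)),
    pk("creatinine", c(678, 846, 910), c(1.00, 0.60, 0.50)),
    pk("phosphate", c(880, 979, 1080), c(0.60, 1.00, 0.70)),
    pk("glucose", c(446, 516, 910, 1080, 1127), c(0.70, 0.60, 0.40, 0.60, 1.00)),
    pk("total_protein", c(1265, 1342, 1449, 1555, 1659),
       c(0.50, 0.60, 1.00, 0.30, 0.80), fwhm = 40, shape = "gaussian"))
}

.validate_peak_table <- function(peaks) {
  stopifnot(all(c("analyte", "center", "relative_height", "fwhm", "shape")
                %in% names(peaks)))
  if (any(peaks$center < 400 | peaks$center > 1800)) {
    stop("peak centers must lie within 400-1800 cm^-1", call. = FALSE)
  }
  if (any(peaks$relative_height <= 0)) stop("peak heights must be > 0", call. = FALSE)
  if (any(peaks$fwhm < 4 | peaks$fwhm > 200)) {
    stop("peak FWHM must lie in [4, 200] cm^-1", call. = FALSE)
  }
  if (!all(peaks$shape %in% c("lorentzian", "gaussian"))) {
    stop("peak shape must be lorentzian or gaussian", call. = FALSE)
  }
  peaks
}

.peak_profile <- function(grid, center, height, fwhm, shape) {
  if (shape == "lorentzian") {
    hwhm <- fwhm / 2
    height / (1 + ((grid - center) / hwhm)^2)
  } else {
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    height * exp(-((grid - center)^2) / (2 * sigma^2))
  }
}

#' Unit component spectrum of one analyte
#'
#' Sum of the analyte's peak functions on the grid, scaled so the maximum
#' equals 1. Multiplying by concentration x response coefficient gives
#' the analyte's contribution to a synthetic spectrum.
#'
#' @param analyte One of the five panel analytes.
#' @param grid A `wavenumber_axis`.
#' @param peaks Peak table as from [default_peak_table()].
#' @return A `raman_spectrum` with max intensity 1.
#' @export
component_spectrum <- function(analyte, grid = default_grid(),
                               peaks = default_peak_table()) {
  analyte <- match.arg(analyte, .analytes)
  peaks <- .validate_peak_table(peaks)
  rows <- peaks[peaks$analyte == analyte, , drop = FALSE]
  if (!nrow(rows)) stop("no peaks defined for analyte ", analyte, call. = FALSE)
  grid <- wavenumber_axis(grid)
  y <- rowSums(vapply(seq_len(nrow(rows)), function(i) {
    .peak_profile(as.numeric(grid), rows$center[i], rows$relative_height[i],
                  rows$fwhm[i], rows$shape[i])
  }, numeric(length(grid))))
  raman_spectrum(grid, y / max(y), list(analyte = analyte))
}

# ---- concentration distributions ---------------------------------------

.dist_normal0 <- function(mean, sd) list(family = "normal_truncated0",
                                         mean = mean, sd = sd)
.dist_lnorm <- function(meanlog, sdlog) list(family = "lognormal",
                                             meanlog = meanlog, sdlog = sdlog)
.dist_mixture <- function(p, components) list(family = "mixture", p = p,
                                              components = components)

.default_group_distributions <- function() {
  # DMHBP glucose: 75% adequately controlled (slightly above the control
  # level) and 25% frank glycosuria modelled lognormal with mean ~68
  # mmol/L, so the pooled mean is ~17.3 mmol/L and ~25% of draws exceed
  # the 0.83 mmol/L reference value.
  list(
    CT = list(
      urea = .dist_normal0(271, 89),
      creatinine = .dist_normal0(12.5, 5.5),
      glucose = .dist_normal0(0.23, 0.04),
      phosphate = .dist_normal0(23.4, 14.1),
      total_protein = .dist_normal0(14.7, 5.5)),
    DMHBP = list(
      urea = .dist_normal0(249, 68),
      creatinine = .dist_normal0(9.3, 4.0),
      glucose = .dist_mixture(c(0.75, 0.25),
                              list(.dist_normal0(0.3, 0.1),
                                   .dist_lnorm(log(68) - 0.5, 1.0))),
      phosphate = .dist_normal0(17.2, 9.9),
      total_protein = .dist_normal0(15.6, 7.2)))
}

.draw_dist <- function(dist, n = 1) {
  switch(dist$family,
    normal_truncated0 = {
      if (is.null(dist$mean) || is.null(dist$sd) || dist$sd < 0) {
        stop("configuration error: normal_truncated0 needs mean and sd >= 0",
             call. = FALSE)
      }
      x <- stats::rnorm(n, dist$mean, dist$sd)
      tries <- 0
      while (any(x < 0)) { # resample below-zero draws (truncation at 0)
        x[x < 0] <- stats::rnorm(sum(x < 0), dist$mean, dist$sd)
        tries <- tries + 1
        if (tries > 1000) {
          stop("configuration error: truncated normal rarely positive",
               call. = FALSE)
        }
      }
      x
    },
    lognormal = {
      if (is.null(dist$meanlog) || is.null(dist$sdlog) || dist$sdlog < 0) {
        stop("configuration error: lognormal needs meanlog and sdlog >= 0",
             call. = FALSE)
      }
      stats::rlnorm(n, dist$meanlog, dist$sdlog)
    },
    mixture = {
      if (abs(sum(dist$p) - 1) > 1e-9 || any(dist$p < 0)) {
        stop("configuration error: mixture weights must be >= 0 and sum to 1",
             call. = FALSE)
      }
      comp <- sample.int(length(dist$p), n, replace = TRUE, prob = dist$p)
      x <- numeric(n)
      for (j in seq_along(dist$p)) {
        if (any(comp == j)) x[comp == j] <- .draw_dist(dist$components[[j]],
                                                       sum(comp == j))
      }
      x
    },
    stop("configuration error: unknown distribution family '", dist$family,
         "'", call. = FALSE))
}

# ---- cohort configuration ----------------------------------------------

#' Synthetic cohort configuration
#'
#' Defaults emulate the study design the package targets: 20 samples per
#' group, six replicate spectra each (240 spectra in total), on the
#' default 400--1800 cm^-1 grid, with group concentration distributions
#' matched to the published clinical means and SDs of the five urine
#' biomarkers.
#'
#' @param n_per_group Samples per clinical group (>= 2).
#' @param replicates_per_sample Replicate spectra per sample (>= 1).
#' @param grid A `wavenumber_axis`.
#' @param group_distributions Nested list `group -> analyte ->
#'   distribution` (families `normal_truncated0`, `lognormal`,
#'   `mixture`); see the default for the structure.
#' @param response_coefficients Named vector: signal gain per analyte
#'   (intensity units per mmol/L; per mg/dL for total protein).
#' @param baseline_params List with `coef` (6 polynomial coefficients on
#'   the scaled axis), `scale` (intensity units) and `jitter` (relative
#'   per-spectrum scale variation).
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param spike_rate Expected cosmic-ray spikes per spectrum (Poisson).
#' @param spike_amp Spike amplitude range as multiples of `noise_sd`.
#' @param water_band List with `center`, `height`, `fwhm` of the broad
#'   water band (Gaussian).
#' @param gain_jitter Relative per-replicate multiplicative intensity
#'   variation (collection geometry); removed later by water-band
#'   normalization.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_per_group = 20L,
                          replicates_per_sample = 6L,
                          grid = default_grid(),
                          group_distributions = .default_group_distributions(),
                          response_coefficients = c(urea = 1.5,
                                                    creatinine = 12,
                                                    glucose = 5,
                                                    phosphate = 8,
                                                    total_protein = 4),
                          baseline_params = list(
                            coef = c(1.2, -0.6, 0.3, 0.5, -0.3, 0.2),
                            scale = 200, jitter = 0.2),
                          noise_sd = 2,
                          spike_rate = 0.2,
                          spike_amp = c(20, 100),
                          water_band = list(center = 1660, height = 600,
                                            fwhm = 120),
                          gain_jitter = 0.1,
                          seed = 1L) {
  n_per_group <- as.integer(n_per_group)
  replicates_per_sample <- as.integer(replicates_per_sample)
  if (n_per_group < 2) stop("n_per_group must be >= 2", call. = FALSE)
  if (replicates_per_sample < 1) stop("replicates_per_sample must be >= 1",
                                      call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (spike_rate < 0) stop("spike_rate must be >= 0", call. = FALSE)
  for (g in .valid_groups) {
    missing_a <- setdiff(.analytes, names(group_distributions[[g]]))
    if (length(missing_a)) {
      stop("configuration error: no distribution for ",
           paste(missing_a, collapse = ", "), " in group ", g, call. = FALSE)
    }
  }
  missing_c <- setdiff(.analytes, names(response_coefficients))
  if (length(missing_c)) {
    stop("configuration error: no response coefficient for ",
         paste(missing_c, collapse = ", "), call. = FALSE)
  }
  structure(list(n_per_group = n_per_group,
                 replicates_per_sample = replicates_per_sample,
                 grid = wavenumber_axis(grid),
                 group_distributions = group_distributions,
                 response_coefficients = response_coefficients,
                 baseline_params = baseline_params,
                 noise_sd = noise_sd,
                 spike_rate = spike_rate,
                 spike_amp = spike_amp,
                 water_band = water_band,
                 gain_jitter = gain_jitter,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Draw one biomarker panel for a group
#'
#' Draws the five concentrations from the group's configured
#' distributions, in the fixed analyte order urea, creatinine, glucose,
#' phosphate, total protein. Uses the current RNG state (seed the session
#' or use [generate_cohort()] for reproducible cohorts).
#'
#' @param group `"CT"` or `"DMHBP"`.
#' @param cfg A [cohort_config()].
#' @param sample_id Identifier written into the panel row.
#' @return One-row `biomarker_panels` table.
#' @export
sample_biomarker_panel <- function(group, cfg = cohort_config(),
                                   sample_id = "S1") {
  group <- match.arg(group, .valid_groups)
  dists <- cfg$group_distributions[[group]]
  values <- vapply(.analytes, function(a) .draw_dist(dists[[a]], 1), numeric(1))
  df <- as.data.frame(as.list(values))
  df$sample_id <- sample_id
  biomarker_panels(df)
}

#' Synthesize one urine Raman spectrum from a biomarker panel
#'
#' The forward model is linear in the concentrations:
#' `intensity = gain x (sum_a coefficient_a x concentration_a x
#' component_a + water band) + baseline + noise + spikes`. With noise,
#' baseline, spikes, water band and gain jitter disabled the output is
#' exactly the linear mixture, so superposition holds to machine
#' precision. The ground-truth panel is attached to the metadata.
#'
#' @param panel One-row `biomarker_panels` table.
#' @param cfg A [cohort_config()].
#' @param meta Named list of metadata fields for the spectrum.
#' @param components Optional precomputed list of component spectra on
#'   `cfg$grid` (one per analyte), to avoid recomputation in loops.
#' @return A `raman_spectrum`; `meta$truth` holds the panel.
#' @export
synthesize_spectrum <- function(panel, cfg = cohort_config(), meta = list(),
                                components = NULL) {
  grid <- cfg$grid
  n <- length(grid)
  if (is.null(components)) {
    components <- lapply(.analytes, function(a)
      component_spectrum(a, grid)$intensity)
    names(components) <- .analytes
  }
  if (any(vapply(components, length, integer(1)) != n)) {
    stop("component spectra are not on the configured grid", call. = FALSE)
  }
  signal <- rep(0, n)
  for (a in .analytes) {
    signal <- signal + cfg$response_coefficients[[a]] * panel[[a]][1] *
      components[[a]]
  }
  wb <- cfg$water_band
  if (wb$height != 0) {
    signal <- signal + .peak_profile(as.numeric(grid), wb$center, wb$height,
                                     wb$fwhm, "gaussian")
  }
  # draw order per replicate: gain, baseline jitter, noise vector, spikes
  gain <- if (cfg$gain_jitter > 0)
    stats::runif(1, 1 - cfg$gain_jitter, 1 + cfg$gain_jitter) else 1
  intensity <- gain * signal
  bp <- cfg$baseline_params
  if (bp$scale != 0) {
    u <- 2 * (as.numeric(grid) - grid[1]) / (grid[n] - grid[1]) - 1
    bl_scale <- bp$scale * (if (bp$jitter > 0)
      stats::runif(1, 1 - bp$jitter, 1 + bp$jitter) else 1)
    intensity <- intensity + bl_scale *
      drop(outer(u, seq_along(bp$coef) - 1, `^`) %*% bp$coef)
  }
  if (cfg$noise_sd > 0) {
    intensity <- intensity + stats::rnorm(n, 0, cfg$noise_sd)
  }
  if (cfg$spike_rate > 0) {
    n_spikes <- stats::rpois(1, cfg$spike_rate)
    if (n_spikes > 0) {
      at <- sample.int(n, n_spikes)
      amp <- stats::runif(n_spikes, cfg$spike_amp[1], cfg$spike_amp[2]) *
        max(cfg$noise_sd, 1)
      intensity[at] <- intensity[at] + amp
    }
  }
  meta$truth <- as.data.frame(panel)
  raman_spectrum(grid, intensity, meta)
}

#' Generate a complete synthetic cohort
#'
#' Seeded and reproducible: the configured seed initializes one RNG from
#' which all draws flow in a documented order (per sample: the five panel
#' concentrations; then per replicate: gain, baseline jitter, noise,
#' spikes). Identical seeds give bit-identical cohorts. Sample sex is
#' assigned alternately M/W within each group.
#'
#' @param cfg A [cohort_config()].
#' @return List with `spectra` (a `spectra_set` of
#'   `2 x n_per_group x replicates_per_sample` spectra) and `panels` (a
#'   `biomarker_panels` table with a `group` attribute column carried in
#'   `attr(panels, "groups")` and per-sample `sex` in
#'   `attr(panels, "sex")`).
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  components <- lapply(.analytes, function(a) component_spectrum(a, cfg$grid)$intensity)
  names(components) <- .analytes
  n_total <- 2L * cfg$n_per_group * cfg$replicates_per_sample
  intensities <- matrix(NA_real_, n_total, length(cfg$grid))
  meta <- data.frame(spectrum_id = character(n_total),
                     sample_id = character(n_total),
                     group = character(n_total),
                     sex = character(n_total),
                     replicate_index = integer(n_total),
                     stringsAsFactors = FALSE)
  panels <- vector("list", 2L * cfg$n_per_group)
  groups_of_sample <- character(2L * cfg$n_per_group)
  sex_of_sample <- character(2L * cfg$n_per_group)
  row <- 0L
  samp <- 0L
  for (g in .valid_groups) {
    for (i in seq_len(cfg$n_per_group)) {
      samp <- samp + 1L
      sid <- sprintf("%s%02d", g, i)
      sex <- if (i %% 2L == 1L) "M" else "W"
      panel <- sample_biomarker_panel(g, cfg, sample_id = sid)
      panels[[samp]] <- as.data.frame(panel)
      groups_of_sample[samp] <- g
      sex_of_sample[samp] <- sex
      for (r in seq_len(cfg$replicates_per_sample)) {
        row <- row + 1L
        s <- synthesize_spectrum(panel, cfg, components = components)
        intensities[row, ] <- s$intensity
        meta$spectrum_id[row] <- sprintf("%s_r%d", sid, r)
        meta$sample_id[row] <- sid
        meta$group[row] <- g
        meta$sex[row] <- sex
        meta$replicate_index[row] <- r
      }
    }
  }
  panels <- biomarker_panels(do.call(rbind, panels))
  attr(panels, "groups") <- groups_of_sample
  attr(panels, "sex") <- sex_of_sample
  list(spectra = spectra_set(cfg$grid, intensities, meta), panels = panels)
}
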