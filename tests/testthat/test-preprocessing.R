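test_that("despike replaces isolated spikes and leaves clean channels alone", {
  s <- smooth_spectrum()
  spiked <- s
  j <- 300
  spiked$intensity[j] <- 100 * spiked$intensity[j]
  out <- despike(spiked)
  expect_identical(out$intensity[-j], spiked$intensity[-j])
  # replacement is the interpolation of the flanking channels
  expect_equal(out$intensity[j],
               mean(spiked$intensity[c(j - 1, j + 1)]), tolerance = 1e-12)
  expect_equal(out$meta$n_spikes_removed, 1L)

  clean <- despike(s)
  expect_identical(clean$intensity, s$intensity)
  expect_equal(clean$meta$n_spikes_removed, 0L)
})

test_that("adjacent spike pairs are bridged by linear interpolation", {
  s <- smooth_spectrum()
  j <- c(412, 413)
  s$intensity[j] <- s$intensity[j] + 5000
  out <- despike(s)
  x <- s$wavenumber
  y <- smooth_spectrum()$intensity
  # hand-computed straight line across the gap: flanking unflagged
  # channels are 411 and 414
  slope <- (y[414] - y[411]) / (x[414] - x[411])
  expect_equal(out$intensity[412], y[411] + slope * (x[412] - x[411]),
               tolerance = 1e-9)
  expect_equal(out$intensity[413], y[411] + slope * (x[413] - x[411]),
               tolerance = 1e-9)
  expect_equal(out$meta$n_spikes_removed, 2L)
})

test_that("despike refuses spectra where >20% of channels deviate", {
  set.seed(1)
  axis <- default_grid()
  y <- 100 + rnorm(length(axis))
  # 22% of channels spiked, in isolated pairs so the scale estimate stays
  # noise-dominated
  for (k in seq(5, 690, by = 9)) y[c(k, k + 2)] <- y[c(k, k + 2)] + 1000
  expect_error(despike(raman_spectrum(axis, y)), "excessive spikes")
})

test_that("baseline removal recovers an exact polynomial completely", {
  axis <- default_grid()
  u <- 2 * (axis - 400) / 1400 - 1
  y <- 300 + 80 * u - 40 * u^2 + 25 * u^3 - 10 * u^4 + 5 * u^5
  res <- remove_baseline(raman_spectrum(axis, y))
  expect_lt(max(abs(res$corrected$intensity)), 1e-6 * diff(range(y)))
  expect_true(res$corrected$meta$baseline_converged)
  # corrected + baseline reconstructs the input
  expect_lt(max(abs(res$corrected$intensity + res$baseline$intensity - y)), 1e-9)
})

test_that("baseline removal recovers a known peak on a polynomial background", {
  axis <- default_grid()
  u <- 2 * (as.numeric(axis) - 400) / 1400 - 1
  base <- 500 + 150 * u - 60 * u^2 + 30 * u^3 + 20 * u^4 - 10 * u^5
  peak <- lorentzian(as.numeric(axis), 1002, 1000, 12)
  res <- remove_baseline(raman_spectrum(axis, base + peak))
  got <- max(res$corrected$intensity[abs(axis - 1002) <= 6])
  expect_gt(got, 950)
  expect_lt(got, 1050)
})

test_that("order-0 baseline stays at or below a constant background", {
  axis <- default_grid()
  # compactly supported (Gaussian) peak: the far channels sit exactly on
  # the constant, which the order-0 fit must not exceed
  x <- as.numeric(axis)
  y <- 100 + 800 * exp(-((x - 900)^2) / (2 * (12 / 2.3548)^2))
  cfg <- preprocess_config(baseline_order = 0)
  res <- remove_baseline(raman_spectrum(axis, y), cfg)
  expect_lte(max(res$baseline$intensity), 100 + 1e-6)
  got <- max(res$corrected$intensity[abs(axis - 900) <= 6])
  expect_gt(got, 760)
  expect_lt(got, 840)
})

test_that("fitted baselines never exceed the input maximum", {
  set.seed(42)
  axis <- default_grid()
  for (i in 1:5) {
    y <- 200 * runif(1) + cumsum(rnorm(length(axis), 0, 0.5)) +
      lorentzian(as.numeric(axis), runif(1, 600, 1400), 500, 12)
    res <- remove_baseline(raman_spectrum(axis, y))
    expect_lte(max(res$baseline$intensity), max(y) + 1e-8)
  }
})

test_that("water-band normalization fixes the band area at one and is idempotent", {
  axis <- default_grid()
  x <- as.numeric(axis)
  y <- lorentzian(x, 1002, 50, 12) + 30 * exp(-((x - 1660)^2) / (2 * 50^2))
  s <- raman_spectrum(axis, y)
  cfg <- preprocess_config()
  n1 <- normalize_water_band(s, cfg)
  idx <- which(x >= 1610 & x <= 1710)
  area <- sum(diff(x[idx]) * (n1$intensity[idx][-1] +
                                n1$intensity[idx][-length(idx)]) / 2)
  expect_equal(area, 1, tolerance = 1e-9)
  # scale invariance: normalizing a scaled copy gives the same spectrum
  scaled <- normalize_water_band(raman_spectrum(axis, 7.3 * y), cfg)
  expect_equal(scaled$intensity, n1$intensity, tolerance = 1e-12)
  # idempotence
  n2 <- normalize_water_band(n1, cfg)
  expect_equal(n2$intensity, n1$intensity, tolerance = 1e-12)
  expect_error(normalize_water_band(raman_spectrum(axis, rep(0, length(x)))),
               "normalization error")
})

test_that("SNR estimates track a constructed amplitude/noise ratio", {
  axis <- default_grid()
  x <- as.numeric(axis)
  peak <- lorentzian(x, 1002, 50, 12)
  set.seed(99)
  vals <- replicate(100, {
    estimate_snr(raman_spectrum(axis, peak + rnorm(length(x), 0, 5)))
  })
  expect_gt(mean(vals), 8)
  expect_lt(mean(vals), 12)
  # zero-noise limit: a compact noiseless band gives the Inf sentinel
  gauss <- 50 * exp(-((x - 1002)^2) / (2 * 5^2))
  expect_identical(estimate_snr(raman_spectrum(axis, gauss)), Inf)
})

test_that("pure noise rarely reaches the SNR acceptance threshold", {
  axis <- default_grid()
  x <- as.numeric(axis)
  set.seed(7)
  vals <- replicate(200, {
    estimate_snr(raman_spectrum(axis, rnorm(length(x), 0, 5)))
  })
  expect_gte(mean(vals < 10), 0.95)
})

test_that("qc_filter keeps exactly the spectra above threshold", {
  axis <- default_grid()
  x <- as.numeric(axis)
  n <- 240
  set.seed(21)
  weak <- sample(n, 8)
  heights <- rep(200, n)
  heights[weak] <- 20 # SNR ~ 4 against noise sd 5
  mat <- t(vapply(seq_len(n), function(i) {
    lorentzian(x, 1002, heights[i], 12) + rnorm(length(x), 0, 5)
  }, numeric(length(x))))
  meta <- data.frame(spectrum_id = sprintf("s%03d", 1:n),
                     sample_id = sprintf("smp%02d", rep(1:40, each = 6)),
                     group = rep(c("CT", "DMHBP"), each = 720)[1:n],
                     sex = "unknown", replicate_index = rep(1:6, 40),
                     stringsAsFactors = FALSE)
  set <- spectra_set(axis, mat, meta)
  kept <- qc_filter(set)
  expect_equal(n_spectra(kept), 232)
  expect_identical(sort(setdiff(set$meta$spectrum_id, kept$meta$spectrum_id)),
                   sort(set$meta$spectrum_id[weak]))
  qt <- attr(kept, "qc_table")
  expect_equal(sum(qt$qc_pass), 232)

  # order independence: permuting the input permutes, not changes, the result
  perm <- sample(n)
  kept_p <- qc_filter(subset_spectra(set, perm))
  expect_setequal(kept_p$meta$spectrum_id, kept$meta$spectrum_id)

  # identity when everything passes
  strong <- subset_spectra(set, setdiff(seq_len(n), weak))
  expect_equal(n_spectra(qc_filter(strong)), n - 8)

  # all excluded -> error
  feeble <- subset_spectra(set, weak)
  expect_error(qc_filter(feeble), "empty set")
})

test_that("group means and differences obey symmetry and linearity", {
  set <- make_toy_set(n = 6, axis = seq(400, 500, by = 5))
  set$meta$group <- rep(c("CT", "DMHBP"), each = 3)
  set$intensities[4:6, ] <- set$intensities[1:3, ]
  gmd <- group_mean_and_difference(set)
  expect_equal(max(abs(gmd$difference$intensity)), 0)
  set$intensities[4:6, ] <- set$intensities[1:3, ] + 1
  gmd <- group_mean_and_difference(set)
  expect_equal(gmd$difference$intensity,
               rep(1, length(set$wavenumber)), tolerance = 1e-12)
  solo <- subset_spectra(set, 1:3)
  expect_error(group_mean_and_difference(solo), "DMHBP")
})

test_that("difference spectrum of a cohort shows glucose bands in DM&HBP", {
  co <- generate_cohort(small_cohort_config(seed = 5))
  kept <- qc_filter(preprocess_spectra(co$spectra))
  d <- group_mean_and_difference(kept)$difference
  for (pk in c(446, 1127)) {
    idx <- which(abs(d$wavenumber - pk) <= 4)
    expect_gt(max(d$intensity[idx]), 0)
  }
})

test_that("the default cohort passes QC nearly in full", {
  co <- generate_cohort(small_cohort_config(seed = 3))
  pre <- preprocess_spectra(co$spectra)
  kept <- qc_filter(pre)
  expect_gte(n_spectra(kept) / n_spectra(pre), 0.95)
})
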