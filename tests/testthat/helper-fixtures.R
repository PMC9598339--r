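# Fixtures and independent oracles shared across test files.

# small aligned set with valid metadata
make_toy_set <- function(n = 4, axis = seq(400, 430, by = 2), seed = 11) {
  set.seed(seed)
  half <- ceiling(n / 2)
  meta <- data.frame(
    spectrum_id = sprintf("s%02d", seq_len(n)),
    sample_id = sprintf("smp%02d", rep(seq_len(half), each = 2, length.out = n)),
    group = rep(c("CT", "DMHBP"), length.out = n),
    sex = rep(c("M", "W"), length.out = n),
    replicate_index = rep(1:2, length.out = n),
    stringsAsFactors = FALSE)
  spectra_set(axis, matrix(rexp(n * length(axis)), n), meta)
}

lorentzian <- function(x, center, height, fwhm) {
  height / (1 + ((x - center) / (fwhm / 2))^2)
}

# a genuinely smooth spectrum (broad Gaussian on an offset), no sharp bands
smooth_spectrum <- function(axis = default_grid()) {
  x <- as.numeric(axis)
  raman_spectrum(axis, 50 + 100 * exp(-((x - 1000)^2) / (2 * 180^2)))
}

# independent PLS oracle: SIMPLS (de Jong), algorithmically distinct from
# the package's NIPALS; for a single response the two agree exactly.
simpls_regression_vector <- function(X, y, A) {
  X <- as.matrix(X)
  x_mean <- colMeans(X)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - mean(y)
  S <- drop(crossprod(Xc, yc))
  p_dim <- ncol(X)
  R <- matrix(0, p_dim, A)
  V <- matrix(0, p_dim, A)
  q <- numeric(A)
  for (a in seq_len(A)) {
    r <- S
    t_ <- drop(Xc %*% r)
    nt <- sqrt(sum(t_^2))
    t_ <- t_ / nt
    r <- r / nt
    p_ <- drop(crossprod(Xc, t_))
    q[a] <- sum(yc * t_)
    v <- p_
    if (a > 1) {
      Vprev <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - drop(Vprev %*% crossprod(Vprev, p_))
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v * sum(v * S)
    R[, a] <- r
    V[, a] <- v
  }
  list(b = drop(R %*% q), x_mean = x_mean, y_mean = mean(y))
}

# brute-force LOOCV oracle: refit and predict every fold with pls_fit
brute_force_loocv_rmse <- function(X, y, k, fold_of) {
  pred <- numeric(length(y))
  for (f in unique(fold_of)) {
    test <- fold_of == f
    m <- pls_fit(X[!test, , drop = FALSE], y[!test], k)
    pred[test] <- pls_predict(m, X[test, , drop = FALSE])
  }
  sqrt(mean((pred - y)^2))
}

# small synthetic cohort reused by several files (kept cheap)
small_cohort_config <- function(seed = 5, n_per_group = 10,
                                replicates_per_sample = 2) {
  cohort_config(seed = seed, n_per_group = n_per_group,
                replicates_per_sample = replicates_per_sample)
}
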