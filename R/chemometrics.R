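# Multivariate model suite: PCA for exploration, NIPALS PLS regression
# with leave-one-out cross-validation for concentration calibration, and
# PLS-DA / LDA for two-group classification.

.as_matrix_X <- function(X) {
  if (inherits(X, "spectra_set")) X <- X$intensities
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  X
}

# ---- PCA ----------------------------------------------------------------

#' Principal component analysis of a spectra set
#'
#' Column-mean-centered singular value decomposition. Loadings are the
#' component directions over wavenumbers (unit norm, one row per
#' component); scores are the per-spectrum projections onto them.
#' `explained_variance_ratio` is each component's share of the total
#' spectral variance, so it sums to 1 over a full decomposition.
#'
#' @param set A `spectra_set` or numeric matrix (spectra x channels).
#' @param n_components Number of components to retain.
#' @return An object of class `"pca_result"` with elements `loadings`
#'   (component x wavenumber), `scores` (spectrum x component),
#'   `explained_variance_ratio`, `eigenvalues` (sample-covariance
#'   eigenvalues for the retained components) and `mean_spectrum`.
#' @export
fit_pca <- function(set, n_components) {
  X <- .as_matrix_X(set)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2) stop("need at least 2 spectra for PCA", call. = FALSE)
  n_components <- as.integer(n_components)
  if (n_components < 1 || n_components > min(n - 1, p)) {
    stop("n_components must be in [1, min(n_spectra - 1, n_channels)] = [1, ",
         min(n - 1, p), "]", call. = FALSE)
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  d2 <- sv$d^2
  k <- n_components
  structure(list(
    loadings = t(sv$v[, seq_len(k), drop = FALSE]),
    scores = Xc %*% sv$v[, seq_len(k), drop = FALSE],
    explained_variance_ratio = d2[seq_len(k)] / sum(d2),
    eigenvalues = d2[seq_len(k)] / (n - 1),
    mean_spectrum = mu,
    n_components = k),
    class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", x$n_components, " components, variance captured ",
      sprintf("%.1f%%", 100 * sum(x$explained_variance_ratio)), "\n", sep = "")
  invisible(x)
}

#' Cumulative variance captured by the first k components
#'
#' @param p A `pca_result`.
#' @param k Number of leading components (0 gives 0).
#' @return Fraction in \[0, 1\].
#' @export
variance_captured <- function(p, k) {
  stopifnot(inherits(p, "pca_result"))
  k <- as.integer(k)
  if (k < 0 || k > p$n_components) {
    stop("k must be between 0 and the ", p$n_components,
         " stored components", call. = FALSE)
  }
  if (k == 0) return(0)
  sum(p$explained_variance_ratio[seq_len(k)])
}

# ---- PLS (NIPALS) -------------------------------------------------------

# Core NIPALS engine for a single response. With one y the weight vector
# of each component is X'y (normalized) and no inner iteration is needed.
# Returns the cumulative regression vector for every component count up
# to K, which makes cross-validation over a range of LVs cheap.
.nipals_pls <- function(X, y, K) {
  n <- nrow(X)
  p <- ncol(X)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2, x_mean)
  f <- y - y_mean
  W <- matrix(0, p, K)
  P <- matrix(0, p, K)
  q <- numeric(K)
  B <- matrix(0, p, K) # column k: regression vector using components 1..k
  for (k in seq_len(K)) {
    w <- drop(crossprod(E, f))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-300) {
      # residual covariance exhausted; freeze remaining components
      if (k > 1) {
        W[, k:K] <- W[, k - 1]
        for (j in k:K) B[, j] <- B[, k - 1]
      }
      K_eff <- k - 1
      return(list(W = W, P = P, q = q, B = B, x_mean = x_mean,
                  y_mean = y_mean, K_eff = K_eff))
    }
    w <- w / wn
    t_ <- drop(E %*% w)
    tt <- sum(t_^2)
    p_ <- drop(crossprod(E, t_)) / tt
    q[k] <- sum(f * t_) / tt
    E <- E - tcrossprod(t_, p_)
    f <- f - q[k] * t_
    W[, k] <- w
    P[, k] <- p_
    Wk <- W[, seq_len(k), drop = FALSE]
    Pk <- P[, seq_len(k), drop = FALSE]
    B[, k] <- drop(Wk %*% solve(crossprod(Pk, Wk), q[seq_len(k)]))
  }
  list(W = W, P = P, q = q, B = B, x_mean = x_mean, y_mean = y_mean, K_eff = K)
}

#' Fit a PLS regression model (NIPALS)
#'
#' Partial least squares regression of a single response on a spectral
#' matrix, computed by NIPALS deflation on mean-centered data (no
#' variance scaling: all channels share units). The returned model is the
#' affine form `predict(x) = (x - x_mean) . regression_vector + y_mean`,
#' which reproduces the sequential NIPALS prediction exactly.
#'
#' @param X Numeric matrix (spectra x wavenumbers) or `spectra_set`.
#' @param y Numeric response, one value per row of `X`.
#' @param n_lv Number of latent variables (>= 1).
#' @return An object of class `"pls_model"` with fields `n_lv`, `x_mean`,
#'   `y_mean`, `weights` and `x_loadings` (LV x wavenumber), `y_loadings`
#'   and `regression_vector`.
#' @export
pls_fit <- function(X, y, n_lv) {
  X <- .as_matrix_X(X)
  y <- as.numeric(y)
  n_lv <- as.integer(n_lv)
  if (nrow(X) != length(y)) stop("rows(X) must equal length(y)", call. = FALSE)
  if (n_lv < 1 || length(y) < n_lv + 1) {
    stop("parameter error: need n_lv >= 1 and at least n_lv + 1 rows",
         call. = FALSE)
  }
  if (n_lv > ncol(X)) {
    stop("parameter error: n_lv exceeds the number of channels", call. = FALSE)
  }
  if (stats::sd(y) == 0) {
    stop("degenerate target: y has zero variance", call. = FALSE)
  }
  fit <- .nipals_pls(X, y, n_lv)
  if (fit$K_eff < n_lv) {
    warning("X'y residual covariance exhausted after ", fit$K_eff,
            " components; using ", fit$K_eff, " LVs")
    n_lv <- max(fit$K_eff, 1L)
  }
  structure(list(n_lv = n_lv,
                 x_mean = fit$x_mean,
                 y_mean = fit$y_mean,
                 weights = t(fit$W[, seq_len(n_lv), drop = FALSE]),
                 x_loadings = t(fit$P[, seq_len(n_lv), drop = FALSE]),
                 y_loadings = fit$q[seq_len(n_lv)],
                 regression_vector = fit$B[, n_lv]),
            class = "pls_model")
}

#' Predict from a PLS model
#'
#' @param m A `pls_model`.
#' @param X Matrix (or `spectra_set`) on the model's wavenumber grid.
#' @return Numeric vector of predictions.
#' @export
pls_predict <- function(m, X) {
  stopifnot(inherits(m, "pls_model"))
  X <- .as_matrix_X(X)
  if (ncol(X) != length(m$x_mean)) {
    stop("X has ", ncol(X), " channels; model expects ", length(m$x_mean),
         call. = FALSE)
  }
  drop(sweep(X, 2, m$x_mean) %*% m$regression_vector) + m$y_mean
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model> ", x$n_lv, " latent variables over ",
      length(x$regression_vector), " channels\n", sep = "")
  invisible(x)
}

# ---- cross-validation ---------------------------------------------------

#' Leave-one-out cross-validation of PLS over a range of latent variables
#'
#' For every latent-variable count 1..`max_lv`, each held-out unit is
#' predicted by a model fitted on the remaining units (centering and
#' deflation recomputed per fold, so the held-out unit never leaks into
#' training). The unit is either a single spectrum or, when
#' `cv_unit = "sample"`, all replicate spectra of one sample held out
#' together -- the default, which avoids replicate leakage between
#' training and test.
#'
#' @param X Matrix (spectra x wavenumbers) or `spectra_set`.
#' @param y Response, one per row.
#' @param max_lv Largest number of latent variables probed.
#' @param cv_unit `"sample"` or `"spectrum"`.
#' @param sample_ids Character vector grouping rows into samples; required
#'   when `cv_unit = "sample"` (taken from the set's metadata when `X` is
#'   a `spectra_set`).
#' @return An object of class `"cv_result"`: `rmsecv_by_lv`, `r_by_lv`,
#'   `chosen_lv` (argmin of RMSEcv, ties toward fewer LVs),
#'   `cv_predictions` (per row of `X`, at the chosen LV count) and
#'   `cv_unit`.
#' @export
loocv_pls <- function(X, y, max_lv = 10L, cv_unit = c("sample", "spectrum"),
                      sample_ids = NULL) {
  cv_unit <- match.arg(cv_unit)
  if (inherits(X, "spectra_set") && is.null(sample_ids)) {
    sample_ids <- X$meta$sample_id
  }
  X <- .as_matrix_X(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("rows(X) must equal length(y)", call. = FALSE)
  if (cv_unit == "sample") {
    if (is.null(sample_ids)) {
      stop("sample_ids required for cv_unit = 'sample'", call. = FALSE)
    }
    fold_of <- match(sample_ids, unique(sample_ids))
  } else {
    fold_of <- seq_len(nrow(X))
  }
  n_folds <- max(fold_of)
  if (n_folds < 3) stop("insufficient data: need at least 3 cross-validation units",
                        call. = FALSE)
  max_lv <- as.integer(max_lv)
  smallest_train <- nrow(X) - max(tabulate(fold_of))
  if (max_lv > smallest_train - 1 || max_lv > ncol(X)) {
    stop("parameter error: max_lv too large for the fold sizes", call. = FALSE)
  }
  pred <- matrix(NA_real_, nrow(X), max_lv)
  for (f in seq_len(n_folds)) {
    test <- fold_of == f
    fit <- .nipals_pls(X[!test, , drop = FALSE], y[!test], max_lv)
    Xt <- sweep(X[test, , drop = FALSE], 2, fit$x_mean)
    k_eff <- max(fit$K_eff, 1L)
    for (k in seq_len(max_lv)) {
      pred[test, k] <- drop(Xt %*% fit$B[, min(k, k_eff)]) + fit$y_mean
    }
  }
  rmsecv <- sqrt(colMeans((pred - y)^2))
  r <- apply(pred, 2, function(p) {
    if (stats::sd(p) == 0) return(NA_real_)
    stats::cor(p, y)
  })
  chosen <- select_latent_variables(rmsecv)
  structure(list(rmsecv_by_lv = rmsecv,
                 r_by_lv = r,
                 chosen_lv = chosen,
                 cv_predictions = pred[, chosen],
                 cv_predictions_by_lv = pred,
                 cv_unit = cv_unit),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> (", x$cv_unit, " folds) chosen LV = ", x$chosen_lv,
      ", RMSEcv = ", format(x$rmsecv_by_lv[x$chosen_lv], digits = 4),
      ", r = ", format(x$r_by_lv[x$chosen_lv], digits = 4), "\n", sep = "")
  invisible(x)
}

#' Select the latent-variable count from a cross-validation curve
#'
#' Returns the number of latent variables minimizing RMSEcv; ties are
#' broken toward fewer latent variables (the simpler model).
#'
#' @param cv A `cv_result` or a numeric RMSEcv-by-LV vector.
#' @return Integer LV count.
#' @export
select_latent_variables <- function(cv) {
  rmsecv <- if (inherits(cv, "cv_result")) cv$rmsecv_by_lv else as.numeric(cv)
  if (!length(rmsecv)) stop("empty RMSEcv curve", call. = FALSE)
  which.min(rmsecv) # which.min returns the first (smallest-LV) minimum
}

# ---- PLS-DA -------------------------------------------------------------

.class_codes <- c(CT = 1, DMHBP = 2)

#' Fit a PLS-DA model
#'
#' PLS regression against the numeric class code (CT = 1, DMHBP = 2).
#'
#' @param X Matrix or `spectra_set`.
#' @param labels Character/factor labels in `{CT, DMHBP}`, one per row.
#' @param n_lv Number of latent variables.
#' @return A `pls_model` additionally classed `"plsda_model"`.
#' @export
plsda_fit <- function(X, labels, n_lv) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), names(.class_codes))
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (length(unique(labels)) < 2) {
    stop("degenerate target: both classes must be present", call. = FALSE)
  }
  m <- pls_fit(X, .class_codes[labels], n_lv)
  class(m) <- c("plsda_model", class(m))
  m
}

#' Classify spectra with a PLS-DA model
#'
#' Predicted scores are thresholded at 1.5, the midpoint of the class
#' codes; a score exactly at the threshold is assigned to DMHBP (fixed,
#' documented tie rule).
#'
#' @param m A `plsda_model`.
#' @param X Matrix or `spectra_set` on the model grid.
#' @return Character vector of labels in `{CT, DMHBP}`.
#' @export
plsda_classify <- function(m, X) {
  stopifnot(inherits(m, "plsda_model"))
  score <- pls_predict(m, X)
  ifelse(score >= 1.5, "DMHBP", "CT")
}

#' Leave-one-unit-out cross-validated PLS-DA labels
#'
#' Each unit (sample or single spectrum) is classified by a PLS-DA model
#' trained on all other units.
#'
#' @inheritParams loocv_pls
#' @param labels Class labels in `{CT, DMHBP}`, one per row.
#' @param n_lv Number of latent variables of each fold's model.
#' @return Character vector of held-out predicted labels, one per row.
#' @export
loocv_plsda <- function(X, labels, n_lv, cv_unit = c("sample", "spectrum"),
                        sample_ids = NULL) {
  cv_unit <- match.arg(cv_unit)
  if (inherits(X, "spectra_set") && is.null(sample_ids)) {
    sample_ids <- X$meta$sample_id
  }
  X <- .as_matrix_X(X)
  labels <- as.character(labels)
  fold_of <- if (cv_unit == "sample") {
    if (is.null(sample_ids)) stop("sample_ids required", call. = FALSE)
    match(sample_ids, unique(sample_ids))
  } else {
    seq_len(nrow(X))
  }
  pred <- character(nrow(X))
  for (f in seq_len(max(fold_of))) {
    test <- fold_of == f
    m <- plsda_fit(X[!test, , drop = FALSE], labels[!test], n_lv)
    pred[test] <- plsda_classify(m, X[test, , drop = FALSE])
  }
  pred
}

# ---- LDA ----------------------------------------------------------------

#' Fit a two-class linear discriminant model
#'
#' Class means, pooled within-class covariance with a small ridge term
#' (lambda = 1e-6 x mean diagonal, for numerical stability) and empirical
#' priors.
#'
#' @param features Numeric matrix (units x features), e.g. a biomarker
#'   concentration table.
#' @param labels Labels in `{CT, DMHBP}`, one per row; each class needs at
#'   least 2 units.
#' @return An object of class `"lda_model"`.
#' @export
lda_fit <- function(features, labels) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), names(.class_codes))
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  counts <- table(factor(labels, levels = names(.class_codes)))
  if (any(counts < 2)) {
    stop("each class needs at least 2 units (got ",
         paste(names(counts), counts, sep = "=", collapse = ", "), ")",
         call. = FALSE)
  }
  mu <- lapply(names(.class_codes), function(g) {
    colMeans(features[labels == g, , drop = FALSE])
  })
  names(mu) <- names(.class_codes)
  n <- nrow(features)
  S <- Reduce(`+`, lapply(names(.class_codes), function(g) {
    Xg <- features[labels == g, , drop = FALSE]
    crossprod(sweep(Xg, 2, colMeans(Xg)))
  })) / (n - 2)
  lambda <- 1e-6 * mean(diag(S))
  S <- S + diag(lambda, ncol(features))
  structure(list(class_means = mu,
                 pooled_covariance = S,
                 priors = as.numeric(counts) / n,
                 ridge_lambda = lambda,
                 classes = names(.class_codes)),
            class = "lda_model")
}

#' Classify with a linear discriminant model
#'
#' Assigns the class maximizing the linear discriminant score
#' `x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 + log pi_k`.
#'
#' @param m An `lda_model`.
#' @param features Matrix of units x features (same columns as training).
#' @return Character vector of labels.
#' @export
lda_classify <- function(m, features) {
  stopifnot(inherits(m, "lda_model"))
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  Sinv <- solve(m$pooled_covariance)
  scores <- vapply(seq_along(m$classes), function(k) {
    mu <- m$class_means[[k]]
    a <- Sinv %*% mu
    drop(features %*% a) - drop(crossprod(mu, a)) / 2 + log(m$priors[k])
  }, numeric(nrow(features)))
  scores <- matrix(scores, nrow = nrow(features))
  m$classes[max.col(scores, ties.method = "first")]
}

#' Leave-one-unit-out cross-validated LDA labels
#'
#' @param features Matrix of units x features.
#' @param labels Labels in `{CT, DMHBP}`.
#' @param unit_ids Optional grouping of rows into units held out together
#'   (e.g. sample ids when rows are replicate spectra); default one row
#'   per unit.
#' @return Character vector of held-out predicted labels, one per row.
#' @export
loocv_lda <- function(features, labels, unit_ids = NULL) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  fold_of <- if (is.null(unit_ids)) seq_len(nrow(features)) else
    match(unit_ids, unique(unit_ids))
  pred <- character(nrow(features))
  for (f in seq_len(max(fold_of))) {
    test <- fold_of == f
    m <- lda_fit(features[!test, , drop = FALSE], labels[!test])
    pred[test] <- lda_classify(m, features[test, , drop = FALSE])
  }
  pred
}
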