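# End-to-end orchestration: simulate (or read) -> preprocess -> explore
# (PCA + group tests) -> calibrate (PLS per analyte) -> classify (LDA on
# assayed panels, LDA on cross-validated PLS predictions, PLS-DA on full
# spectra) -> evaluate. Deterministic given the seed; intermediates can
# be persisted for audit.

#' Pipeline run configuration
#'
#' Exactly one input source: either `simulate` (a [cohort_config()]) or
#' `paths` (a list with `matrix`, `metadata` and `panels` file paths plus
#' a `groups` mapping is taken from the metadata).
#'
#' @param simulate A [cohort_config()], or `NULL` when reading files.
#' @param paths List with elements `matrix`, `metadata`, `panels`
#'   (delimited-text files readable by [read_spectra()] and
#'   [read_biomarker_panels()]), or `NULL` when simulating.
#' @param preprocess A [preprocess_config()].
#' @param max_lv Largest latent-variable count probed in calibration.
#' @param plsda_lv Latent variables of the PLS-DA classifier.
#' @param cv_unit `"sample"` (replicates held out together; default) or
#'   `"spectrum"`.
#' @param pca_components Components retained in the exploratory PCA.
#' @param seed Seed applied to the simulation (overrides the cohort
#'   config's own seed so one number controls the whole run).
#' @param outdir Directory for persisted intermediates, or `NULL` to skip
#'   writing.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(simulate = cohort_config(),
                       paths = NULL,
                       preprocess = preprocess_config(),
                       max_lv = 10L,
                       plsda_lv = 7L,
                       cv_unit = c("sample", "spectrum"),
                       pca_components = 6L,
                       seed = 1L,
                       outdir = NULL) {
  cv_unit <- match.arg(cv_unit)
  if (is.null(simulate) == is.null(paths)) {
    stop("exactly one input source required: simulate xor paths", call. = FALSE)
  }
  if (!is.null(simulate)) {
    stopifnot(inherits(simulate, "cohort_config"))
    simulate$seed <- as.integer(seed)
  }
  structure(list(simulate = simulate, paths = paths, preprocess = preprocess,
                 max_lv = as.integer(max_lv), plsda_lv = as.integer(plsda_lv),
                 cv_unit = cv_unit, pca_components = as.integer(pca_components),
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate/read, pre-processing with QC, exploratory PCA with
#' per-component group tests, per-analyte PLS calibration under
#' leave-one-out cross-validation, and the three classifiers: LDA on the
#' assayed concentration panels (one unit per sample), LDA on the
#' cross-validated PLS-predicted concentrations (per spectrum, folds
#' grouped by sample), and PLS-DA on the full spectra (folds grouped by
#' sample). The LDA-on-predictions block consumes held-out PLS
#' predictions, never training fits.
#'
#' @param cfg A [run_config()].
#' @return An object of class `"run_report"`; see [render_report()].
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))

  inputs <- .stage("input", {
    if (!is.null(cfg$simulate)) {
      generate_cohort(cfg$simulate)
    } else {
      list(spectra = read_spectra(cfg$paths$matrix, cfg$paths$metadata),
           panels = read_biomarker_panels(cfg$paths$panels))
    }
  })
  raw <- inputs$spectra
  panels <- inputs$panels

  pre <- .stage("preprocess", preprocess_spectra(raw, cfg$preprocess))
  kept <- .stage("qc", qc_filter(pre, cfg$preprocess))
  qc_table <- attr(kept, "qc_table")
  qc_summary <- list(n_input = n_spectra(raw),
                     n_retained = n_spectra(kept),
                     n_excluded = n_spectra(raw) - n_spectra(kept))

  k <- min(cfg$pca_components, n_spectra(kept) - 1L, length(kept$wavenumber))
  pca <- .stage("explore", fit_pca(kept, k))
  pca_tests <- lapply(seq_len(k), function(j) {
    compare_component_scores(pca, kept$meta$group, j)
  })

  sample_of_row <- kept$meta$sample_id
  group_of_row <- kept$meta$group
  panel_row <- match(sample_of_row, panels$sample_id)
  if (anyNA(panel_row)) {
    stop("pipeline stage 'calibrate' failed: sample(s) ",
         paste(unique(sample_of_row[is.na(panel_row)]), collapse = ", "),
         " have spectra but no biomarker panel", call. = FALSE)
  }

  calibration <- list()
  cv_pred <- matrix(NA_real_, n_spectra(kept), length(.analytes),
                    dimnames = list(NULL, .analytes))
  for (a in .analytes) {
    y <- panels[[a]][panel_row]
    cv <- .stage(paste0("calibrate:", a),
                 loocv_pls(kept$intensities, y, max_lv = cfg$max_lv,
                           cv_unit = cfg$cv_unit, sample_ids = sample_of_row))
    cv_pred[, a] <- cv$cv_predictions
    rmse <- cv$rmsecv_by_lv[cv$chosen_lv]
    calibration[[a]] <- data.frame(
      analyte = a,
      chosen_lv = cv$chosen_lv,
      rmsecv = rmse,
      rmsecv_mgdl = if (a %in% names(.molar_mass))
        convert_concentration(rmse, a, "mmolL_to_mgdL") else NA_real_,
      r = cv$r_by_lv[cv$chosen_lv],
      units = analyte_units()[[a]],
      stringsAsFactors = FALSE)
  }
  calibration <- do.call(rbind, calibration[.analytes])
  rownames(calibration) <- NULL

  sample_groups <- attr(panels, "groups")
  if (is.null(sample_groups)) {
    sample_groups <- group_of_row[match(panels$sample_id, sample_of_row)]
  }

  # (a) LDA on the assayed concentrations, one unit per sample
  feat_assay <- as.matrix(as.data.frame(panels)[, .analytes])
  keep_sample <- !is.na(sample_groups)
  pred_a <- .stage("classify:lda_assay",
                   loocv_lda(feat_assay[keep_sample, , drop = FALSE],
                             sample_groups[keep_sample]))
  cm_a <- confusion_matrix(sample_groups[keep_sample], pred_a)

  # (b) LDA on cross-validated PLS-predicted concentrations, per spectrum
  pred_b <- .stage("classify:lda_pls",
                   loocv_lda(cv_pred, group_of_row, unit_ids = sample_of_row))
  cm_b <- confusion_matrix(group_of_row, pred_b)

  # (c) PLS-DA on the full spectra, per spectrum, folds grouped by sample
  pred_c <- .stage("classify:plsda",
                   loocv_plsda(kept$intensities, group_of_row,
                               n_lv = cfg$plsda_lv,
                               cv_unit = cfg$cv_unit,
                               sample_ids = sample_of_row))
  cm_c <- confusion_matrix(group_of_row, pred_c)

  blocks <- list(
    lda_assay = list(model = "LDA on assayed concentrations",
                     unit = "sample", cm = cm_a,
                     metrics = classification_metrics(cm_a)),
    lda_pls = list(model = "LDA on PLS-predicted concentrations",
                   unit = "spectrum", cm = cm_b,
                   metrics = classification_metrics(cm_b)),
    plsda = list(model = "PLS-DA on Raman spectra",
                 unit = "spectrum", cm = cm_c,
                 metrics = classification_metrics(cm_c)))

  report <- structure(list(seed = cfg$seed,
                           qc = qc_summary,
                           qc_table = qc_table,
                           pca = pca,
                           pca_tests = pca_tests,
                           calibration = calibration,
                           blocks = blocks,
                           cv_predictions = cv_pred,
                           meta = kept$meta),
                      class = "run_report")

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    write_spectra(kept, file.path(cfg$outdir, "preprocessed_matrix.csv"),
                  file.path(cfg$outdir, "preprocessed_metadata.csv"))
    utils::write.csv(qc_table, file.path(cfg$outdir, "qc_table.csv"),
                     row.names = FALSE)
    write_biomarker_panels(panels, file.path(cfg$outdir, "panels.csv"))
    utils::write.csv(cbind(data.frame(spectrum_id = kept$meta$spectrum_id),
                           as.data.frame(cv_pred)),
                     file.path(cfg$outdir, "pls_cv_predictions.csv"),
                     row.names = FALSE)
    render_report(report, file.path(cfg$outdir, "report.txt"))
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed ", x$seed, "; QC retained ", x$qc$n_retained, "/",
      x$qc$n_input, " spectra\n", sep = "")
  cat("calibration (chosen LV / RMSEcv / r):\n")
  for (i in seq_len(nrow(x$calibration))) {
    r <- x$calibration[i, ]
    cat(sprintf("  %-14s LV=%-2d RMSEcv=%8.3f %-7s r=%.3f\n", r$analyte,
                r$chosen_lv, r$rmsecv, r$units, r$r))
  }
  for (b in x$blocks) {
    cat(sprintf("%-38s acc %.1f%%  sens %.1f%%  spec %.1f%%\n", b$model,
                b$metrics$accuracy_pct, b$metrics$sensitivity_pct,
                b$metrics$specificity_pct))
  }
  invisible(x)
}

#' Render a run report to delimited text
#'
#' Writes a human-readable summary with the three confusion blocks
#' (model, per-class counts, sensitivity/specificity/accuracy at 0.1%
#' display precision) and, when present, the calibration table and PCA
#' component tests. A companion `<path>.metrics.csv` holds the same
#' numbers in machine-readable form.
#'
#' @param r A `run_report` (at minimum the `blocks` element).
#' @param path Output text file.
#' @return Invisibly, the metrics data.frame that was written.
#' @export
render_report <- function(r, path) {
  if (is.null(r$blocks) || !length(r$blocks)) {
    stop("empty report: no classification blocks to render", call. = FALSE)
  }
  lines <- character(0)
  metrics_rows <- list()
  if (!is.null(r$seed)) lines <- c(lines, paste0("seed: ", r$seed))
  if (!is.null(r$qc)) {
    lines <- c(lines, sprintf("spectra retained after QC: %d of %d",
                              r$qc$n_retained, r$qc$n_input))
  }
  if (!is.null(r$calibration)) {
    lines <- c(lines, "", "calibration (leave-one-out cross-validation):")
    for (i in seq_len(nrow(r$calibration))) {
      row <- r$calibration[i, ]
      lines <- c(lines, sprintf("  %-14s LV=%-2d RMSEcv=%.3f %s%s r=%.3f",
                                row$analyte, row$chosen_lv, row$rmsecv,
                                row$units,
                                if (!is.na(row$rmsecv_mgdl))
                                  sprintf(" (%.1f mg/dL)", row$rmsecv_mgdl)
                                else "",
                                row$r))
    }
  }
  if (!is.null(r$pca_tests)) {
    lines <- c(lines, "", "PCA component group tests:")
    for (tst in r$pca_tests) {
      lines <- c(lines, sprintf("  PC%d: t=%.3f p=%.4f%s", tst$component_index,
                                tst$t_statistic, tst$t_p,
                                if (tst$significant) " *" else ""))
    }
  }
  for (nm in names(r$blocks)) {
    b <- r$blocks[[nm]]
    m <- b$metrics
    lines <- c(lines, "", b$model,
               sprintf("  truth\\pred   CT  DMHBP"),
               sprintf("  CT        %5d  %5d", b$cm$tn, b$cm$fp),
               sprintf("  DMHBP     %5d  %5d", b$cm$fn, b$cm$tp),
               sprintf("  sensitivity %.1f%%", m$sensitivity_pct),
               sprintf("  specificity %.1f%%", m$specificity_pct),
               sprintf("  accuracy    %.1f%%", m$accuracy_pct))
    metrics_rows[[nm]] <- data.frame(
      model = nm, n = m$total, tn = b$cm$tn, fp = b$cm$fp, fn = b$cm$fn,
      tp = b$cm$tp, sensitivity_pct = m$sensitivity_pct,
      specificity_pct = m$specificity_pct, accuracy_pct = m$accuracy_pct,
      stringsAsFactors = FALSE)
  }
  writeLines(lines, path)
  metrics <- do.call(rbind, metrics_rows)
  rownames(metrics) <- NULL
  utils::write.csv(metrics, paste0(path, ".metrics.csv"), row.names = FALSE)
  invisible(metrics)
}
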