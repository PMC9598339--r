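#' @keywords internal
"_PACKAGE"

# ---- wavenumber axis ---------------------------------------------------

#' Validate a Raman shift axis
#'
#' A wavenumber axis is a strictly increasing numeric vector of Raman
#' shifts in cm^-1, restricted to the window instruments actually record
#' (100--4000 cm^-1). Most functions in the package assume all spectra of
#' a set share one axis, so the validator is called at every construction
#' point.
#'
#' @param values Numeric vector of Raman shifts (cm^-1).
#' @param min_length Minimum number of channels accepted (default 2;
#'   analysis-grade grids have hundreds).
#' @return The validated numeric vector, invisibly classed as
#'   `"wavenumber_axis"`.
#' @examples
#' ax <- wavenumber_axis(seq(400, 1800, by = 2))
#' length(ax)
#' @export
wavenumber_axis <- function(values, min_length = 2L) {
  values <- as.numeric(values)
  if (anyNA(values)) {
    stop("malformed axis: wavenumber axis contains missing values", call. = FALSE)
  }
  if (length(values) < min_length) {
    stop("malformed axis: need at least ", min_length, " channels", call. = FALSE)
  }
  if (any(diff(values) <= 0)) {
    stop("malformed axis: wavenumbers must be strictly increasing", call. = FALSE)
  }
  if (values[1] < 100 || values[length(values)] > 4000) {
    stop("malformed axis: wavenumbers must lie within [100, 4000] cm^-1", call. = FALSE)
  }
  structure(values, class = "wavenumber_axis")
}

#' Default working grid
#'
#' 400--1800 cm^-1 sampled every 2 cm^-1 (701 channels): the fingerprint
#' window covering the urea, creatinine, glucose, phosphate and protein
#' bands of urine, at a spacing that resolves the ~12 cm^-1 wide bands.
#'
#' @return A `wavenumber_axis` of length 701.
#' @export
default_grid <- function() {
  wavenumber_axis(seq(400, 1800, by = 2))
}

#' Is the axis uniformly spaced?
#'
#' @param axis A `wavenumber_axis`.
#' @param tol Relative tolerance on spacing variation.
#' @return Logical scalar.
#' @export
is_uniform_axis <- function(axis, tol = 1e-8) {
  d <- diff(as.numeric(axis))
  max(d) - min(d) <= tol * mean(d)
}

# ---- spectrum and spectra set ------------------------------------------

#' Construct a single Raman spectrum
#'
#' @param wavenumber Numeric axis (validated via [wavenumber_axis()]).
#' @param intensity Numeric intensities (arbitrary units), same length as
#'   the axis, no missing values.
#' @param meta Named list of provenance fields (`spectrum_id`, `sample_id`,
#'   `group`, `sex`, `replicate_index`, and any quality-control fields).
#' @return An object of class `"raman_spectrum"`.
#' @export
raman_spectrum <- function(wavenumber, intensity, meta = list()) {
  wavenumber <- wavenumber_axis(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(intensity) != length(wavenumber)) {
    stop("intensity length (", length(intensity), ") != axis length (",
         length(wavenumber), ")", call. = FALSE)
  }
  if (anyNA(intensity)) stop("intensity contains missing values", call. = FALSE)
  structure(list(wavenumber = as.numeric(wavenumber),
                 intensity = intensity,
                 meta = as.list(meta)),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat("<raman_spectrum> ", length(x$wavenumber), " channels, ",
      format(x$wavenumber[1]), "-", format(x$wavenumber[length(x$wavenumber)]),
      " cm^-1\n", sep = "")
  if (!is.null(x$meta$spectrum_id)) cat("  spectrum_id:", x$meta$spectrum_id, "\n")
  invisible(x)
}

.valid_groups <- c("CT", "DMHBP")
.valid_sex <- c("M", "W", "unknown")

.validate_meta <- function(meta, n) {
  required <- c("spectrum_id", "sample_id", "group", "sex", "replicate_index")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  meta$spectrum_id <- as.character(meta$spectrum_id)
  meta$sample_id <- as.character(meta$sample_id)
  meta$group <- as.character(meta$group)
  meta$sex <- as.character(meta$sex)
  meta$replicate_index <- as.integer(meta$replicate_index)
  if (anyDuplicated(meta$spectrum_id)) {
    stop("spectrum_id values must be unique within a set", call. = FALSE)
  }
  bad <- setdiff(unique(meta$group), .valid_groups)
  if (length(bad)) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         "; expected CT or DMHBP", call. = FALSE)
  }
  bad <- setdiff(unique(meta$sex), .valid_sex)
  if (length(bad)) {
    stop("unknown sex label(s): ", paste(bad, collapse = ", "),
         "; expected M, W or unknown", call. = FALSE)
  }
  if (any(meta$replicate_index < 1L, na.rm = TRUE)) {
    stop("replicate_index must be >= 1", call. = FALSE)
  }
  if (nrow(meta) != n) {
    stop("metadata has ", nrow(meta), " rows for ", n, " spectra", call. = FALSE)
  }
  meta
}

#' Construct an aligned collection of spectra
#'
#' A `spectra_set` holds an intensity matrix (one row per spectrum) on a
#' single shared wavenumber axis, plus a metadata table with one row per
#' spectrum. All multivariate operations in the package consume this
#' container and refuse mixed axes.
#'
#' @param wavenumber Shared axis (validated).
#' @param intensities Numeric matrix, spectra in rows, channels in columns.
#' @param meta `data.frame` with columns `spectrum_id`, `sample_id`,
#'   `group` (`CT`/`DMHBP`), `sex` (`M`/`W`/`unknown`), `replicate_index`;
#'   quality-control columns (`qc_pass`, `snr`, `n_spikes_removed`,
#'   `baseline_converged`) are added by the pre-processing functions.
#' @return An object of class `"spectra_set"`.
#' @export
spectra_set <- function(wavenumber, intensities, meta) {
  wavenumber <- wavenumber_axis(wavenumber)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (nrow(intensities) > 0 && ncol(intensities) != length(wavenumber)) {
    stop("intensity matrix has ", ncol(intensities), " channels for an axis of length ",
         length(wavenumber), call. = FALSE)
  }
  if (anyNA(intensities)) stop("intensities contain missing values", call. = FALSE)
  meta <- .validate_meta(as.data.frame(meta, stringsAsFactors = FALSE),
                         nrow(intensities))
  rownames(intensities) <- meta$spectrum_id
  rownames(meta) <- NULL
  structure(list(wavenumber = as.numeric(wavenumber),
                 intensities = intensities,
                 meta = meta),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", nrow(x$intensities), " spectra x ",
      length(x$wavenumber), " channels (",
      format(x$wavenumber[1]), "-", format(x$wavenumber[length(x$wavenumber)]),
      " cm^-1)\n", sep = "")
  if (nrow(x$meta)) {
    tab <- table(x$meta$group)
    cat("  groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    if ("qc_pass" %in% names(x$meta) && !all(is.na(x$meta$qc_pass))) {
      cat("  qc_pass:", sum(x$meta$qc_pass, na.rm = TRUE), "of",
          nrow(x$meta), "\n")
    }
  }
  invisible(x)
}

#' Number of spectra in a set
#' @param set A `spectra_set`.
#' @return Integer count.
#' @export
n_spectra <- function(set) nrow(set$intensities)

#' Extract one spectrum from a set
#' @param set A `spectra_set`.
#' @param i Row index or spectrum_id.
#' @return A `raman_spectrum` with the row's metadata.
#' @export
get_spectrum <- function(set, i) {
  if (is.character(i)) i <- match(i, set$meta$spectrum_id)
  if (is.na(i) || i < 1 || i > nrow(set$intensities)) {
    stop("no such spectrum in set", call. = FALSE)
  }
  raman_spectrum(set$wavenumber, set$intensities[i, ],
                 as.list(set$meta[i, , drop = FALSE]))
}

#' Subset a spectra set by row
#' @param set A `spectra_set`.
#' @param idx Integer or logical index over spectra.
#' @return A `spectra_set` with the selected spectra.
#' @export
subset_spectra <- function(set, idx) {
  spectra_set(set$wavenumber,
              set$intensities[idx, , drop = FALSE],
              set$meta[idx, , drop = FALSE])
}

.check_same_axis <- function(a, b) {
  if (length(a) != length(b) || any(abs(a - b) > 1e-9)) {
    stop("spectra are on different wavenumber axes; resample first", call. = FALSE)
  }
  invisible(TRUE)
}

# ---- delimited-text readers and writers --------------------------------

.wn_header <- "wavenumber_cm-1"

.read_numeric_table <- function(path, what) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(raw) < 2) stop(what, " file must have a wavenumber column plus >= 1 spectrum",
                          call. = FALSE)
  out <- matrix(NA_real_, nrow(raw), ncol(raw), dimnames = list(NULL, names(raw)))
  for (j in seq_len(ncol(raw))) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) & !(trimws(raw[[j]]) %in% c("NA", "")))
    if (length(bad)) {
      stop("parse error in ", what, " file: non-numeric value '", raw[bad[1], j],
           "' at row ", bad[1], ", column '", names(raw)[j], "'", call. = FALSE)
    }
    if (anyNA(v)) {
      stop("parse error in ", what, " file: missing value at row ",
           which(is.na(v))[1], ", column '", names(raw)[j], "'", call. = FALSE)
    }
    out[, j] <- v
  }
  out
}

#' Read a spectra set from delimited text
#'
#' The matrix file is comma-separated with a first column named
#' `wavenumber_cm-1` and one column per spectrum, headed by the spectrum
#' id. The metadata file has columns `spectrum_id`, `sample_id`, `group`,
#' `sex`, `replicate_index` (plus any extra columns, carried through).
#'
#' @param matrix_path Path to the intensity matrix file.
#' @param metadata_path Path to the per-spectrum metadata file.
#' @return A `spectra_set`.
#' @export
read_spectra <- function(matrix_path, metadata_path) {
  mat <- .read_numeric_table(matrix_path, "spectral matrix")
  wn <- mat[, 1]
  if (any(diff(wn) <= 0)) {
    stop("malformed axis: wavenumber column of '", matrix_path,
         "' is not strictly increasing", call. = FALSE)
  }
  ids <- colnames(mat)[-1]
  meta <- utils::read.csv(metadata_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"spectrum_id" %in% names(meta)) {
    stop("metadata file lacks a spectrum_id column", call. = FALSE)
  }
  meta$spectrum_id <- as.character(meta$spectrum_id)
  missing_ids <- setdiff(ids, meta$spectrum_id)
  if (length(missing_ids)) {
    stop("join error: spectrum id(s) ", paste(missing_ids, collapse = ", "),
         " present in matrix but absent from metadata", call. = FALSE)
  }
  meta <- meta[match(ids, meta$spectrum_id), , drop = FALSE]
  spectra_set(wn, t(mat[, -1, drop = FALSE]), meta)
}

#' Write a spectra set to delimited text
#'
#' Inverse of [read_spectra()]: intensities round-trip within 1e-9
#' relative, metadata exactly.
#'
#' @param set A `spectra_set`.
#' @param matrix_path,metadata_path Output file paths.
#' @return Invisibly, the set.
#' @export
write_spectra <- function(set, matrix_path, metadata_path) {
  stopifnot(inherits(set, "spectra_set"))
  mat <- cbind(set$wavenumber, t(set$intensities))
  colnames(mat) <- c(.wn_header, set$meta$spectrum_id)
  df <- as.data.frame(mat, check.names = FALSE)
  # keep full double precision through the text representation
  df[] <- lapply(df, function(v) format(v, digits = 17, trim = TRUE,
                                        scientific = FALSE))
  utils::write.csv(df, matrix_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(set$meta, metadata_path, row.names = FALSE)
  invisible(set)
}

#' Linear resampling onto a new wavenumber grid
#'
#' Interpolates intensities linearly onto `target`, which must lie inside
#' the source range (no extrapolation). Exact on affine intensity
#' profiles; metadata is preserved.
#'
#' @param s A `raman_spectrum`.
#' @param target A `wavenumber_axis`.
#' @return A `raman_spectrum` on `target`.
#' @export
resample_to_grid <- function(s, target) {
  stopifnot(inherits(s, "raman_spectrum"))
  target <- wavenumber_axis(target)
  src <- s$wavenumber
  if (target[1] < src[1] - 1e-9 || target[length(target)] > src[length(src)] + 1e-9) {
    stop("extrapolation error: target grid [", target[1], ", ",
         target[length(target)], "] extends beyond source range [",
         src[1], ", ", src[length(src)], "]", call. = FALSE)
  }
  y <- stats::approx(src, s$intensity, xout = as.numeric(target),
                     method = "linear", rule = 1)$y
  raman_spectrum(target, y, s$meta)
}

# ---- biomarker panels ---------------------------------------------------

.analytes <- c("urea", "creatinine", "glucose", "phosphate", "total_protein")

#' Analyte names and fixed units of a urine biomarker panel
#'
#' Urea, creatinine, glucose and phosphate are carried in mmol/L; total
#' protein in mg/dL (its molar mass is undefined, so it is never
#' converted).
#'
#' @return Named character vector: units keyed by analyte.
#' @export
analyte_units <- function() {
  c(urea = "mmol/L", creatinine = "mmol/L", glucose = "mmol/L",
    phosphate = "mmol/L", total_protein = "mg/dL")
}

#' Validate a table of biomarker panels
#'
#' @param df `data.frame` with columns `sample_id` plus the five analytes
#'   (`urea`, `creatinine`, `glucose`, `phosphate` in mmol/L;
#'   `total_protein` in mg/dL). One row per sample; all values >= 0.
#' @return The validated `data.frame`, classed `"biomarker_panels"`.
#' @export
biomarker_panels <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sample_id", .analytes)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("panel table missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in panel table", call. = FALSE)
  }
  for (a in .analytes) {
    df[[a]] <- as.numeric(df[[a]])
    if (anyNA(df[[a]])) stop("missing ", a, " concentration", call. = FALSE)
    if (any(df[[a]] < 0)) stop(a, " concentrations must be >= 0", call. = FALSE)
  }
  class(df) <- c("biomarker_panels", "data.frame")
  df
}

#' Read / write biomarker panel tables
#'
#' Plain comma-separated files with columns `sample_id`, `urea`,
#' `creatinine`, `glucose`, `phosphate` (mmol/L) and `total_protein`
#' (mg/dL).
#'
#' @param path File path.
#' @return `read_biomarker_panels`: a `biomarker_panels` table.
#' @export
read_biomarker_panels <- function(path) {
  biomarker_panels(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_biomarker_panels
#' @param panels A `biomarker_panels` table.
#' @export
write_biomarker_panels <- function(panels, path) {
  utils::write.csv(as.data.frame(panels), path, row.names = FALSE)
  invisible(panels)
}
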