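# Classification metrics, component-score group tests, reference-range
# flagging and concentration unit conversion.

# ---- confusion matrix ---------------------------------------------------

.new_confusion <- function(tn, fp, fn, tp) {
  counts <- c(tn = tn, fp = fp, fn = fn, tp = tp)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) < 1) stop("confusion matrix must contain at least one case",
                            call. = FALSE)
  counts <- as.integer(counts)
  structure(list(tn = counts[1], fp = counts[2], fn = counts[3], tp = counts[4]),
            class = "confusion_matrix")
}

#' Build a confusion matrix from true and predicted labels
#'
#' DMHBP is the positive (disease) class: `tp` counts DMHBP predicted
#' DMHBP, `tn` counts CT predicted CT.
#'
#' @param truth,predicted Equal-length label vectors over `{CT, DMHBP}`.
#' @return An object of class `"confusion_matrix"` with integer fields
#'   `tn`, `fp`, `fn`, `tp`.
#' @seealso [confusion_counts()] to construct one directly from counts.
#' @export
confusion_matrix <- function(truth, predicted) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted) || length(truth) < 1) {
    stop("truth and predicted must have equal length >= 1", call. = FALSE)
  }
  bad <- setdiff(unique(c(truth, predicted)), .valid_groups)
  if (length(bad)) stop("label(s) outside {CT, DMHBP}: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  .new_confusion(tn = sum(truth == "CT" & predicted == "CT"),
                 fp = sum(truth == "CT" & predicted == "DMHBP"),
                 fn = sum(truth == "DMHBP" & predicted == "CT"),
                 tp = sum(truth == "DMHBP" & predicted == "DMHBP"))
}

#' @rdname confusion_matrix
#' @param tn,fp,fn,tp Non-negative integer counts (CT predicted CT, CT
#'   predicted DMHBP, DMHBP predicted CT, DMHBP predicted DMHBP).
#' @export
confusion_counts <- function(tn, fp, fn, tp) .new_confusion(tn, fp, fn, tp)

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), 2, 2, byrow = TRUE,
              dimnames = list(truth = c("CT", "DMHBP"),
                              predicted = c("CT", "DMHBP")))
  print(m)
  invisible(x)
}

# round half up at one decimal in percent, for report display
.pct1 <- function(frac) floor(frac * 1000 + 0.5) / 10

#' Sensitivity, specificity and accuracy of a confusion matrix
#'
#' Sensitivity is the detection rate of the disease class
#' (`tp / (tp + fn)`), specificity the control retention rate
#' (`tn / (tn + fp)`), accuracy the overall fraction correct. Raw
#' fractions are returned together with percentages rounded half-up to
#' one decimal for display.
#'
#' @param cm A `confusion_matrix`.
#' @return An object of class `"class_metrics"`: `sensitivity`,
#'   `specificity`, `accuracy` (fractions) and `*_pct` rounded display
#'   values.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tp + cm$fn == 0) {
    stop("undefined metric: no DMHBP cases, sensitivity undefined", call. = FALSE)
  }
  if (cm$tn + cm$fp == 0) {
    stop("undefined metric: no CT cases, specificity undefined", call. = FALSE)
  }
  total <- cm$tn + cm$fp + cm$fn + cm$tp
  sens <- cm$tp / (cm$tp + cm$fn)
  spec <- cm$tn / (cm$tn + cm$fp)
  acc <- (cm$tp + cm$tn) / total
  structure(list(sensitivity = sens, specificity = spec, accuracy = acc,
                 sensitivity_pct = .pct1(sens), specificity_pct = .pct1(spec),
                 accuracy_pct = .pct1(acc), total = total),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("sensitivity %.1f%%  specificity %.1f%%  accuracy %.1f%%  (n = %d)\n",
              x$sensitivity_pct, x$specificity_pct, x$accuracy_pct, x$total))
  invisible(x)
}

# ---- group tests on component scores -----------------------------------

#' Compare the two groups on one principal component
#'
#' Kolmogorov-Smirnov normality check per group (against a normal with
#' the group's sample mean and SD, flagged non-normal at p < 0.1)
#' followed by a pooled-variance two-tailed Student's t-test on the score
#' sets; `significant` records p < 0.05. The t-test is reported even when
#' normality is rejected -- the comparison is then annotated, not
#' replaced by a nonparametric test.
#'
#' @param p A `pca_result`.
#' @param groups Label vector (`CT`/`DMHBP`), one per spectrum/row of the
#'   scores.
#' @param component_index Which component to test.
#' @return An object of class `"group_comparison"` with fields
#'   `component_index`, `ks_p_ct`, `ks_p_dm`, `normal_ct`, `normal_dm`,
#'   `t_statistic`, `t_p`, `significant`.
#' @export
compare_component_scores <- function(p, groups, component_index) {
  stopifnot(inherits(p, "pca_result"))
  component_index <- as.integer(component_index)
  if (component_index < 1 || component_index > p$n_components) {
    stop("component_index out of range", call. = FALSE)
  }
  groups <- as.character(groups)
  if (length(groups) != nrow(p$scores)) {
    stop("groups must have one label per spectrum", call. = FALSE)
  }
  x_ct <- p$scores[groups == "CT", component_index]
  x_dm <- p$scores[groups == "DMHBP", component_index]
  if (length(x_ct) < 3 || length(x_dm) < 3) {
    stop("each group needs at least 3 scores", call. = FALSE)
  }
  if (stats::sd(x_ct) == 0 && stats::sd(x_dm) == 0) {
    stop("undefined test: zero variance in both groups", call. = FALSE)
  }
  ks_p <- function(x) {
    if (stats::sd(x) == 0) return(0)
    suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
  }
  ks_ct <- ks_p(x_ct)
  ks_dm <- ks_p(x_dm)
  tt <- stats::t.test(x_ct, x_dm, var.equal = TRUE)
  structure(list(component_index = component_index,
                 ks_p_ct = ks_ct, ks_p_dm = ks_dm,
                 normal_ct = ks_ct >= 0.1, normal_dm = ks_dm >= 0.1,
                 t_statistic = unname(tt$statistic),
                 t_p = tt$p.value,
                 significant = tt$p.value < 0.05),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("PC%d: t = %.3f, p = %.4f%s%s\n", x$component_index,
              x$t_statistic, x$t_p,
              if (x$significant) " *" else "",
              if (!x$normal_ct || !x$normal_dm) " (non-normal scores)" else ""))
  invisible(x)
}

# ---- unit conversion ----------------------------------------------------

.molar_mass <- c(urea = 60.06, creatinine = 113.12, glucose = 180.16) # g/mol

#' Convert a concentration between mmol/L and mg/dL
#'
#' `mg/dL = mmol/L x molar_mass / 10`. Registered molar masses: urea
#' 60.06, creatinine 113.12, glucose 180.16 g/mol. Total protein (and any
#' analyte without a molar mass) cannot be converted.
#'
#' @param value Non-negative concentration(s).
#' @param analyte One of `urea`, `creatinine`, `glucose`.
#' @param direction `"mmolL_to_mgdL"` or `"mgdL_to_mmolL"`.
#' @return Converted concentration(s); the round trip is exact.
#' @examples
#' convert_concentration(3.6, "creatinine", "mmolL_to_mgdL") # 40.7
#' convert_concentration(5.1, "glucose", "mmolL_to_mgdL")    # 91.9
#' @export
convert_concentration <- function(value, analyte,
                                  direction = c("mmolL_to_mgdL", "mgdL_to_mmolL")) {
  direction <- match.arg(direction)
  analyte <- match.arg(analyte, .analytes)
  if (!analyte %in% names(.molar_mass)) {
    stop("unsupported conversion: no molar mass registered for ", analyte,
         call. = FALSE)
  }
  value <- as.numeric(value)
  if (any(value < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (direction == "mmolL_to_mgdL") value * .molar_mass[[analyte]] / 10
  else value * 10 / .molar_mass[[analyte]]
}

# ---- reference ranges ---------------------------------------------------

#' Clinical reference ranges of the five urine biomarkers
#'
#' Sex-specific where the clinical reference is sex-specific; units match
#' the panel convention (mmol/L, total protein in mg/dL). Glucose has an
#' upper bound only.
#'
#' @return `data.frame` with columns `analyte`, `sex` (`M`/`W`/`any`),
#'   `lower`, `upper`, `units`.
#' @export
reference_ranges <- function() {
  data.frame(
    analyte = c("urea", "urea", "creatinine", "creatinine", "glucose",
                "phosphate", "phosphate", "total_protein"),
    sex = c("M", "W", "M", "W", "any", "M", "W", "any"),
    lower = c(51.6, 46.9, 2.12, 1.4, NA, 1.6, 2.3, 1),
    upper = c(549, 580, 34.6, 28.9, 0.83, 61, 48, 15),
    units = c("mmol/L", "mmol/L", "mmol/L", "mmol/L", "mmol/L",
              "mmol/L", "mmol/L", "mg/dL"),
    stringsAsFactors = FALSE)
}

.upper_bound_for <- function(ranges, analyte, sex) {
  rows <- ranges[ranges$analyte == analyte, , drop = FALSE]
  if (!nrow(rows)) stop("no reference range for analyte ", analyte, call. = FALSE)
  if ("any" %in% rows$sex) return(rows$upper[rows$sex == "any"][1])
  if (sex %in% rows$sex) return(rows$upper[rows$sex == sex][1])
  # unknown sex: fall back to the wider (larger) of the sex-specific bounds
  max(rows$upper, na.rm = TRUE)
}

#' Flag concentrations above the reference values
#'
#' A value is flagged when it lies strictly above the applicable upper
#' reference bound (values exactly at the bound are not flagged). For a
#' subject of unknown sex the wider of the male/female bounds applies.
#'
#' @param panels A `biomarker_panels` table (or data.frame with the five
#'   analyte columns and `sample_id`).
#' @param sex Character vector (`M`/`W`/`unknown`), one per row, or a
#'   single value recycled; default `"unknown"`.
#' @param ranges Reference table as from [reference_ranges()].
#' @return List with `flags` (logical data.frame, one column per analyte,
#'   plus `sample_id`) and `summary` (per analyte: `n_above`, `n_total`,
#'   `fraction_above`).
#' @export
flag_above_reference <- function(panels, sex = "unknown",
                                 ranges = reference_ranges()) {
  panels <- as.data.frame(panels)
  missing_rng <- setdiff(.analytes, unique(ranges$analyte))
  if (length(missing_rng)) {
    stop("missing reference range for: ", paste(missing_rng, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(panels)
  sex <- rep_len(as.character(sex), n)
  flags <- data.frame(sample_id = panels$sample_id, stringsAsFactors = FALSE)
  for (a in .analytes) {
    ub <- vapply(sex, function(sx) .upper_bound_for(ranges, a, sx), numeric(1))
    flags[[a]] <- panels[[a]] > ub
  }
  summary <- data.frame(
    analyte = .analytes,
    n_above = vapply(.analytes, function(a) sum(flags[[a]]), integer(1)),
    n_total = n,
    fraction_above = vapply(.analytes, function(a) mean(flags[[a]]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(flags = flags, summary = summary)
}
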