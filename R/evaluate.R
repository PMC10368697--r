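#' Confusion counts from patch-level predictions
#'
#' @param predictions numeric vector of predicted probabilities (decided at
#'   `> 0.5`) or integer 0/1 decisions.
#' @param labels integer vector of true patch labels in `{0, 1}`.
#' @return an object of class `confusion_counts`: list with TP, FP, TN, FN.
#' @export
confusion_from_patches <- function(predictions, labels) {
  if (length(predictions) == 0) stop("no predictions to evaluate")
  if (length(predictions) != length(labels))
    stop("predictions and labels differ in length")
  pred <- as.integer(predictions > 0.5)
  lab <- as.integer(labels)
  stopifnot(all(lab %in% c(0L, 1L)))
  structure(list(TP = sum(pred == 1 & lab == 1),
                 FP = sum(pred == 1 & lab == 0),
                 TN = sum(pred == 0 & lab == 0),
                 FN = sum(pred == 0 & lab == 1)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion: TP %d, FP %d, TN %d, FN %d>\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Classification metric panel
#'
#' Accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, positive predictive value `TP/(TP+FP)` and negative
#' predictive value `TN/(TN+FN)`. Metrics with a zero denominator are
#' reported as `NA` (undefined), never as 0.
#'
#' @param counts a [confusion_from_patches()] result, or a list with
#'   elements TP, FP, TN, FN.
#' @param percent report on the 0-100 scale instead of 0-1.
#' @return named numeric vector: accuracy, sensitivity, specificity, ppv,
#'   npv.
#' @export
metric_panel <- function(counts, percent = FALSE) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- c(accuracy = safe(tp + tn, tp + fp + tn + fn),
           sensitivity = safe(tp, tp + fn),
           specificity = safe(tn, tn + fp),
           ppv = safe(tp, tp + fp),
           npv = safe(tn, tn + fn))
  if (percent) out * 100 else out
}

#' Dice similarity coefficient of two masks
#'
#' `2 |GT intersect PRED| / (|GT| + |PRED|)`. When both masks are empty the
#' coefficient is undefined and `NA` is returned; aneurysm-free cases are
#' therefore excluded from mean DSC summaries.
#'
#' @param gt ground-truth [binary_mask()] or logical array.
#' @param pred predicted [binary_mask()] or logical array on the same grid.
#' @return DSC in `[0, 1]`, or `NA` when both masks are empty.
#' @export
dsc <- function(gt, pred) {
  g <- if (inherits(gt, "binary_mask")) gt$data else gt
  p <- if (inherits(pred, "binary_mask")) pred$data else pred
  if (!identical(dim(g), dim(p)))
    stop(sprintf("mask grids do not match: %s vs %s",
                 paste(dim(g), collapse = "x"), paste(dim(p), collapse = "x")))
  vg <- sum(g)
  vp <- sum(p)
  if (vg + vp == 0) return(NA_real_)
  2 * sum(g & p) / (vg + vp)
}

#' Per-case segmentation scores
#'
#' @param gt_list list of ground-truth masks.
#' @param pred_list list of predicted masks on the same grids.
#' @param case_ids optional identifiers.
#' @return an object of class `seg_scores`: data.frame with case_id, dsc,
#'   v_gt (ground-truth voxels), v_pred; attributes `mean_dsc` and
#'   `std_dsc` computed over cases with a defined DSC.
#' @export
seg_scores <- function(gt_list, pred_list, case_ids = NULL) {
  stopifnot(length(gt_list) == length(pred_list))
  ids <- case_ids %||% sprintf("case%03d", seq_along(gt_list))
  df <- data.frame(
    case_id = ids,
    dsc = mapply(dsc, gt_list, pred_list),
    v_gt = vapply(gt_list, function(m)
      sum(if (inherits(m, "binary_mask")) m$data else m), 0),
    v_pred = vapply(pred_list, function(m)
      sum(if (inherits(m, "binary_mask")) m$data else m), 0),
    stringsAsFactors = FALSE)
  attr(df, "mean_dsc") <- mean(df$dsc, na.rm = TRUE)
  attr(df, "std_dsc") <- sd(df$dsc, na.rm = TRUE)
  class(df) <- c("seg_scores", "data.frame")
  df
}

#' Assign aneurysm size strata
#'
#' The clinical strata: very small (`< 5 mm`), small (`5-10 mm`, inclusive)
#' and large (`> 10 mm`).
#'
#' @param diameters_mm numeric vector of maximum aneurysm diameters.
#' @return factor with levels `"<5 mm"`, `"5-10 mm"`, `">10 mm"`.
#' @export
size_stratum <- function(diameters_mm) {
  lv <- c("<5 mm", "5-10 mm", ">10 mm")
  s <- ifelse(diameters_mm < 5, lv[1], ifelse(diameters_mm <= 10, lv[2], lv[3]))
  factor(s, levels = lv)
}

#' Size-stratified performance report
#'
#' Bins aneurysm-bearing cases into the three clinical size strata and
#' reports per-stratum mean accuracy and mean DSC. Strata without cases
#' are reported as empty (`NA`), not zero; cases without a diameter
#' annotation are excluded with a warning.
#'
#' @param case_metrics data.frame with one row per case, containing at
#'   least `dsc` and optionally `accuracy`.
#' @param diameters_mm per-case maximum aneurysm diameter (NA allowed).
#' @return data.frame with stratum, n, mean_accuracy, mean_dsc, sd_dsc.
#' @export
stratified_report <- function(case_metrics, diameters_mm) {
  stopifnot(nrow(case_metrics) == length(diameters_mm))
  keep <- !is.na(diameters_mm)
  if (any(!keep))
    warning(sprintf("%d case(s) without diameter annotation excluded",
                    sum(!keep)))
  cm <- case_metrics[keep, , drop = FALSE]
  st <- size_stratum(diameters_mm[keep])
  out <- data.frame(stratum = levels(st), n = as.vector(table(st)),
                    mean_accuracy = NA_real_, mean_dsc = NA_real_,
                    sd_dsc = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    sel <- st == out$stratum[i]
    if (!any(sel)) next
    if ("accuracy" %in% names(cm))
      out$mean_accuracy[i] <- mean(cm$accuracy[sel], na.rm = TRUE)
    out$mean_dsc[i] <- mean(cm$dsc[sel], na.rm = TRUE)
    out$sd_dsc[i] <- sd(cm$dsc[sel], na.rm = TRUE)
  }
  out
}
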