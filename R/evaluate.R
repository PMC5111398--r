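#' Confusion summary of detections against a truth table
#'
#' Cellwise comparison over the full reference-species x sample grid:
#' reference species absent from both tables count as true negatives (this
#' full grid is what makes profiling success comparable across data sets).
#' Detection rate is `tp / (tp + fn)` (the fraction of truth detections
#' recovered); profiling success is `(tp + tn) / (tp + tn + fp + fn)`.
#'
#' @param detected logical species x samples matrix of presence calls.
#' @param truth logical species x samples matrix of true presences. Must
#'   share dimnames with `detected`.
#' @return List of class `confusion_summary`: counts `tp`, `tn`, `fp`,
#'   `fn`, rates `detection_rate` and `profiling_success`, and
#'   `discrepancies` (data frame of species, sample, kind).
#' @export
confusion <- function(detected, truth) {
  if (!identical(dim(detected), dim(truth)))
    stop("detected and truth have different shapes: ",
         paste(dim(detected), collapse = "x"), " vs ",
         paste(dim(truth), collapse = "x"))
  if (!identical(rownames(detected), rownames(truth)) ||
      !identical(colnames(detected), colnames(truth))) {
    diff <- c(setdiff(rownames(detected), rownames(truth)),
              setdiff(rownames(truth), rownames(detected)),
              setdiff(colnames(detected), colnames(truth)),
              setdiff(colnames(truth), colnames(detected)))
    stop("label mismatch between detected and truth: ",
         paste(unique(diff), collapse = ", "))
  }
  d <- detected > 0
  t_ <- truth > 0
  tp <- sum(d & t_)
  tn <- sum(!d & !t_)
  fp <- sum(d & !t_)
  fn <- sum(!d & t_)
  fp_idx <- which(d & !t_, arr.ind = TRUE)
  fn_idx <- which(!d & t_, arr.ind = TRUE)
  disc <- rbind(
    if (nrow(fn_idx)) data.frame(species_id = rownames(d)[fn_idx[, 1]],
                                 sample_id = colnames(d)[fn_idx[, 2]],
                                 kind = "false_negative",
                                 stringsAsFactors = FALSE),
    if (nrow(fp_idx)) data.frame(species_id = rownames(d)[fp_idx[, 1]],
                                 sample_id = colnames(d)[fp_idx[, 2]],
                                 kind = "false_positive",
                                 stringsAsFactors = FALSE)
  )
  if (is.null(disc))
    disc <- data.frame(species_id = character(), sample_id = character(),
                       kind = character(), stringsAsFactors = FALSE)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 detection_rate = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 profiling_success = (tp + tn) / (tp + tn + fp + fn),
                 discrepancies = disc),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("confusion: tp=%d tn=%d fp=%d fn=%d\n", x$tp, x$tn, x$fp, x$fn))
  cat(sprintf("  detection rate    = %.1f%%\n", 100 * x$detection_rate))
  cat(sprintf("  profiling success = %.1f%%\n", 100 * x$profiling_success))
  invisible(x)
}

#' Confusion summaries across a sweep of detection thresholds
#'
#' Applies strict `coverage > threshold` calls at each threshold and
#' summarises each against the truth. Raising the threshold can only flip
#' cells from present to absent.
#'
#' @param coverage_matrix species x samples matrix of coverage fractions.
#' @param truth logical species x samples truth matrix (same dimnames).
#' @param thresholds strictly increasing thresholds in (0, 1).
#' @return Data frame: one row per threshold with counts and rates.
#' @export
threshold_sweep <- function(coverage_matrix, truth, thresholds) {
  if (any(diff(thresholds) <= 0) || any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must be strictly increasing within (0, 1)")
  rows <- lapply(thresholds, function(th) {
    cs <- confusion(coverage_matrix > th, truth)
    data.frame(threshold = th, tp = cs$tp, tn = cs$tn, fp = cs$fp,
               fn = cs$fn, detection_rate = cs$detection_rate,
               profiling_success = cs$profiling_success)
  })
  do.call(rbind, rows)
}
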