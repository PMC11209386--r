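#' Confusion counts inside the field of view
#'
#' Counts true/false positives/negatives of a binary vessel prediction
#' against ground truth, restricted to the FoV pixels; vessels are the
#' positive class.
#'
#' @param pred,gt binary masks (0/1 or logical) of equal size.
#' @param fov binary FoV mask of the same size; `NULL` evaluates every pixel.
#' @return object of class `confusion_counts` with fields `tp, fp, tn, fn`.
#' @export
confusion <- function(pred, gt, fov = NULL) {
  if (!identical(dim(pred), dim(gt)))
    stop("prediction and ground truth have different geometry")
  if (is.null(fov)) fov <- array(1L, dim(pred))
  if (!identical(dim(fov), dim(gt)))
    stop("FoV mask has different geometry from the masks")
  keep <- fov > 0
  p <- pred[keep] > 0
  g <- gt[keep] > 0
  structure(list(tp = sum(p & g), fp = sum(p & !g),
                 tn = sum(!p & !g), fn = sum(!p & g)),
            class = "confusion_counts")
}

metric_ratio <- function(num, den, what) {
  if (den == 0) {
    message(sprintf("%s has zero denominator; returning 1 (vacuous)", what))
    return(1)
  }
  num / den
}

#' Segmentation metrics from confusion counts
#'
#' Computes the five standard scores: `IOU = TP/(TP+FP+FN)`,
#' `Acc = (TP+TN)/total`, `Sen = TP/(TP+FN)`, `Spe = TN/(TN+FP)`,
#' `F1 = 2TP/(2TP+FP+FN)`. When a denominator is zero the condition is
#' vacuously satisfied (no pixels of that kind exist and none were
#' predicted), so 1 is returned with a logged message.
#'
#' @param counts a [confusion()] object or list with `tp, fp, tn, fn`.
#' @return object of class `metric_report` with fields
#'   `iou, acc, sen, spe, f1` and the originating `counts`.
#' @export
metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  if (total == 0) stop("confusion counts are empty; nothing to evaluate")
  structure(list(iou = metric_ratio(tp, tp + fp + fn, "IOU"),
                 acc = (tp + tn) / total,
                 sen = metric_ratio(tp, tp + fn, "Sen"),
                 spe = metric_ratio(tn, tn + fp, "Spe"),
                 f1 = metric_ratio(2 * tp, 2 * tp + fp + fn, "F1"),
                 counts = counts),
            class = "metric_report")
}

#' @export
as.data.frame.metric_report <- function(x, ...) {
  data.frame(acc = x$acc, sen = x$sen, spe = x$spe, f1 = x$f1, iou = x$iou)
}

#' F1 from IOU
#'
#' The two scores derive from the same counts, so `F1 = 2 IOU / (1 + IOU)`
#' identically.
#'
#' @param iou IOU value in `[0, 1]`.
#' @return the corresponding F1 score.
#' @export
f1_from_iou <- function(iou) 2 * iou / (1 + iou)

#' Aggregate per-image reports
#'
#' Default `"pooled"` mode sums the confusion counts of all images and
#' recomputes the metrics, equivalent to evaluating one concatenated mask;
#' `"mean"` averages the per-image scores unweighted. The mode used is
#' recorded on the result.
#'
#' @param reports nonempty list of `metric_report` objects.
#' @param mode `"pooled"` (default) or `"mean"`.
#' @return a `metric_report` (pooled) carrying attribute `mode`.
#' @export
aggregate_reports <- function(reports, mode = c("pooled", "mean")) {
  mode <- match.arg(mode)
  if (length(reports) == 0L) stop("no reports to aggregate")
  if (mode == "pooled") {
    cc <- list(tp = 0, fp = 0, tn = 0, fn = 0)
    for (r in reports) for (k in names(cc)) cc[[k]] <- cc[[k]] + r$counts[[k]]
    out <- metrics(structure(cc, class = "confusion_counts"))
  } else {
    avg <- function(k) mean(vapply(reports, `[[`, numeric(1), k))
    out <- structure(list(iou = avg("iou"), acc = avg("acc"),
                          sen = avg("sen"), spe = avg("spe"), f1 = avg("f1"),
                          counts = NULL),
                     class = "metric_report")
  }
  attr(out, "mode") <- mode
  out
}

#' Per-metric deltas between two reports
#'
#' Differences `(a - b) * 100` in percentage points, rounded to two decimals
#' for display (the convention used when comparing segmentation tables).
#'
#' @param a,b `metric_report` objects or named lists containing
#'   `iou, acc, sen, spe, f1`.
#' @return named numeric vector of deltas in percentage points.
#' @export
compare_reports <- function(a, b) {
  ks <- c("acc", "sen", "spe", "f1", "iou")
  out <- vapply(ks, function(k) round((a[[k]] - b[[k]]) * 100, 2), numeric(1))
  names(out) <- ks
  out
}

#' Write an evaluation report
#'
#' Writes per-image rows plus an aggregate row, with columns in the order
#' `Acc, Sen, Spe, F1, IOU`, as CSV and/or JSON.
#'
#' @param evaluation result of [evaluate_model()].
#' @param csv,json optional output paths.
#' @return the combined data.frame, invisibly.
#' @export
write_report <- function(evaluation, csv = NULL, json = NULL) {
  agg <- data.frame(id = "aggregate",
                    as.data.frame(evaluation$aggregate))
  tab <- rbind(evaluation$per_image, agg)
  if (!is.null(csv)) utils::write.csv(tab, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(tab, json, dataframe = "rows", digits = NA)
  invisible(tab)
}
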