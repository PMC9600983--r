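#' Slice-level confusion counts
#'
#' @param calls Logical vector of per-slice CAC calls.
#' @param truth Logical vector of per-slice ground truth, same length.
#' @return A `confusion_counts` list with `tp`, `fp`, `fn`, `tn`.
#' @export
#' @examples
#' confusion_counts(c(TRUE, FALSE, TRUE), c(TRUE, TRUE, FALSE))
confusion_counts <- function(calls, truth) {
  calls <- as.logical(calls)
  truth <- as.logical(truth)
  if (length(calls) != length(truth)) {
    stop_arg("calls and truth lengths differ (", length(calls), " vs ",
             length(truth), ")")
  }
  if (anyNA(calls) || anyNA(truth)) stop_arg("calls/truth contain NA")
  new_confusion_counts(
    tp = sum(calls & truth), fp = sum(calls & !truth),
    fn = sum(!calls & truth), tn = sum(!calls & !truth)
  )
}

#' @rdname confusion_counts
#' @param tp,fp,fn,tn Non-negative integer counts (for building a
#'   confusion table directly, e.g. from a published table).
#' @export
new_confusion_counts <- function(tp, fp, fn, tn) {
  for (v in list(tp, fp, fn, tn)) {
    if (!is_count(v)) stop_arg("confusion counts must be non-negative integers")
  }
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> TP ", x$tp, " | FP ", x$fp, " | FN ", x$fn,
      " | TN ", x$tn, "\n", sep = "")
  invisible(x)
}

#' Diagnostic metrics from confusion counts
#'
#' Computes sensitivity, specificity, positive and negative predictive
#' value, and diagnostic accuracy as percentages, rounded half-up.  A
#' metric whose denominator is zero is reported as `NA` (undefined),
#' never silently as 0.
#'
#' @param counts A [confusion_counts()].
#' @param round_digits `NULL` for the conventional clinical rounding
#'   (1 decimal for sensitivity/specificity/PPV/NPV, 2 for accuracy), a
#'   single number applied to all five metrics, or a named vector.
#' @return One-row tibble with the five metrics in percent.
#' @export
#' @examples
#' diagnostic_metrics(new_confusion_counts(178, 135, 11, 3681))
diagnostic_metrics <- function(counts, round_digits = NULL) {
  stopifnot(inherits(counts, "confusion_counts"))
  digits <- c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1,
              accuracy = 2)
  if (!is.null(round_digits)) {
    if (length(round_digits) == 1L && is.null(names(round_digits))) {
      digits[] <- round_digits
    } else {
      digits[names(round_digits)] <- round_digits
    }
  }
  safe <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  raw <- c(
    sensitivity = safe(counts$tp, counts$tp + counts$fn),
    specificity = safe(counts$tn, counts$tn + counts$fp),
    ppv = safe(counts$tp, counts$tp + counts$fp),
    npv = safe(counts$tn, counts$tn + counts$fn),
    accuracy = safe(counts$tp + counts$tn,
                    counts$tp + counts$fp + counts$fn + counts$tn)
  )
  out <- mapply(function(v, d) if (is.na(v)) NA_real_ else
    round_half_up(v, d), raw, digits[names(raw)])
  as_tibble(as.list(out))
}

mask_as_binary <- function(x) {
  if (!all(x %in% c(0, 1))) stop_arg("masks must contain only {0,1}")
  x
}

#' Per-class intersection over union
#'
#' IoU of the class-`cls` indicator sets of two masks; defined as 1 when
#' both sets are empty.
#'
#' @param pred,truth 0/1 matrices of equal shape.
#' @param cls Class indicator, 0 (background) or 1 (foreground).
#' @return Fraction in [0,1].
#' @export
iou <- function(pred, truth, cls = 1) {
  if (!identical(dim(pred), dim(truth))) {
    stop_arg("pred and truth shapes differ")
  }
  mask_as_binary(pred)
  mask_as_binary(truth)
  a <- pred == cls
  b <- truth == cls
  un <- sum(a | b)
  if (un == 0) return(1)
  sum(a & b) / un
}

#' Mean IoU over a collection of mask pairs
#'
#' Two aggregations are implemented because published mean-IoU figures
#' rarely state theirs: `per_class_pooled` pools intersections and unions
#' per class over all pairs and then averages the two class IoUs (the
#' default); `per_image_mean` averages the per-pair two-class mean.
#'
#' @param pairs List of `list(pred, truth)` mask pairs.
#' @param aggregation `"per_class_pooled"` or `"per_image_mean"`.
#' @return One-row tibble: `iou_background`, `iou_foreground`, `mean_iou`,
#'   `aggregation`.
#' @export
mean_iou <- function(pairs, aggregation = c("per_class_pooled",
                                            "per_image_mean")) {
  aggregation <- match.arg(aggregation)
  if (length(pairs) == 0L) stop_arg("empty collection of mask pairs")
  if (aggregation == "per_class_pooled") {
    inter <- c(`0` = 0, `1` = 0)
    un <- c(`0` = 0, `1` = 0)
    for (p in pairs) {
      if (!identical(dim(p[[1]]), dim(p[[2]]))) {
        stop_arg("pred and truth shapes differ")
      }
      for (cls in c(0, 1)) {
        a <- p[[1]] == cls
        b <- p[[2]] == cls
        k <- as.character(cls)
        inter[k] <- inter[k] + sum(a & b)
        un[k] <- un[k] + sum(a | b)
      }
    }
    per_class <- ifelse(un == 0, 1, inter / pmax(un, 1))
    tibble(iou_background = per_class[["0"]],
           iou_foreground = per_class[["1"]],
           mean_iou = mean(per_class),
           aggregation = aggregation)
  } else {
    per_pair <- vapply(pairs, function(p) {
      (iou(p[[1]], p[[2]], 0) + iou(p[[1]], p[[2]], 1)) / 2
    }, numeric(1))
    bg <- mean(vapply(pairs, function(p) iou(p[[1]], p[[2]], 0), numeric(1)))
    fg <- mean(vapply(pairs, function(p) iou(p[[1]], p[[2]], 1), numeric(1)))
    tibble(iou_background = bg, iou_foreground = fg,
           mean_iou = mean(per_pair), aggregation = aggregation)
  }
}

#' Boundary-error summary over scans
#'
#' @param predicted,truth Integer vectors of boundary slice indices.
#' @param scan_id Optional scan identifiers.
#' @return A `boundary_report`: list with a per-scan tibble,
#'   `max_abs_error` and `median_abs_error` (slices).
#' @export
#' @examples
#' boundary_report(predicted = 357, truth = 345)
boundary_report <- function(predicted, truth, scan_id = NULL) {
  if (length(predicted) == 0L) stop_arg("no boundary results supplied")
  if (length(predicted) != length(truth)) {
    stop_arg("predicted and truth lengths differ")
  }
  err <- boundary_error(predicted, truth)
  per_scan <- tibble(
    scan_id = scan_id %||% sprintf("scan_%03d", seq_along(err)),
    predicted = as.integer(predicted),
    truth = as.integer(truth),
    abs_error = err
  )
  structure(
    list(per_scan = per_scan, max_abs_error = max(err),
         median_abs_error = median(err)),
    class = "boundary_report"
  )
}

#' @export
print.boundary_report <- function(x, ...) {
  cat("<boundary_report> ", nrow(x$per_scan), " scans, max |error| ",
      x$max_abs_error, " slices, median ", x$median_abs_error, "\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.boundary_report <- function(x, ...) x$per_scan

#' @export
glance.boundary_report <- function(x, ...) {
  tibble(n_scans = nrow(x$per_scan), max_abs_error = x$max_abs_error,
         median_abs_error = x$median_abs_error)
}
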