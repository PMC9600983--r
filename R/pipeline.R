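#' Run the full two-stage CAC detection pipeline on one stack
#'
#' Stage 1 trims the artifact margin, classifies every retained slice and
#' fits the 0-to-100 step function to gate the stack at the C2-C3
#' boundary.  Stage 2 segments only the slices at or below the fitted
#' boundary and reduces each to a CAC call; gated-out slices are reported
#' as negative without being segmented.
#'
#' @param stack A [slice_stack()].
#' @param classifier A trained [train_slice_classifier()] model.
#' @param segmenter A trained [train_segmenter()] model.
#' @param margin Artifact margin (slices trimmed at each end).
#' @param method Patch sampling for stage 2, `"B"` or `"A"`.
#' @param rule A [slice_decision_rule()].
#' @param ... Passed on to [predict_mask()].
#' @return A `cac_result`: list with `confidences` (the stage-1 series),
#'   `boundary` (the [fit_step_function()] result) and `slices` (tibble of
#'   per-retained-slice calls with `gated` marking slices above the
#'   boundary).
#' @export
detect_cac <- function(stack, classifier, segmenter, margin = 7L,
                       method = "B", rule = slice_decision_rule(), ...) {
  conf <- predict_confidence(classifier, stack, margin)
  fit <- fit_step_function(conf)
  retained <- conf$slice_index
  below <- retained[retained >= fit$boundary_index]
  seg <- if (length(below) > 0) {
    predict_mask(segmenter, stack$slices[, , below, drop = FALSE],
                 method = method, rule = rule, slice_index = below, ...)
  } else {
    NULL
  }
  slices <- tibble(
    slice_index = retained,
    gated = retained < fit$boundary_index,
    cac_call = FALSE,
    foreground_pixels = 0L
  )
  if (!is.null(seg)) {
    m <- match(seg$slice_index, slices$slice_index)
    slices$cac_call[m] <- seg$cac_call
    slices$foreground_pixels[m] <- seg$foreground_pixels
  }
  structure(
    list(scan_id = stack$scan_id, confidences = conf, boundary = fit,
         slices = slices, segmentation = seg),
    class = "cac_result"
  )
}

#' @export
print.cac_result <- function(x, ...) {
  cat("<cac_result> ", x$scan_id, ": boundary at slice ",
      x$boundary$boundary_index, "; ", sum(x$slices$cac_call),
      " positive of ", nrow(x$slices), " retained slices\n", sep = "")
  invisible(x)
}

#' @export
glance.cac_result <- function(x, ...) {
  tibble(scan_id = x$scan_id, boundary_index = x$boundary$boundary_index,
         boundary_sse = x$boundary$sse,
         n_retained = nrow(x$slices),
         n_positive_slices = sum(x$slices$cac_call),
         scan_positive = any(x$slices$cac_call))
}
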