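#' Fit a 0-to-100 step function to a confidence series
#'
#' The per-slice below-boundary confidences of a clean scan look like a
#' step: near 0 above the C2-C3 level and near 100 below it.  The boundary
#' is recovered by least squares over the single free parameter, the
#' breakpoint `k`: `SSE(k) = sum_(i<k+1) v_i^2 + sum_(i>=k+1) (v_i-100)^2`
#' where `k` slices precede the step (`k` ranges over `0..n`, so "all
#' below" and "all above" are admissible).  Ties are broken toward the
#' smallest `k`, i.e. the superior-most boundary.
#'
#' @param series A `confidence_series` (from [predict_confidence()] or
#'   [confidence_series()]) or a bare numeric vector of values in [0,100].
#' @param offset Index offset of the series within the original stack;
#'   taken from the series attribute when available.
#' @param levels `"fixed"` fits the step at levels 0 and 100 (the
#'   default); `"free"` estimates the two levels by segment means.
#' @return A `boundary_fit`: list with `boundary_index` (1-based index,
#'   in original-stack coordinates, of the first below-boundary slice;
#'   `offset + n + 1` means the whole series is above), `sse`,
#'   `candidate_sse` (tibble of all breakpoints), `offset` and `n`.
#' @export
#' @examples
#' fit_step_function(confidence_series(c(0, 0, 0, 100, 100)))
fit_step_function <- function(series, offset = NULL,
                              levels = c("fixed", "free")) {
  levels <- match.arg(levels)
  if (inherits(series, "confidence_series")) {
    if (is.null(offset)) offset <- attr(series, "offset")
    v <- series$confidence
  } else {
    v <- as.numeric(series)
  }
  offset <- as.integer(offset %||% 0L)
  n <- length(v)
  if (n == 0L) stop_arg("confidence series is empty")
  if (any(is.na(v))) stop_arg("confidence series contains NA")

  k <- 0:n
  if (levels == "fixed") {
    low <- c(0, cumsum(v^2))                 # residuals of slices before step
    high <- rev(c(0, cumsum(rev((v - 100)^2))))
    sse <- low + high
  } else {
    # free levels: per-segment means; empty segments contribute 0
    cs <- c(0, cumsum(v))
    cs2 <- c(0, cumsum(v^2))
    nl <- k
    nr <- n - k
    ssl <- cs2[k + 1] - ifelse(nl > 0, (cs[k + 1])^2 / pmax(nl, 1), 0)
    ssr <- (cs2[n + 1] - cs2[k + 1]) -
      ifelse(nr > 0, (cs[n + 1] - cs[k + 1])^2 / pmax(nr, 1), 0)
    sse <- ssl + ssr
  }
  best <- which.min(sse)                     # smallest k on ties
  k_best <- k[best]
  structure(
    list(
      boundary_index = offset + k_best + 1L,
      sse = sse[best],
      candidate_sse = tibble(k = k, boundary_index = offset + k + 1L,
                             sse = sse),
      offset = offset,
      n = n,
      levels = levels
    ),
    class = "boundary_fit"
  )
}

#' @export
print.boundary_fit <- function(x, ...) {
  cat("<boundary_fit> boundary at slice ", x$boundary_index,
      " (offset ", x$offset, ", ", x$n, " retained slices), SSE ",
      signif(x$sse, 6), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.boundary_fit <- function(x, ...) x$candidate_sse

#' @export
glance.boundary_fit <- function(x, ...) {
  tibble(boundary_index = x$boundary_index, sse = x$sse,
         n = x$n, offset = x$offset)
}

#' Absolute boundary localization error
#'
#' @param predicted,truth Slice indices (same coordinate system).
#' @return `abs(predicted - truth)`, in slices.
#' @export
#' @examples
#' boundary_error(357, 345)  # 12
boundary_error <- function(predicted, truth) {
  if (any(!is.finite(predicted)) || any(!is.finite(truth))) {
    stop_arg("slice indices must be finite")
  }
  abs(as.integer(predicted) - as.integer(truth))
}
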