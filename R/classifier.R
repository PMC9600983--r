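#' Configuration for the stage-1 slice classifier
#'
#' A small convolutional network (three conv/pool blocks, global average
#' pooling, 2-way softmax) trained from scratch assigns each axial slice a
#' confidence of lying at or below the C2-C3 boundary.  The backbone slot
#' is pluggable: any list providing `fit(x, y, config)` and
#' `predict(model, x)` can replace the built-in network, e.g. to slot in a
#' transfer-learned classifier.
#'
#' @param backbone `"tiny_cnn"` (default) or a list with elements `fit`
#'   and `predict` (see Details).
#' @param base_channels Channel width of the first conv block.
#' @param input_size Square side length slices are resized to before
#'   classification (must be divisible by 4).
#' @param epochs,batch_size,learning_rate Training hyperparameters.
#' @param seed Integer seed controlling initialization and batch order.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(backbone = "tiny_cnn",
                              base_channels = 8L,
                              input_size = 96L,
                              epochs = 5L,
                              batch_size = 8L,
                              learning_rate = 3e-3,
                              seed = 1L) {
  if (!is_count(epochs, 1L)) stop_cfg("epochs must be >= 1")
  if (!is_count(input_size, 4L) || input_size %% 4L != 0L) {
    stop_cfg("input_size must be a positive multiple of 4")
  }
  if (is.character(backbone) && !identical(backbone, "tiny_cnn")) {
    stop_cfg("unknown backbone '", backbone,
             "'; use \"tiny_cnn\" or supply a fit/predict list")
  }
  if (is.list(backbone) &&
      !all(c("fit", "predict") %in% names(backbone))) {
    stop_cfg("a pluggable backbone must provide fit() and predict()")
  }
  structure(
    list(backbone = backbone, base_channels = as.integer(base_channels),
         input_size = as.integer(input_size), epochs = as.integer(epochs),
         batch_size = as.integer(batch_size),
         learning_rate = learning_rate, seed = as.integer(seed)),
    class = "classifier_config"
  )
}

#' Trim cone-beam artifact slices from both stack ends
#'
#' CBCT stacks carry degraded slices at the superior and inferior ends of
#' the field of view; these are removed before classification.
#'
#' @param stack A [slice_stack()].
#' @param margin Number of slices to drop at each end (default 7).
#' @return List with `stack` (the trimmed [slice_stack()]) and `offset`
#'   (= `margin`): retained slice `i` was original slice `i + offset`.
#' @export
#' @examples
#' st <- slice_stack(array(runif(16 * 16 * 20), c(16, 16, 20)))
#' trimmed <- trim_artifact_slices(st, margin = 3)
#' n_slices(trimmed$stack)  # 14
trim_artifact_slices <- function(stack, margin = 7L) {
  if (!is_count(margin, 0L)) stop_arg("margin must be a non-negative integer")
  n <- n_slices(stack)
  if (2L * margin >= n) {
    stop_arg("margin ", margin, " too large for a ", n, "-slice stack ",
             "(need 2*margin < n)")
  }
  keep <- (margin + 1L):(n - margin)
  list(
    stack = slice_stack(stack$slices[, , keep, drop = FALSE],
                        scan_id = stack$scan_id,
                        voxel_size_mm = stack$voxel_size_mm),
    offset = as.integer(margin)
  )
}

resize_slice <- function(img, size) {
  if (all(dim(img) == size)) return(img)
  as.matrix(EBImage::resize(EBImage::Image(img), w = size, h = size))
}

prep_slices <- function(slices, size) {
  lapply(as_slice_list(slices), resize_slice, size = size)
}

#' Build labeled training slices from phantom scans
#'
#' Trims the artifact margin of every scan and labels each retained slice
#' `"above"` or `"below"` using the known boundary index.
#'
#' @param scans A `phantom_dataset` or list of `phantom_scan`s.
#' @param margin Artifact margin to trim.
#' @return List with `slices` (list of matrices) and `labels`
#'   (factor with levels `above`, `below`).
#' @export
slice_training_data <- function(scans, margin = 7L) {
  slices <- list()
  labels <- character()
  for (sc in scans) {
    tr <- trim_artifact_slices(sc$stack, margin)
    idx <- seq_len(n_slices(tr$stack)) + tr$offset
    slices <- c(slices, as_slice_list(tr$stack))
    labels <- c(labels, ifelse(idx >= sc$boundary_index, "below", "above"))
  }
  list(slices = slices, labels = factor(labels, levels = c("above", "below")))
}

#' Train the stage-1 slice classifier
#'
#' @param slices List of slice matrices (or H x W x n array).
#' @param labels Factor/character vector with values `above` / `below`,
#'   one per slice.
#' @param config A [classifier_config()].
#' @return A `slice_classifier` with elements `params`, `config`, and a
#'   per-epoch training `log` tibble.
#' @export
train_slice_classifier <- function(slices, labels,
                                   config = classifier_config()) {
  slices <- prep_slices(slices, config$input_size)
  labels <- factor(as.character(labels), levels = c("above", "below"))
  if (anyNA(labels)) stop_arg("labels must be 'above' or 'below'")
  if (length(slices) != length(labels)) {
    stop_arg("slices and labels lengths differ")
  }
  if (nlevels(droplevels(labels)) < 2L) {
    abort("training data must contain both classes (above and below)",
          class = "cacseg_training_error")
  }
  if (is.list(config$backbone)) {
    model <- config$backbone$fit(slices, labels, config)
    return(structure(list(params = NULL, backbone = config$backbone,
                          external = model, config = config,
                          log = tibble(epoch = integer(), loss = numeric())),
                     class = "slice_classifier"))
  }
  y <- as.integer(labels == "below")          # 1 = below boundary
  local_seed(config$seed, {
    params <- tiny_cnn_init(config$base_channels)
    state <- adam_init(params)
    n <- length(slices)
    log <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = config$batch_size)) {
        ids <- ord[start:min(start + config$batch_size - 1L, n)]
        grad_acc <- NULL
        batch_loss <- 0
        for (id in ids) {
          fwd <- tiny_cnn_forward(params, slices[[id]])
          p <- softmax2_vec(fwd$logits)
          yi <- y[id]
          batch_loss <- batch_loss - log(max(p[yi + 1L], 1e-12))
          dlog <- p - c(1 - yi, yi)
          g <- tiny_cnn_backward(params, fwd$cache, dlog)
          grad_acc <- if (is.null(grad_acc)) g else tree_map2(grad_acc, g, `+`)
        }
        grad_acc <- tree_map(grad_acc, function(x) x / length(ids))
        upd <- adam_step(params, grad_acc, state, config$learning_rate)
        params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + batch_loss
      }
      log[ep] <- ep_loss / n
    }
    structure(
      list(params = params, config = config,
           log = tibble(epoch = seq_len(config$epochs), loss = log)),
      class = "slice_classifier"
    )
  })
}

#' @export
print.slice_classifier <- function(x, ...) {
  cat("<slice_classifier> ", n_parameters(x), " parameters, trained ",
      nrow(x$log), " epochs", sep = "")
  if (nrow(x$log) > 0) cat(", final loss ", signif(tail(x$log$loss, 1), 4),
                           sep = "")
  cat("\n")
  invisible(x)
}

#' @export
tidy.slice_classifier <- function(x, ...) x$log

#' @export
glance.slice_classifier <- function(x, ...) {
  tibble(n_parameters = n_parameters(x), epochs = nrow(x$log),
         final_loss = if (nrow(x$log)) tail(x$log$loss, 1) else NA_real_)
}

predict_below_prob <- function(model, slices) {
  slices <- prep_slices(slices, model$config$input_size)
  if (!is.null(model$external)) {
    return(as.numeric(model$backbone$predict(model$external, slices)))
  }
  if (is.null(model$params)) stop_state("classifier has not been trained")
  vapply(slices, function(sl) {
    softmax2_vec(tiny_cnn_forward(model$params, sl)$logits)[2]
  }, numeric(1))
}

#' Per-slice below-boundary confidence for a stack
#'
#' Each retained slice is classified independently; the confidence is the
#' softmax probability of the below-boundary class expressed in percent,
#' so values near 100 mean "below the C2-C3 level" and values near 0 mean
#' "above" (a confidence of 4 means the classifier is 96 percent sure the
#' slice is above the boundary).
#'
#' @param model A trained [train_slice_classifier()] model.
#' @param stack A [slice_stack()].
#' @param margin Artifact margin trimmed before classification.
#' @return A `confidence_series` tibble with columns `slice_index`
#'   (original 1-based stack index) and `confidence` (0-100), plus an
#'   `offset` attribute.
#' @export
predict_confidence <- function(model, stack, margin = 7L) {
  tr <- trim_artifact_slices(stack, margin)
  conf <- 100 * predict_below_prob(model, tr$stack)
  out <- tibble(
    slice_index = seq_len(n_slices(tr$stack)) + tr$offset,
    confidence = conf
  )
  new_confidence_series(out, offset = tr$offset)
}

new_confidence_series <- function(tbl, offset) {
  structure(tbl, offset = as.integer(offset),
            class = c("confidence_series", class(tbl)))
}

#' Construct a confidence series from raw values
#'
#' @param values Numeric vector of confidences in [0,100], one per
#'   retained slice.
#' @param offset Index of the last trimmed slice before the series
#'   (0 if nothing was trimmed).
#' @return A `confidence_series` tibble.
#' @export
confidence_series <- function(values, offset = 0L) {
  if (any(values < 0 | values > 100)) {
    stop_arg("confidences must lie in [0,100]")
  }
  new_confidence_series(
    tibble(slice_index = seq_along(values) + as.integer(offset),
           confidence = as.numeric(values)),
    offset = offset
  )
}
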