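#' Configuration for the encoder-decoder segmenter
#'
#' The segmenter is a small U-shaped fully convolutional network: `depth`
#' encoder levels of two 3x3 convolutions each with 2x2 max pooling
#' between levels, a mirrored decoder with nearest-neighbour upsampling
#' and skip connections, and a final 1x1 convolution to two per-pixel
#' class logits (background, calcification).  Defaults are desk-scale
#' (depth 3, 8 base channels) so CPU training takes minutes; deeper and
#' wider configurations reproduce the published architecture family.
#'
#' @param depth Number of encoder levels (>= 2).
#' @param base_channels Channels in the first encoder level; doubled per
#'   level.
#' @param loss `"weighted_cross_entropy"` or `"cross_entropy"`.
#' @param class_weights `"auto"` (inverse pixel frequency, background
#'   weight normalized to 1) or a positive pair `c(background, foreground)`.
#'   Ignored for the unweighted loss.
#' @param threshold Probability cutoff for binarizing the foreground map.
#' @param epochs,batch_size,learning_rate Training hyperparameters.
#' @param grad_clip Maximum global gradient norm per update (`Inf`
#'   disables clipping).  Heavily weighted losses occasionally produce
#'   very large batch gradients; clipping keeps training stable.
#' @param seed Integer seed for initialization and batch order.
#' @return A `seg_config` list.
#' @export
seg_config <- function(depth = 3L,
                       base_channels = 8L,
                       loss = c("weighted_cross_entropy", "cross_entropy"),
                       class_weights = "auto",
                       threshold = 0.5,
                       epochs = 8L,
                       batch_size = 8L,
                       learning_rate = 1e-3,
                       grad_clip = 5,
                       seed = 1L) {
  loss <- match.arg(loss)
  if (!is_count(depth, 2L)) stop_cfg("depth must be an integer >= 2")
  if (!is_count(epochs, 1L)) stop_cfg("epochs must be >= 1")
  if (threshold <= 0 || threshold >= 1) {
    stop_cfg("threshold must lie in (0,1)")
  }
  if (!identical(class_weights, "auto")) {
    if (length(class_weights) != 2L || any(class_weights <= 0)) {
      stop_cfg("class_weights must be \"auto\" or two positive numbers")
    }
  }
  structure(
    list(depth = as.integer(depth), base_channels = as.integer(base_channels),
         loss = loss, class_weights = class_weights, threshold = threshold,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, grad_clip = grad_clip,
         seed = as.integer(seed)),
    class = "seg_config"
  )
}

#' Build an (untrained) segmenter
#'
#' @param config A [seg_config()].
#' @param input_size Optional square input side; when given it is checked
#'   for divisibility by `2^(depth-1)` (the network itself is fully
#'   convolutional and accepts any divisible size).
#' @return A `seg_model` with seeded initial parameters.
#' @export
build_segmenter <- function(config = seg_config(), input_size = NULL) {
  if (!is.null(input_size)) {
    div <- 2L^(config$depth - 1L)
    if (input_size %% div != 0L) {
      stop_cfg("input_size ", input_size, " is not divisible by ", div,
               " (required for depth ", config$depth, ")")
    }
  }
  params <- local_seed(config$seed, unet_init(config$depth,
                                              config$base_channels))
  structure(
    list(params = params, config = config, trained = FALSE,
         class_weights = NULL,
         log = tibble(epoch = integer(), loss = numeric())),
    class = "seg_model"
  )
}

#' @export
print.seg_model <- function(x, ...) {
  cat("<seg_model> depth ", x$config$depth, ", base ",
      x$config$base_channels, " channels, ", n_parameters(x),
      " parameters, ", if (x$trained) "trained" else "untrained", "\n",
      sep = "")
  if (!is.null(x$class_weights)) {
    cat("  class weights (bg, fg): ", signif(x$class_weights[1], 4), ", ",
        signif(x$class_weights[2], 4), "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.seg_model <- function(x, ...) x$log

#' @export
glance.seg_model <- function(x, ...) {
  tibble(n_parameters = n_parameters(x), depth = x$config$depth,
         epochs = nrow(x$log),
         final_loss = if (nrow(x$log)) tail(x$log$loss, 1) else NA_real_,
         weight_foreground = if (is.null(x$class_weights)) NA_real_
         else x$class_weights[2])
}

#' Class-weighted cross-entropy on a probability map
#'
#' `loss = -mean_p( w[class(p)] * log prob_p(class(p)) )` over pixels `p`.
#' With weights `c(1, 1)` this is the standard cross-entropy; raising the
#' foreground weight adds penalty for every misclassified calcification
#' pixel, which counteracts the extreme background/foreground imbalance.
#'
#' @param probabilities H x W x 2 array of per-pixel class probabilities
#'   (background, foreground).
#' @param target H x W 0/1 matrix.
#' @param weights Positive pair `c(background, foreground)`.
#' @return Non-negative scalar loss.
#' @export
#' @examples
#' p <- array(c(0.9, 0.2, 0.1, 0.8), c(1, 2, 2))
#' weighted_cross_entropy(p, matrix(c(0, 1), 1, 2), weights = c(1, 10))
weighted_cross_entropy <- function(probabilities, target, weights = c(1, 1)) {
  if (length(weights) != 2L || any(!is.finite(weights)) || any(weights <= 0)) {
    stop_arg("weights must be two positive finite numbers")
  }
  d <- dim(probabilities)
  if (length(d) != 3L || d[3] != 2L || !all(d[1:2] == dim(target))) {
    stop_arg("probabilities must be H x W x 2 and match the target shape")
  }
  wmat <- ifelse(target == 1, weights[2], weights[1])
  py <- ifelse(target == 1, probabilities[, , 2], probabilities[, , 1])
  mean(-wmat * log(pmax(py, 1e-12)))
}

auto_class_weights <- function(patches) {
  fg <- sum(vapply(patches, function(p) sum(p$mask), numeric(1)))
  tot <- sum(vapply(patches, function(p) length(p$mask), numeric(1)))
  if (fg == 0) {
    stop_cfg("class_weights = \"auto\" is undefined on an all-background ",
             "training set (foreground frequency is zero)")
  }
  c(1, (tot - fg) / fg)
}

resolve_class_weights <- function(config, patches) {
  if (config$loss == "cross_entropy") return(c(1, 1))
  if (identical(config$class_weights, "auto")) {
    auto_class_weights(patches)
  } else {
    as.numeric(config$class_weights)
  }
}

#' Train the segmenter on patch pairs
#'
#' @param patches List of [patch_pair()]s with masks.
#' @param config A [seg_config()].
#' @param model Optionally a pre-built [build_segmenter()] model to
#'   continue training.
#' @return A trained `seg_model` with a per-epoch `log` tibble and the
#'   resolved `class_weights`.
#' @export
train_segmenter <- function(patches, config = seg_config(), model = NULL) {
  if (length(patches) == 0L) stop_arg("no training patches supplied")
  if (any(vapply(patches, function(p) is.null(p$mask), logical(1)))) {
    stop_arg("all training patches need masks")
  }
  weights <- resolve_class_weights(config, patches)
  if (is.null(model)) model <- build_segmenter(config)
  params <- model$params
  local_seed(config$seed + 1L, {
    state <- adam_init(nn_param_tree(params))
    n <- length(patches)
    log <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = config$batch_size)) {
        ids <- ord[start:min(start + config$batch_size - 1L, n)]
        grad_acc <- NULL
        for (id in ids) {
          p <- patches[[id]]
          fwd <- unet_forward(params, p$image)
          lr <- wce_from_logits(fwd$logits, p$mask, weights)
          ep_loss <- ep_loss + lr$loss
          g <- unet_backward(params, fwd$cache, lr$dz)
          gt <- nn_param_tree(g)
          grad_acc <- if (is.null(grad_acc)) gt else
            tree_map2(grad_acc, gt, `+`)
        }
        grad_acc <- tree_map(grad_acc, function(x) x / length(ids))
        grad_acc <- clip_grads(grad_acc, config$grad_clip %||% Inf)
        upd <- adam_step(nn_param_tree(params), grad_acc, state,
                         config$learning_rate)
        params[names(upd$params)] <- upd$params
        state <- upd$state
      }
      log[ep] <- ep_loss / n
    }
    model$params <- params
    model$config <- config
    model$trained <- TRUE
    model$class_weights <- weights
    model$log <- tibble(epoch = seq_len(config$epochs), loss = log)
    model
  })
}

#' Per-pixel foreground probability for one patch image
#'
#' @param model A trained `seg_model`.
#' @param image Square matrix whose side is divisible by `2^(depth-1)`.
#' @return Matrix of foreground probabilities.
#' @export
predict_patch_prob <- function(model, image) {
  if (!isTRUE(model$trained)) stop_state("segmenter has not been trained")
  fwd <- unet_forward(model$params, image)
  softmax2_map(fwd$logits)[, , 2]
}

#' Slice-level decision rule
#'
#' Converts a binarized foreground map into a per-slice CAC call: small
#' connected components (below `min_component_size` pixels) are suppressed
#' as noise, then the slice is called positive when at least
#' `min_foreground_pixels` foreground pixels survive.
#'
#' @param min_foreground_pixels Positive integer.
#' @param apply_component_filter Logical.
#' @param min_component_size Positive integer.
#' @return A `slice_decision_rule` list.
#' @export
slice_decision_rule <- function(min_foreground_pixels = 3L,
                                apply_component_filter = TRUE,
                                min_component_size = 3L) {
  if (!is_count(min_foreground_pixels, 1L)) {
    stop_cfg("min_foreground_pixels must be >= 1")
  }
  if (!is_count(min_component_size, 1L)) {
    stop_cfg("min_component_size must be >= 1")
  }
  structure(
    list(min_foreground_pixels = as.integer(min_foreground_pixels),
         apply_component_filter = isTRUE(apply_component_filter),
         min_component_size = as.integer(min_component_size)),
    class = "slice_decision_rule"
  )
}

filter_components <- function(mask, min_size) {
  if (sum(mask) == 0 || min_size <= 1L) return(mask)
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  lab <- as.matrix(EBImage::imageData(lab))
  sizes <- table(lab[lab > 0])
  drop <- as.integer(names(sizes)[sizes < min_size])
  mask[lab %in% drop] <- 0L
  mask
}

#' Apply the slice decision rule to a binarized mask
#'
#' @param mask 0/1 matrix.
#' @param rule A [slice_decision_rule()].
#' @return List with the filtered `mask`, `foreground_pixels` and the
#'   boolean `call`.
#' @export
apply_decision_rule <- function(mask, rule = slice_decision_rule()) {
  if (rule$apply_component_filter) {
    mask <- filter_components(mask, rule$min_component_size)
  }
  fg <- sum(mask)
  list(mask = mask, foreground_pixels = as.integer(fg),
       call = fg >= rule$min_foreground_pixels)
}

#' Segment slices and make per-slice CAC calls
#'
#' For each slice, patches are extracted per the chosen sampling method
#' (A: random overlapping windows; B: the two fixed central windows),
#' foreground probabilities are predicted per patch, reassembled into a
#' full-slice map, binarized at `model$config$threshold`, filtered by the
#' decision rule, and reduced to a boolean call.  The Method B path is
#' fully deterministic.
#'
#' @param model A trained `seg_model`.
#' @param slices A [slice_stack()], 3-D array, matrix or list of matrices.
#' @param method `"B"` (fixed patches, default) or `"A"` (random patches).
#' @param rule A [slice_decision_rule()].
#' @param patch_size Patch side; defaults to half the slice width rounded
#'   down to the nearest multiple of `2^(depth-1)`.
#' @param n_patches Patches per slice for Method A.
#' @param seed Seed for Method A's random windows.
#' @param slice_index Optional original-stack indices of `slices`.
#' @return A tibble with columns `slice_index`, `cac_call`,
#'   `foreground_pixels`, and list-columns `mask` (filtered 0/1 matrix)
#'   and `prob` (reassembled probability map).
#' @export
predict_mask <- function(model, slices, method = c("B", "A"),
                         rule = slice_decision_rule(),
                         patch_size = NULL, n_patches = 8L, seed = 1L,
                         slice_index = NULL) {
  method <- match.arg(method)
  if (!isTRUE(model$trained)) stop_state("segmenter has not been trained")
  sl <- as_slice_list(slices)
  if (is.null(slice_index)) slice_index <- seq_along(sl)
  div <- 2L^(model$config$depth - 1L)
  if (is.null(patch_size)) {
    patch_size <- max((ncol(sl[[1]]) %/% 2L) %/% div * div, div)
  }
  rows <- lapply(seq_along(sl), function(i) {
    img <- sl[[i]]
    patches <- if (method == "B") {
      extract_fixed_patches(img, size = patch_size)
    } else {
      extract_random_patches(img, size = patch_size, n_patches = n_patches,
                             seed = derive_seed(seed, i))
    }
    preds <- lapply(patches, function(p) {
      list(prob = predict_patch_prob(model, p$image), origin = p$origin)
    })
    prob <- reassemble(preds, dim(img))
    bin <- matrix(as.integer(prob >= model$config$threshold),
                  nrow(prob), ncol(prob))
    dec <- apply_decision_rule(bin, rule)
    tibble(slice_index = slice_index[i], cac_call = dec$call,
           foreground_pixels = dec$foreground_pixels,
           mask = list(dec$mask), prob = list(prob))
  })
  dplyr::bind_rows(rows)
}
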