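#' A co-cropped image/mask patch
#'
#' @param image,mask Equal square matrices (mask 0/1, or NULL when only
#'   the image is needed).
#' @param origin Length-2 integer, 1-based (row, col) of the top-left
#'   corner in the source slice.
#' @param source_slice Optional 1-based source slice index.
#' @return A `patch_pair`.
#' @export
patch_pair <- function(image, mask = NULL, origin = c(1L, 1L),
                       source_slice = NA_integer_) {
  if (!is.null(mask)) {
    if (!identical(dim(image), dim(mask))) {
      stop_arg("image and mask shapes differ")
    }
    if (!all(mask %in% c(0, 1))) stop_arg("mask values must be in {0,1}")
  }
  if (nrow(image) != ncol(image)) stop_arg("patches must be square")
  structure(
    list(image = image, mask = mask, origin = as.integer(origin),
         source_slice = source_slice),
    class = "patch_pair"
  )
}

#' @export
print.patch_pair <- function(x, ...) {
  cat("<patch_pair> ", nrow(x$image), "x", ncol(x$image), " at (",
      x$origin[1], ",", x$origin[2], ")",
      if (!is.null(x$mask)) paste0(", ", sum(x$mask), " fg px"), "\n",
      sep = "")
  invisible(x)
}

crop_patch <- function(image, mask, origin, size, source_slice) {
  rows <- origin[1]:(origin[1] + size - 1L)
  cols <- origin[2]:(origin[2] + size - 1L)
  patch_pair(image[rows, cols],
             if (!is.null(mask)) mask[rows, cols],
             origin = origin, source_slice = source_slice)
}

#' Extract random overlapping patches (multi-patch sampling)
#'
#' Patch origins are drawn uniformly over all positions that keep the
#' window fully inside the image; overlap is allowed.  Deterministic for a
#' fixed seed.
#'
#' @param image Source slice matrix.
#' @param mask Aligned 0/1 mask matrix, or NULL.
#' @param size Patch side length (192 at clinical scale).
#' @param n_patches Number of patches to draw.
#' @param seed Integer seed.
#' @param source_slice Optional source slice index recorded on each patch.
#' @return List of [patch_pair()]s.
#' @export
extract_random_patches <- function(image, mask = NULL, size = 192L,
                                   n_patches = 8L, seed = 1L,
                                   source_slice = NA_integer_) {
  size <- as.integer(size)
  if (size > min(dim(image))) {
    stop_arg("patch size ", size, " exceeds image dimensions ",
             nrow(image), "x", ncol(image))
  }
  if (!is_count(n_patches, 1L)) stop_arg("n_patches must be >= 1")
  local_seed(seed, {
    r <- sample.int(nrow(image) - size + 1L, n_patches, replace = TRUE)
    cl <- sample.int(ncol(image) - size + 1L, n_patches, replace = TRUE)
    lapply(seq_len(n_patches), function(i) {
      crop_patch(image, mask, c(r[i], cl[i]), size, source_slice)
    })
  })
}

#' Extract the two fixed central patches (2-patch sampling)
#'
#' Two windows symmetric about the vertical midline and vertically
#' centered: the left window's right edge sits at the midline and the
#' right window's left edge starts just past it (windows are clipped
#' inward, and may overlap, when the image is narrower than two windows).
#' This is a pure function: identical inputs give identical patches.
#'
#' @param image Source slice matrix.
#' @param mask Aligned 0/1 mask, or NULL.
#' @param size Window side length (224 at clinical scale).
#' @param source_slice Optional source slice index.
#' @return List of two [patch_pair()]s (left, right).
#' @export
#' @examples
#' img <- matrix(0, 96, 96)
#' p <- extract_fixed_patches(img, size = 48)
#' vapply(p, function(x) x$origin, integer(2))
extract_fixed_patches <- function(image, mask = NULL, size = 224L,
                                  source_slice = NA_integer_) {
  size <- as.integer(size)
  h <- nrow(image)
  w <- ncol(image)
  if (size > h || size > w) {
    stop_arg("patch size ", size, " exceeds image dimensions ", h, "x", w)
  }
  row0 <- (h - size) %/% 2L + 1L
  mid <- w %/% 2L
  left_col <- max(mid - size + 1L, 1L)
  right_col <- min(mid + 1L, w - size + 1L)
  list(
    crop_patch(image, mask, c(row0, left_col), size, source_slice),
    crop_patch(image, mask, c(row0, right_col), size, source_slice)
  )
}

#' Augmentation specification
#'
#' Families follow standard radiographic augmentation practice: random
#' rotation, skew (horizontal shear), isotropic scaling, brightness shift,
#' and horizontal flips.  Geometric transforms are applied identically to
#' image and mask; brightness touches the image only.
#'
#' @param rotation_deg_range,skew_deg_range Length-2 numeric, degrees.
#' @param scale_range Length-2 positive numeric, isotropic scale factors.
#' @param brightness_range Length-2 numeric, additive intensity shift on
#'   the [0,1] scale.
#' @param allow_flips Allow horizontal (left-right) flips.
#' @param n_variants Number of variants [augment_variants()] generates.
#' @param seed Integer seed from which per-variant seeds are derived.
#' @return An `augmentation_spec` list.
#' @export
augmentation_spec <- function(rotation_deg_range = c(-15, 15),
                              skew_deg_range = c(-8, 8),
                              scale_range = c(0.9, 1.1),
                              brightness_range = c(-0.1, 0.1),
                              allow_flips = TRUE,
                              n_variants = 1L,
                              seed = 1L) {
  if (any(scale_range <= 0)) stop_cfg("scale_range must be positive")
  if (!is_count(n_variants, 1L)) stop_cfg("n_variants must be >= 1")
  rng_ok <- function(r) length(r) == 2L && r[1] <= r[2]
  if (!rng_ok(rotation_deg_range) || !rng_ok(skew_deg_range) ||
      !rng_ok(scale_range) || !rng_ok(brightness_range)) {
    stop_cfg("all ranges must be increasing length-2 numerics")
  }
  structure(
    list(rotation_deg_range = rotation_deg_range,
         skew_deg_range = skew_deg_range,
         scale_range = scale_range,
         brightness_range = brightness_range,
         allow_flips = isTRUE(allow_flips),
         n_variants = as.integer(n_variants),
         seed = as.integer(seed)),
    class = "augmentation_spec"
  )
}

is_identity_spec <- function(spec) {
  all(spec$rotation_deg_range == 0) && all(spec$skew_deg_range == 0) &&
    all(spec$scale_range == 1) && all(spec$brightness_range == 0) &&
    !spec$allow_flips
}

# Draw one set of transform parameters from the spec.
draw_aug_params <- function(spec) {
  list(
    rotation = runif(1, spec$rotation_deg_range[1], spec$rotation_deg_range[2]),
    skew = runif(1, spec$skew_deg_range[1], spec$skew_deg_range[2]),
    scale = runif(1, spec$scale_range[1], spec$scale_range[2]),
    brightness = runif(1, spec$brightness_range[1], spec$brightness_range[2]),
    flip = spec$allow_flips && runif(1) < 0.5
  )
}

# Linear part of the geometric transform (rotation o shear o scale) acting
# on (row, col) offsets from the patch center.
aug_matrix <- function(params) {
  th <- params$rotation * pi / 180
  sh <- tan(params$skew * pi / 180)
  rot <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  shear <- matrix(c(1, sh, 0, 1), 2, 2, byrow = TRUE)
  rot %*% shear * params$scale
}

# Warp with EBImage: the 3x2 matrix rbind(t(M), c - c %*% t(M)) realizes
# the point map p_out = M (p_in - c) + c on 1-based array indices.
affine_warp <- function(img, M, filter) {
  d <- dim(img)
  ctr <- (d + 1) / 2
  m <- rbind(t(M), as.numeric(ctr - ctr %*% t(M)))
  out <- EBImage::affine(EBImage::Image(img), m, filter = filter,
                         output.dim = d, bg.col = 0)
  matrix(EBImage::imageData(out), d[1], d[2])
}

#' Map patch coordinates through an augmentation's geometric transform
#'
#' Used to verify image/mask alignment: the transformed foreground
#' centroid of a mask must match the transform of the original centroid.
#'
#' @param points n x 2 matrix of (row, col) coordinates.
#' @param params A parameter draw, as stored in an augmented patch's
#'   `aug_params` attribute.
#' @param dims Patch dimensions.
#' @return n x 2 matrix of transformed coordinates.
#' @export
transform_points <- function(points, params, dims) {
  points <- matrix(points, ncol = 2)
  if (isTRUE(params$flip)) {
    points[, 2] <- dims[2] + 1 - points[, 2]
  }
  M <- aug_matrix(params)
  ctr <- (dims + 1) / 2
  sweep(sweep(points, 2, ctr) %*% t(M), 2, ctr, "+")
}

#' Augment one patch pair
#'
#' Flips, rotation, skew and scaling are applied jointly to image and mask
#' (bilinear interpolation for the image, nearest-neighbour for the mask,
#' which therefore stays binary); the brightness shift is applied to the
#' image only.  An all-zero spec with flips disabled returns the input
#' unchanged, bit for bit.
#'
#' @param pair A [patch_pair()].
#' @param spec An [augmentation_spec()].
#' @param variant_seed Seed for this variant's parameter draw.
#' @return A [patch_pair()] with an `aug_params` attribute recording the
#'   transform actually applied.
#' @export
augment <- function(pair, spec = augmentation_spec(), variant_seed = 1L) {
  if (is_identity_spec(spec)) return(pair)
  params <- local_seed(variant_seed, draw_aug_params(spec))
  img <- pair$image
  msk <- pair$mask
  if (params$flip) {
    img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
    if (!is.null(msk)) msk <- msk[, rev(seq_len(ncol(msk))), drop = FALSE]
  }
  M <- aug_matrix(params)
  img <- affine_warp(img, M, filter = "bilinear")
  img <- clip01(img + params$brightness)
  if (!is.null(msk)) {
    msk <- affine_warp(msk, M, filter = "none")
    msk <- matrix(as.integer(msk > 0.5), nrow(msk), ncol(msk))
  }
  out <- patch_pair(img, msk, origin = pair$origin,
                    source_slice = pair$source_slice)
  attr(out, "aug_params") <- params
  out
}

#' Generate many augmentation variants of one patch
#'
#' Per-variant seeds are derived from `spec$seed`, so the full set is
#' reproducible; with the default continuous parameter ranges the variants
#' are almost surely pairwise distinct, supporting the several-thousandfold
#' expansion of scarce annotated slices used when training the segmenter.
#'
#' @param pair A [patch_pair()].
#' @param spec An [augmentation_spec()]; `spec$n_variants` sets the count.
#' @return List of augmented [patch_pair()]s.
#' @export
augment_variants <- function(pair, spec) {
  lapply(seq_len(spec$n_variants), function(i) {
    augment(pair, spec, variant_seed = derive_seed(spec$seed, i))
  })
}

#' Reassemble patch probability maps into a full-slice map
#'
#' Pixels covered by several patches receive the mean of the covering
#' probabilities; uncovered pixels get probability 0.
#'
#' @param predictions List of `list(prob = matrix, origin = c(row, col))`
#'   entries (1-based origins).
#' @param slice_shape Length-2 integer, the output (rows, cols).
#' @return Probability matrix of dimension `slice_shape`.
#' @export
reassemble <- function(predictions, slice_shape) {
  acc <- matrix(0, slice_shape[1], slice_shape[2])
  cnt <- matrix(0, slice_shape[1], slice_shape[2])
  for (p in predictions) {
    d <- dim(p$prob)
    o <- p$origin
    if (o[1] < 1 || o[2] < 1 || o[1] + d[1] - 1 > slice_shape[1] ||
        o[2] + d[2] - 1 > slice_shape[2]) {
      stop_arg("patch window at (", o[1], ",", o[2], ") of size ",
               d[1], "x", d[2], " falls outside the slice")
    }
    rows <- o[1]:(o[1] + d[1] - 1L)
    cols <- o[2]:(o[2] + d[2] - 1L)
    acc[rows, cols] <- acc[rows, cols] + p$prob
    cnt[rows, cols] <- cnt[rows, cols] + 1
  }
  out <- acc
  covered <- cnt > 0
  out[covered] <- acc[covered] / cnt[covered]
  out
}
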