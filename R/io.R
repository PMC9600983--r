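#' Ordered stack of axial slices
#'
#' The unit the pipeline consumes: an ordered sequence of equally shaped
#' 2-D grayscale intensity grids, superior slice first.
#'
#' @param slices H x W x n numeric array, or a list of equally shaped
#'   matrices, intensities in [0,1].
#' @param scan_id Identifier string.
#' @param voxel_size_mm Optional isotropic voxel size in millimetres.
#' @return A `slice_stack` object.
#' @export
slice_stack <- function(slices, scan_id = "scan", voxel_size_mm = NULL) {
  if (is.list(slices)) {
    dims <- unique(lapply(slices, dim))
    if (length(dims) != 1L) {
      stop_fmt("all slices must share the same height and width")
    }
    slices <- array(unlist(slices), dim = c(dims[[1]], length(slices)))
  }
  if (!is.array(slices) || length(dim(slices)) != 3L) {
    stop_fmt("slices must be an H x W x n array or list of matrices")
  }
  if (!is.null(voxel_size_mm) && voxel_size_mm <= 0) {
    stop_arg("voxel_size_mm must be positive")
  }
  structure(
    list(slices = slices, scan_id = scan_id, voxel_size_mm = voxel_size_mm),
    class = "slice_stack"
  )
}

#' @export
print.slice_stack <- function(x, ...) {
  d <- dim(x$slices)
  cat("<slice_stack> ", x$scan_id, ": ", d[3], " slices of ", d[1], "x",
      d[2], "\n", sep = "")
  invisible(x)
}

#' Number of slices in a stack
#' @param stack A `slice_stack`.
#' @return Integer.
#' @export
n_slices <- function(stack) dim(stack$slices)[3]

#' Extract one slice as a matrix
#' @param stack A `slice_stack`.
#' @param i 1-based slice index.
#' @return H x W numeric matrix.
#' @export
get_slice <- function(stack, i) stack$slices[, , i]

read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_fmt("unsupported image format '.", ext, "' for '", path, "'")
  )
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
  img
}

#' Read a directory of slice images into a stack
#'
#' Slices are PNG or TIFF files whose names contain a numeric index
#' (e.g. `slice_0001.png`); they are sorted by that index, not by raw
#' filename, so zero-padding is not required.  RGB images are converted to
#' grayscale by channel averaging.  DICOM series are not supported by this
#' build; export the series to PNG/TIFF first.
#'
#' @param path Directory containing the slice images.
#' @param pattern Regular expression selecting slice files.
#' @param normalize `"none"` keeps the stored 8/16-bit values mapped to
#'   [0,1]; `"minmax"` rescales the whole scan to span [0,1] exactly.
#' @param scan_id Identifier; defaults to the directory name.
#' @return A [slice_stack()].
#' @export
read_image_stack <- function(path, pattern = "^slice_.*\\.(png|tiff?)$",
                             normalize = c("none", "minmax"),
                             scan_id = basename(path)) {
  normalize <- match.arg(normalize)
  if (!dir.exists(path)) {
    if (grepl("\\.dcm$", path, ignore.case = TRUE)) {
      stop_fmt("DICOM series are not supported; export to PNG/TIFF slices")
    }
    abort(paste0("no such directory: '", path, "'"),
          class = "cacseg_not_found_error")
  }
  files <- list.files(path, pattern = pattern, full.names = TRUE)
  if (length(files) == 0L) {
    abort(paste0("no slice images matching '", pattern, "' in '", path, "'"),
          class = "cacseg_not_found_error")
  }
  idx <- as.integer(sub(".*?(\\d+)\\.[A-Za-z]+$", "\\1", basename(files)))
  if (anyNA(idx)) stop_fmt("slice filenames must contain a numeric index")
  files <- files[order(idx)]
  imgs <- lapply(files, read_gray_image)
  dims <- unique(lapply(imgs, dim))
  if (length(dims) != 1L) {
    stop_fmt("mixed slice shapes in '", path, "': ",
             paste(vapply(dims, paste, "", collapse = "x"), collapse = ", "))
  }
  arr <- array(unlist(imgs), dim = c(dims[[1]], length(imgs)))
  if (normalize == "minmax") {
    rng <- range(arr)
    if (diff(rng) > 0) arr <- (arr - rng[1]) / diff(rng)
  }
  slice_stack(arr, scan_id = scan_id)
}

#' Write a stack as a directory of PNG slices
#'
#' @param stack A [slice_stack()].
#' @param path Output directory (created if needed).
#' @param prefix Filename prefix; files are `<prefix>_0001.png`, ...
#' @return Invisibly, the written file paths.
#' @export
write_stack <- function(stack, path, prefix = "slice") {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  n <- n_slices(stack)
  files <- character(n)
  for (i in seq_len(n)) {
    files[i] <- file.path(path, sprintf("%s_%04d.png", prefix, i))
    png::writePNG(clip01(get_slice(stack, i)), files[i])
  }
  invisible(files)
}

#' Thresholding rule that identifies annotation strokes as "red"
#'
#' Radiologist overlays mark calcifications with red strokes; a pixel is
#' accepted as annotation when its 8-bit channels satisfy
#' `R >= r_min & G <= g_max & B <= b_max`.  Thresholds (rather than exact
#' equality) tolerate anti-aliased stroke edges.
#'
#' @param r_min,g_max,b_max Channel thresholds on the 0-255 scale.
#' @return A `red_rule` list.
#' @export
red_rule <- function(r_min = 200, g_max = 80, b_max = 80) {
  structure(list(r_min = r_min, g_max = g_max, b_max = b_max),
            class = "red_rule")
}

#' Convert a red-overlay annotation image to a binary mask
#'
#' @param annotated_rgb H x W x 3 numeric array, values in [0,1] or 0-255.
#' @param rule A [red_rule()].
#' @return H x W integer matrix with values in \{0,1\}.
#' @export
#' @examples
#' img <- array(0, c(4, 4, 3))
#' img[2, 3, ] <- c(1, 0, 0)
#' annotation_to_mask(img)
annotation_to_mask <- function(annotated_rgb, rule = red_rule()) {
  if (!is.array(annotated_rgb) || length(dim(annotated_rgb)) != 3L ||
      dim(annotated_rgb)[3] < 3L) {
    stop_fmt("annotation image must be an H x W x 3 RGB array")
  }
  x <- annotated_rgb
  if (max(x) <= 1) x <- x * 255
  sel <- x[, , 1] >= rule$r_min & x[, , 2] <= rule$g_max &
    x[, , 3] <= rule$b_max
  mask <- matrix(0L, dim(x)[1], dim(x)[2])
  mask[sel] <- 1L
  mask
}

#' Write / read a binary mask as PNG
#'
#' Masks are serialized with foreground = 255, background = 0; the round
#' trip is lossless.
#'
#' @param mask H x W matrix with values in \{0,1\}.
#' @param path PNG file path.
#' @return `read_mask()` returns the 0/1 integer matrix; `write_mask()`
#'   returns `path` invisibly.
#' @export
write_mask <- function(mask, path) {
  if (!all(mask %in% c(0, 1))) stop_fmt("mask values must be exactly {0,1}")
  ok <- tryCatch({
    png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    abort(paste0("cannot write mask to '", path, "': ",
                 conditionMessage(ok)), class = "cacseg_io_error")
  }
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- read_gray_image(path)
  mask <- matrix(0L, nrow(img), ncol(img))
  mask[img > 0.5] <- 1L
  mask
}

#' Write a phantom scan as slices + masks + JSON sidecar
#'
#' Produces `slice_0001.png`..., parallel `mask_0001.png`..., and a
#' `scan.json` sidecar recording `scan_id`, `boundary_index` and
#' `n_slices`.
#'
#' @param scan A `phantom_scan`.
#' @param path Output directory.
#' @param seed Optional seed to record in the sidecar.
#' @return Invisibly, `path`.
#' @export
write_scan <- function(scan, path, seed = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_stack(scan$stack, path, prefix = "slice")
  n <- dim(scan$masks)[3]
  for (i in seq_len(n)) {
    write_mask(scan$masks[, , i],
               file.path(path, sprintf("mask_%04d.png", i)))
  }
  side <- list(scan_id = scan$scan_id,
               boundary_index = scan$boundary_index,
               n_slices = n)
  if (!is.null(seed)) side$seed <- seed
  jsonlite::write_json(side, file.path(path, "scan.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a phantom scan directory written by [write_scan()]
#'
#' @param path Directory containing slices, masks and `scan.json`.
#' @return A `phantom_scan`.
#' @export
read_scan <- function(path) {
  stack <- read_image_stack(path, scan_id = basename(path))
  side <- jsonlite::read_json(file.path(path, "scan.json"),
                              simplifyVector = TRUE)
  mask_files <- list.files(path, pattern = "^mask_.*\\.png$",
                           full.names = TRUE)
  masks <- NULL
  if (length(mask_files) > 0) {
    idx <- as.integer(sub(".*?(\\d+)\\.png$", "\\1", basename(mask_files)))
    mask_files <- mask_files[order(idx)]
    ml <- lapply(mask_files, read_mask)
    masks <- array(unlist(ml), dim = c(dim(ml[[1]]), length(ml)))
  }
  stack$scan_id <- side$scan_id
  structure(
    list(stack = stack, masks = masks,
         boundary_index = as.integer(side$boundary_index),
         scan_id = side$scan_id),
    class = "phantom_scan"
  )
}
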