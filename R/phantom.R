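#' Configuration for the synthetic CBCT phantom generator
#'
#' The phantom emulates the features of a cervical CBCT stack that the
#' two-stage pipeline depends on: a stack of axial slices with degraded
#' cone-beam artifact slices at both ends, an anatomical boundary index
#' splitting the stack into an "above" and a "below" regime with visibly
#' different simulated vertebral cross-sections, and rare small
#' hyperintense calcification blobs seeded only below the boundary, inside
#' two lateral carotid-space regions.  Foreground prevalence stays well
#' under 1 percent of all pixels, reproducing the extreme class imbalance
#' that motivates the weighted segmentation loss.
#'
#' @param n_slices Number of axial slices per scan.
#' @param slice_size Pixels per side of each (square) slice.  The default
#'   96 is a desk-scale stand-in for clinical 536x536 slices.
#' @param artifact_margin Number of degraded cone-beam artifact slices at
#'   each end of the stack (default 7, the typical trim for this scanner
#'   class).
#' @param boundary_fraction_range Length-2 numeric in (0,1): the boundary
#'   index is drawn uniformly from this fraction of the stack depth,
#'   clipped to lie strictly inside the non-artifact region.
#' @param lesion_prob Probability that any given below-boundary,
#'   non-artifact slice carries a calcification.
#' @param lesion_radius_range Length-2 numeric, lesion radius bounds in
#'   pixels.
#' @param lesion_intensity Maximum peak additive intensity of a lesion
#'   above the local background, on the [0,1] intensity scale.  Each
#'   lesion draws its peak uniformly from 30-100 percent of this value,
#'   emulating the wide conspicuity range of real calcifications (faint
#'   deposits sit barely above the noise floor), and intensity falls off
#'   quadratically toward the rim (partial-volume softening), so rim
#'   pixels carry the foreground label while looking like background.
#' @param confounder_prob Probability that a below-boundary slice carries
#'   a calcified-cartilage-like bright structure at a medial location,
#'   outside the carotid regions.  Confounders look like lesions but are
#'   background in the mask, so appearance alone cannot separate the
#'   classes; location context is required (and false positives arise
#'   when it is ignored).
#' @param noise_sd Standard deviation of the additive Gaussian intensity
#'   noise.
#' @param seed Integer master seed; per-scan seeds are derived from it.
#' @return A `phantom_config` list.
#' @export
#' @examples
#' cfg <- phantom_config(n_slices = 32, slice_size = 48, artifact_margin = 3)
#' scan <- generate_phantom_scan(cfg, scan_seed = 1)
phantom_config <- function(n_slices = 64L,
                           slice_size = 96L,
                           artifact_margin = 7L,
                           boundary_fraction_range = c(0.35, 0.65),
                           lesion_prob = 0.5,
                           lesion_radius_range = c(1, 4),
                           lesion_intensity = 0.35,
                           confounder_prob = 0.3,
                           noise_sd = 0.05,
                           seed = 1L) {
  cfg <- list(
    n_slices = as.integer(n_slices),
    slice_size = as.integer(slice_size),
    artifact_margin = as.integer(artifact_margin),
    boundary_fraction_range = as.numeric(boundary_fraction_range),
    lesion_prob = as.numeric(lesion_prob),
    lesion_radius_range = as.numeric(lesion_radius_range),
    lesion_intensity = as.numeric(lesion_intensity),
    confounder_prob = as.numeric(confounder_prob),
    noise_sd = as.numeric(noise_sd),
    seed = as.integer(seed)
  )
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  if (!is_count(cfg$n_slices, 1L)) {
    stop_cfg("n_slices must be a positive integer")
  }
  if (!is_count(cfg$slice_size, 8L)) {
    stop_cfg("slice_size must be an integer >= 8")
  }
  if (!is_count(cfg$artifact_margin, 0L)) {
    stop_cfg("artifact_margin must be a non-negative integer")
  }
  if (2L * cfg$artifact_margin >= cfg$n_slices) {
    stop_cfg("invariant violated: artifact_margin * 2 < n_slices (got ",
             cfg$artifact_margin, " * 2 >= ", cfg$n_slices, ")")
  }
  r <- cfg$boundary_fraction_range
  if (length(r) != 2L || any(r <= 0) || any(r >= 1) || r[1] > r[2]) {
    stop_cfg("boundary_fraction_range must be an increasing pair in (0,1)")
  }
  if (cfg$lesion_prob < 0 || cfg$lesion_prob > 1) {
    stop_cfg("lesion_prob must lie in [0,1]")
  }
  lr <- cfg$lesion_radius_range
  if (length(lr) != 2L || any(lr <= 0) || lr[1] > lr[2]) {
    stop_cfg("lesion_radius_range must be an increasing pair of positive radii")
  }
  if (lr[2] > cfg$slice_size / 8) {
    stop_cfg("lesion radius too large for slice_size (must be <= slice_size/8)")
  }
  if (cfg$lesion_intensity <= 0) stop_cfg("lesion_intensity must be positive")
  if (cfg$confounder_prob < 0 || cfg$confounder_prob > 1) {
    stop_cfg("confounder_prob must lie in [0,1]")
  }
  if (cfg$noise_sd < 0) stop_cfg("noise_sd must be non-negative")
  # boundary must be drawable strictly inside the non-artifact region
  lo <- max(ceiling(cfg$boundary_fraction_range[1] * cfg$n_slices),
            cfg$artifact_margin + 2L)
  hi <- min(floor(cfg$boundary_fraction_range[2] * cfg$n_slices),
            cfg$n_slices - cfg$artifact_margin)
  if (lo > hi) {
    stop_cfg("boundary_fraction_range does not intersect the non-artifact ",
             "slice range [", cfg$artifact_margin + 2L, ", ",
             cfg$n_slices - cfg$artifact_margin, "]")
  }
  invisible(cfg)
}

# Geometry of the phantom, all relative to slice_size.  The two lateral
# discs stand in for the left/right carotid spaces; the central ellipse for
# the vertebral body, whose cross-section changes at the boundary.
phantom_geometry <- function(s) {
  list(
    head_center = c(0.50, 0.50) * s, head_radius = 0.46 * s,
    vert_center = c(0.62, 0.50) * s,
    vert_axes_above = c(0.21, 0.11) * s,   # wide, flat (C2 body + dens)
    vert_axes_below = c(0.12, 0.15) * s,   # rounder (C3/C4 body)
    airway_center = c(0.38, 0.50) * s, airway_radius = 0.07 * s,
    lesion_centers = list(c(0.45, 0.22) * s, c(0.45, 0.78) * s),
    lesion_region_radius = 0.09 * s,
    confounder_centers = list(c(0.48, 0.38) * s, c(0.48, 0.62) * s),
    confounder_region_radius = 0.05 * s
  )
}

#' Region where phantom lesions may be seeded
#'
#' Returns a logical matrix marking the two lateral carotid-space discs in
#' which `generate_phantom_scan()` places calcifications.
#'
#' @param slice_size Pixels per side.
#' @return Logical `slice_size` x `slice_size` matrix.
#' @export
phantom_lesion_region <- function(slice_size) {
  g <- phantom_geometry(slice_size)
  rr <- row(matrix(0, slice_size, slice_size))
  cc <- col(matrix(0, slice_size, slice_size))
  inside <- matrix(FALSE, slice_size, slice_size)
  for (ctr in g$lesion_centers) {
    inside <- inside |
      ((rr - ctr[1])^2 + (cc - ctr[2])^2 <= g$lesion_region_radius^2)
  }
  inside
}

render_anatomy <- function(s, below) {
  g <- phantom_geometry(s)
  rr <- row(matrix(0, s, s))
  cc <- col(matrix(0, s, s))
  img <- matrix(0.05, s, s)                                   # air
  head <- (rr - g$head_center[1])^2 + (cc - g$head_center[2])^2 <=
    g$head_radius^2
  img[head] <- 0.30                                           # soft tissue
  ax <- if (below) g$vert_axes_below else g$vert_axes_above
  vert <- ((rr - g$vert_center[1]) / ax[1])^2 +
    ((cc - g$vert_center[2]) / ax[2])^2 <= 1
  img[vert] <- if (below) 0.75 else 0.70                      # bone
  air <- (rr - g$airway_center[1])^2 + (cc - g$airway_center[2])^2 <=
    g$airway_radius^2
  img[air] <- 0.02                                            # airway
  img
}

# Bright blob with quadratic falloff to zero at the rim (partial-volume
# softening): the mask covers the whole disc, but rim pixels are barely
# brighter than background.
draw_blob <- function(img, center, radius, intensity) {
  rr <- row(img)
  cc <- col(img)
  d2 <- (rr - center[1])^2 + (cc - center[2])^2
  disc <- d2 <= radius^2
  img[disc] <- clip01(img[disc] + intensity * (1 - d2[disc] / radius^2))
  list(img = img, disc = disc)
}

draw_lesion <- function(img, mask, center, radius, intensity) {
  b <- draw_blob(img, center, radius, intensity)
  mask[b$disc] <- 1L
  list(img = b$img, mask = mask)
}

#' Generate one synthetic phantom scan
#'
#' Deterministic for a fixed `(config, scan_seed)` pair.  Artifact-margin
#' slices are rendered as high-noise, low-signal frames; remaining slices
#' show the above- or below-boundary anatomy; below-boundary non-artifact
#' slices carry a lesion with probability `config$lesion_prob`, drawn in
#' one of the two lateral carotid-space regions.
#'
#' @param config A [phantom_config()].
#' @param scan_seed Integer seed for this scan.
#' @param scan_id Scan identifier string.
#' @return A `phantom_scan`: list with `stack` (a `slice_stack`), `masks`
#'   (H x W x n_slices 0/1 array), `boundary_index` (1-based index of the
#'   first below-boundary slice) and `scan_id`.
#' @export
generate_phantom_scan <- function(config, scan_seed,
                                  scan_id = sprintf("phantom_%06d",
                                                    as.integer(scan_seed) %%
                                                      1000000L)) {
  validate_phantom_config(config)
  s <- config$slice_size
  n <- config$n_slices
  m <- config$artifact_margin
  g <- phantom_geometry(s)
  local_seed(scan_seed, {
    lo <- max(ceiling(config$boundary_fraction_range[1] * n), m + 2L)
    hi <- min(floor(config$boundary_fraction_range[2] * n), n - m)
    boundary <- if (lo == hi) lo else sample(lo:hi, 1L)
    slices <- array(0, dim = c(s, s, n))
    masks <- array(0L, dim = c(s, s, n))
    for (i in seq_len(n)) {
      artifact <- i <= m || i > n - m
      if (artifact) {
        img <- clip01(matrix(0.5 + rnorm(s * s, sd = 0.25), s, s))
      } else {
        below <- i >= boundary
        img <- render_anatomy(s, below)
        mask <- matrix(0L, s, s)
        if (below && runif(1) < config$lesion_prob) {
          side <- sample(1:2, 1L)
          ctr0 <- g$lesion_centers[[side]]
          radius <- runif(1, config$lesion_radius_range[1],
                          config$lesion_radius_range[2])
          max_off <- max(g$lesion_region_radius - radius, 0)
          ang <- runif(1, 0, 2 * pi)
          off <- runif(1, 0, max_off)
          ctr <- ctr0 + off * c(cos(ang), sin(ang))
          peak <- config$lesion_intensity * runif(1, 0.3, 1)
          res <- draw_lesion(img, mask, ctr, radius, peak)
          img <- res$img
          mask <- res$mask
        }
        if (below && runif(1) < config$confounder_prob) {
          # calcified-cartilage look-alike: same appearance, medial
          # location, background label
          side <- sample(1:2, 1L)
          ctr0 <- g$confounder_centers[[side]]
          radius <- runif(1, config$lesion_radius_range[1],
                          config$lesion_radius_range[2])
          ang <- runif(1, 0, 2 * pi)
          off <- runif(1, 0, max(g$confounder_region_radius - radius, 0))
          ctr <- ctr0 + off * c(cos(ang), sin(ang))
          img <- draw_blob(img, ctr, radius,
                           config$lesion_intensity * runif(1, 0.3, 1))$img
        }
        masks[, , i] <- mask
        img <- clip01(img + matrix(rnorm(s * s, sd = config$noise_sd), s, s))
      }
      slices[, , i] <- img
    }
    structure(
      list(
        stack = slice_stack(slices, scan_id = scan_id),
        masks = masks,
        boundary_index = as.integer(boundary),
        scan_id = scan_id
      ),
      class = "phantom_scan"
    )
  })
}

#' @export
print.phantom_scan <- function(x, ...) {
  d <- dim(x$masks)
  cat("<phantom_scan> ", x$scan_id, ": ", d[3], " slices of ", d[1], "x",
      d[2], ", boundary at slice ", x$boundary_index, ", ",
      sum(x$masks), " foreground px\n", sep = "")
  invisible(x)
}

#' Generate a dataset of phantom scans
#'
#' A fixed fraction of the scans (default one half, mirroring a balanced
#' case/control design) contains at least one calcification; the rest are
#' lesion-free.  Per-scan seeds are derived deterministically from
#' `config$seed`, so the whole dataset is reproducible.
#'
#' @param n_scans Number of scans.
#' @param config A [phantom_config()].
#' @param positive_fraction Fraction of scans that must contain lesions.
#' @return List of `phantom_scan` objects (class `phantom_dataset`).
#' @export
generate_dataset <- function(n_scans, config, positive_fraction = 0.5) {
  validate_phantom_config(config)
  if (!is_count(n_scans, 1L)) stop_cfg("n_scans must be a positive integer")
  if (positive_fraction < 0 || positive_fraction > 1) {
    stop_cfg("positive_fraction must lie in [0,1]")
  }
  n_pos <- as.integer(round(n_scans * positive_fraction))
  if (positive_fraction > 0 && positive_fraction < 1) {
    if (n_scans < 2L) {
      stop_cfg("n_scans must be >= 2 for a mixed positive_fraction")
    }
    if (n_pos == 0L || n_pos == n_scans) {
      stop_cfg("positive_fraction ", positive_fraction, " with ", n_scans,
               " scans rounds to an all-", if (n_pos == 0L) "negative"
               else "positive", " dataset; choose a compatible combination")
    }
  }
  if (positive_fraction > 0 && config$lesion_prob <= 0) {
    stop_cfg("positive scans requested but config$lesion_prob is 0")
  }
  neg_cfg <- config
  neg_cfg$lesion_prob <- 0
  # spread positives evenly so contiguous train/test splits stay balanced
  pos_ids <- if (n_pos > 0) unique(round(seq(1, n_scans, length.out = n_pos)))
             else integer(0)
  scans <- vector("list", n_scans)
  for (i in seq_len(n_scans)) {
    positive <- i %in% pos_ids
    cfg_i <- if (positive) config else neg_cfg
    attempt <- 0L
    repeat {
      seed_i <- derive_seed(config$seed, i, salt = attempt)
      sc <- generate_phantom_scan(cfg_i, seed_i,
                                  scan_id = sprintf("scan_%03d", i))
      if (!positive || sum(sc$masks) > 0) break
      attempt <- attempt + 1L     # redraw until the scan truly is positive
      if (attempt > 100L) {
        stop_cfg("could not realize a positive scan; lesion_prob too small")
      }
    }
    attr(sc, "positive") <- positive
    scans[[i]] <- sc
  }
  structure(scans, class = "phantom_dataset")
}
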