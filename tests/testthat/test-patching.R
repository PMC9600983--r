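test_that("random patches stay inside the image and are seed-deterministic", {
  img <- matrix(runif(536 * 536), 536, 536)
  ps <- extract_random_patches(img, size = 192, n_patches = 10, seed = 4)
  expect_length(ps, 10)
  for (p in ps) {
    expect_true(all(p$origin >= 1 & p$origin <= 536 - 192 + 1))
    expect_equal(dim(p$image), c(192, 192))
  }
  ps2 <- extract_random_patches(img, size = 192, n_patches = 10, seed = 4)
  expect_identical(lapply(ps, `[[`, "origin"), lapply(ps2, `[[`, "origin"))

  whole <- extract_random_patches(img, size = 536, n_patches = 3, seed = 1)
  expect_true(all(vapply(whole, function(p) all(p$origin == c(1, 1)),
                         logical(1))))
  expect_error(extract_random_patches(img, size = 600, n_patches = 1),
               class = "cacseg_argument_error")
})

test_that("fixed central windows sit symmetric about the vertical midline", {
  img536 <- matrix(0, 536, 536)
  p <- extract_fixed_patches(img536, size = 224)
  expect_equal(p[[1]]$origin, c(157L, 45L))    # (156, 44) zero-based
  expect_equal(p[[2]]$origin, c(157L, 269L))   # (156, 268) zero-based

  img224 <- matrix(0, 224, 224)
  q <- extract_fixed_patches(img224, size = 224)
  expect_equal(q[[1]]$origin, c(1L, 1L))
  expect_equal(q[[2]]$origin, c(1L, 1L))

  # pure function: repeated calls identical
  img <- matrix(runif(96 * 96), 96, 96)
  a <- extract_fixed_patches(img, size = 48)
  b <- extract_fixed_patches(img, size = 48)
  expect_identical(a, b)
  expect_equal(a[[1]]$origin, c(25L, 1L))
  expect_equal(a[[2]]$origin, c(25L, 49L))
  expect_error(extract_fixed_patches(matrix(0, 40, 40), size = 48),
               class = "cacseg_argument_error")
})

test_that("identity augmentation returns the input unchanged", {
  pr <- patch_pair(matrix(runif(64), 8, 8), random_mask(8, seed = 2))
  spec <- augmentation_spec(rotation_deg_range = c(0, 0),
                            skew_deg_range = c(0, 0),
                            scale_range = c(1, 1),
                            brightness_range = c(0, 0),
                            allow_flips = FALSE)
  expect_identical(augment(pr, spec, variant_seed = 5), pr)
})

test_that("horizontal flips mirror mask pixels across the vertical midline", {
  msk <- matrix(0L, 9, 9)
  msk[3, 2] <- 1L
  pr <- patch_pair(matrix(runif(81), 9, 9), msk)
  spec <- augmentation_spec(rotation_deg_range = c(0, 0),
                            skew_deg_range = c(0, 0),
                            scale_range = c(1, 1),
                            brightness_range = c(0, 0),
                            allow_flips = TRUE)
  seen_flip <- FALSE
  for (s in 1:20) {
    out <- augment(pr, spec, variant_seed = s)
    if (isTRUE(attr(out, "aug_params")$flip)) {
      seen_flip <- TRUE
      expect_equal(out$mask[3, 9 + 1 - 2], 1L)
      expect_equal(sum(out$mask), 1)
    } else {
      expect_equal(out$mask, msk)
    }
  }
  expect_true(seen_flip)
})

test_that("geometric augmentation keeps image and mask aligned (centroid test)", {
  img <- matrix(0.3, 33, 33)
  msk <- matrix(0L, 33, 33)
  msk[14:18, 20:23] <- 1L          # off-center blob
  img[msk == 1] <- 0.9
  pr <- patch_pair(img, msk)
  spec <- augmentation_spec(n_variants = 1)
  for (s in 1:25) {
    out <- augment(pr, spec, variant_seed = s)
    expect_true(all(out$mask %in% c(0L, 1L)))
    if (sum(out$mask) == 0) next
    params <- attr(out, "aug_params")
    got <- colMeans(which(out$mask == 1, arr.ind = TRUE))
    ctr0 <- colMeans(which(msk == 1, arr.ind = TRUE))
    want <- transform_points(ctr0, params, dim(msk))
    expect_lt(max(abs(got - as.numeric(want))), 1)
  }
})

test_that("variant generation is reproducible and brightness only touches the image", {
  pr <- patch_pair(matrix(runif(256), 16, 16), random_mask(16, seed = 8))
  spec <- augmentation_spec(rotation_deg_range = c(0, 0),
                            skew_deg_range = c(0, 0),
                            scale_range = c(1, 1),
                            brightness_range = c(0.1, 0.1),
                            allow_flips = FALSE, n_variants = 3, seed = 2)
  vs <- augment_variants(pr, spec)
  expect_length(vs, 3)
  expect_identical(vs[[1]]$mask, pr$mask)
  expect_equal(vs[[1]]$image, pmin(pmax(pr$image + 0.1, 0), 1),
               tolerance = 1e-6)
  vs2 <- augment_variants(pr, spec)
  expect_identical(vs, vs2)
})

test_that("reassembly averages overlapping windows and zero-fills gaps", {
  # single full-size patch is the identity
  pm <- matrix(runif(36), 6, 6)
  expect_equal(reassemble(list(list(prob = pm, origin = c(1, 1))), c(6, 6)),
               pm)
  # two overlapping constant patches average on the overlap
  a <- list(prob = matrix(0.2, 4, 4), origin = c(1, 1))    # cols 1-4
  b <- list(prob = matrix(0.8, 4, 4), origin = c(1, 3))    # cols 3-6
  out <- reassemble(list(a, b), c(4, 8))
  expect_equal(out[1, 3], 0.5)                             # overlap mean
  expect_equal(out[1, 1], 0.2)
  expect_equal(out[1, 6], 0.8)
  expect_equal(out[1, 7], 0)                               # uncovered
  expect_equal(out[1, 8], 0)
  expect_error(reassemble(list(list(prob = matrix(0, 4, 4),
                                    origin = c(3, 3))), c(5, 5)),
               class = "cacseg_argument_error")
})

test_that("reassembly matches a brute-force per-pixel accumulation oracle", {
  set.seed(17)
  shape <- c(12, 15)
  preds <- lapply(1:7, function(i) {
    sz <- sample(3:6, 1)
    list(prob = matrix(runif(sz * sz), sz, sz),
         origin = c(sample(shape[1] - sz + 1, 1),
                    sample(shape[2] - sz + 1, 1)))
  })
  want_sum <- matrix(0, shape[1], shape[2])
  want_cnt <- matrix(0, shape[1], shape[2])
  for (p in preds) {
    for (i in seq_len(nrow(p$prob))) {
      for (j in seq_len(ncol(p$prob))) {
        r <- p$origin[1] + i - 1
        cc <- p$origin[2] + j - 1
        want_sum[r, cc] <- want_sum[r, cc] + p$prob[i, j]
        want_cnt[r, cc] <- want_cnt[r, cc] + 1
      }
    }
  }
  want <- ifelse(want_cnt > 0, want_sum / pmax(want_cnt, 1), 0)
  expect_equal(reassemble(preds, shape), want)
})
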