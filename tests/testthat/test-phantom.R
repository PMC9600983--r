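test_that("zero lesion probability forces empty masks", {
  cfg <- phantom_config(n_slices = 64, artifact_margin = 7, lesion_prob = 0)
  sc <- generate_phantom_scan(cfg, scan_seed = 5)
  expect_equal(sum(sc$masks), 0)
  expect_equal(dim(sc$masks)[3], n_slices(sc$stack))
})

test_that("phantom generation is deterministic for fixed config and seed", {
  cfg <- tiny_phantom_config()
  a <- generate_phantom_scan(cfg, scan_seed = 123)
  b <- generate_phantom_scan(cfg, scan_seed = 123)
  expect_identical(a$stack$slices, b$stack$slices)
  expect_identical(a$masks, b$masks)
  expect_identical(a$boundary_index, b$boundary_index)
  c <- generate_phantom_scan(cfg, scan_seed = 124)
  expect_false(identical(a$stack$slices, c$stack$slices))
})

test_that("per-slice lesion occurrence matches the configured probability", {
  # pooled below-boundary slices over many seeds form Bernoulli(p) draws;
  # the empirical fraction must sit inside the exact binomial 99% CI
  cfg <- phantom_config(n_slices = 64, slice_size = 96, lesion_prob = 0.5)
  hits <- 0L
  total <- 0L
  for (s in 1:100) {
    sc <- generate_phantom_scan(cfg, scan_seed = s)
    below <- sc$boundary_index:(64 - cfg$artifact_margin)
    carries <- vapply(below, function(i) sum(sc$masks[, , i]) > 0, logical(1))
    hits <- hits + sum(carries)
    total <- total + length(carries)
  }
  ci <- qbinom(c(0.005, 0.995), total, 0.5) / total
  expect_gte(hits / total, ci[1])
  expect_lte(hits / total, ci[2])
})

test_that("foreground stays rare, below the boundary, and inside the lateral regions", {
  cfg <- tiny_phantom_config()
  region <- phantom_lesion_region(cfg$slice_size)
  ds <- generate_dataset(6, cfg, positive_fraction = 0.5)
  total_fg <- 0
  total_px <- 0
  for (sc in ds) {
    total_fg <- total_fg + sum(sc$masks)
    total_px <- total_px + length(sc$masks)
    for (i in seq_len(dim(sc$masks)[3])) {
      m <- sc$masks[, , i]
      if (sum(m) > 0) {
        expect_gte(i, sc$boundary_index)
        expect_true(all(region[m == 1]))
      }
    }
  }
  expect_lt(total_fg / total_px, 0.01)
})

test_that("dataset positive fraction is honored and spread across the set", {
  cfg <- tiny_phantom_config()
  pos <- function(ds) vapply(ds, function(s) sum(s$masks) > 0, logical(1))
  ds <- generate_dataset(16, cfg, positive_fraction = 0.5)
  expect_equal(sum(pos(ds)), 8)
  ds2 <- generate_dataset(10, cfg, positive_fraction = 0.3)
  expect_equal(sum(pos(ds2)), 3)
  ds3 <- generate_dataset(4, cfg, positive_fraction = 0)
  expect_equal(sum(pos(ds3)), 0)
  # prefix/suffix splits keep both classes on each side
  expect_true(any(pos(ds)[1:8]) && any(!pos(ds)[1:8]))
  expect_true(any(pos(ds)[9:16]) && any(!pos(ds)[9:16]))
})

test_that("impossible dataset configurations raise configuration errors", {
  cfg <- tiny_phantom_config()
  expect_error(generate_dataset(1, cfg, positive_fraction = 0.5),
               class = "cacseg_config_error")
  expect_error(generate_dataset(10, cfg, positive_fraction = 0.01),
               class = "cacseg_config_error")
  neg <- tiny_phantom_config()
  neg$lesion_prob <- 0
  expect_error(generate_dataset(4, neg, positive_fraction = 0.5),
               class = "cacseg_config_error")
})

test_that("invalid phantom configs name the violated invariant", {
  expect_error(phantom_config(n_slices = 10, artifact_margin = 5),
               "artifact_margin")
  expect_error(phantom_config(boundary_fraction_range = c(0.9, 0.2)),
               "boundary_fraction_range")
  expect_error(phantom_config(lesion_prob = 1.5), "lesion_prob")
  expect_error(phantom_config(n_slices = 20, artifact_margin = 9,
                              boundary_fraction_range = c(0.01, 0.05)),
               "non-artifact")
})

test_that("above- and below-boundary slices are more distinguishable than within-class pairs", {
  cfg <- tiny_phantom_config()
  sc <- generate_phantom_scan(cfg, scan_seed = 42)
  b <- sc$boundary_index
  m <- cfg$artifact_margin
  hist_of <- function(i) {
    tabulate(cut(sc$stack$slices[, , i], seq(0, 1, by = 0.05),
                 labels = FALSE), 20)
  }
  hdist <- function(i, j) sum(abs(hist_of(i) - hist_of(j)))
  above <- (m + 1):(b - 1)
  below <- b:(24 - m)
  # compare lesion-free below slices to isolate the anatomy change
  below <- below[vapply(below, function(i) sum(sc$masks[, , i]) == 0,
                        logical(1))]
  cross <- hdist(above[1], below[1])
  within_a <- hdist(above[1], above[length(above)])
  within_b <- hdist(below[1], below[length(below)])
  expect_gt(cross, within_a)
  expect_gt(cross, within_b)
})
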