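test_that("segmenter forward pass preserves spatial shape with two class maps", {
  m <- build_segmenter(seg_config(depth = 3, base_channels = 4, seed = 2))
  m$trained <- TRUE        # untrained forward, shape contract only
  prob <- predict_patch_prob(m, matrix(runif(24 * 24), 24, 24))
  expect_equal(dim(prob), c(24, 24))
  expect_true(all(prob >= 0 & prob <= 1))
  expect_error(predict_patch_prob(m, matrix(0, 10, 10)),
               class = "cacseg_config_error")
})

test_that("seeded builds are identical and parameter count matches the architecture arithmetic", {
  cfg <- seg_config(depth = 3, base_channels = 8, seed = 5)
  a <- build_segmenter(cfg)
  b <- build_segmenter(cfg)
  expect_identical(a$params, b$params)

  # hand-computed: two 3x3 convs per encoder level (1->8->8, 8->16->16,
  # 16->32->32), decoder up-convs 32->16, 16->8 plus two 3x3 convs after
  # skip concat (32->16->16, 16->8->8), final 1x1 conv 8->2
  conv_p <- function(cin, cout) cout * cin * 9 + cout
  want <- conv_p(1, 8) + conv_p(8, 8) +
    conv_p(8, 16) + conv_p(16, 16) +
    conv_p(16, 32) + conv_p(32, 32) +
    conv_p(32, 16) + conv_p(32, 16) + conv_p(16, 16) +
    conv_p(16, 8) + conv_p(16, 8) + conv_p(8, 8) +
    (2 * 8 + 2)
  expect_equal(n_parameters(a), want)
})

test_that("weighted cross-entropy reduces to the standard form and matches hand computation", {
  set.seed(6)
  p_fg <- matrix(runif(64, 0.05, 0.95), 8, 8)
  prob <- array(c(1 - p_fg, p_fg), c(8, 8, 2))
  tgt <- random_mask(8, seed = 6)
  plain <- -mean(ifelse(tgt == 1, log(p_fg), log(1 - p_fg)))
  expect_equal(weighted_cross_entropy(prob, tgt, c(1, 1)), plain)

  perfect <- array(c(1 - tgt, tgt), c(8, 8, 2))
  expect_equal(weighted_cross_entropy(perfect, tgt), 0)

  # 2x2 toy grid, weights (1, 10), by hand
  p2 <- array(c(0.9, 0.2, 0.6, 0.3,      # background probs
                0.1, 0.8, 0.4, 0.7),     # foreground probs
              c(2, 2, 2))
  t2 <- matrix(c(0L, 1L, 0L, 1L), 2, 2)
  want <- -(log(0.9) + 10 * log(0.8) + log(0.6) + 10 * log(0.7)) / 4
  expect_equal(weighted_cross_entropy(p2, t2, c(1, 10)), want)

  expect_error(weighted_cross_entropy(prob, tgt, c(1, 0)),
               class = "cacseg_argument_error")
  expect_error(weighted_cross_entropy(prob, tgt, c(-1, 2)),
               class = "cacseg_argument_error")
})

test_that("raising the foreground weight strictly raises loss when foreground is missed", {
  p_fg <- matrix(0.5, 4, 4)
  p_fg[2, 2] <- 0.2                       # misclassified foreground pixel
  prob <- array(c(1 - p_fg, p_fg), c(4, 4, 2))
  tgt <- matrix(0L, 4, 4)
  tgt[2, 2] <- 1L
  l1 <- weighted_cross_entropy(prob, tgt, c(1, 5))
  l2 <- weighted_cross_entropy(prob, tgt, c(1, 20))
  expect_gt(l2, l1)
})

test_that("training reduces the loss, records auto weights, and serializes", {
  m <- tiny_segmenter()
  expect_true(m$trained)
  expect_lt(tail(m$log$loss, 1), m$log$loss[1])
  expect_gt(m$class_weights[2], 1)

  img <- tiny_dataset()[[1]]$stack$slices[, , 12]
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(predict_mask(m2, img, patch_size = 24),
                   predict_mask(m, img, patch_size = 24))
})

test_that("auto class weights are undefined on all-background training sets", {
  patches <- lapply(1:4, function(i) {
    patch_pair(matrix(runif(64), 8, 8), matrix(0L, 8, 8))
  })
  expect_error(train_segmenter(patches, seg_config(epochs = 1)),
               class = "cacseg_config_error")
})

test_that("decision rule suppresses small components and counts survivors", {
  msk <- matrix(0L, 12, 12)
  msk[2:3, 2:4] <- 1L                      # 6-pixel component
  msk[9, 9] <- 1L                          # isolated pixel
  rule <- slice_decision_rule(min_foreground_pixels = 1,
                              min_component_size = 5)
  dec <- apply_decision_rule(msk, rule)
  expect_true(dec$call)
  expect_equal(dec$foreground_pixels, 6)
  expect_equal(dec$mask[9, 9], 0L)

  none <- apply_decision_rule(matrix(0L, 6, 6), rule)
  expect_false(none$call)
  expect_equal(none$foreground_pixels, 0)
})

test_that("Method B prediction is deterministic and all-background maps give negative calls", {
  m <- tiny_segmenter()
  ds <- tiny_dataset()
  img <- ds[[1]]$stack$slices[, , ds[[1]]$boundary_index + 1]
  a <- predict_mask(m, img, method = "B", patch_size = 24)
  b <- predict_mask(m, img, method = "B", patch_size = 24)
  expect_identical(a, b)
  expect_true(all(c("slice_index", "cac_call", "foreground_pixels") %in%
                    names(a)))

  flat <- matrix(0.02, 48, 48)             # featureless background
  out <- predict_mask(m, flat, method = "B", patch_size = 24)
  expect_false(out$cac_call)
  expect_equal(out$foreground_pixels, 0)
})

test_that("Method A prediction covers the slice with seeded random windows", {
  m <- tiny_segmenter()
  img <- tiny_dataset()[[1]]$stack$slices[, , 12]
  a <- predict_mask(m, img, method = "A", patch_size = 24, n_patches = 6,
                    seed = 3)
  b <- predict_mask(m, img, method = "A", patch_size = 24, n_patches = 6,
                    seed = 3)
  expect_identical(a, b)
  expect_equal(dim(a$prob[[1]]), c(48, 48))
})

test_that("weighted training recovers lesions end to end on default phantoms", {
  # reference recovery conditions: 16 training scans at the default
  # phantom geometry, tiny segmenter, 8 epochs, fixed central windows
  cfg <- phantom_config(seed = 1L)
  ds <- generate_dataset(20, cfg, positive_fraction = 0.5)
  tr_s <- list(); tr_m <- list(); te_s <- list(); te_m <- list()
  for (i in seq_along(ds)) {
    sc <- ds[[i]]
    for (s in sc$boundary_index:(cfg$n_slices - cfg$artifact_margin)) {
      if (i <= 16) {
        tr_s <- c(tr_s, list(sc$stack$slices[, , s]))
        tr_m <- c(tr_m, list(sc$masks[, , s]))
      } else {
        te_s <- c(te_s, list(sc$stack$slices[, , s]))
        te_m <- c(te_m, list(sc$masks[, , s]))
      }
    }
  }
  pb <- list()
  for (k in seq_along(tr_s)) {
    pb <- c(pb, extract_fixed_patches(tr_s[[k]], tr_m[[k]], size = 48))
  }
  model <- train_segmenter(pb, seg_config(loss = "weighted_cross_entropy",
                                          epochs = 8L, seed = 1L))
  pred <- predict_mask(model, te_s, method = "B", patch_size = 48)
  pairs <- Map(function(p, t) list(p, t), pred$mask, te_m)
  expect_gt(mean_iou(pairs)$iou_foreground, 0.3)
  truth <- vapply(te_m, function(m) sum(m) > 0, logical(1))
  cc <- confusion_counts(pred$cac_call, truth)
  expect_gt(cc$tp / (cc$tp + cc$fn), 0.7)   # slice-level sensitivity
})

test_that("seg config validates its arguments", {
  expect_error(seg_config(depth = 1), class = "cacseg_config_error")
  expect_error(seg_config(threshold = 0), class = "cacseg_config_error")
  expect_error(seg_config(class_weights = c(1, -2)),
               class = "cacseg_config_error")
  expect_error(build_segmenter(seg_config(depth = 3), input_size = 30),
               class = "cacseg_config_error")
})
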