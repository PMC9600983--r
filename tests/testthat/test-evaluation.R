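test_that("confusion tallies match direct counting", {
  all_right <- confusion_counts(rep(c(TRUE, FALSE), each = 10),
                                rep(c(TRUE, FALSE), each = 10))
  expect_equal(unclass(all_right)[c("tp", "fp", "fn", "tn")],
               list(tp = 10L, fp = 0L, fn = 0L, tn = 10L))
  inverted <- confusion_counts(rep(c(FALSE, TRUE), each = 10),
                               rep(c(TRUE, FALSE), each = 10))
  expect_equal(unclass(inverted)[c("tp", "fp", "fn", "tn")],
               list(tp = 0L, fp = 10L, fn = 10L, tn = 0L))

  set.seed(21)
  for (rep in 1:20) {
    n <- sample(5:200, 1)
    calls <- runif(n) < 0.4
    truth <- runif(n) < 0.2
    got <- confusion_counts(calls, truth)
    tp <- fp <- fn <- tn <- 0L
    for (i in seq_len(n)) {              # loop oracle
      if (calls[i] && truth[i]) tp <- tp + 1L
      else if (calls[i]) fp <- fp + 1L
      else if (truth[i]) fn <- fn + 1L
      else tn <- tn + 1L
    }
    expect_identical(c(got$tp, got$fp, got$fn, got$tn), c(tp, fp, fn, tn))
  }
  expect_error(confusion_counts(c(TRUE, FALSE), TRUE),
               class = "cacseg_argument_error")
})

test_that("diagnostic metrics reproduce a published slice-level confusion table", {
  m <- diagnostic_metrics(new_confusion_counts(178, 135, 11, 3681))
  expect_equal(m$sensitivity, 94.2)
  expect_equal(m$specificity, 96.5)
  expect_equal(m$ppv, 56.9)
  expect_equal(m$npv, 99.7)
  expect_equal(m$accuracy, 96.35)
})

test_that("diagnostic metrics handle perfect, hand-computed, and degenerate counts", {
  perfect <- diagnostic_metrics(new_confusion_counts(1, 0, 0, 1))
  expect_true(all(unlist(perfect) == 100))

  hand <- diagnostic_metrics(new_confusion_counts(3, 1, 2, 4))
  expect_equal(hand$sensitivity, 60.0)
  expect_equal(hand$specificity, 80.0)
  expect_equal(hand$ppv, 75.0)
  expect_equal(hand$npv, 66.7)
  expect_equal(hand$accuracy, 70.0)

  none <- diagnostic_metrics(new_confusion_counts(0, 0, 0, 0))
  expect_true(all(is.na(unlist(none))))
  no_pos <- diagnostic_metrics(new_confusion_counts(0, 0, 0, 5))
  expect_true(is.na(no_pos$sensitivity))
  expect_equal(no_pos$specificity, 100)

  # rounding is half-up, and configurable
  m2 <- diagnostic_metrics(new_confusion_counts(178, 135, 11, 3681),
                           round_digits = 3)
  expect_equal(m2$sensitivity, round(100 * 178 / 189 * 1000) / 1000,
               tolerance = 1e-9)
})

test_that("per-class IoU follows set arithmetic and its conventions", {
  a <- random_mask(6, seed = 31)
  expect_equal(iou(a, a, 1), 1)
  expect_equal(iou(a, a, 0), 1)

  d1 <- matrix(0L, 4, 4); d1[1, 1:2] <- 1L
  d2 <- matrix(0L, 4, 4); d2[4, 3:4] <- 1L
  expect_equal(iou(d1, d2, 1), 0)

  p <- matrix(0L, 4, 4); p[1, 1:3] <- 1L        # 3-pixel set
  t2 <- matrix(0L, 4, 4); t2[1, 2:4] <- 1L      # 3-pixel set, 2 overlap
  expect_equal(iou(p, t2, 1), 2 / 4)

  # symmetry and bounds on random pairs
  set.seed(9)
  for (i in 1:10) {
    x <- random_mask(5, seed = i)
    y <- random_mask(5, seed = i + 100)
    for (cls in c(0, 1)) {
      expect_equal(iou(x, y, cls), iou(y, x, cls))
      expect_gte(iou(x, y, cls), 0)
      expect_lte(iou(x, y, cls), 1)
    }
  }
  expect_equal(iou(matrix(0L, 3, 3), matrix(0L, 3, 3), 1), 1)
  expect_error(iou(matrix(0L, 3, 3), matrix(0L, 4, 4)),
               class = "cacseg_argument_error")
})

test_that("mean IoU aggregations agree on identical pairs and pool correctly", {
  a <- random_mask(6, seed = 51)
  single <- list(list(a, a))
  expect_equal(mean_iou(single, "per_class_pooled")$mean_iou, 1)
  expect_equal(mean_iou(single, "per_image_mean")$mean_iou, 1)

  # constructed pooled value by hand
  p1 <- matrix(0L, 2, 2); p1[1, 1] <- 1L
  t1 <- matrix(0L, 2, 2); t1[1, 1] <- 1L; t1[1, 2] <- 1L
  p2 <- matrix(0L, 2, 2); p2[2, 2] <- 1L
  t2 <- matrix(0L, 2, 2)
  pairs <- list(list(p1, t1), list(p2, t2))
  # fg: inter 1, union 3; bg: inter 2+3=5, union 3+4=7
  got <- mean_iou(pairs, "per_class_pooled")
  expect_equal(got$iou_foreground, 1 / 3)
  expect_equal(got$iou_background, 5 / 7)
  expect_equal(got$mean_iou, (1 / 3 + 5 / 7) / 2)

  # pooled aggregation is invariant to pair order
  expect_equal(mean_iou(rev(pairs), "per_class_pooled")$mean_iou,
               got$mean_iou)
  expect_error(mean_iou(list()), class = "cacseg_argument_error")
})

test_that("boundary reports summarize per-scan absolute errors", {
  r <- boundary_report(predicted = 357, truth = 345)
  expect_equal(r$max_abs_error, 12)
  expect_equal(nrow(tidy(r)), 1)

  exact <- boundary_report(predicted = c(5, 9, 30), truth = c(5, 9, 30))
  expect_equal(exact$max_abs_error, 0)

  two <- boundary_report(predicted = c(3, 9), truth = c(1, 2))
  expect_equal(two$max_abs_error, 7)
  expect_equal(two$median_abs_error, 4.5)
  expect_equal(glance(two)$n_scans, 2)
  expect_error(boundary_report(integer(0), integer(0)),
               class = "cacseg_argument_error")
})
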