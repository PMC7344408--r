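test_that("confusion counts and accuracy satisfy the exact identities", {
  pred <- random_plane(8, 8, 0.5, seed = 900)
  cc <- confusion_counts(pred, pred)
  expect_identical(c(cc$fp, cc$fn), c(0L, 0L))
  expect_identical(accuracy(cc), 1)

  comp <- 1L - pred
  cc2 <- confusion_counts(pred, comp)
  expect_identical(c(cc2$tp, cc2$tn), c(0L, 0L))
  expect_identical(accuracy(cc2), 0)

  expect_identical(accuracy(list(tp = 90L, tn = 5L, fp = 3L, fn = 2L)), 0.95)
  expect_error(accuracy(list(tp = 0L, tn = 0L, fp = 0L, fn = 0L)), "undefined")
  expect_error(confusion_counts(pred, matrix(0L, 4, 4)), "same height and width")
})

test_that("counts match a nested-loop tally and complements are symmetric", {
  for (seed in 1:10) {
    pred <- random_plane(8, 8, runif(1), seed = 910 + seed)
    truth <- random_plane(8, 8, runif(1))
    cc <- confusion_counts(pred, truth)
    tally <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
    for (r in 1:8) {
      for (c in 1:8) {
        key <- if (pred[r, c] == 1L && truth[r, c] == 1L) "tp"
          else if (pred[r, c] == 1L) "fp"
          else if (truth[r, c] == 1L) "fn"
          else "tn"
        tally[key] <- tally[key] + 1L
      }
    }
    expect_identical(unlist(cc[1, ]), tally[c("tp", "fp", "tn", "fn")],
                     ignore_attr = TRUE)
    expect_identical(cc$tp + cc$fp + cc$tn + cc$fn, 64L)
    # complementing the prediction flips accuracy
    expect_equal(accuracy(cc) + accuracy(confusion_counts(1L - pred, truth)), 1)
    # complementing both swaps TP<->TN and FP<->FN
    cc_both <- confusion_counts(1L - pred, 1L - truth)
    expect_identical(c(cc_both$tp, cc_both$tn, cc_both$fp, cc_both$fn),
                     c(cc$tn, cc$tp, cc$fn, cc$fp))
  }
})

test_that("mask_metrics reports coherent companion metrics", {
  pred <- matrix(0L, 6, 6)
  pred[2:4, 2:4] <- 1L
  truth <- matrix(0L, 6, 6)
  truth[3:5, 3:5] <- 1L
  m <- mask_metrics(pred, truth)
  expect_equal(m$dice, 2 * m$tp / (2 * m$tp + m$fp + m$fn))
  expect_equal(m$jaccard, m$tp / (m$tp + m$fp + m$fn))
  expect_true(m$jaccard <= m$dice)
  expect_equal(m$sensitivity, m$tp / 9)
})

test_that("dataset evaluation averages per image and tolerates failures", {
  suite <- generate_suite(4, synthetic_spec(size = 96L, radius = 24),
                          master_seed = 7L)
  ev <- evaluate_dataset(suite)
  expect_identical(ev$n_images, 4L)
  expect_equal(ev$mean_accuracy, mean(ev$per_image$accuracy))

  # order invariance of the mean
  ev_rev <- evaluate_dataset(rev(suite))
  expect_equal(ev_rev$mean_accuracy, ev$mean_accuracy)
  expect_identical(sort(ev_rev$per_image$id), sort(ev$per_image$id))

  # a shape-mismatched case is skipped and counted, others still evaluated
  broken <- suite
  broken[[2]]$truth <- matrix(0L, 10, 10)
  expect_warning(ev2 <- evaluate_dataset(broken), "skipping")
  expect_identical(ev2$n_images, 3L)
  expect_identical(ev2$n_skipped, 1L)
  expect_identical(ev2$skipped_ids, "synth_001")

  expect_error(evaluate_dataset(list()), "non-empty")

  g <- glance(ev)
  expect_identical(g$n_images, 4L)
  t <- tidy(ev)
  expect_identical(nrow(t), 4L)
})

test_that("a segmentation that reproduces the truth gives mean accuracy 1", {
  fx <- generate_fixture(synthetic_spec(size = 64L, radius = 16, seed = 3L))
  truth <- segment_lesion(fx$image)$mask # truth defined as the method's output
  ev <- evaluate_dataset(list(list(image = fx$image, truth = truth, id = "a")))
  expect_identical(ev$mean_accuracy, 1)
  expect_identical(ev$per_image$fp + ev$per_image$fn, 0L)
})
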