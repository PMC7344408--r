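test_that("plane summation matches the per-pixel oracle and stays in 0..3", {
  expect_identical(sum_planes(matrix(1L, 2, 2), matrix(1L, 2, 2), matrix(1L, 2, 2)),
                   matrix(3L, 2, 2))
  expect_identical(
    sum_planes(matrix(1L, 1, 1), matrix(0L, 1, 1), matrix(0L, 1, 1)),
    matrix(1L, 1, 1)
  )
  for (seed in 1:10) {
    set.seed(500 + seed)
    pr <- random_plane(16, 16, runif(1))
    pg <- random_plane(16, 16, runif(1))
    pb <- random_plane(16, 16, runif(1))
    lev <- sum_planes(pr, pg, pb)
    brute <- matrix(0L, 16, 16)
    for (r in 1:16) for (c in 1:16) brute[r, c] <- pr[r, c] + pg[r, c] + pb[r, c]
    expect_identical(lev, brute)
    expect_identical(tabulate(lev + 1L, 4L), tabulate(brute + 1L, 4L))
    expect_true(min(lev) >= 0L && max(lev) <= 3L)
  }
  expect_error(sum_planes(matrix(0L, 2, 2), matrix(0L, 2, 3), matrix(0L, 2, 2)),
               "same height and width")
})

test_that("component labelling agrees with a flood-fill oracle", {
  for (seed in 1:6) {
    m <- random_plane(20, 20, 0.45, seed = 600 + seed)
    for (conn in c(8L, 4L)) {
      lab <- label_components(m, conn)
      oracle <- flood_fill_label(m, conn)
      # same partition: labels are a bijection
      expect_identical(lab > 0L, oracle > 0L)
      expect_identical(max(lab), max(oracle))
      for (l in seq_len(max(lab))) {
        ol <- unique(oracle[lab == l])
        expect_length(ol, 1L)
      }
    }
  }
})

test_that("hole filling fills only interior background", {
  m <- matrix(0L, 9, 9)
  m[3:7, 3:7] <- 1L
  m[5, 5] <- 0L # interior hole
  filled <- fill_holes(m)
  expect_identical(filled[5, 5], 1L)
  expect_identical(sum(filled), 25L)
  # background reaching the border is never filled
  expect_identical(fill_holes(matrix(0L, 5, 5)), matrix(0L, 5, 5))
  ring <- matrix(0L, 5, 5)
  ring[2:4, 2:4] <- 1L
  expect_identical(fill_holes(ring), ring)
})

test_that("lesion mask selection: levels, corners, largest component, holes", {
  cfg <- segmentation_config()

  all3 <- matrix(3L, 10, 10)
  expect_identical(lesion_mask_from_levels(all3, cfg), matrix(0L, 10, 10))

  # central disk of level 0 in level-3 background
  lev <- matrix(3L, 21, 21)
  for (r in 1:21) for (c in 1:21) {
    if ((r - 11)^2 + (c - 11)^2 <= 36) lev[r, c] <- 0L
  }
  expect_identical(lesion_mask_from_levels(lev, cfg),
                   matrix(as.integer(lev == 0L), 21, 21))

  # dark corner wedges are excluded, the central blob kept
  lev2 <- lev
  lev2[1:3, 1:3] <- 0L
  lev2[1:3, 19:21] <- 0L
  lev2[19:21, 1:3] <- 0L
  lev2[19:21, 19:21] <- 0L
  mask <- lesion_mask_from_levels(lev2, cfg)
  expect_identical(mask, matrix(as.integer(lev == 0L), 21, 21))
  # and the selected region is one component of the candidate set (oracle)
  oracle <- flood_fill_label(matrix(as.integer(lev2 <= 2L), 21, 21), 8L)
  expect_length(unique(oracle[mask == 1L]), 1L)

  # with corner exclusion off, the largest component wins instead
  cfg_off <- segmentation_config(exclude_corner_components = FALSE)
  mask2 <- lesion_mask_from_levels(lev2, cfg_off)
  expect_identical(mask2, mask) # blob is larger than any wedge

  # a mask with interior level-3 speckle is hole-filled
  lev3 <- lev
  lev3[11, 11] <- 3L
  expect_identical(lesion_mask_from_levels(lev3, cfg),
                   matrix(as.integer(lev == 0L), 21, 21))
  expect_identical(
    lesion_mask_from_levels(lev3, segmentation_config(fill_holes = FALSE))[11, 11],
    0L
  )
})

test_that("raising lesion_level_max never shrinks the candidate set", {
  set.seed(700)
  lev <- matrix(sample(0:3, 400, replace = TRUE), 20, 20)
  cand <- lapply(0:2, function(lmax) lev <= lmax)
  expect_true(all(cand[[1]] <= cand[[2]]))
  expect_true(all(cand[[2]] <= cand[[3]]))
  # through the full mask path with postprocessing disabled
  masks <- lapply(0:2, function(lmax) {
    lesion_mask_from_levels(lev, segmentation_config(
      lesion_level_max = lmax, exclude_corner_components = FALSE,
      keep_largest_component = FALSE, fill_holes = FALSE
    ))
  })
  expect_true(all(masks[[1]] <= masks[[2]]))
  expect_true(all(masks[[2]] <= masks[[3]]))
})

test_that("degenerate uniform images give the degenerate masks", {
  bright <- rgb_image(array(200L, dim = c(32, 32, 3)))
  seg <- segment_lesion(bright)
  expect_true(all(seg$levels == 3L))
  expect_identical(sum(seg$mask), 0L)
  expect_identical(nrow(seg$contour), 0L)

  dark <- rgb_image(array(50L, dim = c(32, 32, 3)))
  seg <- segment_lesion(dark)
  expect_true(all(seg$levels == 0L))
  # the whole frame touches the corners -> excluded by default
  expect_identical(sum(seg$mask), 0L)
})
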