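test_that("degenerate spec yields an exact disk with exact colors", {
  sp <- synthetic_spec(size = 64L, radius = 16, irregularity = 0,
                       harmonics = 0L, noise_sd = 0, n_hairs = 0L,
                       vignette = 0, seed = 1L)
  fx <- generate_fixture(sp)
  # truth is the exact discrete disk (strictly inside the circle)
  rowm <- matrix(1:64, 64, 64)
  colm <- t(rowm)
  disk <- matrix(as.integer(sqrt((rowm - 32.5)^2 + (colm - 32.5)^2) < 16), 64, 64)
  expect_identical(fx$truth, disk)
  # deep lesion core and far skin carry the exact mean colors
  core <- sqrt((rowm - 32.5)^2 + (colm - 32.5)^2) < 16 - 3
  skin <- sqrt((rowm - 32.5)^2 + (colm - 32.5)^2) > 16 + 3
  arr <- unclass(fx$image)
  expect_true(all(arr[, , 1][core] == 90L) && all(arr[, , 1][skin] == 200L))
  expect_true(all(arr[, , 2][core] == 60L) && all(arr[, , 2][skin] == 160L))
  expect_true(all(arr[, , 3][core] == 50L) && all(arr[, , 3][skin] == 140L))
})

test_that("identical specs give bit-identical fixtures and restore the RNG", {
  sp <- synthetic_spec(size = 96L, seed = 42L, radius = 25)
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  fx1 <- generate_fixture(sp)
  after <- runif(1) # generator must not consume the caller's RNG stream
  expect_identical(before, after)
  fx2 <- generate_fixture(sp)
  expect_identical(unclass(fx1$image), unclass(fx2$image))
  expect_identical(fx1$truth, fx2$truth)
})

test_that("default fixtures live in the MSB contrast regime", {
  fx <- generate_fixture(synthetic_spec(seed = 0L))
  arr <- unclass(fx$image)
  all_dark <- arr[, , 1] < 128L & arr[, , 2] < 128L & arr[, , 3] < 128L
  all_bright <- arr[, , 1] >= 128L & arr[, , 2] >= 128L & arr[, , 3] >= 128L
  lesion <- fx$truth == 1L
  expect_gt(mean(all_dark[lesion]), 0.8)
  expect_gt(mean(all_bright[!lesion]), 0.8)
})

test_that("truth area matches the analytic boundary polygon within 5%", {
  for (seed in c(0L, 7L, 19L)) {
    fx <- generate_fixture(synthetic_spec(seed = seed))
    x <- fx$boundary$col
    y <- fx$boundary$row
    poly_area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
    expect_lt(abs(sum(fx$truth) - poly_area) / poly_area, 0.05)
  }
})

test_that("suites are deterministic, labelled and single-component", {
  s1 <- generate_suite(5, synthetic_spec(size = 128L, radius = 30),
                       master_seed = 9L)
  s2 <- generate_suite(5, synthetic_spec(size = 128L, radius = 30),
                       master_seed = 9L)
  expect_identical(lapply(s1, function(x) unclass(x$image)),
                   lapply(s2, function(x) unclass(x$image)))
  expect_identical(vapply(s1, `[[`, "", "id"),
                   sprintf("synth_%03d", 0:4))
  for (case in s1) {
    lab <- flood_fill_label(case$truth, 8L)
    expect_identical(max(lab), 1L)
  }
  expect_error(generate_suite(0, synthetic_spec()), "positive")
})

test_that("spec invariants are enforced", {
  expect_error(synthetic_spec(size = 64L, radius = 40), "half")
  expect_error(synthetic_spec(irregularity = 1.2), "\\[0, 1\\)")
  expect_error(synthetic_spec(skin_color = c(300, 0, 0)), "\\[0, 255\\]")
  expect_error(synthetic_spec(hair_width = 3L), "1 or 2")
})

test_that("noiseless artifact-free fixtures are recovered almost exactly", {
  sp <- synthetic_spec(noise_sd = 0, n_hairs = 0L, seed = 0L)
  fx <- generate_fixture(sp)
  seg <- segment_lesion(fx$image)
  acc <- accuracy(confusion_counts(seg$mask, fx$truth))
  expect_gte(acc, 0.99) # transition band is the only error source
})
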