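test_that("subtraction image is the signed post-minus-pre difference", {
  arr <- array(10, dim = c(9, 8, 8))
  arr[4, , ] <- 25
  arr[4, 1, 1] <- 4          # darker than pre: negative preserved
  s <- dce_series(arr)
  sub <- subtraction_image(s, 3)
  expect_equal(sub[2, 2], 15)
  expect_equal(sub[1, 1], -6)

  expect_equal(subtraction_image(s, 1), matrix(0, 8, 8))  # phase == baseline
  expect_error(subtraction_image(s, 9), "out of range")
  expect_error(subtraction_image(s, 0), "out of range")
})

test_that("otsu separates a perfect bimodal sample and guards constants", {
  vals <- c(rep(10, 50), rep(200, 50))
  t <- otsu_threshold(vals)
  expect_true(t >= 10 && t < 200)
  expect_equal(sum(vals > t), 50)   # foreground = the bright class
  expect_error(otsu_threshold(rep(5, 20)), "degenerate")
})

test_that("otsu equals the exhaustive between-class-variance maximizer", {
  set.seed(202)
  # two gaussian clusters
  vals <- c(rnorm(500, 30, 5), rnorm(500, 180, 10))
  expect_equal(otsu_threshold(vals), oracle_otsu(vals))
  # 200 random arrays of varied shape
  for (i in 1:200) {
    n <- sample(10:200, 1)
    vals <- switch(sample(3, 1),
                   runif(n, 0, 100),
                   c(rnorm(n, 20, 4), rnorm(n, 60, 12)),
                   rexp(n, 0.1))
    expect_equal(otsu_threshold(vals, bins = 64), oracle_otsu(vals, bins = 64),
                 info = paste("array", i))
  }
})

test_that("erosion and dilation reproduce the worked block examples", {
  se <- structuring_element(4)
  expect_setequal(unique(se$offsets[, 1]), -1:2)
  expect_setequal(unique(se$offsets[, 2]), -1:2)
  expect_equal(nrow(se$offsets), 16)

  m <- matrix(FALSE, 12, 12); m[1:5, 1:5] <- TRUE
  er <- binary_erode(mask_image(m, "roi"), se)
  expected <- matrix(FALSE, 12, 12); expected[2:3, 2:3] <- TRUE
  expect_identical(er$data, expected)

  di <- binary_dilate(er, se)
  expect_identical(di$data, m)   # opening restores the block

  # single pixel at (5,5) 0-based -> 4x4 block rows/cols 4..7 0-based
  one <- matrix(FALSE, 12, 12); one[6, 6] <- TRUE
  d1 <- binary_dilate(mask_image(one, "roi"), se)
  expected <- matrix(FALSE, 12, 12); expected[5:8, 5:8] <- TRUE
  expect_identical(d1$data, expected)

  # empty in, empty out; isolated pixel erodes away
  empty <- mask_image(matrix(FALSE, 12, 12), "roi")
  expect_equal(mask_area(binary_erode(empty, se)), 0)
  expect_equal(mask_area(binary_dilate(empty, se)), 0)
  expect_equal(mask_area(binary_erode(mask_image(one, "roi"), se)), 0)
})

test_that("morphology matches brute-force set definitions on random masks", {
  set.seed(303)
  for (i in 1:100) {
    m <- random_mask(32, 32, p = runif(1, 0.2, 0.7))
    size <- sample(c(2, 3, 4), 1)
    se <- structuring_element(size)
    mm <- mask_image(m, "roi")
    expect_identical(binary_erode(mm, se)$data, oracle_erode(m, se$offsets),
                     info = paste("erode", i))
    expect_identical(binary_dilate(mm, se)$data, oracle_dilate(m, se$offsets),
                     info = paste("dilate", i))
  }
})

test_that("erode-then-dilate is an algebraic opening", {
  set.seed(404)
  se <- structuring_element(4)
  for (i in 1:30) {
    x <- mask_image(random_mask(32, 32, 0.5), "roi")
    opened <- binary_dilate(binary_erode(x, se), se)
    expect_true(all(!opened$data | x$data))   # opening(x) subset of x
    twice <- binary_dilate(binary_erode(opened, se), se)
    expect_identical(twice$data, opened$data) # idempotent
  }
})

test_that("largest 8-connected component and its tie-break", {
  m <- matrix(FALSE, 10, 10)
  m[2:4, 2:4] <- TRUE           # size 9
  m[7:8, 7:8] <- TRUE           # size 4
  out <- largest_component_8(mask_image(m, "lesion"))
  expect_equal(mask_area(out), 9)
  expect_true(all(which(out$data, arr.ind = TRUE) <= 4))

  # two size-4 components: keep the one containing (0,0)
  m2 <- matrix(FALSE, 10, 10)
  m2[1:2, 1:2] <- TRUE
  m2[6:7, 6:7] <- TRUE
  out2 <- largest_component_8(mask_image(m2, "lesion"))
  expect_true(out2$data[1, 1])
  expect_equal(mask_area(out2), 4)

  # a diagonal chain is one component under 8-connectivity
  m3 <- matrix(FALSE, 10, 10)
  for (k in 1:8) m3[k, k] <- TRUE
  expect_equal(mask_area(largest_component_8(mask_image(m3, "lesion"))), 8)

  expect_error(largest_component_8(mask_image(matrix(FALSE, 5, 5), "lesion")),
               "empty")
})

test_that("component labelling agrees with a flood-fill oracle", {
  set.seed(505)
  for (i in 1:30) {
    m <- random_mask(24, 24, 0.35)
    if (!any(m)) next
    lab <- oracle_components8(m)
    sizes <- table(lab[lab > 0])
    biggest <- max(sizes)
    out <- largest_component_8(mask_image(m, "lesion"))
    expect_equal(mask_area(out), as.integer(biggest), info = paste("mask", i))
    # the kept pixels form exactly one oracle component
    expect_equal(length(unique(lab[out$data])), 1L, info = paste("mask", i))
  }
})

test_that("segment_lesion recovers a block and drops the speck", {
  s <- block_series(speck = c(11, 11))
  lesion <- segment_lesion(s, full_roi(12))
  expected <- matrix(FALSE, 12, 12); expected[4:8, 4:8] <- TRUE
  expect_identical(lesion$data, expected)
  counts <- attr(lesion, "stage_counts")
  expect_equal(unname(counts["final"]), 25)
  expect_equal(unname(counts["foreground"]), 26)  # block + speck
})

test_that("segment_lesion guards degenerate and too-small inputs", {
  flat <- uniform_series(rep(100, 9), size = 12)
  expect_error(segment_lesion(flat, full_roi(12)), "degenerate")

  small <- block_series(block_rows = 5:7, block_cols = 5:7)  # 3x3 < 4x4 SE
  expect_error(segment_lesion(small, full_roi(12)),
               "enlarge ROI or reduce SE size")
})

test_that("segmented lesion stays inside the ROI and is connected", {
  set.seed(606)
  for (i in 1:5) {
    kspec <- lesion_kinetic_spec(sample(c("I", "II", "III"), 1))
    cs <- simulate_case(phantom_spec(sigma = 0.05), kspec, seed = 600 + i)
    roi <- rasterize_roi(cs$roi, dim(cs$series$data)[2:3])
    lesion <- segment_lesion(cs$series, roi)
    expect_true(all(!lesion$data | roi$data))
    lab <- oracle_components8(lesion$data)
    expect_equal(max(lab), 1L)
  }
})
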