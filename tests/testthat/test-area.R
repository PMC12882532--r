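test_that("the adaptive threshold reproduces hand-evaluated values", {
  # nine values, five at 0 and four at 100: population sd 49.69, T = 25.46
  expect_equal(
    region_threshold(c(0, 0, 0, 0, 0, 100, 100, 100, 100)),
    100 - 1.5 * sqrt((5 * (400 / 9)^2 + 4 * (100 - 400 / 9)^2) / 9)
  )
  expect_equal(
    signif(region_threshold(c(0, 0, 0, 0, 0, 100, 100, 100, 100)), 4), 25.46
  )
  expect_equal(region_threshold(c(0, 0, 100, 100)), 25) # sigma = 50
  expect_equal(region_threshold(rep(7.3, 12)), 0) # constant region
  expect_error(region_threshold(numeric(0)), "empty")
})

test_that("kappa scales the sd term and invert negates before everything", {
  v <- c(0, 0, 100, 100)
  expect_equal(region_threshold(v, kappa = 0), 100)
  expect_equal(region_threshold(v, kappa = 2), 0)
  expect_equal(region_threshold(v, invert = TRUE), region_threshold(v)) # symmetric data
  skewed <- c(0, 0, 0, 50)
  expect_equal(region_threshold(skewed, invert = TRUE), region_threshold(-skewed))
})

test_that("the 7x7 worked example yields T = 25.02 and 2.576 nm2", {
  img <- matrix(0, 7, 7)
  img[2:6, 2:6] <- 100
  rec <- measure_aggregate_area(
    micrograph(img, pixel_size = 3.21), label_mask(matrix(1L, 7, 7)), 1
  )
  expect_equal(rec$region_pixel_count, 49L)
  expect_equal(round(rec$threshold, 2), 25.02)
  expect_equal(rec$above_threshold_pixels, 25L)
  expect_equal(round(rec$area_nm2, 3), 2.576)
})

test_that("a uniform region warns and counts every pixel", {
  img <- micrograph(matrix(42, 5, 5), pixel_size = 3.21)
  expect_warning(
    rec <- measure_aggregate_area(img, label_mask(matrix(1L, 5, 5)), 1),
    "constant"
  )
  expect_equal(rec$above_threshold_pixels, 25L)
  expect_equal(rec$area_nm2, 25 * (3.21 / 10)^2)
})

test_that("absent labels and misaligned masks are rejected by name", {
  img <- micrograph(matrix(rnorm(25), 5), pixel_size = 3.21)
  expect_error(measure_aggregate_area(img, label_mask(matrix(1L, 5, 5)), 9), "9")
  expect_error(
    measure_aggregate_area(img, label_mask(matrix(1L, 4, 4)), 1),
    "aligned"
  )
})

test_that("each aggregate gets its own threshold from its own distribution", {
  img <- matrix(rnorm(64 * 64, 10, 1), 64)
  img[10:20, 10:20] <- rnorm(121, 100, 5)
  img[40:55, 40:55] <- rnorm(256, 300, 40)
  mask <- matrix(0L, 64, 64)
  mask[8:22, 8:22] <- 1L
  mask[38:57, 38:57] <- 2L
  tab <- measure_aggregates(micrograph(img, pixel_size = 3.21), label_mask(mask))
  expect_equal(nrow(tab), 2L)
  expect_false(tab$threshold[1] == tab$threshold[2])
})

test_that("an empty mask yields an empty table with a warning", {
  img <- micrograph(matrix(rnorm(16), 4), pixel_size = 3.21)
  expect_warning(tab <- measure_aggregates(img, label_mask(matrix(0L, 4, 4))), "no labels")
  expect_equal(nrow(tab), 0L)
})

test_that("relabelling aggregates permutes records but not the measured areas", {
  sim <- simulate_micrograph(micrograph_spec(
    n_aggregates = 3, background_noise_sd = 5, seed = 31
  ))
  tab1 <- measure_aggregates(sim$image, sim$mask)
  permuted <- unclass(sim$mask)
  permuted[] <- c(0L, 3L, 1L, 2L)[permuted + 1L] # 1->3, 2->1, 3->2
  tab2 <- measure_aggregates(sim$image, label_mask(permuted))
  expect_setequal(tab1$area_nm2, tab2$area_nm2)
})

test_that("passing pixels grow monotonically with kappa and ignore offsets", {
  set.seed(404)
  for (i in 1:50) {
    v <- rnorm(sample(20:200, 1), sd = runif(1, 0.5, 50))
    img <- micrograph(matrix(v, nrow = 1), pixel_size = 3.21)
    msk <- label_mask(matrix(1L, 1, length(v)))
    counts <- vapply(
      c(0, 0.5, 1, 1.5, 2, 3),
      function(k) measure_aggregate_area(img, msk, 1, kappa = k)$above_threshold_pixels,
      integer(1)
    )
    expect_true(all(diff(counts) >= 0L)) # lower threshold level, more pixels
    # adding a constant changes neither T nor the passing set
    off <- runif(1, -1000, 1000)
    img2 <- micrograph(matrix(v + off, nrow = 1), pixel_size = 3.21)
    r1 <- measure_aggregate_area(img, msk, 1)
    r2 <- measure_aggregate_area(img2, msk, 1)
    expect_equal(r1$threshold, r2$threshold)
    expect_equal(r1$above_threshold_pixels, r2$above_threshold_pixels)
  }
})

test_that("noise-free synthetic aggregates are recovered exactly", {
  for (seed in c(1, 2, 3)) {
    sim <- simulate_micrograph(micrograph_spec(
      n_aggregates = 3, aggregate_shape = "ellipse", seed = seed
    ))
    tab <- suppressWarnings(measure_aggregates(sim$image, sim$mask))
    expect_identical(tab$above_threshold_pixels, sim$truth$pixel_count)
    expect_equal(tab$area_nm2, sim$truth$area_nm2)
  }
})
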