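test_that("q/d conversion is reciprocal and rejects non-positive input", {
  expect_equal(q_to_d(0.4), 2.5)
  expect_equal(q_to_d(0.3125), 3.2)
  expect_equal(d_to_q(q_to_d(0.731)), 0.731)
  expect_error(q_to_d(0), "positive")
  expect_error(d_to_q(-1), "positive")
})

test_that("radial averaging agrees bin-for-bin with a brute-force scan", {
  set.seed(64)
  v <- matrix(runif(64 * 64, 10, 20), 64, 64)
  img <- diffraction_image(v, nyquist_q = 1.75)
  ctr <- c(31.2, 34.7)
  prof <- radial_average(img, center = ctr)
  oracle <- brute_radial_average(v, ctr, 1.75 / 32, 0.03, 0.95 * 1.75)
  expect_equal(prof$q, oracle$q)
  expect_equal(prof$intensity, oracle$intensity)
  expect_equal(prof$n_pixels, oracle$n_pixels)
})

test_that("a constant image averages to a constant profile", {
  img <- diffraction_image(matrix(3.5, 128, 128))
  prof <- radial_average(img, center = c(64.5, 64.5))
  expect_true(all(prof$intensity == 3.5))
  expect_true(all(diff(prof$q) > 0))
})

test_that("a delta ring shows up in its own radial bin", {
  n <- 512
  ctr <- c((n + 1) / 2, (n + 1) / 2)
  rr <- round(sqrt(outer((1:n - ctr[1])^2, (1:n - ctr[2])^2, "+")))
  v <- matrix(0.001, n, n)
  v[rr == 120] <- 50
  prof <- radial_average(diffraction_image(v), center = ctr)
  qpp <- 1.75 / (n / 2)
  expect_lt(abs(prof$q[which.max(prof$intensity)] / qpp - 120), 1.5)
})

test_that("mis-centering broadens a delta ring and lowers its peak", {
  n <- 512
  ctr <- c((n + 1) / 2, (n + 1) / 2)
  rr <- round(sqrt(outer((1:n - ctr[1])^2, (1:n - ctr[2])^2, "+")))
  v <- matrix(0, n, n)
  v[rr == 120] <- 50
  img <- diffraction_image(v)
  good <- radial_average(img, center = ctr)
  bad <- radial_average(img, center = ctr + c(5, 0))
  expect_lt(max(bad$intensity), max(good$intensity))
})

test_that("beam-centre estimation recovers injected offsets within a pixel", {
  pair0 <- simulate_diffraction_pair(diffraction_spec(center_offset = c(0, 0), seed = 1))
  est0 <- estimate_beam_center(pair0$target)
  expect_lt(max(abs(est0 - pair0$truth$center)), 0.5)

  pair <- simulate_diffraction_pair(diffraction_spec(
    center_offset = c(5, -3), poisson_noise = TRUE, seed = 2
  ))
  est <- estimate_beam_center(pair$target)
  expect_lt(max(abs(est - pair$truth$center)), 1)

  expect_error(
    estimate_beam_center(diffraction_image(matrix(1, 64, 64))),
    "Constant"
  )
})

test_that("radial profiles are invariant under rotating the image 90 degrees", {
  pair <- simulate_diffraction_pair(diffraction_spec(
    image_size = 256, center_offset = c(0, 0), seed = 6
  ))
  v <- unclass(pair$target)
  n <- nrow(v)
  ctr <- c((n + 1) / 2, (n + 1) / 2)
  p1 <- radial_average(pair$target, center = ctr)
  p2 <- radial_average(diffraction_image(t(v)[n:1, ]), center = ctr)
  expect_equal(p1$intensity, p2$intensity, tolerance = 1e-12)
})

test_that("band normalisation divides by the band mean and is scale-free", {
  pair <- simulate_diffraction_pair(diffraction_spec(seed = 3))
  ctr <- pair$truth$center
  prof <- radial_average(pair$target, center = ctr)
  norm <- normalize_profile(prof)
  in_band <- norm$q >= 0.094 & norm$q <= 0.113
  expect_gte(sum(in_band), 3)
  expect_equal(mean(norm$intensity[in_band]), 1, tolerance = 1e-12)

  # doubling all intensities changes nothing after normalisation
  prof2 <- prof
  prof2$intensity <- prof$intensity * 2
  norm2 <- normalize_profile(capsheet:::new_radial_profile(prof2, FALSE, NULL))
  expect_equal(norm$intensity, norm2$intensity)

  # constant profile maps to all ones; arithmetic check on a known band mean
  constp <- prof
  constp$intensity <- rep(7, nrow(prof))
  expect_true(all(normalize_profile(
    capsheet:::new_radial_profile(constp, FALSE, NULL)
  )$intensity == 1))
  known <- prof
  known$intensity <- rep(4, nrow(prof))
  known$intensity[42] <- 6 # outside the band at default binning
  nk <- normalize_profile(capsheet:::new_radial_profile(known, FALSE, NULL))
  band_mean <- mean(known$intensity[in_band])
  expect_equal(nk$intensity[42], 6 / band_mean)
})

test_that("background ratio is exactly 1 for matched profiles and dampens ice", {
  pair <- simulate_diffraction_pair(diffraction_spec(mineral_band = NULL, seed = 4))
  ctr <- pair$truth$center
  tp <- normalize_profile(radial_average(pair$target, center = ctr))
  bp <- normalize_profile(radial_average(pair$background, center = ctr))
  rat <- background_ratio(tp, bp)
  expect_true(all(rat$valid))
  expect_true(all(abs(rat$ratio - 1) < 1e-12))
  expect_equal(rat$d * rat$q, rep(1, nrow(rat)))

  # with the band present, the ice position still divides out to 1 +/- 0.05
  pair2 <- simulate_diffraction_pair(diffraction_spec(seed = 4))
  tp2 <- normalize_profile(radial_average(pair2$target, center = ctr))
  rat2 <- background_ratio(tp2, bp)
  at_ice <- which.min(abs(rat2$d - 3.71))
  expect_lt(abs(rat2$ratio[at_ice] - 1), 0.05)
})

test_that("a multiplicative perturbation is recovered exactly by the ratio", {
  pair <- simulate_diffraction_pair(diffraction_spec(mineral_band = NULL, seed = 5))
  ctr <- pair$truth$center
  bp <- normalize_profile(radial_average(pair$background, center = ctr))
  g <- 0.2 * sin(bp$q * 40) # arbitrary smooth perturbation
  tp <- bp
  tp$intensity <- bp$intensity * (1 + g)
  tp <- capsheet:::new_radial_profile(tp, TRUE, attr(bp, "normalization_band"))
  rat <- background_ratio(tp, bp)
  expect_equal(rat$ratio, 1 + g, tolerance = 1e-12)
})

test_that("binning or normalisation mismatches are refused", {
  pair <- simulate_diffraction_pair(diffraction_spec(seed = 6))
  ctr <- pair$truth$center
  tp <- radial_average(pair$target, center = ctr)
  bp <- normalize_profile(radial_average(pair$background, center = ctr))
  expect_error(background_ratio(tp, bp), "normalised")
  short <- capsheet:::new_radial_profile(
    bp[-1, ], TRUE, attr(bp, "normalization_band")
  )
  expect_error(
    background_ratio(normalize_profile(tp), short),
    "binning"
  )
})

test_that("band scoring is near zero on a flat ratio and matches the formula oracle", {
  pair <- simulate_diffraction_pair(diffraction_spec(mineral_band = NULL, seed = 7))
  ctr <- pair$truth$center
  tp <- normalize_profile(radial_average(pair$target, center = ctr))
  bp <- normalize_profile(radial_average(pair$background, center = ctr))
  flat <- detect_band(background_ratio(tp, bp))
  expect_lt(abs(flat$score), 1e-9)
  expect_false(flat$detected)

  # noise-free pair with the default 0.10-amplitude band at 2.85 A
  spec <- diffraction_spec(seed = 8)
  pair2 <- simulate_diffraction_pair(spec)
  tp2 <- normalize_profile(radial_average(pair2$target, center = ctr))
  det <- detect_band(background_ratio(tp2, bp))
  expect_true(det$detected)

  # oracle: evaluate 1 + a*G(q) at the bin centres, fit the same linear
  # baseline over the flank windows, average the excess over the band
  rat <- background_ratio(tp2, bp)
  gq <- 1 + 0.10 * exp(-(rat$q - 1 / 2.85)^2 / (2 * 0.022^2))
  fl <- (rat$d >= 2.30 & rat$d <= 2.45) | (rat$d >= 3.40 & rat$d <= 3.60)
  fit <- lm(y ~ q, data = data.frame(q = rat$q[fl], y = gq[fl]))
  in_band <- rat$d >= 2.5 & rat$d <= 3.2
  oracle <- mean(gq[in_band] - predict(fit, data.frame(q = rat$q[in_band])))
  expect_equal(det$score, oracle, tolerance = 0.02)
})

test_that("an excess at the 3.71 A ice position alone is not called a band", {
  # target carries an extra ring at 3.71 A (outside band and flanks)
  spec <- diffraction_spec(mineral_band = c(3.71, 0.10, 0.02), seed = 9)
  pair <- simulate_diffraction_pair(spec)
  ctr <- pair$truth$center
  tp <- normalize_profile(radial_average(pair$target, center = ctr))
  bp <- normalize_profile(radial_average(pair$background, center = ctr))
  det <- detect_band(background_ratio(tp, bp))
  expect_false(det$detected)
})

test_that("band and flank windows must be disjoint and sufficiently covered", {
  pair <- simulate_diffraction_pair(diffraction_spec(seed = 10))
  ctr <- pair$truth$center
  tp <- normalize_profile(radial_average(pair$target, center = ctr))
  bp <- normalize_profile(radial_average(pair$background, center = ctr))
  rat <- background_ratio(tp, bp)
  expect_error(
    detect_band(rat, band = c(2.5, 3.5), flanks = list(c(2.3, 2.45), c(3.4, 3.6))),
    "disjoint"
  )
  rat_bad <- rat
  rat_bad$valid[rat_bad$d >= 2.5 & rat_bad$d <= 3.2] <- FALSE
  expect_error(detect_band(rat_bad), "invalid")
})
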