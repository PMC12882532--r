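test_that("the published marker table reproduces its printed statistics", {
  fr <- fisher_exact_2x2(28, 18, 33, 3)
  expect_equal(round(fr$odds_ratio, 3), 0.141)
  expect_equal(signif(fr$p_value, 4), 0.001883)
  expect_equal(round(100 * fr$prop_intra_positive), 92)
  expect_equal(round(100 * fr$prop_extra_positive), 61)
  td <- tidy(fr)
  expect_equal(td$estimate, fr$odds_ratio)
  expect_true(td$conf.low < fr$odds_ratio, fr$odds_ratio < td$conf.high)
})

test_that("degenerate and symmetric tables behave as enumeration dictates", {
  sym <- fisher_exact_2x2(1, 1, 1, 1)
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p_value, 1)
  enum <- fisher_exact_2x2(2, 0, 0, 2)
  expect_equal(enum$p_value, 1 / 3) # 3 tables share the margins
  expect_equal(enum$p_value, enum_fisher_p(2, 0, 0, 2))
  expect_true(is.infinite(enum$odds_ratio))
  zero_cross <- fisher_exact_2x2(0, 5, 3, 0)
  expect_true(zero_cross$odds_ratio == 0)
  expect_true(fisher_exact_2x2(0, 5, 0, 3)$or_undefined)
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "All-zero")
})

test_that("fisher p matches brute-force enumeration on random tables", {
  set.seed(2024)
  for (i in 1:100) {
    tb <- as.integer(rmultinom(1, sample(4:60, 1), prob = runif(4, 0.1, 1)))
    if (sum(tb) == 0) next
    expect_equal(
      fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4])$p_value,
      enum_fisher_p(tb[1], tb[2], tb[3], tb[4]),
      tolerance = 1e-10
    )
  }
})

test_that("fisher p is invariant under the table symmetries", {
  set.seed(99)
  for (i in 1:25) {
    tb <- as.integer(rmultinom(1, sample(6:40, 1), prob = rep(0.25, 4)))
    p <- fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4])$p_value
    expect_equal(fisher_exact_2x2(tb[3], tb[4], tb[1], tb[2])$p_value, p) # row swap
    expect_equal(fisher_exact_2x2(tb[2], tb[1], tb[4], tb[3])$p_value, p) # col swap
    expect_equal(fisher_exact_2x2(tb[1], tb[3], tb[2], tb[4])$p_value, p) # transpose
  }
})

test_that("rank-sum p-values match enumeration and handle the null", {
  wt <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(wt$p_value, 2 / 6) # all 6 assignments enumerated by hand
  expect_equal(wt$method, "exact")
  expect_equal(wt$p_value, enum_wilcoxon_p(c(1, 2), c(3, 4)))

  same <- wilcoxon_rank_sum(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$p_value, 1)
  expect_equal(same$method, "normal_approx") # ties force the approximation

  expect_error(wilcoxon_rank_sum(numeric(0), 1:5), "at least 2")
})

test_that("the normal approximation tracks exact enumeration at n = 8 + 8", {
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(8)
    y <- rnorm(8, mean = runif(1, -1, 1))
    exact_p <- wilcoxon_rank_sum(x, y)$p_value # tie-free, min n <= 10 -> exact
    approx_p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    )
    expect_equal(exact_p, enum_wilcoxon_p(x, y), tolerance = 1e-10)
    expect_lt(abs(approx_p - exact_p), 0.02)
  }
})

test_that("rank-sum p is invariant under monotone transforms of the data", {
  set.seed(11)
  x <- rlnorm(9)
  y <- rlnorm(12, meanlog = 0.8)
  p0 <- wilcoxon_rank_sum(x, y)$p_value
  expect_equal(wilcoxon_rank_sum(log(x), log(y))$p_value, p0)
  expect_equal(wilcoxon_rank_sum(x^3, y^3)$p_value, p0)
  expect_equal(wilcoxon_rank_sum(exp(x), exp(y))$p_value, p0)
})

test_that("BH adjustment matches the hand-computed step-up examples", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.05)), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.005)), c(0.02, 0.04, 0.04, 0.02))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH adjustment matches an independent step-up implementation", {
  step_up <- function(p) {
    # sort ascending, scale p_(i) by m/i, cumulative min from the top, cap at 1
    m <- length(p)
    o <- order(p)
    scaled <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(pmin(scaled, 1))))
    out <- numeric(m)
    out[o] <- adj
    out
  }
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(2:12, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, step_up(p))
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    # order-preserving on sorted inputs
    expect_true(all(diff(bh_adjust(sort(p))) >= -1e-12))
  }
})

test_that("star labels apply strict cutoffs", {
  expect_equal(p_stars(c(0.0005, 0.02, 0.05, 0.009, 0.2)), c("***", "*", "", "**", ""))
  expect_equal(p_stars(0.001), "**") # boundary falls to the weaker label
  expect_error(p_stars(1.5), "\\[0, 1\\]")
})
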