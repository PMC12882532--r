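# Shared fixtures and independent oracles used across the test files.

# Brute-force radial grouping: per-pixel loop, no vectorised shortcuts.
brute_radial_average <- function(values, center, q_pp, q_min, q_max) {
  acc <- list()
  for (i in seq_len(nrow(values))) {
    for (j in seq_len(ncol(values))) {
      r <- round(sqrt((i - center[1])^2 + (j - center[2])^2))
      key <- as.character(r)
      acc[[key]] <- c(acc[[key]], values[i, j])
    }
  }
  radii <- sort(as.integer(names(acc)))
  q <- radii * q_pp
  keep <- q >= q_min & q <= q_max
  data.frame(
    q = q[keep],
    intensity = vapply(as.character(radii[keep]), function(k) mean(acc[[k]]), 0),
    n_pixels = vapply(as.character(radii[keep]), function(k) length(acc[[k]]), 0L)
  )
}

# Exhaustive hypergeometric enumeration of the two-sided Fisher p-value:
# total probability of all tables with the observed margins that are at most
# as probable as the observed one (1e-7 relative tolerance for float ties).
enum_fisher_p <- function(a, b, c, d) {
  m <- a + b # first row margin
  k <- a + c # first column margin
  n <- a + b + c + d
  support <- max(0L, k - (n - m)):min(m, k)
  probs <- dhyper(support, m, n - m, k)
  p_obs <- dhyper(a, m, n - m, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided rank-sum p by full enumeration of group assignments.
enum_wilcoxon_p <- function(x, y) {
  nx <- length(x)
  pooled <- rank(c(x, y))
  obs <- sum(pooled[seq_len(nx)])
  combos <- utils::combn(length(pooled), nx)
  sums <- apply(combos, 2, function(ix) sum(pooled[ix]))
  mu <- mean(sums)
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# Band-free noisy diffraction spec used for null simulations.
null_diffraction_spec <- function(seed) {
  diffraction_spec(mineral_band = NULL, poisson_noise = TRUE, seed = seed)
}

band_score_of_pair <- function(pair) {
  ctr <- estimate_beam_center(pair$target)
  tp <- normalize_profile(radial_average(pair$target, center = ctr))
  bp <- normalize_profile(radial_average(pair$background, center = ctr))
  detect_band(background_ratio(tp, bp), threshold = Inf)$score
}
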