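#' Construct a 2x2 marker-colocalization contingency table
#'
#' Counts follow the layout of the intracellular/extracellular marker
#' analysis: `a` extracellular marker-positive, `b` extracellular
#' marker-negative, `c` intracellular marker-positive, `d` intracellular
#' marker-negative.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @return A list of class `capsheet_contingency`.
#' @export
contingency_table <- function(a, b, c, d) {
  for (nm in c("a", "b", "c", "d")) {
    check_number(get(nm), nm, lower = 0, integer = TRUE)
  }
  structure(
    list(a = as.integer(a), b = as.integer(b), c = as.integer(c), d = as.integer(d)),
    class = "capsheet_contingency"
  )
}

#' @export
print.capsheet_contingency <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
    dimnames = list(c("extracellular", "intracellular"), c("positive", "negative"))
  )
  print(m)
  invisible(x)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' The two-sided p-value is the total hypergeometric probability of every
#' table with the observed margins whose probability does not exceed that
#' of the observed table (probability-mass rule, with a 1e-7 relative
#' tolerance for floating-point ties), as computed by
#' [stats::fisher.test()]. The reported odds ratio is the *sample*
#' cross-product ratio `(a * d) / (b * c)` — not the conditional MLE —
#' with `x/0 = Inf` and `0/0` flagged undefined. The default 95% CI is the
#' Woolf (log-odds normal) interval, tagged with its method; it is
#' unavailable when any cell is zero.
#'
#' @param table A [contingency_table()], a 2x2 matrix, or the count `a`
#'   when `b`, `c`, `d` are given.
#' @param b,c,d Remaining counts when `table` is the scalar `a`.
#' @return A list of class `fisher_2x2` with `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `or_undefined`, `p_value`, `conf_low`, `conf_high`,
#'   `ci_method`, `prop_extra_positive` (`a/(a+b)`) and
#'   `prop_intra_positive` (`c/(c+d)`). Has [tidy()] and [glance()]
#'   methods.
#' @examples
#' fisher_exact_2x2(28, 18, 33, 3)
#' @export
fisher_exact_2x2 <- function(table, b = NULL, c = NULL, d = NULL) {
  if (inherits(table, "capsheet_contingency")) {
    tb <- table
  } else if (is.matrix(table)) {
    stopifnot(all(dim(table) == 2L))
    tb <- contingency_table(table[1, 1], table[1, 2], table[2, 1], table[2, 2])
  } else {
    tb <- contingency_table(table, b, c, d)
  }
  n <- tb$a + tb$b + tb$c + tb$d
  if (n == 0L) abort("All-zero contingency table; nothing to test.")

  m <- matrix(c(tb$a, tb$b, tb$c, tb$d), 2, byrow = TRUE)
  p <- fisher.test(m, alternative = "two.sided")$p.value

  or_undefined <- (tb$a * tb$d == 0L) && (tb$b * tb$c == 0L)
  odds_ratio <- if (or_undefined) {
    NaN
  } else if (tb$b * tb$c == 0L) {
    Inf
  } else {
    (tb$a * tb$d) / (tb$b * tb$c)
  }

  if (all(c(tb$a, tb$b, tb$c, tb$d) > 0L)) {
    se <- sqrt(1 / tb$a + 1 / tb$b + 1 / tb$c + 1 / tb$d)
    ci <- exp(log(odds_ratio) + c(-1, 1) * qnorm(0.975) * se)
  } else {
    ci <- c(NA_real_, NA_real_)
  }

  structure(
    list(
      a = tb$a, b = tb$b, c = tb$c, d = tb$d,
      odds_ratio = odds_ratio, or_undefined = or_undefined,
      p_value = min(p, 1),
      conf_low = ci[1], conf_high = ci[2], ci_method = "woolf",
      prop_extra_positive = if (tb$a + tb$b > 0) tb$a / (tb$a + tb$b) else NA_real_,
      prop_intra_positive = if (tb$c + tb$d > 0) tb$c / (tb$c + tb$d) else NA_real_
    ),
    class = "fisher_2x2"
  )
}

#' @importFrom stats qnorm
#' @export
print.fisher_2x2 <- function(x, ...) {
  cat("Two-sided Fisher's exact test (2x2)\n")
  cat(sprintf("  counts: a=%d b=%d c=%d d=%d\n", x$a, x$b, x$c, x$d))
  cat(sprintf(
    "  odds ratio = %.4g, p = %.4g, 95%% CI [%s] (%.3g, %.3g)\n",
    x$odds_ratio, x$p_value, x$ci_method, x$conf_low, x$conf_high
  ))
  cat(sprintf(
    "  positive fraction: extracellular %.1f%%, intracellular %.1f%%\n",
    100 * x$prop_extra_positive, 100 * x$prop_intra_positive
  ))
  invisible(x)
}

#' @method tidy fisher_2x2
#' @export
tidy.fisher_2x2 <- function(x, ...) {
  tibble(
    estimate = x$odds_ratio, p.value = x$p_value,
    conf.low = x$conf_low, conf.high = x$conf_high,
    method = paste0("fisher.exact.two.sided/ci.", x$ci_method)
  )
}

#' @method glance fisher_2x2
#' @export
glance.fisher_2x2 <- function(x, ...) {
  tibble(
    odds_ratio = x$odds_ratio, p.value = x$p_value,
    prop_extra_positive = x$prop_extra_positive,
    prop_intra_positive = x$prop_intra_positive,
    n = x$a + x$b + x$c + x$d
  )
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided rank-sum test via [stats::wilcox.test()]. The exact
#' permutation distribution is used when the smaller sample has at most 10
#' observations and the pooled data are tie-free; otherwise the normal
#' approximation with tie-corrected variance and continuity correction is
#' used. The method actually applied is recorded.
#'
#' @param x,y Numeric samples, each with at least 2 observations.
#' @return One-row tibble: `statistic` (Mann-Whitney U of `x`), `p_value`,
#'   `method` (`"exact"` or `"normal_approx"`), `n_x`, `n_y`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    abort("Each sample needs at least 2 observations.")
  }
  if (anyNA(x) || anyNA(y)) abort("Samples must not contain missing values.")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- min(length(x), length(y)) <= 10L && !ties
  if (length(unique(c(x, y))) == 1L) {
    # every pooled value tied: the rank-sum variance is 0 and any split is
    # as extreme as any other, so the two-sided p is 1 by convention
    return(tibble(
      statistic = length(x) * length(y) / 2, p_value = 1,
      method = "normal_approx", n_x = length(x), n_y = length(y)
    ))
  }
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  tibble(
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    method = if (exact) "exact" else "normal_approx",
    n_x = length(x), n_y = length(y)
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjustment: sort ascending, multiply `p_(i)` by
#' `m / i`, take the cumulative minimum from the largest downward, cap at 1
#' and restore input order (delegated to [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0) || any(p_values > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' Significance star labels
#'
#' `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05,
#' `""` otherwise — strict inequalities, so p = 0.05 gets no star.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of star labels.
#' @export
p_stars <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}
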