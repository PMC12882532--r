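#' Pairwise comparison of aggregate areas across conditions
#'
#' Compares every pair of conditions in an area table with the two-sided
#' Wilcoxon rank-sum test ([wilcoxon_rank_sum()]), adjusts the resulting
#' p-values across all pairs with the Benjamini-Hochberg procedure
#' ([bh_adjust()]), attaches star labels at the 0.05 / 0.01 / 0.001
#' cutoffs, and summarises each condition by its median and interquartile
#' range.
#'
#' @param table A data frame with columns `condition` and `area_nm2` (any
#'   further columns are ignored), e.g. from [measure_aggregates()] or
#'   [simulate_area_groups()].
#' @return An object of class `area_comparison`: a list with `pairs`
#'   (tibble: `condition_a`, `condition_b`, `n_a`, `n_b`, `p_value`,
#'   `p_adjusted`, `stars`, `method`) and `summary` (tibble: `condition`,
#'   `n`, `median_nm2`, `q25_nm2`, `q75_nm2`). Has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @examples
#' areas <- simulate_area_groups(
#'   data.frame(condition = c("A", "B"), n = 20,
#'              median_nm2 = c(99318, 56475), log_sd = 0.8),
#'   seed = 1
#' )
#' compare_area_groups(areas)
#' @export
compare_area_groups <- function(table) {
  table <- as_tibble(table)
  if (!all(c("condition", "area_nm2") %in% names(table))) {
    abort("`table` needs columns `condition` and `area_nm2`.")
  }
  counts <- base::table(factor(table$condition))
  if (length(counts) < 2L) {
    abort("At least two conditions are required.")
  }
  if (any(counts < 2L)) {
    abort(sprintf(
      "Each condition needs >= 2 records; too few in: %s.",
      paste(names(counts)[counts < 2L], collapse = ", ")
    ))
  }
  conds <- names(counts)
  pairs <- utils::combn(conds, 2L)
  tests <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    x <- table$area_nm2[table$condition == pairs[1, i]]
    y <- table$area_nm2[table$condition == pairs[2, i]]
    wt <- wilcoxon_rank_sum(x, y)
    tibble(
      condition_a = pairs[1, i], condition_b = pairs[2, i],
      n_a = length(x), n_b = length(y),
      p_value = wt$p_value, method = wt$method
    )
  })
  tests$p_adjusted <- bh_adjust(tests$p_value)
  tests$stars <- p_stars(tests$p_adjusted)
  tests <- tests[, c(
    "condition_a", "condition_b", "n_a", "n_b",
    "p_value", "p_adjusted", "stars", "method"
  )]

  summary <- table |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_nm2 = median(.data$area_nm2),
      q25_nm2 = unname(quantile(.data$area_nm2, 0.25)),
      q75_nm2 = unname(quantile(.data$area_nm2, 0.75)),
      .groups = "drop"
    )

  structure(
    list(pairs = tests, summary = summary, data = table[, c("condition", "area_nm2")]),
    class = "area_comparison"
  )
}

#' @export
print.area_comparison <- function(x, ...) {
  cat("Aggregate-area group comparison (rank-sum + Benjamini-Hochberg)\n\n")
  print(x$summary)
  cat("\n")
  print(x$pairs)
  invisible(x)
}

#' @method tidy area_comparison
#' @export
tidy.area_comparison <- function(x, ...) x$pairs

#' @method glance area_comparison
#' @export
glance.area_comparison <- function(x, ...) {
  tibble(
    n_conditions = nrow(x$summary),
    n_pairs = nrow(x$pairs),
    n_records = sum(x$summary$n),
    n_significant = sum(x$pairs$p_adjusted < 0.05)
  )
}

#' @describeIn compare_area_groups Jittered per-condition areas with the
#'   median and interquartile range overlaid, on a log10 axis.
#' @param object An `area_comparison`.
#' @param ... Unused.
#' @method autoplot area_comparison
#' @export
autoplot.area_comparison <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$condition, y = .data$area_nm2)) +
    ggplot2::geom_jitter(width = 0.18, alpha = 0.45, size = 0.9) +
    ggplot2::geom_pointrange(
      data = object$summary,
      ggplot2::aes(y = .data$median_nm2, ymin = .data$q25_nm2, ymax = .data$q75_nm2),
      colour = "red", linewidth = 0.7, fatten = 2
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = NULL, y = expression(Aggregate~area~(nm^2)),
      title = "Aggregate area by condition (median and IQR in red)"
    ) +
    ggplot2::theme_minimal()
}
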