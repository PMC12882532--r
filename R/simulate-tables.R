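#' Simulate marker-colocalization counts
#'
#' Draws Bernoulli marker status for `n_intra` intracellular and `n_extra`
#' extracellular aggregates (one binomial draw per group) and assembles the
#' 2x2 contingency table used by [fisher_exact_2x2()]. Under a fixed seed
#' the draws are reproducible; the intracellular group is drawn first, then
#' the extracellular group, each as a single `rbinom()` call.
#'
#' @param n_intra,n_extra Number of aggregates per location group.
#' @param p_intra,p_extra Marker-positive probability per group.
#' @param seed Integer seed.
#' @return A [contingency_table()] with `a` = extracellular positive,
#'   `b` = extracellular negative, `c` = intracellular positive,
#'   `d` = intracellular negative.
#' @export
simulate_colocalization <- function(n_intra, n_extra, p_intra, p_extra, seed = 1L) {
  check_number(n_intra, "n_intra", lower = 0, integer = TRUE)
  check_number(n_extra, "n_extra", lower = 0, integer = TRUE)
  check_number(p_intra, "p_intra", lower = 0, upper = 1)
  check_number(p_extra, "p_extra", lower = 0, upper = 1)
  check_number(seed, "seed", integer = TRUE)
  with_seed(seed, {
    pos_intra <- rbinom(1L, n_intra, p_intra)
    pos_extra <- rbinom(1L, n_extra, p_extra)
    contingency_table(
      a = pos_extra, b = n_extra - pos_extra,
      c = pos_intra, d = n_intra - pos_intra
    )
  })
}

#' Simulate per-condition aggregate-area samples
#'
#' Draws log-normally distributed areas for each condition — aggregate
#' areas are strictly positive and right-skewed, which a log-normal with
#' the stated median captures: `meanlog = log(median)`, `sdlog = log_sd`.
#' With `log_sd = 0` every sample equals the median exactly.
#'
#' @param groups A data frame (or tibble) with columns `condition`, `n`,
#'   `median_nm2` and `log_sd`, one row per condition.
#' @param seed Integer seed.
#' @return A tibble with columns `condition` and `area_nm2`, rows grouped
#'   in the order the conditions are given.
#' @examples
#' simulate_area_groups(
#'   data.frame(condition = c("1 DIV NB", "20 DIV NB"), n = 3,
#'              median_nm2 = c(99318, 56475), log_sd = 0.8),
#'   seed = 42
#' )
#' @export
simulate_area_groups <- function(groups, seed = 1L) {
  groups <- as_tibble(groups)
  required <- c("condition", "n", "median_nm2", "log_sd")
  missing <- setdiff(required, names(groups))
  if (length(missing)) {
    abort(sprintf("`groups` is missing column(s): %s.", paste(missing, collapse = ", ")))
  }
  if (any(groups$n < 1) || any(groups$n != round(groups$n))) {
    abort("Each group's `n` must be a positive whole number.")
  }
  if (any(groups$log_sd < 0) || any(groups$median_nm2 <= 0)) {
    abort("`log_sd` must be >= 0 and `median_nm2` > 0.")
  }
  check_number(seed, "seed", integer = TRUE)
  with_seed(seed, {
    purrr::pmap_dfr(groups, function(condition, n, median_nm2, log_sd, ...) {
      tibble(
        condition = as.character(condition),
        # sdlog = 0 must return the median *exactly*, not exp(log(median))
        area_nm2 = if (log_sd == 0) rep(median_nm2, n) else {
          rlnorm(n, meanlog = log(median_nm2), sdlog = log_sd)
        }
      )
    })
  })
}
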