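# Simulation output analysis: warm-up truncation, replication confidence
# intervals, validation against reference means, policy comparison.

#' MSER-m warm-up truncation
#'
#' Groups the series into consecutive batches of `m`, then for each
#' candidate truncation `d` (in batches) computes the marginal-standard-
#' error statistic `sum((z_j - mean)^2) / (k - d)^2` over the retained
#' batch means and returns the minimising `d`. Candidates are restricted
#' to the first half of the batched series (the usual safeguard against
#' spurious end-of-series minima); ties go to the smallest `d`.
#'
#' @param series Numeric output series (e.g. weekly KPI values).
#' @param m Batch size (default 2).
#' @return Object of class `mser_result`: list with `m`, `d_star`
#'   (truncation in batches) and `statistics` (tibble `d`, `value`).
#' @examples
#' mser(c(rep(100, 10), rep(0, 90)), m = 2)$d_star  # 5
#' @export
mser <- function(series, m = 2) {
  n <- length(series)
  if (n < 2 * m) stop("series must contain at least 2 * m points", call. = FALSE)
  k <- n %/% m
  z <- colMeans(matrix(series[seq_len(k * m)], nrow = m))
  dmax <- k %/% 2
  vals <- vapply(0:dmax, function(d) {
    zz <- z[(d + 1):k]
    sum((zz - mean(zz))^2) / (k - d)^2
  }, numeric(1))
  d_star <- which.min(vals) - 1L   # which.min returns the first minimum
  structure(list(m = as.integer(m), d_star = d_star,
                 statistics = tibble(d = 0:dmax, value = vals)),
            class = "mser_result")
}

#' @export
print.mser_result <- function(x, ...) {
  cat("<mser_result> m = ", x$m, ", optimal truncation d* = ", x$d_star,
      " batches (", x$d_star * x$m, " points)\n", sep = "")
  invisible(x)
}

#' Student-t replication confidence interval
#'
#' @param values One KPI value per independent replication (n >= 2).
#' @param level Confidence level (default 0.95).
#' @return One-row tibble with `mean`, `half_width`, `n`, `level`.
#' @examples
#' replication_ci(c(0, 2))  # half width 12.7062
#' @export
replication_ci <- function(values, level = 0.95) {
  n <- length(values)
  if (n < 2) stop("need at least two replications", call. = FALSE)
  hw <- qt(1 - (1 - level) / 2, n - 1) * sd(values) / sqrt(n)
  tibble(mean = mean(values), half_width = hw, n = n, level = level)
}

#' Confidence interval for the difference to a reference mean
#'
#' Validation against operational data: a t-interval for (simulated mean
#' minus reference). The simulation is flagged consistent with the
#' reference when the interval contains zero.
#'
#' @param sim_values Per-replication simulated means.
#' @param reference_mean Reference (e.g. operational) mean.
#' @param level Confidence level.
#' @return One-row tibble with `difference`, `lower`, `upper`, `level`,
#'   `consistent`.
#' @export
means_difference_ci <- function(sim_values, reference_mean, level = 0.95) {
  n <- length(sim_values)
  if (n < 2) stop("need at least two replications", call. = FALSE)
  d <- mean(sim_values) - reference_mean
  hw <- qt(1 - (1 - level) / 2, n - 1) * sd(sim_values) / sqrt(n)
  tibble(difference = d, lower = d - hw, upper = d + hw, level = level,
         consistent = (d - hw) <= 0 && 0 <= (d + hw))
}

#' Compare inventory policies under common random numbers
#'
#' Simulates every policy over the same replication seeds (schedule and
#' service randomness are both reused across policies), removes the
#' warm-up, and reports mean reschedule and alternative-tray percentages
#' with t-based half-widths per policy.
#'
#' @param instance A `css_instance`.
#' @param policies Named list of inventory policy tibbles.
#' @param n_reps Replications per policy (>= 1).
#' @param horizon_days Run length per replication (including warm-up).
#' @param warmup_days Warm-up discarded from every KPI.
#' @param seed Master seed; replication r uses seeds derived from
#'   `(seed, r)`, identical for all policies.
#' @param level Confidence level for the half-widths.
#' @return A `css_comparison` tibble: one row per policy with
#'   `total_inventory`, `reschedule_pct`, `reschedule_hw`,
#'   `alternative_pct`, `alternative_hw`, `trays_cleaned_per_week`.
#' @export
compare_policies <- function(instance, policies, n_reps = 5,
                             horizon_days = 140, warmup_days = 14,
                             seed = 1, level = 0.95) {
  stopifnot(n_reps >= 1, length(policies) >= 1, !is.null(names(policies)))
  schedules <- purrr::map(seq_len(n_reps), function(r) {
    generate_schedule(instance, horizon_days,
                      seed = derive_seed(seed, paste0("rep_sched_", r)))
  })
  rows <- purrr::imap_dfr(policies, function(policy, label) {
    kpis <- purrr::map_dfr(seq_len(n_reps), function(r) {
      res <- simulate_cycle(instance, schedules[[r]], policy,
                            warmup_days = warmup_days,
                            seed = derive_seed(seed, paste0("rep_sim_", r)),
                            log_moves = FALSE)
      compute_kpis(res)
    })
    hw <- function(x) {
      if (n_reps < 2) NA_real_ else
        qt(1 - (1 - level) / 2, n_reps - 1) * sd(x) / sqrt(n_reps)
    }
    total_q <- sum(policy$Q)
    tibble(
      policy = label,
      total_inventory = total_q,
      reschedule_pct = mean(kpis$reschedule_pct),
      reschedule_hw = hw(kpis$reschedule_pct),
      alternative_pct = mean(kpis$alternative_tray_pct),
      alternative_hw = hw(kpis$alternative_tray_pct),
      trays_cleaned_per_week = mean(kpis$trays_cleaned_per_week)
    )
  })
  class(rows) <- c("css_comparison", class(rows))
  attr(rows, "n_reps") <- n_reps
  attr(rows, "level") <- level
  rows
}
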