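# Shared fixtures built in code.

# Toy variant with reference-size machines (48-unit disinfectors at a 20%
# threshold, 30-tray autoclaves at 50%) and a second compatibility class,
# used for the capacity / threshold / purity audits.
toy_with_reference_machines <- function() {
  inst <- toy_instance()
  inst$machines <- default_resources()$machines
  inst$tray_types$compat_class[inst$tray_types$id == "B"] <- "eye"
  inst
}

# Generous policy: ten times the maximum daily demand seen in a table.
abundant_policy <- function(demand) {
  demand |>
    dplyr::group_by(tray_type) |>
    dplyr::summarise(Q = as.integer(pmax(1, 10 * max(count))), .groups = "drop")
}

# Hand-built daily-demand table for one tray type (class css_demand).
manual_demand <- function(counts_by_day, tray_type = "s") {
  d <- tibble::tibble(
    tray_type = tray_type,
    day = seq_along(counts_by_day) - 1L,
    weekday = weekday_of(seq_along(counts_by_day) - 1L),
    count = as.integer(counts_by_day)
  )
  class(d) <- c("css_demand", class(d))
  d
}

# Reconstruct per-(type, time) location totals from a move log and check
# the closed-loop conservation law sum_locations n_s(t) == Q_s throughout.
conservation_holds <- function(result) {
  mv <- result$moves
  Q <- result$policy
  for (ty in Q$tray_type) {
    sub <- mv[mv$tray_type == ty, ]
    bal <- setNames(rep(0L, 13), traycycle:::LOCATIONS)
    bal["sterile_storage"] <- Q$Q[Q$tray_type == ty]
    if (nrow(sub)) {
      for (i in seq_len(nrow(sub))) {
        bal[sub$from[i]] <- bal[sub$from[i]] - sub$n[i]
        bal[sub$to[i]] <- bal[sub$to[i]] + sub$n[i]
        if (any(bal < 0) || sum(bal) != Q$Q[Q$tray_type == ty]) return(FALSE)
      }
    }
    fin <- result$final_counts[result$final_counts$tray_type == ty, ]
    if (!all(bal[fin$location] == fin$n)) return(FALSE)
  }
  TRUE
}

# Poisson goodness-of-fit p-value with cells pooled to expected count >= 5.
poisson_gof_p <- function(x, lambda) {
  kmax <- max(x, ceiling(lambda + 6 * sqrt(lambda)))
  pk <- dpois(0:kmax, lambda)
  pk[kmax + 1] <- pk[kmax + 1] + ppois(kmax, lambda, lower.tail = FALSE)
  obs <- tabulate(x + 1L, kmax + 1L)
  n <- length(x)
  # pool adjacent cells until every expected count is at least 5
  grp <- integer(0); o <- numeric(0); e <- numeric(0)
  co <- 0; ce <- 0
  for (i in seq_along(pk)) {
    co <- co + obs[i]; ce <- ce + n * pk[i]
    if (ce >= 5) { o <- c(o, co); e <- c(e, ce); co <- 0; ce <- 0 }
  }
  if (ce > 0) { o[length(o)] <- o[length(o)] + co; e[length(e)] <- e[length(e)] + ce }
  stat <- sum((o - e)^2 / e)
  pchisq(stat, df = length(o) - 1, lower.tail = FALSE)
}
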