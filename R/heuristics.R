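# Tray base-stock sizing heuristics. All three consume demand generated by
# the schedule generator and return an inventory policy tibble
# (tray_type, Q) comparable with simulate_cycle().

emp_quantile <- function(x, alpha) {
  # smallest observed value whose empirical CDF reaches alpha
  sort(x)[ceiling(alpha * length(x))]
}

#' Base-stock levels from empirical weekday demand quantiles
#'
#' For each tray type, the stock level is the maximum over weekdays of the
#' empirical `alpha`-quantile of daily demand on that weekday, using the
#' inverse-CDF convention (smallest observed value `x` with
#' `F(x) >= alpha`).
#'
#' @param demand A `css_demand` table (see [demand_table()]).
#' @param alpha Quantile level in (0, 1].
#' @return Inventory policy tibble with `tray_type` and `Q`.
#' @examples
#' inst <- toy_instance()
#' dem <- demand_table(generate_schedule(inst, 28, seed = 1), inst)
#' base_stock(dem, 0.9)
#' @export
base_stock <- function(demand, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1) {
    stop("alpha must be in (0, 1]", call. = FALSE)
  }
  demand |>
    dplyr::group_by(.data$tray_type, .data$weekday) |>
    dplyr::summarise(q = emp_quantile(.data$count, alpha), .groups = "drop") |>
    dplyr::group_by(.data$tray_type) |>
    dplyr::summarise(Q = as.integer(max(.data$q)), .groups = "drop")
}

#' Estimate the mean tray cycle time from a simulation
#'
#' Sample mean of the post-warm-up tray makespans (CSS arrival to sterile
#' storage), in days, as needed by [fk_levels()].
#'
#' @param result A `css_sim_result`.
#' @param warmup_days Warm-up to discard (defaults to the run's value).
#' @return Mean cycle time in days.
#' @export
mean_cycle_days <- function(result, warmup_days = NULL) {
  warmup_days <- warmup_days %||% result$warmup_days
  mk <- result$makespan[result$makespan$completed >= warmup_days * 1440, ]
  if (!nrow(mk)) stop("no completed tray cycles after the warm-up", call. = FALSE)
  mean(mk$minutes) / 1440
}

#' Stock levels from daily demand and mean cycle time
#'
#' The cycle-time rule: `Q_s = ceiling(stat(d_s) * tau)`, where `stat` is
#' the mean, median or max of the daily demand for tray type `s` over all
#' days of the horizon and `tau` is the expected tray cycle time in days
#' (see [mean_cycle_days()]).
#'
#' @param demand A `css_demand` table.
#' @param mean_cycle_days Expected cycle time in days (> 0).
#' @param statistic One of `"mean"`, `"median"`, `"max"`.
#' @return Inventory policy tibble with `tray_type` and `Q`.
#' @export
fk_levels <- function(demand, mean_cycle_days,
                      statistic = c("mean", "median", "max")) {
  statistic <- match.arg(statistic)
  stopifnot(mean_cycle_days > 0)
  f <- switch(statistic, mean = mean, median = median, max = max)
  demand |>
    dplyr::group_by(.data$tray_type) |>
    dplyr::summarise(stat = f(.data$count), .groups = "drop") |>
    dplyr::mutate(Q = as.integer(ceiling(.data$stat * mean_cycle_days))) |>
    dplyr::select("tray_type", "Q")
}

#' Empirical per-period demand distributions
#'
#' Discretises the horizon into consecutive periods of `period_hours`
#' (starting at day 0, hour 0; nights and other quiet periods contribute
#' zero counts) and tabulates the empirical PMF of per-period demand for
#' each tray type. Demand events are the trays requested by each
#' scheduled surgery (preferred configuration, at surgery start) plus all
#' outpatient events; alternatively pass a prepared event tibble.
#'
#' @param x A `css_schedule`, or a tibble with columns `time` (absolute
#'   minutes) and `tray_type`.
#' @param instance The generating `css_instance` (required for a
#'   schedule; optional otherwise, used for the tray-type universe).
#' @param period_hours Period length in hours; must divide 24.
#' @param horizon_days Horizon (required when `x` is an event tibble).
#' @return Tibble with `tray_type`, `k` (demand per period) and `prob`;
#'   probabilities sum to 1 within each tray type.
#' @export
discretize_demand <- function(x, instance = NULL, period_hours = 4,
                              horizon_days = NULL) {
  if (24 %% period_hours != 0) stop("period_hours must divide 24", call. = FALSE)
  if (inherits(x, "css_schedule")) {
    horizon_days <- x$horizon_days
    s <- x$surgeries
    surg_events <- s |>
      dplyr::inner_join(instance$config_trays,
                        by = c("surgery_type", "config_id"),
                        relationship = "many-to-many") |>
      dplyr::mutate(time = .data$day * 1440 + .data$start_time) |>
      tidyr::uncount(.data$n) |>
      dplyr::select("time", "tray_type")
    events <- dplyr::bind_rows(surg_events,
                               x$outpatient[, c("time", "tray_type")])
    universe <- instance$tray_types$id
  } else {
    if (is.null(horizon_days)) stop("horizon_days required for event input",
                                    call. = FALSE)
    events <- x
    universe <- if (is.null(instance)) unique(x$tray_type) else instance$tray_types$id
  }
  n_periods <- horizon_days * 24 / period_hours
  period_min <- period_hours * 60
  counts <- events |>
    dplyr::mutate(period = pmin(floor(.data$time / period_min), n_periods - 1)) |>
    dplyr::count(.data$tray_type, .data$period)
  per_type <- counts |>
    dplyr::group_by(.data$tray_type) |>
    dplyr::summarise(tab = list(table(factor(.data$n))),
                     busy = dplyr::n(), .groups = "drop")
  out <- purrr::map_dfr(universe, function(ty) {
    row <- per_type[per_type$tray_type == ty, ]
    if (!nrow(row) || row$busy == 0) {
      return(tibble(tray_type = ty, k = 0L, prob = 1))
    }
    tab <- row$tab[[1]]
    ks <- as.integer(names(tab))
    n_busy <- row$busy
    n_zero <- n_periods - n_busy
    k <- c(if (n_zero > 0) 0L, ks)
    cnt <- c(if (n_zero > 0) n_zero, as.integer(tab))
    tibble(tray_type = ty, k = k, prob = cnt / n_periods)
  })
  out
}

# -- Markov-chain service-level method ---------------------------------------

pmf_tail <- function(p) rev(cumsum(rev(p)))   # tail[i] = P(d >= i - 1)

p_ge <- function(tail, x) {
  K <- length(tail) - 1L
  if (x <= 0) 1 else if (x > K) 0 else tail[x + 1L]
}
p_eq <- function(p, x) {
  if (x < 0 || x > length(p) - 1L) 0 else p[x + 1L]
}

#' Steady state of the two-state-inventory tray chain
#'
#' Models one tray type over equal periods: inventory is either sterile
#' (ready to use) or dirty; trays used in period `k` are processed in
#' `k + 1` and usable again at `k + 2`. With i.i.d. per-period demand the
#' sterile on-hand level `u_k` is a discrete-time Markov chain on
#' `{0, ..., Q}`; its boundary probabilities have a closed form and the
#' interior follows by a two-ended recursion. The chain's transition
#' matrix is available from [di_transition_matrix()] for cross-checks.
#'
#' @param pmf Numeric probability vector over demand values `0..K`
#'   (`pmf[i]` is `P(d = i - 1)`), or a tibble with columns `k`, `prob`.
#' @param Q Total inventory of the tray type (>= 1).
#' @return Object of class `di_fit`: list with `Q`, `pi` (stationary
#'   probabilities of `u = 0..Q`) and `service_level`.
#' @examples
#' di_steady_state(c(0.5, 0.5), Q = 1)$pi  # c(1/3, 2/3)
#' @export
di_steady_state <- function(pmf, Q) {
  p <- as_pmf_vector(pmf)
  stopifnot(Q >= 1)
  tail <- pmf_tail(p)
  pi <- rep(NA_real_, Q + 1)
  den <- function(i) 1 - p_ge(tail, Q - i) * p_ge(tail, i + 1)
  d0 <- den(0)
  if (abs(d0) < 1e-12) {
    stop("degenerate demand chain: denominator vanishes at boundary",
         call. = FALSE)
  }
  pi[1] <- p_eq(p, 0) * p_ge(tail, Q) / d0
  pi[Q + 1] <- p_eq(p, 0) / d0
  s_low <- pi[1]       # sum of pi_0 .. pi_{i-1}
  s_high <- pi[Q + 1]  # sum of pi_{Q+1-i} .. pi_Q
  i <- 1L
  while (Q - i >= i) {
    di <- den(i)
    if (abs(di) < 1e-12) {
      stop("degenerate demand chain: denominator vanishes at i = ", i,
           call. = FALSE)
    }
    pi_hi <- p_eq(p, i) / di * (1 - s_low) +
      p_ge(tail, i + 1) * p_eq(p, Q - i) / di * s_high
    pi_lo <- p_ge(tail, Q - i) * p_eq(p, i) / di * (1 - s_low) +
      p_eq(p, Q - i) / di * s_high
    if (Q - i == i) {
      pi[i + 1] <- pi_hi
      break
    }
    pi[Q - i + 1] <- pi_hi
    pi[i + 1] <- pi_lo
    s_high <- s_high + pi_hi
    s_low <- s_low + pi_lo
    i <- i + 1L
  }
  drift <- abs(sum(pi) - 1)
  if (is.na(drift) || drift > 1e-6) {
    stop("steady-state probabilities drifted from unit mass (", drift, ")",
         call. = FALSE)
  }
  pi <- pmax(pi, 0)
  pi <- pi / sum(pi)
  beta <- 1 - sum(pi * vapply(seq_len(Q + 1) - 1L,
                              function(i) p_ge(tail, i + 1), numeric(1)))
  structure(list(Q = as.integer(Q), pi = pi, service_level = beta, pmf = p),
            class = "di_fit")
}

#' @export
print.di_fit <- function(x, ...) {
  cat("<di_fit> Q = ", x$Q, ", service level = ",
      format(x$service_level, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Service level for a tray type at inventory Q
#'
#' Probability that per-period demand does not exceed the ready-to-use
#' sterile inventory, in steady state:
#' `beta = 1 - sum_i pi_i(Q) P(d > i)`.
#'
#' @inheritParams di_steady_state
#' @return Service level in `[0, 1]`.
#' @export
di_service <- function(pmf, Q) {
  di_steady_state(pmf, Q)$service_level
}

#' Transition matrix of the sterile-inventory chain
#'
#' Builds the `(Q+1) x (Q+1)` transition matrix of the chain explicitly
#' from the demand PMF: from state `u = i`, demand `d >= i` leads to
#' `Q - i`, demand `d < i` leads to `Q - d`. Useful as an independent
#' cross-check of the closed-form/recursive steady state.
#'
#' @inheritParams di_steady_state
#' @return Row-stochastic matrix with states `0..Q` in order.
#' @export
di_transition_matrix <- function(pmf, Q) {
  p <- as_pmf_vector(pmf)
  tail <- pmf_tail(p)
  P <- matrix(0, Q + 1, Q + 1)
  for (i in 0:Q) {
    P[i + 1, Q - i + 1] <- P[i + 1, Q - i + 1] + p_ge(tail, i)
    if (i >= 1) {
      for (d in 0:min(i - 1, length(p) - 1L)) {
        P[i + 1, Q - d + 1] <- P[i + 1, Q - d + 1] + p[d + 1]
      }
    }
  }
  P
}

#' Stationary distribution of a finite Markov chain
#'
#' Solves `pi P = pi`, `sum(pi) = 1` by a least-squares linear solve.
#'
#' @param P Row-stochastic transition matrix.
#' @return Stationary probability vector.
#' @export
stationary_distribution <- function(P) {
  n <- nrow(P)
  A <- rbind(t(P) - diag(n), rep(1, n))
  b <- c(rep(0, n), 1)
  pi <- qr.solve(A, b)
  pmax(pi, 0) / sum(pmax(pi, 0))
}

as_pmf_vector <- function(pmf) {
  if (is.data.frame(pmf)) {
    K <- max(pmf$k)
    p <- rep(0, K + 1)
    p[pmf$k + 1] <- pmf$prob
  } else {
    p <- as.numeric(pmf)
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("pmf must be nonnegative and sum to 1", call. = FALSE)
  }
  p
}

#' Inventory levels meeting a target service level
#'
#' For each tray type, the smallest `Q >= 1` whose steady-state service
#' level (see [di_service()]) reaches `beta`; tray types with zero demand
#' get `Q = 0`. The search is bounded by twice the maximum demand support;
#' an unreachable target raises an error naming the tray type.
#'
#' @param pmf Per-type demand PMFs as returned by [discretize_demand()].
#' @param beta Target service level in (0, 1).
#' @return Inventory policy tibble with `tray_type` and `Q`.
#' @export
di_levels <- function(pmf, beta) {
  stopifnot(beta > 0, beta < 1)
  purrr::map_dfr(unique(pmf$tray_type), function(ty) {
    sub <- pmf[pmf$tray_type == ty, ]
    K <- max(sub$k[sub$prob > 0])
    if (K == 0) return(tibble(tray_type = ty, Q = 0L))
    p <- as_pmf_vector(sub[, c("k", "prob")])
    bound <- max(2L, 2L * K)
    for (Q in seq_len(bound)) {
      if (di_service(p, Q) >= beta) return(tibble(tray_type = ty, Q = as.integer(Q)))
    }
    stop("service target ", beta, " unreachable within Q <= ", bound,
         " for tray type '", ty, "'", call. = FALSE)
  })
}
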