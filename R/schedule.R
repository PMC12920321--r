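#' Evenly spread start times over the OR day
#'
#' With `n` surgeries in window `(open, close)` the i-th start time is
#' `open + (i - 1) * (close - open) / n`: the first surgery starts when
#' the window opens and spacing is uniform.
#'
#' @param n Number of surgeries (>= 0).
#' @param window Length-2 numeric `(open, close)`, minutes from midnight.
#' @return Numeric vector of `n` start times.
#' @examples
#' spread_start_times(4, c(480, 960))
#' @export
spread_start_times <- function(n, window) {
  stopifnot(n >= 0, length(window) == 2, window[1] < window[2])
  if (n == 0) return(numeric(0))
  window[1] + (seq_len(n) - 1) * (window[2] - window[1]) / n
}

#' Worst-fit operating-room choice
#'
#' Returns the room with the smallest accumulated expected surgery
#' duration (the room with the most remaining time); ties are broken by
#' the lowest room position.
#'
#' @param room_loads Numeric vector of accumulated expected durations,
#'   one per room, optionally named.
#' @return The name (if named) or index of the chosen room.
#' @examples
#' worst_fit_room(c(OR1 = 100, OR2 = 50, OR3 = 80))
#' @export
worst_fit_room <- function(room_loads) {
  if (!length(room_loads)) stop("no operating rooms", call. = FALSE)
  i <- which.min(room_loads)
  if (!is.null(names(room_loads))) names(room_loads)[i] else i
}

#' Generate a surgery schedule
#'
#' For every day of the horizon and every surgery type, the number of
#' surgeries is a Poisson draw with that weekday's rate; each surgery
#' receives a lognormal realized duration and a preferred tray
#' configuration sampled by configuration probability. Surgeries are
#' assigned to operating rooms by a worst-fit rule on accumulated expected
#' duration (lognormal mean), then shuffled within each room-day and given
#' evenly spaced start times (see [spread_start_times()]). Outpatient
#' demand is attached via [generate_outpatient_demand()].
#'
#' Three independent random streams (counts; durations and
#' configurations; shuffling) are derived from `seed`, so demand
#' randomness can be reused while service randomness changes.
#'
#' @param instance A `css_instance`.
#' @param horizon_days Days to generate (day 0 = Monday).
#' @param seed Integer master seed.
#' @return A `css_schedule`: list with `surgeries` (tibble: `day`, `room`,
#'   `start_time`, `surgery_type`, `realized_duration`, `config_id`,
#'   `gen_order`), `outpatient` (tibble: `time`, `tray_type`) and
#'   `horizon_days`.
#' @export
generate_schedule <- function(instance, horizon_days, seed = 1) {
  stopifnot(horizon_days >= 1)
  st <- instance$surgery_types
  rates <- instance$surgery_rates
  if (any(rates$rate < 0, na.rm = TRUE) || anyNA(rates$rate)) {
    stop("negative or missing surgery rate", call. = FALSE)
  }
  bad <- setdiff(rates$weekday, weekdays_short())
  if (length(bad)) stop("unknown weekday key '", bad[1], "'", call. = FALSE)

  # rate lookup matrix: surgery type x weekday
  rate_mat <- matrix(0, nrow(st), 7, dimnames = list(st$id, weekdays_short()))
  rate_mat[cbind(match(rates$surgery_type, st$id),
                 match(rates$weekday, weekdays_short()))] <- rates$rate

  days <- seq_len(horizon_days) - 1L
  wd_idx <- days %% 7L + 1L

  # stream 1: daily Poisson counts per surgery type
  set.seed(derive_seed(seed, "counts"))
  lam <- rate_mat[, wd_idx, drop = FALSE]           # types x days
  counts <- rpois(length(lam), as.vector(lam))
  cnt_mat <- matrix(counts, nrow(st), horizon_days)

  total <- sum(cnt_mat)
  if (total == 0) {
    surgeries <- tibble(day = integer(), room = character(),
                        start_time = numeric(), surgery_type = character(),
                        realized_duration = numeric(), config_id = integer(),
                        gen_order = integer())
  } else {
    type_idx <- rep(rep(seq_len(nrow(st)), horizon_days), as.vector(cnt_mat))
    day <- rep(rep(days, each = nrow(st)), as.vector(cnt_mat))

    # stream 2: realized durations and preferred configurations
    set.seed(derive_seed(seed, "service"))
    dur <- rlnorm(total, st$duration_mu[type_idx], st$duration_sigma[type_idx])
    cfg_list <- split(instance$configurations,
                      instance$configurations$surgery_type)
    config_id <- integer(total)
    for (i in seq_len(nrow(st))) {
      sel <- which(type_idx == i)
      if (!length(sel)) next
      cf <- cfg_list[[st$id[i]]]
      config_id[sel] <- if (nrow(cf) == 1) cf$config_id else {
        cf$config_id[sample.int(nrow(cf), length(sel), replace = TRUE,
                                prob = cf$probability)]
      }
    }

    exp_dur <- lognormal_mean(st$duration_mu, st$duration_sigma)
    rooms <- instance$operating_rooms
    room_of <- integer(total)
    gen_order <- integer(total)
    E <- numeric(length(rooms))
    cur_day <- -1L
    ord <- 0L
    for (i in seq_len(total)) {                      # worst-fit packing
      if (day[i] != cur_day) {
        E[] <- 0; cur_day <- day[i]; ord <- 0L
      }
      r <- which.min(E)
      room_of[i] <- r
      ord <- ord + 1L
      gen_order[i] <- ord
      E[r] <- E[r] + exp_dur[type_idx[i]]
    }

    # stream 3: shuffle within each room-day, then spread start times
    set.seed(derive_seed(seed, "shuffle"))
    u <- runif(total)
    grp <- day * length(rooms) + (room_of - 1L)
    o <- order(grp, u)
    start_time <- numeric(total)
    w <- instance$or_day_window
    grp_sizes <- rle(grp[o])$lengths
    pos <- sequence(grp_sizes)
    n_in_grp <- rep(grp_sizes, grp_sizes)
    start_time[o] <- w[1] + (pos - 1) * (w[2] - w[1]) / n_in_grp

    surgeries <- tibble(
      day = as.integer(day), room = rooms[room_of], start_time = start_time,
      surgery_type = st$id[type_idx], realized_duration = dur,
      config_id = config_id, gen_order = gen_order
    ) |>
      dplyr::arrange(.data$day, .data$room, .data$start_time)
  }

  outpatient <- generate_outpatient_demand(instance, horizon_days,
                                           derive_seed(seed, "outpatient"))
  structure(list(surgeries = surgeries, outpatient = outpatient,
                 horizon_days = as.integer(horizon_days)),
            class = "css_schedule")
}

#' @export
print.css_schedule <- function(x, ...) {
  cat("<css_schedule> ", x$horizon_days, " days, ",
      nrow(x$surgeries), " surgeries, ",
      nrow(x$outpatient), " outpatient events\n", sep = "")
  invisible(x)
}

#' Generate outpatient tray demand
#'
#' Homogeneous Poisson events per outpatient tray type (instance tray
#' types with `source == "outpatient"`), at `instance$outpatient_rate`
#' events per day, placed uniformly within the daily outpatient window.
#'
#' @param instance A `css_instance`.
#' @param horizon_days Days to generate.
#' @param seed Integer seed.
#' @return Tibble with `time` (absolute minutes) and `tray_type`, sorted
#'   by time.
#' @export
generate_outpatient_demand <- function(instance, horizon_days, seed = 1) {
  types <- instance$tray_types$id[instance$tray_types$source == "outpatient"]
  rate <- instance$outpatient_rate
  stopifnot(rate >= 0)
  if (!length(types) || rate == 0) {
    return(tibble(time = numeric(), tray_type = character()))
  }
  set.seed(derive_seed(seed, "outpatient_events"))
  w <- instance$outpatient_window
  n_cells <- length(types) * horizon_days
  counts <- rpois(n_cells, rate)
  tray_type <- rep(rep(types, each = horizon_days), counts)
  day <- rep(rep(seq_len(horizon_days) - 1L, length(types)), counts)
  time <- day * 1440 + runif(sum(counts), w[1], w[2])
  tibble(time = time, tray_type = tray_type) |>
    dplyr::arrange(.data$time)
}

#' Tabulate tray demand per day
#'
#' Counts how many trays of each type are requested on each day: the
#' preferred configurations of all scheduled surgeries plus all outpatient
#' events. The grid is complete (every tray type x every day of the
#' horizon), so quiet days contribute zero counts to the empirical
#' weekday distributions used by the sizing heuristics.
#'
#' @param schedule A `css_schedule`.
#' @param instance The `css_instance` the schedule was generated from.
#' @return A `css_demand` tibble with `tray_type`, `day`, `weekday`,
#'   `count`.
#' @export
demand_table <- function(schedule, instance) {
  stopifnot(inherits(schedule, "css_schedule"))
  h <- schedule$horizon_days
  s <- schedule$surgeries
  from_surg <- if (nrow(s)) {
    s |>
      dplyr::inner_join(instance$config_trays,
                        by = c("surgery_type", "config_id"),
                        relationship = "many-to-many") |>
      dplyr::group_by(.data$tray_type, .data$day) |>
      dplyr::summarise(count = sum(.data$n), .groups = "drop")
  } else {
    tibble(tray_type = character(), day = integer(), count = integer())
  }
  from_out <- if (nrow(schedule$outpatient)) {
    schedule$outpatient |>
      dplyr::mutate(day = as.integer(.data$time %/% 1440)) |>
      dplyr::count(.data$tray_type, .data$day, name = "count")
  } else {
    tibble(tray_type = character(), day = integer(), count = integer())
  }
  out <- tidyr::expand_grid(tray_type = instance$tray_types$id,
                            day = seq_len(h) - 1L) |>
    dplyr::left_join(dplyr::bind_rows(from_surg, from_out) |>
                       dplyr::group_by(.data$tray_type, .data$day) |>
                       dplyr::summarise(count = sum(.data$count),
                                        .groups = "drop"),
                     by = c("tray_type", "day")) |>
    dplyr::mutate(count = as.integer(dplyr::coalesce(.data$count, 0L)),
                  weekday = weekday_of(.data$day)) |>
    dplyr::select("tray_type", "day", "weekday", "count")
  class(out) <- c("css_demand", class(out))
  attr(out, "horizon_days") <- h
  out
}

#' Check the worst-fit property of a generated schedule
#'
#' Replays the room-assignment decisions of a schedule in generation
#' order and verifies that each surgery went to a room with minimal
#' accumulated expected duration at decision time (ties to the lowest
#' room position).
#'
#' @param schedule A `css_schedule`.
#' @param instance The generating `css_instance`.
#' @return `TRUE` if every assignment was worst-fit, else `FALSE`.
#' @export
check_worst_fit <- function(schedule, instance) {
  s <- schedule$surgeries
  if (!nrow(s)) return(TRUE)
  st <- instance$surgery_types
  exp_dur <- setNames(lognormal_mean(st$duration_mu, st$duration_sigma), st$id)
  rooms <- instance$operating_rooms
  s <- s[order(s$day, s$gen_order), ]
  E <- numeric(length(rooms))
  cur_day <- -1L
  for (i in seq_len(nrow(s))) {
    if (s$day[i] != cur_day) { E[] <- 0; cur_day <- s$day[i] }
    r <- match(s$room[i], rooms)
    if (E[r] > min(E) || r != which.min(E)) return(FALSE)
    E[r] <- E[r] + exp_dur[[s$surgery_type[i]]]
  }
  TRUE
}
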