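# Discrete-event engine for the closed tray cycle:
# surgery -> (use) -> [batch buffer ->] pre-clean queue -> pre-clean ->
# disinfector queue -> disinfector (load/charge/unload) -> assembly ->
# wrapping -> autoclave queue -> autoclave (load/charge) -> sterile storage.
# All queues are FIFO with infinite capacity; manual stages need one free
# staff member of the mapped team plus a free workstation slot; machines
# only start once they can be filled to their start threshold.

LOCATIONS <- c("sterile_storage", "in_use", "batch_buffer",
               "preclean_queue", "preclean", "disinfect_queue", "disinfector",
               "assembly_queue", "assembly", "wrap_queue", "wrap",
               "autoclave_queue", "autoclave")

# -- charge building ---------------------------------------------------------

# FIFO scan with layer bookkeeping; returns positions (1-based, increasing)
# of the selected trays, or integer(0) when the threshold cannot be met.
# The charge's class is that of its first selected tray: candidate classes
# are tried in order of first appearance in the queue, and the first class
# whose packed charge reaches the threshold wins (a head-of-queue tray of a
# low-volume class must not stall charges of the other classes).
charge_select_disinfector <- function(units, classes, capacity,
                                      layers, layer_units, alpha) {
  n <- length(units)
  if (n == 0) return(integer(0))
  for (cls in unique(classes)) {
    rem <- rep(layer_units, layers)
    sel <- integer(0)
    for (i in seq_len(n)) {
      if (classes[i] != cls) next
      u <- units[i]
      j <- which(rem >= u)
      if (!length(j)) next     # does not fit any layer remainder: skip
      rem[j[1]] <- rem[j[1]] - u
      sel <- c(sel, i)
      if (!any(rem >= 1)) break
    }
    if (sum(units[sel]) + 1e-9 >= alpha * capacity) return(sel)
  }
  integer(0)
}

charge_select_autoclave <- function(n_queued, capacity, alpha) {
  if (n_queued + 1e-9 < alpha * capacity) return(0L)
  as.integer(min(n_queued, capacity))
}

#' Build a disinfector charge from a FIFO queue
#'
#' Scans the queue in FIFO order. The charge's compatibility class is that
#' of the first tray; each selected tray is placed on the first rack layer
#' with enough remaining size units; trays of another class or that fit no
#' layer are skipped. The charge is only formed when the selected trays
#' fill at least `start_threshold * capacity` size units.
#'
#' @param queue Tibble of queued trays in FIFO order, with columns
#'   `size_units` and `compat_class` (other columns are carried through).
#' @param spec One-row tibble with `capacity`, `layers`, `layer_units`,
#'   `start_threshold` (see the `machines` slot of a `css_instance`).
#' @return The selected rows of `queue` (with a `position` column), or
#'   `NULL` when no admissible charge meets the threshold.
#' @export
build_disinfector_charge <- function(queue, spec) {
  sel <- charge_select_disinfector(queue$size_units, queue$compat_class,
                                   spec$capacity, spec$layers,
                                   spec$layer_units, spec$start_threshold)
  if (!length(sel)) return(NULL)
  out <- queue[sel, , drop = FALSE]
  out$position <- sel
  out
}

#' Build an autoclave charge from a FIFO queue
#'
#' Pure FIFO: the first `min(queue length, capacity)` trays form the
#' charge, provided the queue holds at least `start_threshold * capacity`
#' trays.
#'
#' @param queue Tibble of queued trays in FIFO order.
#' @param spec One-row tibble with `capacity` and `start_threshold`.
#' @return The selected rows of `queue` (with `position`), or `NULL`.
#' @export
build_autoclave_charge <- function(queue, spec) {
  k <- charge_select_autoclave(nrow(queue), spec$capacity, spec$start_threshold)
  if (k == 0L) return(NULL)
  out <- queue[seq_len(k), , drop = FALSE]
  out$position <- seq_len(k)
  out
}

#' Pick a feasible tray configuration for a surgery
#'
#' The preferred configuration is taken when all its trays are in sterile
#' storage; otherwise the remaining configurations of the surgery type are
#' tried in descending probability and the first fully available one is
#' used as an alternative. Waiting and rescheduling (the two-hour rule)
#' are handled by the simulator, which re-runs this check on every
#' restock.
#'
#' @param instance A `css_instance`.
#' @param surgery_type Surgery type id.
#' @param preferred_config Preferred configuration id.
#' @param stock Named integer vector of sterile-storage counts per tray
#'   type.
#' @return List with `outcome` ("preferred", "alternative" or "none") and
#'   `config_id` (NA when none is feasible).
#' @export
select_configuration <- function(instance, surgery_type, preferred_config,
                                 stock) {
  cfg <- instance$configurations[
    instance$configurations$surgery_type == surgery_type, ]
  cfg <- cfg[order(-cfg$probability, cfg$config_id), ]
  avail <- function(cid) {
    tr <- instance$config_trays[
      instance$config_trays$surgery_type == surgery_type &
        instance$config_trays$config_id == cid, ]
    all(stock[tr$tray_type] >= tr$n)
  }
  if (avail(preferred_config)) {
    return(list(outcome = "preferred", config_id = preferred_config))
  }
  for (cid in setdiff(cfg$config_id, preferred_config)) {
    if (avail(cid)) return(list(outcome = "alternative", config_id = cid))
  }
  list(outcome = "none", config_id = NA_integer_)
}

# -- main engine -------------------------------------------------------------

#' Simulate the closed tray cycle
#'
#' Runs the discrete-event simulation of one instance under a given
#' surgery schedule and tray inventory policy. The system is closed: the
#' policy's `Q` trays per type start in sterile storage and circulate;
#' nothing is created or destroyed. Surgeries consume sterile trays
#' (preferred configuration if available, else the most likely feasible
#' alternative); a surgery whose demand cannot be met keeps retrying on
#' every restock and is rescheduled after 120 minutes. Used trays return
#' to the CSS at surgery start + realized duration (batched sources
#' accumulate in a buffer released at the batch insertion times) and flow
#' through pre-cleaning, disinfection, assembly, wrapping and
#' sterilisation back to storage.
#'
#' @param instance A `css_instance`.
#' @param schedule A `css_schedule` generated from the same instance.
#' @param policy Tibble with `tray_type` and `Q` covering every tray type.
#' @param warmup_days Default warm-up carried into [compute_kpis()].
#' @param seed Integer seed for all service-time randomness; identical
#'   inputs and seed give identical event logs.
#' @param log_moves Record every tray movement (needed for conservation
#'   audits; disable for long experiment runs).
#' @param disinfector_load_team Team performing disinfector loading,
#'   `"pre_cleaning"` (default) or `"post_cleaning"`.
#' @return A `css_sim_result` list: `weekly` KPI series, per-`surgeries`
#'   outcomes, `makespan` samples (CSS arrival to sterile storage),
#'   `charges` records, `outpatient` service log, `moves` event log (or
#'   `NULL`), `final_counts` per (tray type, location), plus run metadata.
#' @export
simulate_cycle <- function(instance, schedule, policy, warmup_days = 42,
                           seed = 1, log_moves = TRUE,
                           disinfector_load_team = "pre_cleaning") {
  stopifnot(inherits(instance, "css_instance"), inherits(schedule, "css_schedule"))
  tt <- instance$tray_types
  missing_q <- setdiff(tt$id, policy$tray_type)
  if (length(missing_q)) {
    stop("policy is missing tray type(s): ", paste(missing_q, collapse = ", "),
         call. = FALSE)
  }
  if (!all(schedule$surgeries$surgery_type %in% instance$surgery_types$id)) {
    stop("schedule references surgery types unknown to the instance", call. = FALSE)
  }

  S <- nrow(tt)
  type_ids <- tt$id
  units <- as.integer(tt$size_units)
  compat <- as.integer(factor(tt$compat_class))
  compat_lab <- as.character(tt$compat_class)
  batched <- tt$source %in% instance$batch_schedule$batched_sources
  Q <- as.integer(policy$Q[match(type_ids, policy$tray_type)])
  if (anyNA(Q) || any(Q < 0)) stop("policy Q must be >= 0 for every tray type",
                                   call. = FALSE)

  h <- schedule$horizon_days
  end_time <- h * 1440
  nweeks <- ceiling(h / 7)

  # configurations per surgery type, descending probability
  cfg_by_type <- list()
  for (oid in instance$surgery_types$id) {
    cf <- instance$configurations[instance$configurations$surgery_type == oid, ]
    cf <- cf[order(-cf$probability, cf$config_id), ]
    cfg_by_type[[oid]] <- lapply(cf$config_id, function(cid) {
      tr <- instance$config_trays[
        instance$config_trays$surgery_type == oid &
          instance$config_trays$config_id == cid, ]
      list(cid = cid, ty = match(tr$tray_type, type_ids), n = as.integer(tr$n))
    })
  }

  sg <- schedule$surgeries
  n_surg <- nrow(sg)
  s_type <- sg$surgery_type
  s_cfg <- sg$config_id
  s_day <- sg$day
  s_abs <- sg$day * 1440 + sg$start_time
  s_dur <- sg$realized_duration

  op <- schedule$outpatient
  n_out <- nrow(op)
  o_time <- op$time
  o_ty <- match(op$tray_type, type_ids)

  # staffing: headcount per (weekday, minute-of-day) and team
  HC <- list(matrix(0L, 7, 1440), matrix(0L, 7, 1440))
  team_id <- c(pre_cleaning = 1L, post_cleaning = 2L)
  sh <- instance$staff_shifts
  for (i in seq_len(nrow(sh))) {
    tm <- team_id[[sh$team[i]]]
    d <- match(sh$weekday[i], weekdays_short())
    a <- floor(sh$start[i]) + 1L
    b <- floor(sh$end[i])
    HC[[tm]][d, a:b] <- HC[[tm]][d, a:b] + sh$headcount[i]
  }
  hc_at <- function(team, t) {
    d <- (floor(t / 1440) %% 7) + 1L
    m <- floor(t %% 1440) + 1L
    HC[[team]][d, m]
  }

  ws <- instance$workstations
  st_row <- match(c("pre_clean", "assemble", "wrap"), ws$kind)
  st_slots <- as.integer(ws$count[st_row] * ws$capacity[st_row])
  st_mu <- ws$service_mu[st_row]
  st_sigma <- ws$service_sigma[st_row]
  st_team <- c(1L, 2L, 2L)   # pre-clean by pre team; assembly/wrap by post team

  mc <- instance$machines
  dis_spec <- mc[mc$kind == "disinfector", ]
  aut_spec <- mc[mc$kind == "autoclave", ]
  stopifnot(nrow(dis_spec) == 1, nrow(aut_spec) == 1)
  n_dis <- dis_spec$count
  n_aut <- aut_spec$count
  m_kind <- c(rep(1L, n_dis), rep(2L, n_aut))
  n_mach <- length(m_kind)
  m_state <- rep(0L, n_mach)   # 0 idle, 1 loading, 2 running, 3 await unload, 4 unloading
  m_toks <- vector("list", n_mach)
  dis_load_team <- team_id[[disinfector_load_team]]

  # tray tokens
  stock <- as.integer(Q)
  tok_type <- integer(0); tok_css <- numeric(0); tok_loc <- integer(0)
  n_tok <- 0L

  q_pre <- integer(0); q_dis <- integer(0); q_asm <- integer(0)
  q_wrap <- integer(0); q_aut <- integer(0); batch_buf <- integer(0)
  busy_staff <- c(0L, 0L)
  st_busy <- c(0L, 0L, 0L)

  # time-average queue-length accounting, split by week
  qint <- matrix(0, 5, nweeks)
  qlast <- rep(0, 5)
  q_len <- function(k) switch(k, length(q_pre), length(q_dis), length(q_asm),
                              length(q_wrap), length(q_aut))
  add_q_time <- function(k, t1) {
    t0 <- qlast[k]
    if (t1 > t0) {
      len <- q_len(k)
      if (len > 0) {
        w0 <- floor(t0 / 10080) + 1
        w1 <- floor((t1 - 1e-9) / 10080) + 1
        if (w0 == w1) {
          if (w0 <= nweeks) qint[k, w0] <<- qint[k, w0] + len * (t1 - t0)
        } else {
          for (w in w0:min(w1, nweeks)) {
            lo <- max(t0, (w - 1) * 10080); hi <- min(t1, w * 10080)
            qint[k, w] <<- qint[k, w] + len * (hi - lo)
          }
        }
      }
      qlast[k] <<- t1
    }
  }

  # move log
  mv_t <- numeric(0); mv_from <- integer(0); mv_to <- integer(0)
  mv_ty <- integer(0); mv_n <- integer(0); mvn <- 0L
  log_move <- function(t, from, to, ty, n) {
    if (!log_moves) return(invisible())
    mvn <<- mvn + 1L
    mv_t[mvn] <<- t; mv_from[mvn] <<- from; mv_to[mvn] <<- to
    mv_ty[mvn] <<- ty; mv_n[mvn] <<- n
  }
  route_tokens <- function(toks, from, to, t) {
    tok_loc[toks] <<- to
    if (log_moves) {
      tb <- tabulate(tok_type[toks], S)
      for (ty in which(tb > 0L)) log_move(t, from, to, ty, tb[ty])
    }
  }

  # event heap keyed by (time, insertion sequence)
  ht <- numeric(256); hk <- integer(256); h1 <- integer(256); h2 <- integer(256)
  hs <- integer(256); hn <- 0L; hseq <- 0L
  heap_less <- function(a, b) ht[a] < ht[b] || (ht[a] == ht[b] && hs[a] < hs[b])
  heap_push <- function(t, kind, i1 = 0L, i2 = 0L) {
    hn <<- hn + 1L; hseq <<- hseq + 1L
    ht[hn] <<- t; hk[hn] <<- kind; h1[hn] <<- i1; h2[hn] <<- i2; hs[hn] <<- hseq
    i <- hn
    while (i > 1L) {
      p <- i %/% 2L
      if (heap_less(i, p)) {
        tmp <- ht[i]; ht[i] <<- ht[p]; ht[p] <<- tmp
        tmpi <- hk[i]; hk[i] <<- hk[p]; hk[p] <<- tmpi
        tmpi <- h1[i]; h1[i] <<- h1[p]; h1[p] <<- tmpi
        tmpi <- h2[i]; h2[i] <<- h2[p]; h2[p] <<- tmpi
        tmpi <- hs[i]; hs[i] <<- hs[p]; hs[p] <<- tmpi
        i <- p
      } else break
    }
  }
  ev <- list(t = 0, k = 0L, i1 = 0L, i2 = 0L)
  heap_pop <- function() {
    ev$t <<- ht[1]; ev$k <<- hk[1]; ev$i1 <<- h1[1]; ev$i2 <<- h2[1]
    ht[1] <<- ht[hn]; hk[1] <<- hk[hn]; h1[1] <<- h1[hn]; h2[1] <<- h2[hn]
    hs[1] <<- hs[hn]
    hn <<- hn - 1L
    i <- 1L
    repeat {
      l <- 2L * i; r <- l + 1L
      sm <- i
      if (l <= hn && heap_less(l, sm)) sm <- l
      if (r <= hn && heap_less(r, sm)) sm <- r
      if (sm == i) break
      tmp <- ht[i]; ht[i] <<- ht[sm]; ht[sm] <<- tmp
      tmpi <- hk[i]; hk[i] <<- hk[sm]; hk[sm] <<- tmpi
      tmpi <- h1[i]; h1[i] <<- h1[sm]; h1[sm] <<- tmpi
      tmpi <- h2[i]; h2[i] <<- h2[sm]; h2[sm] <<- tmpi
      tmpi <- hs[i]; hs[i] <<- hs[sm]; hs[sm] <<- tmpi
      i <- sm
    }
  }

  # records
  outcome <- rep(NA_character_, n_surg)
  acq_time <- rep(NA_real_, n_surg)
  used_cfg <- rep(NA_integer_, n_surg)
  ret_toks <- vector("list", n_surg)
  o_served <- rep(NA, n_out)
  mk_ty <- integer(0); mk_done <- numeric(0); mk_min <- numeric(0); mkn <- 0L
  ch_kind <- integer(0); ch_mach <- integer(0); ch_t <- numeric(0)
  ch_n <- integer(0); ch_units <- integer(0); ch_cls <- integer(0)
  ch_qlen <- integer(0); ch_pos <- list(); ch_types <- list(); chn <- 0L

  waiting <- integer(0)        # surgery indices still looking for trays
  w_active <- logical(n_surg)

  staff_ok <- function(team, t) busy_staff[team] < hc_at(team, t)

  config_avail <- function(cf) all(stock[cf$ty] >= cf$n)
  consume_config <- function(cf, t) {
    toks <- integer(0)
    for (j in seq_along(cf$ty)) {
      ty <- cf$ty[j]; k <- cf$n[j]
      stock[ty] <<- stock[ty] - k
      new <- n_tok + seq_len(k)
      tok_type[new] <<- ty
      tok_css[new] <<- NA_real_
      tok_loc[new] <<- 2L
      n_tok <<- n_tok + k
      log_move(t, 1L, 2L, ty, k)
      toks <- c(toks, new)
    }
    toks
  }

  try_surgery <- function(i, t) {
    cfgs <- cfg_by_type[[s_type[i]]]
    pref <- s_cfg[i]
    pick <- NULL; alt <- FALSE
    for (cf in cfgs) {
      if (cf$cid == pref && config_avail(cf)) { pick <- cf; break }
    }
    if (is.null(pick)) {
      for (cf in cfgs) {
        if (cf$cid == pref) next
        if (config_avail(cf)) { pick <- cf; alt <- TRUE; break }
      }
    }
    if (is.null(pick)) return(FALSE)
    outcome[i] <<- if (alt) "alternative" else "preferred"
    used_cfg[i] <<- pick$cid
    acq_time[i] <<- t
    toks <- consume_config(pick, t)
    ret_toks[[i]] <<- toks
    heap_push(t + s_dur[i], 10L, i)
    TRUE
  }

  arrive_css <- function(toks, t, from = 2L) {
    tok_css[toks] <<- t
    add_q_time(1L, t)
    route_tokens(toks, from, 4L, t)
    q_pre <<- c(q_pre, toks)
  }

  retry_waiting <- function(t) {
    if (!length(waiting)) return(invisible())
    still <- logical(length(waiting))
    for (j in seq_along(waiting)) {
      i <- waiting[j]
      if (!w_active[i]) next
      if (try_surgery(i, t)) w_active[i] <- FALSE else still[j] <- TRUE
    }
    waiting <<- waiting[still]
  }

  deliver_autoclave <- function(m, t) {
    toks <- m_toks[[m]]
    for (tk in toks) {
      ty <- tok_type[tk]
      stock[ty] <<- stock[ty] + 1L
      mkn <<- mkn + 1L
      mk_ty[mkn] <<- ty; mk_done[mkn] <<- t; mk_min[mkn] <<- t - tok_css[tk]
    }
    route_tokens(toks, 13L, 1L, t)
    tok_loc[toks] <<- 0L       # back to anonymous sterile stock
    m_toks[m] <<- list(NULL)
    m_state[m] <<- 0L
    retry_waiting(t)
  }

  record_charge <- function(kind, m, t, toks, sel_units, cls, qlen, pos) {
    chn <<- chn + 1L
    ch_kind[chn] <<- kind; ch_mach[chn] <<- m; ch_t[chn] <<- t
    ch_n[chn] <<- length(toks); ch_units[chn] <<- sel_units
    ch_cls[chn] <<- cls; ch_qlen[chn] <<- qlen; ch_pos[[chn]] <<- pos
    ch_types[[chn]] <<- type_ids[tok_type[toks]]
  }

  try_station <- function(st, t) {
    repeat {
      len <- switch(st, length(q_pre), length(q_asm), length(q_wrap))
      if (len == 0L || st_busy[st] >= st_slots[st] || !staff_ok(st_team[st], t)) break
      qk <- switch(st, 1L, 3L, 4L)
      add_q_time(qk, t)
      if (st == 1L) { tk <- q_pre[1]; q_pre <<- q_pre[-1] }
      else if (st == 2L) { tk <- q_asm[1]; q_asm <<- q_asm[-1] }
      else { tk <- q_wrap[1]; q_wrap <<- q_wrap[-1] }
      st_busy[st] <<- st_busy[st] + 1L
      busy_staff[st_team[st]] <<- busy_staff[st_team[st]] + 1L
      from <- switch(st, 4L, 8L, 10L); to <- switch(st, 5L, 9L, 11L)
      route_tokens(tk, from, to, t)
      heap_push(t + rlnorm(1, st_mu[st], st_sigma[st]), 5L, st, tk)
    }
  }

  try_disinfectors <- function(t) {
    for (m in which(m_kind == 1L & m_state == 0L)) {
      if (!length(q_dis) || !staff_ok(dis_load_team, t)) break
      sel <- charge_select_disinfector(units[tok_type[q_dis]],
                                       compat[tok_type[q_dis]],
                                       dis_spec$capacity, dis_spec$layers,
                                       dis_spec$layer_units,
                                       dis_spec$start_threshold)
      if (!length(sel)) break
      toks <- q_dis[sel]
      record_charge(1L, m, t, toks, sum(units[tok_type[toks]]),
                    compat[tok_type[toks[1]]], length(q_dis), sel)
      add_q_time(2L, t)
      q_dis <<- q_dis[-sel]
      route_tokens(toks, 6L, 7L, t)
      m_toks[[m]] <<- toks
      m_state[m] <<- 1L
      busy_staff[dis_load_team] <<- busy_staff[dis_load_team] + 1L
      heap_push(t + rlnorm(1, dis_spec$load_mu, dis_spec$load_sigma), 6L, m)
    }
  }

  try_autoclaves <- function(t) {
    for (m in which(m_kind == 2L & m_state == 0L)) {
      if (!staff_ok(2L, t)) break
      k <- charge_select_autoclave(length(q_aut), aut_spec$capacity,
                                   aut_spec$start_threshold)
      if (k == 0L) break
      toks <- q_aut[seq_len(k)]
      record_charge(2L, m, t, toks, NA_integer_, NA_integer_,
                    length(q_aut), seq_len(k))
      add_q_time(5L, t)
      q_aut <<- q_aut[-seq_len(k)]
      route_tokens(toks, 12L, 13L, t)
      m_toks[[m]] <<- toks
      m_state[m] <<- 1L
      busy_staff[2L] <<- busy_staff[2L] + 1L
      heap_push(t + rlnorm(1, aut_spec$load_mu, aut_spec$load_sigma), 6L, m)
    }
  }

  try_unloads <- function(t) {
    for (m in which(m_kind == 1L & m_state == 3L)) {
      if (!staff_ok(2L, t)) break
      busy_staff[2L] <<- busy_staff[2L] + 1L
      m_state[m] <<- 4L
      heap_push(t + rlnorm(1, dis_spec$unload_mu, dis_spec$unload_sigma), 8L, m)
    }
  }

  try_all <- function(t) {
    try_station(1L, t)
    try_disinfectors(t)
    try_unloads(t)
    try_station(2L, t)
    try_station(3L, t)
    try_autoclaves(t)
  }

  # -- initial events --------------------------------------------------------
  set.seed(derive_seed(seed, "simulate"))
  for (i in seq_len(n_surg)) heap_push(s_abs[i], 1L, i)
  for (j in seq_len(n_out)) heap_push(o_time[j], 3L, j)
  bt <- instance$batch_schedule$insertion_times
  for (d in seq_len(h) - 1L) for (b in bt) heap_push(d * 1440 + b, 4L)
  starts <- unique(sh[, c("weekday", "start")])
  for (d in seq_len(h) - 1L) {
    wd <- weekday_of(d)
    for (s0 in starts$start[starts$weekday == wd]) heap_push(d * 1440 + s0, 9L)
  }

  # -- event loop ------------------------------------------------------------
  while (hn > 0L) {
    heap_pop()
    t <- ev$t
    if (t > end_time) break
    k <- ev$k
    if (k == 1L) {                       # surgery due
      i <- ev$i1
      if (!try_surgery(i, t)) {
        w_active[i] <- TRUE
        waiting <- c(waiting, i)
        heap_push(t + 120, 2L, i)
      }
    } else if (k == 2L) {                # two-hour limit reached
      i <- ev$i1
      if (w_active[i]) {
        w_active[i] <- FALSE
        outcome[i] <- "rescheduled"
      }
    } else if (k == 3L) {                # outpatient procedure
      j <- ev$i1; ty <- o_ty[j]
      if (stock[ty] > 0L) {
        o_served[j] <- TRUE
        stock[ty] <- stock[ty] - 1L
        n_tok <- n_tok + 1L
        tok_type[n_tok] <- ty; tok_css[n_tok] <- NA_real_; tok_loc[n_tok] <- 2L
        log_move(t, 1L, 2L, ty, 1L)
        if (batched[ty]) {
          route_tokens(n_tok, 2L, 3L, t)
          batch_buf <- c(batch_buf, n_tok)
        } else {
          arrive_css(n_tok, t)
        }
      } else {
        o_served[j] <- FALSE             # unmet outpatient demand is lost
      }
    } else if (k == 4L) {                # batch insertion time
      if (length(batch_buf)) {
        arrive_css(batch_buf, t, from = 3L)
        batch_buf <- integer(0)
      }
    } else if (k == 5L) {                # manual stage finished
      st <- ev$i1; tk <- ev$i2
      st_busy[st] <- st_busy[st] - 1L
      busy_staff[st_team[st]] <- busy_staff[st_team[st]] - 1L
      if (st == 1L) {
        add_q_time(2L, t); route_tokens(tk, 5L, 6L, t); q_dis <- c(q_dis, tk)
      } else if (st == 2L) {
        add_q_time(4L, t); route_tokens(tk, 9L, 10L, t); q_wrap <- c(q_wrap, tk)
      } else {
        add_q_time(5L, t); route_tokens(tk, 11L, 12L, t); q_aut <- c(q_aut, tk)
      }
    } else if (k == 6L) {                # machine loaded, cycle starts
      m <- ev$i1
      team <- if (m_kind[m] == 1L) dis_load_team else 2L
      busy_staff[team] <- busy_staff[team] - 1L
      m_state[m] <- 2L
      cm <- if (m_kind[m] == 1L) dis_spec$charge_minutes else aut_spec$charge_minutes
      heap_push(t + cm, 7L, m)
    } else if (k == 7L) {                # machine cycle done
      m <- ev$i1
      if (m_kind[m] == 1L) m_state[m] <- 3L else deliver_autoclave(m, t)
    } else if (k == 8L) {                # disinfector unloaded
      m <- ev$i1
      busy_staff[2L] <- busy_staff[2L] - 1L
      toks <- m_toks[[m]]
      add_q_time(3L, t)
      route_tokens(toks, 7L, 8L, t)
      q_asm <- c(q_asm, toks)
      m_toks[m] <- list(NULL)
      m_state[m] <- 0L
    } else if (k == 10L) {               # used trays return to the CSS
      toks <- ret_toks[[ev$i1]]
      bt_mask <- batched[tok_type[toks]]
      if (any(bt_mask)) {
        route_tokens(toks[bt_mask], 2L, 3L, t)
        batch_buf <- c(batch_buf, toks[bt_mask])
      }
      if (any(!bt_mask)) arrive_css(toks[!bt_mask], t)
    }
    # k == 9L (shift start) only triggers the resource scan below
    try_all(t)
  }

  for (kq in 1:5) add_q_time(kq, end_time)

  # any surgery still waiting when the loop stopped resolves via its
  # timeout event, which always falls inside the horizon (OR day << 24h)
  outcome[is.na(outcome)] <- "rescheduled"

  # final location census, independent of the move log
  live <- which(tok_loc > 1L)
  final_counts <- tibble(
    tray_type = rep(type_ids, length(LOCATIONS)),
    location = rep(LOCATIONS, each = S),
    n = c(stock, rep(0L, S * (length(LOCATIONS) - 1L)))
  )
  if (length(live)) {
    tb <- table(factor(tok_type[live], levels = seq_len(S)),
                factor(tok_loc[live], levels = seq_along(LOCATIONS)))
    final_counts$n <- final_counts$n +
      as.integer(tb[cbind(match(final_counts$tray_type, type_ids),
                          match(final_counts$location, LOCATIONS))])
  }

  surgeries_out <- sg |>
    dplyr::mutate(outcome = outcome, config_used = used_cfg,
                  acquired_time = acq_time)

  makespan <- tibble(tray_type = type_ids[mk_ty[seq_len(mkn)]],
                     completed = mk_done[seq_len(mkn)],
                     minutes = mk_min[seq_len(mkn)])
  charges <- tibble(
    machine_kind = c("disinfector", "autoclave")[ch_kind[seq_len(chn)]],
    machine = ch_mach[seq_len(chn)],
    start = ch_t[seq_len(chn)],
    n_trays = ch_n[seq_len(chn)],
    size_units = ch_units[seq_len(chn)],
    compat_class = levels(factor(tt$compat_class))[ch_cls[seq_len(chn)]],
    queue_length = ch_qlen[seq_len(chn)],
    positions = ch_pos[seq_len(chn)],
    tray_types = ch_types[seq_len(chn)]
  )
  moves <- if (log_moves) {
    tibble(time = mv_t[seq_len(mvn)],
           from = LOCATIONS[mv_from[seq_len(mvn)]],
           to = LOCATIONS[mv_to[seq_len(mvn)]],
           tray_type = type_ids[mv_ty[seq_len(mvn)]],
           n = mv_n[seq_len(mvn)])
  } else NULL

  week_of_day <- function(d) pmin(d %/% 7L + 1L, nweeks)
  week_of_t <- function(tm) pmin(floor(tm / 10080) + 1, nweeks)
  wk_surg <- factor(week_of_day(s_day), levels = seq_len(nweeks))
  weekly <- tibble(
    week = seq_len(nweeks),
    surgeries = as.integer(table(wk_surg)),
    alternatives = as.integer(table(wk_surg[outcome == "alternative"])),
    reschedules = as.integer(table(wk_surg[outcome == "rescheduled"])),
    dis_charges = as.integer(table(factor(
      week_of_t(ch_t[seq_len(chn)][ch_kind[seq_len(chn)] == 1L]),
      levels = seq_len(nweeks)))),
    ster_charges = as.integer(table(factor(
      week_of_t(ch_t[seq_len(chn)][ch_kind[seq_len(chn)] == 2L]),
      levels = seq_len(nweeks)))),
    trays_cleaned = as.integer(table(factor(week_of_t(mk_done[seq_len(mkn)]),
                                            levels = seq_len(nweeks))))
  )
  week_minutes <- pmin(seq_len(nweeks) * 10080, end_time) -
    (seq_len(nweeks) - 1) * 10080
  qnames <- c("q_preclean", "q_disinfect", "q_assembly", "q_wrap", "q_sterilize")
  for (kq in 1:5) weekly[[qnames[kq]]] <- qint[kq, ] / week_minutes

  structure(list(
    weekly = weekly,
    surgeries = surgeries_out,
    outpatient = op |> dplyr::mutate(served = o_served),
    makespan = makespan,
    charges = charges,
    moves = moves,
    final_counts = final_counts,
    policy = tibble(tray_type = type_ids, Q = Q),
    horizon_days = h,
    warmup_days = warmup_days,
    seed = seed
  ), class = "css_sim_result")
}

#' @export
print.css_sim_result <- function(x, ...) {
  cat("<css_sim_result> ", x$horizon_days, " days, ",
      nrow(x$surgeries), " surgeries, ",
      nrow(x$charges), " machine charges, ",
      nrow(x$makespan), " tray cycles completed\n", sep = "")
  invisible(x)
}

#' Summarise simulation KPIs
#'
#' Performance KPIs (alternative-tray percentage, reschedule percentage,
#' total inventory) and validation KPIs (time-average queue lengths,
#' weekly machine charges and trays cleaned, tray makespan summary),
#' computed over the post-warm-up part of the run only.
#'
#' @param result A `css_sim_result`.
#' @param warmup_days Warm-up to discard; defaults to the value stored in
#'   the result.
#' @return One-row tibble of KPIs. If no surgery falls after the warm-up,
#'   rates are reported as 0 and `no_surgeries` is `TRUE`.
#' @export
compute_kpis <- function(result, warmup_days = NULL) {
  warmup_days <- warmup_days %||% result$warmup_days
  sg <- result$surgeries[result$surgeries$day >= warmup_days, ]
  n <- nrow(sg)
  no_surg <- n == 0
  alt_pct <- if (no_surg) 0 else 100 * mean(sg$outcome == "alternative")
  res_pct <- if (no_surg) 0 else 100 * mean(sg$outcome == "rescheduled")

  wk <- result$weekly
  post <- wk[(wk$week - 1) * 7 >= warmup_days, ]
  week_minutes <- pmin(post$week * 10080, result$horizon_days * 1440) -
    (post$week - 1) * 10080
  qcols <- c("q_preclean", "q_disinfect", "q_assembly", "q_wrap", "q_sterilize")
  qavg <- vapply(qcols, function(cl) {
    sum(post[[cl]] * week_minutes) / sum(week_minutes)
  }, numeric(1))

  mk <- result$makespan[result$makespan$completed >= warmup_days * 1440, ]
  tibble(
    alternative_tray_pct = alt_pct,
    reschedule_pct = res_pct,
    total_inventory = sum(result$policy$Q),
    q_preclean = qavg[["q_preclean"]],
    q_disinfect = qavg[["q_disinfect"]],
    q_assembly = qavg[["q_assembly"]],
    q_wrap = qavg[["q_wrap"]],
    q_sterilize = qavg[["q_sterilize"]],
    dis_charges_per_week = mean(post$dis_charges),
    ster_charges_per_week = mean(post$ster_charges),
    trays_cleaned_per_week = mean(post$trays_cleaned),
    makespan_median_min = if (nrow(mk)) median(mk$minutes) else NA_real_,
    makespan_p95_min = if (nrow(mk)) unname(quantile(mk$minutes, 0.95)) else NA_real_,
    n_surgeries = n,
    no_surgeries = no_surg
  )
}
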