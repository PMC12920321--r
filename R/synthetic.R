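#' Minimal hand-written test instance
#'
#' A deterministic toy hospital: two operating rooms, three tray types
#' (`A`, `B` surgical, `C` outpatient), two surgery types and one machine
#' of each kind, with deliberately small machine capacities so that every
#' stage of the cycle is exercised within a few simulated days. Expected
#' weekly tray demand is computable in closed form from the rates:
#' `hernia` runs 17/week and draws `{A}` w.p. 0.6 / `{B}` w.p. 0.4,
#' `ortho` runs 11/week and draws `{A,B}` w.p. 0.7 / `{B x2}` w.p. 0.3,
#' so E(weekly demand) is A: 17.9, B: 21.1, and C: 14 (2/day outpatient).
#'
#' @return A valid `css_instance`.
#' @export
toy_instance <- function() {
  pre <- lognormal_params(1, 0.5)
  asm <- lognormal_params(2, 1)
  wrp <- lognormal_params(0.5, 0.2)
  dlo <- lognormal_params(1, 0.3)
  dun <- lognormal_params(0.5, 0.2)
  alo <- lognormal_params(1, 0.3)
  dur1 <- lognormal_params(60, 20)
  dur2 <- lognormal_params(90, 30)
  wd <- weekdays_short()

  css_instance(
    tray_types = tibble(
      id = c("A", "B", "C"),
      size_class = c("M", "L", "S"),
      compat_class = c("regular", "regular", "regular"),
      current_inventory = c(6L, 8L, 4L),
      source = c("surgical", "surgical", "outpatient")
    ),
    surgery_types = tibble(
      id = c("hernia", "ortho"),
      duration_mu = c(dur1$mu, dur2$mu),
      duration_sigma = c(dur1$sigma, dur2$sigma)
    ),
    surgery_rates = dplyr::bind_rows(
      tibble(surgery_type = "hernia", weekday = wd,
             rate = c(3, 3, 3, 3, 3, 1, 1)),
      tibble(surgery_type = "ortho", weekday = wd,
             rate = c(2, 2, 2, 2, 2, 0.5, 0.5))
    ),
    configurations = tibble(
      surgery_type = c("hernia", "hernia", "ortho", "ortho"),
      config_id = c(1L, 2L, 1L, 2L),
      probability = c(0.6, 0.4, 0.7, 0.3)
    ),
    config_trays = tibble(
      surgery_type = c("hernia", "hernia", "ortho", "ortho", "ortho"),
      config_id = c(1L, 2L, 1L, 1L, 2L),
      tray_type = c("A", "B", "A", "B", "B"),
      n = c(1L, 1L, 1L, 1L, 2L)
    ),
    workstations = tibble(
      kind = c("pre_clean", "assemble", "wrap"),
      count = c(1L, 1L, 1L),
      capacity = c(1L, 1L, 1L),
      service_mu = c(pre$mu, asm$mu, wrp$mu),
      service_sigma = c(pre$sigma, asm$sigma, wrp$sigma)
    ),
    machines = tibble(
      kind = c("disinfector", "autoclave"),
      count = c(1L, 1L),
      capacity = c(8L, 4L),
      layers = c(2L, NA_integer_),
      layer_units = c(4L, NA_integer_),
      charge_minutes = c(30, 30),
      load_mu = c(dlo$mu, alo$mu),
      load_sigma = c(dlo$sigma, alo$sigma),
      unload_mu = c(dun$mu, NA_real_),
      unload_sigma = c(dun$sigma, NA_real_),
      start_threshold = c(0.25, 0.5)
    ),
    staff_shifts = dplyr::bind_rows(
      tibble(team = "pre_cleaning", weekday = wd,
             start = 420, end = 1080, headcount = 2L),
      tibble(team = "post_cleaning", weekday = wd,
             start = 420, end = 1080, headcount = 2L)
    ),
    operating_rooms = c("OR1", "OR2"),
    batch_schedule = list(insertion_times = c(660, 960),
                          batched_sources = "outpatient"),
    outpatient_rate = 2,
    outpatient_window = c(480, 1020),
    or_day_window = c(480, 960)
  )
}

#' Parameters for the synthetic-instance generator
#'
#' Defaults emulate the demand structure of the mid-size reference
#' hospital after clustering its tray catalogue into three groups:
#' high-use surgical trays (32 types, mean stock 9.97, expected weekly
#' demand 13.98 per type), low-use surgical trays (77 types, stock 2.15,
#' weekly demand 0.78) and outpatient trays (10 types, stock 2.35,
#' weekly demand 11.88).
#'
#' @param n_tray_types Integer vector of length 3: tray types per cluster.
#' @param mean_stock Mean current stock per tray type, per cluster.
#' @param weekly_demand Target expected weekly demand per tray type, per
#'   cluster.
#' @param n_surgery_types Total number of surgery types (split between a
#'   common group using cluster-1 trays and a specialised group using
#'   cluster-2 trays).
#' @param configs_per_surgery Configurations per surgery type (>= 1).
#' @param overlap Fraction of a preferred configuration's trays retained
#'   in each alternative configuration; this shared-tray structure is what
#'   induces dependent tray demand.
#' @param n_rooms Number of operating rooms.
#' @param anaesthetic_frac Fraction of cluster-1 tray types washed in a
#'   separate disinfector compatibility class.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(n_tray_types = c(32L, 77L, 10L),
                         mean_stock = c(9.97, 2.15, 2.35),
                         weekly_demand = c(13.98, 0.78, 11.88),
                         n_surgery_types = 30L,
                         configs_per_surgery = 3L,
                         overlap = 0.5,
                         n_rooms = 8L,
                         anaesthetic_frac = 0.1) {
  stopifnot(length(n_tray_types) == 3, all(n_tray_types >= 1),
            all(mean_stock > 0), all(weekly_demand > 0),
            n_surgery_types >= 2, configs_per_surgery >= 1,
            overlap >= 0, overlap <= 1, n_rooms >= 1)
  structure(list(n_tray_types = as.integer(n_tray_types),
                 mean_stock = mean_stock, weekly_demand = weekly_demand,
                 n_surgery_types = as.integer(n_surgery_types),
                 configs_per_surgery = as.integer(configs_per_surgery),
                 overlap = overlap, n_rooms = as.integer(n_rooms),
                 anaesthetic_frac = anaesthetic_frac),
            class = "synth_params")
}

#' Generate a synthetic hospital instance
#'
#' Builds a full instance whose demand process has the statistical
#' structure of a real mid-size hospital: a cluster of high-use surgical
#' tray types appearing in many configurations, a long tail of low-use
#' specialised trays, and a group of outpatient trays returned to the CSS
#' in batches. Weekday surgery rates are scaled so the expected weekly
#' tray demand per cluster hits the requested targets exactly (weekday
#' profile: Mon-Fri full rate, Sat 30%, Sun 20%). Resources default to
#' [default_resources()].
#'
#' @param params A [synth_params()] list.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A valid `css_instance`.
#' @export
make_synthetic_instance <- function(params = synth_params(), seed = 1) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(derive_seed(seed, "synth"))
  n <- params$n_tray_types
  ids <- list(
    sprintf("HU%03d", seq_len(n[1])),   # high-use surgical
    sprintf("LU%03d", seq_len(n[2])),   # low-use surgical
    sprintf("OP%03d", seq_len(n[3]))    # outpatient
  )
  size_classes <- c("S", "M", "L", "XL")
  draw_sizes <- function(k) sample(size_classes, k, TRUE, prob = c(0.2, 0.4, 0.3, 0.1))
  n_anae <- round(params$anaesthetic_frac * n[1])
  compat1 <- c(rep("anaesthetic", n_anae), rep("regular", n[1] - n_anae))
  tray_types <- dplyr::bind_rows(
    tibble(id = ids[[1]], size_class = draw_sizes(n[1]), compat_class = compat1,
           current_inventory = pmax(1L, rpois(n[1], params$mean_stock[1])),
           source = "surgical"),
    tibble(id = ids[[2]], size_class = draw_sizes(n[2]), compat_class = "regular",
           current_inventory = pmax(1L, rpois(n[2], params$mean_stock[2])),
           source = "surgical"),
    tibble(id = ids[[3]], size_class = draw_sizes(n[3]), compat_class = "regular",
           current_inventory = pmax(1L, rpois(n[3], params$mean_stock[3])),
           source = "outpatient")
  )

  n_common <- params$n_surgery_types %/% 2L
  n_spec <- params$n_surgery_types - n_common
  groups <- list(
    list(prefix = "SRG-C", count = n_common, pool = ids[[1]], cluster = 1L),
    list(prefix = "SRG-S", count = n_spec, pool = ids[[2]], cluster = 2L)
  )

  st <- list(); cfg <- list(); ct <- list(); grp_of <- character()
  cfg_probs <- function(k) {
    p <- 0.6 * 0.45^(seq_len(k) - 1)
    p[k] <- p[k] + (1 - sum(p))   # exact unit mass, preferred most likely
    p
  }
  for (g in groups) {
    for (i in seq_len(g$count)) {
      oid <- sprintf("%s%02d", g$prefix, i)
      grp_of[oid] <- g$prefix
      m <- lognormal_params(runif(1, 45, 150), runif(1, 10, 40))
      st[[oid]] <- tibble(id = oid, duration_mu = m$mu, duration_sigma = m$sigma)
      k_tr <- sample(1:3, 1, prob = c(0.3, 0.5, 0.2))
      pref <- sample(g$pool, min(k_tr, length(g$pool)))
      probs <- cfg_probs(params$configs_per_surgery)
      for (j in seq_len(params$configs_per_surgery)) {
        trays <- if (j == 1) pref else {
          keep <- ceiling(params$overlap * length(pref))
          kept <- pref[seq_len(keep)]
          extra <- sample(setdiff(g$pool, kept),
                          max(0L, length(pref) - keep))
          unique(c(kept, extra))
        }
        cnt <- ifelse(runif(length(trays)) < 0.1, 2L, 1L)
        cfg[[length(cfg) + 1L]] <- tibble(surgery_type = oid, config_id = j,
                                          probability = probs[j])
        ct[[length(ct) + 1L]] <- tibble(surgery_type = oid, config_id = j,
                                        tray_type = trays, n = cnt)
      }
    }
  }
  surgery_types <- dplyr::bind_rows(st)
  configurations <- dplyr::bind_rows(cfg)
  config_trays <- dplyr::bind_rows(ct)

  # expected trays drawn from cluster c per surgery of type o (all configs,
  # weighted by configuration probability)
  exp_trays <- config_trays |>
    dplyr::left_join(configurations, by = c("surgery_type", "config_id")) |>
    dplyr::group_by(.data$surgery_type) |>
    dplyr::summarise(per_surgery = sum(.data$n * .data$probability),
                     .groups = "drop")

  profile <- c(1, 1, 1, 1, 1, 0.3, 0.2)  # Mon..Sun weights, sum 5.5
  rel <- runif(nrow(surgery_types), 0.5, 1.5)
  names(rel) <- surgery_types$id
  sr <- list()
  for (g in groups) {
    members <- surgery_types$id[grp_of[surgery_types$id] == g$prefix]
    if (!length(members)) stop("infeasible targets: no surgery types for cluster ",
                               g$cluster, call. = FALSE)
    target_week <- params$weekly_demand[g$cluster] * n[g$cluster]
    per <- exp_trays$per_surgery[match(members, exp_trays$surgery_type)]
    # weekly demand = sum_o rel_o * scale * sum_v profile_v * per_o
    scale <- target_week / (sum(rel[members] * per) * sum(profile))
    for (oid in members) {
      sr[[oid]] <- tibble(surgery_type = oid, weekday = weekdays_short(),
                          rate = rel[oid] * scale * profile)
    }
  }

  res <- default_resources()
  inst <- css_instance(
    tray_types = tray_types,
    surgery_types = surgery_types,
    surgery_rates = dplyr::bind_rows(sr),
    configurations = configurations,
    config_trays = config_trays,
    workstations = res$workstations,
    machines = res$machines,
    staff_shifts = res$staff_shifts,
    operating_rooms = sprintf("OR%d", seq_len(params$n_rooms)),
    batch_schedule = list(insertion_times = c(660, 960),
                          batched_sources = "outpatient"),
    outpatient_rate = params$weekly_demand[3] / 7,
    outpatient_window = c(480, 1020),
    or_day_window = c(480, 960)
  )
  assert_valid_instance(inst)
  inst
}
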