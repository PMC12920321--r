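dis_spec <- function() default_resources()$machines[1, ]
aut_spec <- function() default_resources()$machines[2, ]

queue_of <- function(units, classes = "regular") {
  tibble::tibble(tray_type = sprintf("t%02d", seq_along(units)),
                 size_units = as.integer(units),
                 compat_class = rep_len(classes, length(units)))
}

test_that("disinfector charges respect FIFO, layers and the threshold", {
  # 24 two-unit trays fill the machine exactly (4 layers x 12 units)
  ch <- build_disinfector_charge(queue_of(rep(2, 24)), dis_spec())
  expect_equal(nrow(ch), 24L)
  expect_equal(sum(ch$size_units), 48L)
  expect_equal(ch$position, 1:24)

  # 9 queued units cannot reach the 20% threshold (9.6 units)
  expect_null(build_disinfector_charge(queue_of(rep(1, 9)), dis_spec()))

  # 11 XL trays leave a 4-unit layer remainder that the S trays fill
  ch <- build_disinfector_charge(queue_of(c(rep(4, 11), rep(1, 4))), dis_spec())
  expect_equal(nrow(ch), 15L)
  expect_equal(sum(ch$size_units), 48L)

  # a selected tray set never mixes compatibility classes, and a head tray
  # of a class below threshold volume does not block the feasible class
  q <- queue_of(c(2, rep(2, 20)), classes = c("eye", rep("regular", 20)))
  ch <- build_disinfector_charge(q, dis_spec())
  expect_equal(unique(ch$compat_class), "regular")
  expect_gte(sum(ch$size_units), 0.2 * 48)
})

test_that("autoclave charges are pure FIFO with a 50% start threshold", {
  ch <- build_autoclave_charge(queue_of(rep(1, 35)), aut_spec())
  expect_equal(ch$position, 1:30)
  expect_null(build_autoclave_charge(queue_of(rep(1, 10)), aut_spec()))
  ch <- build_autoclave_charge(queue_of(rep(1, 15)), aut_spec())
  expect_equal(nrow(ch), 15L)
})

test_that("configuration selection prefers the scheduled set then falls back", {
  inst <- toy_instance()
  sel <- select_configuration(inst, "hernia", 1L, c(A = 2L, B = 0L, C = 0L))
  expect_equal(sel$outcome, "preferred")
  sel <- select_configuration(inst, "hernia", 1L, c(A = 0L, B = 1L, C = 0L))
  expect_equal(sel$outcome, "alternative")
  expect_equal(sel$config_id, 2L)
  sel <- select_configuration(inst, "hernia", 1L, c(A = 0L, B = 0L, C = 5L))
  expect_equal(sel$outcome, "none")
})

test_that("abundant inventory yields no reschedules or alternatives", {
  inst <- toy_instance()
  sch <- generate_schedule(inst, 28, seed = 11)
  pol <- abundant_policy(demand_table(sch, inst))
  res <- simulate_cycle(inst, sch, pol, warmup_days = 0, seed = 1,
                        log_moves = FALSE)
  expect_equal(compute_kpis(res)$reschedule_pct, 0)
  expect_equal(compute_kpis(res)$alternative_tray_pct, 0)
})

test_that("a type at Q = 0 that is the sole option reschedules every surgery", {
  inst <- toy_instance()
  # make hernia depend on tray A only
  keep <- !(inst$configurations$surgery_type == "hernia" &
              inst$configurations$config_id == 2L)
  inst$configurations <- inst$configurations[keep, ]
  inst$configurations$probability[
    inst$configurations$surgery_type == "hernia"] <- 1
  inst$config_trays <- inst$config_trays[
    !(inst$config_trays$surgery_type == "hernia" &
        inst$config_trays$config_id == 2L), ]
  sch <- generate_schedule(inst, 14, seed = 5)
  pol <- tibble::tibble(tray_type = c("A", "B", "C"), Q = c(0L, 50L, 50L))
  res <- simulate_cycle(inst, sch, pol, warmup_days = 0, seed = 1,
                        log_moves = FALSE)
  hern <- res$surgeries[res$surgeries$surgery_type == "hernia", ]
  expect_true(all(hern$outcome == "rescheduled"))
})

test_that("the closed loop conserves every tray type at every instant", {
  inst <- toy_instance()
  sch <- generate_schedule(inst, 21, seed = 9)
  res <- simulate_cycle(inst, sch, current_policy(inst), warmup_days = 0,
                        seed = 3, log_moves = TRUE)
  expect_true(conservation_holds(res))
  totals <- res$final_counts |>
    dplyr::group_by(tray_type) |>
    dplyr::summarise(n = sum(n), .groups = "drop")
  expect_equal(totals$n[match(res$policy$tray_type, totals$tray_type)],
               res$policy$Q)
})

test_that("simulation is deterministic given instance, schedule and seed", {
  inst <- toy_instance()
  sch <- generate_schedule(inst, 14, seed = 2)
  pol <- current_policy(inst)
  r1 <- simulate_cycle(inst, sch, pol, warmup_days = 0, seed = 6)
  r2 <- simulate_cycle(inst, sch, pol, warmup_days = 0, seed = 6)
  expect_identical(r1$moves, r2$moves)
  expect_identical(r1$weekly, r2$weekly)
  expect_identical(r1$surgeries, r2$surgeries)
  r3 <- simulate_cycle(inst, sch, pol, warmup_days = 0, seed = 7)
  expect_false(identical(r1$moves, r3$moves))
})

test_that("every recorded charge obeys capacity, threshold, purity and FIFO", {
  inst <- toy_with_reference_machines()
  dem <- demand_table(generate_schedule(inst, 28, seed = 1), inst)
  sch <- generate_schedule(inst, 28, seed = 1)
  pol <- abundant_policy(dem)
  res <- simulate_cycle(inst, sch, pol, warmup_days = 0, seed = 4,
                        log_moves = FALSE)
  ch <- res$charges
  dis <- ch[ch$machine_kind == "disinfector", ]
  aut <- ch[ch$machine_kind == "autoclave", ]
  expect_gt(nrow(dis), 0)
  expect_gt(nrow(aut), 0)
  expect_true(all(dis$size_units <= 48))
  expect_true(all(dis$size_units >= 0.2 * 48))
  expect_true(all(aut$n_trays <= 30))
  expect_true(all(aut$n_trays >= 0.5 * 30))
  classes <- setNames(inst$tray_types$compat_class, inst$tray_types$id)
  for (i in seq_len(nrow(dis))) {
    expect_equal(length(unique(classes[dis$tray_types[[i]]])), 1L)
  }
  # FIFO among selected items: queue positions strictly increasing
  for (pos in ch$positions) expect_true(all(diff(pos) > 0))
})

test_that("policy must cover every tray type", {
  inst <- toy_instance()
  sch <- generate_schedule(inst, 7, seed = 1)
  expect_error(
    simulate_cycle(inst, sch, tibble::tibble(tray_type = "A", Q = 5L)),
    "missing tray type")
})

test_that("adding a tray of every type never increases reschedules (CRN)", {
  inst <- toy_instance()
  sch <- generate_schedule(inst, 28, seed = 13)
  base <- tibble::tibble(tray_type = c("A", "B", "C"), Q = c(2L, 2L, 1L))
  n_res <- function(pol, s) {
    r <- simulate_cycle(inst, sch, pol, warmup_days = 0, seed = s,
                        log_moves = FALSE)
    sum(r$surgeries$outcome == "rescheduled")
  }
  for (s in 1:3) {
    lo <- n_res(base, s)
    hi <- n_res(dplyr::mutate(base, Q = Q + 1L), s)
    expect_lte(hi, lo)
  }
})

test_that("KPIs are computed over post-warm-up surgeries only", {
  fake <- structure(list(
    surgeries = tibble::tibble(
      day = rep(c(1L, 10L), c(20, 100)),
      outcome = c(rep("rescheduled", 20),
                  rep("rescheduled", 2), rep("alternative", 5),
                  rep("preferred", 93))),
    weekly = tibble::tibble(
      week = 1:2, surgeries = c(20L, 100L), alternatives = c(0L, 5L),
      reschedules = c(20L, 2L), dis_charges = c(3L, 4L),
      ster_charges = c(2L, 3L), trays_cleaned = c(50L, 60L),
      q_preclean = c(1, 2), q_disinfect = c(0, 0), q_assembly = c(0, 0),
      q_wrap = c(0, 0), q_sterilize = c(0, 0)),
    makespan = tibble::tibble(tray_type = "A",
                              completed = c(100, 99999), minutes = c(5, 198)),
    policy = tibble::tibble(tray_type = c("A", "B", "C"), Q = c(3L, 4L, 5L)),
    horizon_days = 14L, warmup_days = 7L),
    class = "css_sim_result")
  k <- compute_kpis(fake)
  expect_equal(k$reschedule_pct, 2.0)
  expect_equal(k$alternative_tray_pct, 5.0)
  expect_equal(k$total_inventory, 12L)
  expect_equal(k$makespan_median_min, 198)
  expect_equal(k$trays_cleaned_per_week, 60)
  # a run with no post-warm-up surgeries is flagged
  fake$surgeries <- fake$surgeries[fake$surgeries$day < 7, ]
  k0 <- compute_kpis(fake)
  expect_true(k0$no_surgeries)
  expect_equal(k0$reschedule_pct, 0)
})
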