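test_that("zero rates produce an empty schedule", {
  inst <- toy_instance()
  inst$surgery_rates$rate <- 0
  inst$outpatient_rate <- 0
  sch <- generate_schedule(inst, 30, seed = 1)
  expect_equal(nrow(sch$surgeries), 0L)
  expect_equal(nrow(sch$outpatient), 0L)
  dem <- demand_table(sch, inst)
  expect_true(all(dem$count == 0L))
  expect_equal(nrow(dem), 3L * 30L)
})

test_that("daily surgery counts match the Poisson rates", {
  inst <- toy_instance()
  inst$surgery_types <- inst$surgery_types[1, ]
  inst$surgery_rates <- tibble::tibble(
    surgery_type = "hernia", weekday = weekdays_short(), rate = 3)
  inst$configurations <- inst$configurations[1:2, ]
  inst$config_trays <- inst$config_trays[1:2, ]
  h <- 10000
  sch <- generate_schedule(inst, h, seed = 1)
  daily <- tabulate(sch$surgeries$day + 1L, h)
  # 99% CI for the mean of h Poisson(3) draws
  expect_lt(abs(mean(daily) - 3), 2.576 * sqrt(3 / h))
  expect_lt(abs(var(daily) - 3), 0.2)
})

test_that("schedules are reproducible by seed and differ across seeds", {
  inst <- toy_instance()
  expect_identical(generate_schedule(inst, 30, seed = 7),
                   generate_schedule(inst, 30, seed = 7))
  expect_false(identical(generate_schedule(inst, 30, seed = 7)$surgeries,
                         generate_schedule(inst, 30, seed = 8)$surgeries))
})

test_that("worst-fit picks the least-loaded room with low-index ties", {
  expect_equal(worst_fit_room(c(100, 50, 80)), 2)
  expect_equal(worst_fit_room(c(50, 50)), 1)
  expect_equal(worst_fit_room(c(OR9 = 42)), "OR9")
  expect_error(worst_fit_room(numeric(0)), "no operating rooms")
})

test_that("replayed room assignments were always worst-fit", {
  inst <- toy_instance()
  sch <- generate_schedule(inst, 200, seed = 3)
  expect_true(check_worst_fit(sch, inst))
})

test_that("start times are evenly spread from window open", {
  expect_identical(spread_start_times(0, c(480, 960)), numeric(0))
  expect_equal(spread_start_times(1, c(480, 960)), 480)
  expect_equal(spread_start_times(4, c(480, 960)), c(480, 600, 720, 840))
  sch <- generate_schedule(toy_instance(), 50, seed = 2)
  by_room_day <- split(sch$surgeries$start_time,
                       paste(sch$surgeries$day, sch$surgeries$room))
  for (sts in by_room_day) {
    expect_equal(sort(sts), spread_start_times(length(sts), c(480, 960)))
  }
})

test_that("outpatient demand is a per-type Poisson process", {
  inst <- toy_instance()
  inst$outpatient_rate <- 0
  expect_equal(nrow(generate_outpatient_demand(inst, 100, 1)), 0L)

  inst$outpatient_rate <- 5
  ev <- generate_outpatient_demand(inst, 2000, 1)
  # 99% CI for a Poisson(10000) total
  expect_lt(abs(nrow(ev) - 10000), 2.576 * sqrt(10000))
  per_type <- split(ev$time, ev$tray_type)
  for (tms in per_type) expect_true(all(diff(tms) > 0))
  tod <- ev$time %% 1440
  expect_true(all(tod >= inst$outpatient_window[1] &
                    tod <= inst$outpatient_window[2]))
})

test_that("demand table counts preferred configurations plus outpatient", {
  inst <- toy_instance()
  sch <- structure(list(
    surgeries = tibble::tibble(
      day = 3L, room = "OR1", start_time = 480, surgery_type = "ortho",
      realized_duration = 90, config_id = 1L, gen_order = 1L),
    outpatient = tibble::tibble(time = numeric(), tray_type = character()),
    horizon_days = 7L), class = "css_schedule")
  dem <- demand_table(sch, inst)
  expect_equal(dem$count[dem$tray_type == "A" & dem$day == 3], 1L)
  expect_equal(dem$count[dem$tray_type == "B" & dem$day == 3], 1L)
  expect_equal(sum(dem$count), 2L)
  expect_equal(dem$weekday[dem$day == 3][1], "Thu")
})

test_that("demand conservation: table total equals requested trays", {
  inst <- toy_instance()
  sch <- generate_schedule(inst, 60, seed = 4)
  dem <- demand_table(sch, inst)
  expected <- sch$surgeries |>
    dplyr::inner_join(inst$config_trays, by = c("surgery_type", "config_id"),
                      relationship = "many-to-many") |>
    dplyr::pull(n) |>
    sum()
  expect_equal(sum(dem$count), expected + nrow(sch$outpatient))
})
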