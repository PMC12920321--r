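test_that("instance YAML round trip is the identity", {
  inst <- toy_instance()
  txt1 <- save_instance(inst)
  inst2 <- load_instance(txt1)
  txt2 <- save_instance(inst2)
  expect_identical(txt1, txt2)
  expect_equal(inst2$tray_types, inst$tray_types)
  expect_equal(inst2$surgery_types, inst$surgery_types)
  expect_equal(inst2$machines, inst$machines)
  expect_equal(inst2$batch_schedule, inst$batch_schedule)
  expect_equal(sort(unlist(split(inst2$surgery_rates$rate,
                                 inst2$surgery_rates$surgery_type))),
               sort(unlist(split(inst$surgery_rates$rate,
                                 inst$surgery_rates$surgery_type))))
})

test_that("omitted resource sections default to the reference hospital", {
  doc <- '
operating_rooms: [OR1]
tray_types:
  - {id: A, size_class: M}
surgery_types:
  - id: s1
    duration_mu: 4
    duration_sigma: 0.3
    rates: {Mon: 1}
    configurations:
      - probability: 1
        trays: {A: 1}
'
  inst <- load_instance(doc)
  dis <- inst$machines[inst$machines$kind == "disinfector", ]
  aut <- inst$machines[inst$machines$kind == "autoclave", ]
  expect_equal(dis$count, 4L)
  expect_equal(dis$capacity, 48L)
  expect_equal(dis$layers * dis$layer_units, 48L)
  expect_equal(dis$start_threshold, 0.20)
  expect_equal(aut$capacity, 30L)
  expect_equal(aut$start_threshold, 0.50)
  expect_equal(dis$charge_minutes, 60)
  expect_equal(aut$charge_minutes, 60)
  expect_equal(sum(inst$workstations$count), 6L)
})

test_that("schema errors name the offending path", {
  base <- '
operating_rooms: [OR1]
tray_types:
  - {id: A, size_class: M}
surgery_types:
  - id: s1
    duration_mu: 4
    duration_sigma: 0.3
    rates: {Mon: 1}
    configurations:
      - probability: 1
        trays: {%s: 1}
'
  expect_error(load_instance(sprintf(base, "X")), "undefined tray 'X'")
  expect_error(load_instance(gsub("size_class", "sizes", sprintf(base, "A"))),
               "unknown field|missing required")
  expect_error(load_instance(gsub("duration_mu: 4", "duration_mu: noodle",
                                  sprintf(base, "A"))),
               "expected a number")
  expect_error(load_instance(gsub("rates: \\{Mon: 1\\}", "rates: {Funday: 1}",
                                  sprintf(base, "A"))),
               "unknown weekday")
})

test_that("validation reports violations as data and is empty iff valid", {
  expect_identical(validate_instance(toy_instance()), character(0))

  bad_prob <- toy_instance()
  bad_prob$configurations$probability <- c(0.5, 0.6, 0.7, 0.3)
  expect_match(validate_instance(bad_prob), "sum != 1", all = FALSE)

  bad_shift <- toy_instance()
  bad_shift$staff_shifts$end[1] <- bad_shift$staff_shifts$start[1]
  expect_match(validate_instance(bad_shift), "end must be after start",
               all = FALSE)
})

test_that("randomly corrupted instances are always flagged", {
  corruptions <- list(
    function(i) { i$tray_types$current_inventory[1] <- -1L; i },
    function(i) { i$tray_types$id[2] <- i$tray_types$id[1]; i },
    function(i) { i$surgery_types$duration_sigma[1] <- -0.1; i },
    function(i) { i$surgery_rates$rate[3] <- -2; i },
    function(i) { i$config_trays$tray_type[1] <- "GHOST"; i },
    function(i) { i$config_trays$n[1] <- 0L; i },
    function(i) { i$machines$start_threshold[1] <- 1.5; i },
    function(i) { i$machines$layer_units[1] <- i$machines$layer_units[1] + 1L; i },
    function(i) { i$staff_shifts$headcount[1] <- 0L; i },
    function(i) { i$batch_schedule$insertion_times <- c(960, 660); i },
    function(i) { i$operating_rooms <- character(0); i },
    function(i) { i$workstations$capacity[2] <- 0L; i }
  )
  for (f in corruptions) {
    expect_gt(length(validate_instance(f(toy_instance()))), 0)
  }
})

test_that("current_policy mirrors the tray catalogue", {
  pol <- current_policy(toy_instance())
  expect_equal(pol$Q, c(6L, 8L, 4L))
  expect_equal(pol$tray_type, c("A", "B", "C"))
})
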