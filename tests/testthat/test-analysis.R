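test_that("MSER truncation finds the transient", {
  expect_equal(mser(rep(7, 50), m = 2)$d_star, 0L)
  # 10 transient points then stationary zeros: minimum exactly past the
  # transient, ties resolved to the smallest d
  expect_equal(mser(c(rep(100, 10), rep(0, 90)), m = 2)$d_star, 5L)
  expect_error(mser(c(1, 2, 3), m = 2), "at least")
})

test_that("MSER on stationary noise truncates early and within the guard", {
  set.seed(99)
  ds <- replicate(200, mser(rnorm(200), m = 2)$d_star)
  expect_true(all(ds <= 50))       # half of the 100 batch means
  expect_lte(median(ds), 10)
})

test_that("replication CI follows the Student-t formula", {
  expect_equal(replication_ci(rep(3.3, 10))$half_width, 0)
  ci <- replication_ci(c(0, 2), level = 0.95)
  expect_equal(ci$mean, 1)
  expect_equal(ci$half_width, qt(0.975, 1) * sqrt(2) / sqrt(2))
  expect_equal(ci$half_width, 12.7062, tolerance = 1e-5)
  expect_error(replication_ci(5), "at least two")
})

test_that("CI half width shrinks like one over root n", {
  # unit-variance samples by construction make the ratio deterministic
  set.seed(1)
  x10 <- as.numeric(scale(rnorm(10)))
  x40 <- as.numeric(scale(rnorm(40)))
  ratio <- replication_ci(x10)$half_width / replication_ci(x40)$half_width
  expect_equal(ratio, 2, tolerance = 0.2)
})

test_that("means-difference interval flags consistency with a reference", {
  out <- means_difference_ci(rep(4.2, 5), 4.2)
  expect_equal(out$lower, 0)
  expect_equal(out$upper, 0)
  expect_true(out$consistent)

  set.seed(3)
  x <- rnorm(20, 10)
  a <- means_difference_ci(x, 9.5)
  expect_equal(a$difference, mean(x) - 9.5)
  expect_equal(a$upper - a$difference, a$difference - a$lower)
  b <- means_difference_ci(x + 2, 9.5)
  expect_equal(b$lower, a$lower + 2)
  expect_equal(b$upper, a$upper + 2)
  far <- means_difference_ci(x + 100, 9.5)
  expect_false(far$consistent)
})

test_that("policy comparison is reproducible and label-invariant", {
  inst <- toy_instance()
  pol <- current_policy(inst)
  cmp <- compare_policies(inst, list(one = pol, two = pol),
                          n_reps = 2, horizon_days = 21, warmup_days = 7,
                          seed = 5)
  expect_equal(nrow(cmp), 2L)
  expect_equal(cmp$total_inventory, rep(sum(pol$Q), 2))
  # identical policies under two names give identical rows (CRN)
  expect_equal(cmp$reschedule_pct[1], cmp$reschedule_pct[2])
  expect_equal(cmp$alternative_pct[1], cmp$alternative_pct[2])
  expect_true(all(cmp$reschedule_hw >= 0))
  cmp2 <- compare_policies(inst, list(one = pol, two = pol),
                           n_reps = 2, horizon_days = 21, warmup_days = 7,
                           seed = 5)
  expect_equal(cmp, cmp2)
})

test_that("tidiers expose steady states and truncation diagnostics", {
  fit <- di_steady_state(c(0.5, 0.5), 1)
  td <- tidy(fit)
  expect_equal(td$state, 0:1)
  expect_equal(sum(td$pi), 1)
  g <- glance(fit)
  expect_equal(g$service_level + g$p_stockout, 1)

  m <- mser(c(rep(100, 10), rep(0, 90)), 2)
  expect_equal(tidy(m)$d[tidy(m)$selected], 5)
  expect_equal(glance(m)$points_truncated, 10)
})

test_that("autoplot methods return ggplot objects", {
  inst <- toy_instance()
  sch <- generate_schedule(inst, 14, seed = 1)
  res <- simulate_cycle(inst, sch, current_policy(inst), warmup_days = 0,
                        seed = 1, log_moves = FALSE)
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(autoplot(mser(rnorm(50), 2)), "ggplot")
  cmp <- compare_policies(inst, list(cur = current_policy(inst)),
                          n_reps = 2, horizon_days = 14, warmup_days = 0,
                          seed = 2)
  expect_s3_class(autoplot(cmp), "ggplot")
})
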