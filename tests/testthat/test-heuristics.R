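test_that("base stock takes the max weekday empirical quantile", {
  # constant demand: any alpha returns the constant
  dem <- manual_demand(rep(5L, 28))
  for (a in c(0.1, 0.5, 0.95, 1)) expect_equal(base_stock(dem, a)$Q, 5L)

  # Mondays {1,2,3}, all other weekdays 0: alpha = 0.5 -> 2
  counts <- rep(0L, 21)
  counts[c(1, 8, 15)] <- c(1L, 2L, 3L)
  dem <- manual_demand(counts)
  expect_equal(base_stock(dem, 0.5)$Q, 2L)
  expect_equal(base_stock(dem, 0.34)$Q, 2L)   # F(1) = 1/3 < 0.34
  expect_equal(base_stock(dem, 1 / 3)$Q, 1L)  # F(1) = 1/3 >= 1/3
  expect_equal(base_stock(dem, 1)$Q, 3L)

  expect_error(base_stock(dem, 0), "alpha")
  expect_error(base_stock(dem, 1.2), "alpha")
})

test_that("base stock is monotone in alpha on random demand", {
  set.seed(101)
  for (rep in 1:20) {
    dem <- manual_demand(rpois(35, runif(1, 0.5, 6)))
    alphas <- sort(runif(2, 0.05, 1))
    expect_lte(base_stock(dem, alphas[1])$Q, base_stock(dem, alphas[2])$Q)
  }
})

test_that("cycle-time rule returns the stated ceilings", {
  expect_equal(fk_levels(manual_demand(rep(2L, 14)), 1.5, "mean")$Q, 3L)
  dem <- manual_demand(c(rep(1L, 13), 4L))
  expect_equal(fk_levels(dem, 1.2, "max")$Q, 5L)
  expect_equal(fk_levels(manual_demand(rep(0L, 14)), 1.5, "median")$Q, 0L)
  expect_error(fk_levels(manual_demand(rep(1L, 14)), 1.5, "mode"))
  expect_error(fk_levels(manual_demand(rep(1L, 14)), 0, "mean"))
})

test_that("per-period demand PMFs include quiet periods and sum to one", {
  # no events at all
  ev <- tibble::tibble(time = numeric(), tray_type = character())
  pmf <- discretize_demand(ev, period_hours = 4, horizon_days = 2)
  expect_equal(nrow(pmf), 0L)  # no types known from empty events

  # events at hours 1 and 3 of a single day, 4-hour periods
  ev <- tibble::tibble(time = c(60, 180), tray_type = "A")
  pmf <- discretize_demand(ev, period_hours = 4, horizon_days = 1)
  expect_equal(pmf$prob[pmf$k == 2], 1 / 6)
  expect_equal(pmf$prob[pmf$k == 0], 5 / 6)

  inst <- toy_instance()
  sch <- generate_schedule(inst, 14, seed = 3)
  pmf <- discretize_demand(sch, inst, period_hours = 4)
  sums <- tapply(pmf$prob, pmf$tray_type, sum)
  expect_equal(as.numeric(sums), rep(1, 3), tolerance = 1e-12)
  expect_error(discretize_demand(sch, inst, period_hours = 5),
               "divide 24")
})

test_that("steady state boundary cases match hand calculations", {
  # no demand ever: all inventory stays sterile
  fit <- di_steady_state(c(1), Q = 3)
  expect_equal(fit$pi, c(0, 0, 0, 1))
  expect_equal(fit$service_level, 1)

  # Bernoulli(1/2) demand with a single tray: two-state chain
  fit <- di_steady_state(c(0.5, 0.5), Q = 1)
  expect_equal(fit$pi, c(1 / 3, 2 / 3), tolerance = 1e-12)
  expect_equal(fit$service_level, 5 / 6, tolerance = 1e-12)

  # demand always >= 1 with Q inside the support is degenerate
  expect_error(di_steady_state(c(0, 1), Q = 1), "degenerate")
})

test_that("closed form and recursion match the transition-matrix oracle", {
  set.seed(2024)
  for (rep in 1:100) {
    K <- sample(1:6, 1)
    p <- runif(K + 1)
    p <- p / sum(p)
    Q <- sample(1:8, 1)
    fit <- di_steady_state(p, Q)
    oracle <- stationary_distribution(di_transition_matrix(p, Q))
    expect_lt(max(abs(fit$pi - oracle)), 1e-8)
    expect_true(all(fit$pi >= 0))
    expect_equal(sum(fit$pi), 1, tolerance = 1e-9)
    # service level from the oracle's stationary vector agrees too
    tail <- rev(cumsum(rev(p)))
    pgt <- function(i) if (i + 1 > K) 0 else tail[i + 2]
    beta_oracle <- 1 - sum(oracle * vapply(0:Q, pgt, numeric(1)))
    expect_equal(fit$service_level, beta_oracle, tolerance = 1e-8)
  }
})

test_that("service level is non-decreasing in Q", {
  set.seed(55)
  for (rep in 1:20) {
    K <- sample(1:5, 1)
    p <- runif(K + 1)
    p <- p / sum(p)
    svc <- vapply(1:10, function(Q) di_service(p, Q), numeric(1))
    expect_true(all(diff(svc) >= -1e-12))
  }
})

test_that("di_levels returns the minimal feasible Q", {
  pmf <- tibble::tibble(tray_type = c("zero", "bern", "bern"),
                        k = c(0, 0, 1), prob = c(1, 0.5, 0.5))
  pol <- di_levels(pmf, beta = 0.8)
  expect_equal(pol$Q[pol$tray_type == "zero"], 0L)
  expect_equal(pol$Q[pol$tray_type == "bern"], 1L)  # service 5/6 >= 0.8

  set.seed(7)
  for (rep in 1:10) {
    K <- sample(2:5, 1)
    p <- runif(K + 1)
    p <- p / sum(p)
    beta <- runif(1, 0.7, 0.99)
    pol <- di_levels(tibble::tibble(tray_type = "x", k = 0:K, prob = p), beta)
    Q <- pol$Q
    expect_gte(di_service(p, Q), beta)
    if (Q >= 2) expect_lt(di_service(p, Q - 1), beta)
  }
})

test_that("di_levels is monotone in beta", {
  set.seed(8)
  p <- c(0.4, 0.3, 0.2, 0.1)
  qs <- vapply(c(0.8, 0.9, 0.99, 0.999),
               function(b) di_levels(tibble::tibble(tray_type = "x", k = 0:3,
                                                    prob = p), b)$Q,
               integer(1))
  expect_true(all(diff(qs) >= 0))
})

test_that("mean cycle time comes from post-warm-up makespans", {
  fake <- structure(list(
    makespan = tibble::tibble(tray_type = "A",
                              completed = c(100, 20000, 30000),
                              minutes = c(1000, 720, 1440)),
    warmup_days = 7L), class = "css_sim_result")
  expect_equal(mean_cycle_days(fake), mean(c(720, 1440)) / 1440)
})
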