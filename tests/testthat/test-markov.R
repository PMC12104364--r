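test_that("transition matrices honour the schedule cap and shared transplant rate", {
  p <- generate_parameter_set(seed = 9)
  # year-10 probabilities apply to all later years
  expect_identical(transition_matrix(p, "APD", 15, age = 30),
                   transition_matrix(p, "APD", 10, age = 30))
  # both arms transplant from PD at the same rate
  m_apd <- transition_matrix(p, "APD", 4, age = 5)
  m_capd <- transition_matrix(p, "CAPD", 4, age = 5)
  expect_equal(m_apd["PD", "KT"], m_capd["PD", "KT"])
  # rows are stochastic and death is absorbing
  for (m in list(m_apd, m_capd)) {
    expect_equal(unname(rowSums(m)), rep(1, 4), tolerance = 1e-12)
    expect_equal(unname(m["DEAD", ]), c(0, 0, 0, 1))
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("zero transitions and zero mortality give the identity matrix", {
  p <- toy_params()
  m <- transition_matrix(p, "APD", 1, age = 1)
  expect_equal(unname(m), diag(4))
})

test_that("background mortality merges into every alive state's death entry", {
  p <- toy_params(flat_transitions(pd_dead = 0.1), mortality_p = 0.2)
  m <- transition_matrix(p, "CAPD", 1, age = 1)
  expect_equal(m["PD", "DEAD"], 1 - 0.9 * 0.8)   # competing risks
  expect_equal(m["HD", "DEAD"], 0.2)
  p2 <- toy_params(flat_transitions(pd_dead = 0.1), mortality_p = 0.2,
                   mortality_rule = "max")
  expect_equal(transition_matrix(p2, "CAPD", 1, 1)["PD", "DEAD"], 0.2)
})

test_that("an infeasible row after the mortality merge is a named error", {
  p <- toy_params(flat_transitions(pd_hd = 0.5, pd_kt = 0.3, pd_dead = 0.19),
                  mortality_p = 0.5)
  expect_error(run_cohort(p, "APD"), "infeasible transition row.*PD")
})

test_that("cohort totals match closed forms for a static cohort", {
  # no transitions, utility 0.9, cost 100/cycle, no discounting, 10 cycles
  p <- toy_params()
  r <- run_cohort(p, "APD")
  expect_equal(r$ly, 10)
  expect_equal(r$qaly, 9)
  expect_equal(r$cost, 1000)
  expect_equal(r$cost, r$cost_undiscounted)
  # discounted at 3%: geometric series, first cycle undiscounted
  p3 <- toy_params(dr_costs = 0.03, dr_outcomes = 0.03)
  r3 <- run_cohort(p3, "APD")
  annuity <- sum(100 / 1.03^(0:9))
  expect_equal(r3$cost, annuity, tolerance = 1e-12)
  expect_equal(round(r3$cost, 2), 878.61)
  expect_lt(r3$cost, r3$cost_undiscounted)
})

test_that("unit utilities make QALYs equal life years exactly", {
  p <- generate_parameter_set(seed = 21, config = list(horizon = 30))
  p$utilities$u <- 1
  r <- run_cohort(p, "CAPD")
  expect_identical(r$qaly, r$ly)
})

test_that("discounted totals are monotone non-increasing in the discount rate", {
  vals <- sapply(c(0, 0.015, 0.03, 0.06), function(dr) {
    p <- generate_parameter_set(seed = 33, config = list(horizon = 40))
    p$discounting$costs <- dr; p$discounting$outcomes <- dr
    r <- run_cohort(p, "APD")
    c(r$cost, r$qaly)
  })
  expect_true(all(diff(vals[1, ]) <= 0))
  expect_true(all(diff(vals[2, ]) <= 0))
})

test_that("the engine is deterministic and conserves probability", {
  p <- generate_parameter_set(seed = 13)
  r1 <- run_cohort(p, "APD")
  r2 <- run_cohort(p, "APD")
  expect_identical(r1, r2)
  expect_equal(unname(rowSums(r1$trace)), rep(1, nrow(r1$trace)),
               tolerance = 1e-10)
  expect_true(all(diff(r1$trace[, "DEAD"]) >= -1e-12))
})

test_that("transplant-year costs flow through the tunnel compartment", {
  # everyone transplants after cycle 0 and stays; transplant-year cost 1000,
  # maintenance 10: undiscounted cost over 3 cycles = 100 + 1000 + 10
  tr <- flat_transitions(pd_kt = 1)
  p <- toy_params(tr, cost_kt = c(dmc_y1 = 1000, dmc_y2plus = 10, dnmc = 0),
                  horizon = 3)
  r <- run_cohort(p, "APD")
  expect_equal(r$cost, 100 + 1000 + 10)
  expect_equal(r$ly, 3)
})

test_that("first-year PD costs are indexed by time since model start", {
  p <- toy_params(cost_pd = c(dmc_y1 = 500, dmc_y2plus = 100, dnmc = 7),
                  horizon = 4)
  r <- run_cohort(p, "CAPD")
  expect_equal(r$cost, (500 + 7) + 3 * (100 + 7))
})

test_that("the year1-forever scenario applies the first-year schedule throughout", {
  tr <- flat_transitions(pd_dead = c(0.5, rep(0, 9)))
  p <- toy_params(tr, u_apd = 1, u_capd = 1, horizon = 3)
  base <- run_cohort(p, "APD", scenario = "base")
  sc <- run_cohort(p, "APD", scenario = "year1_forever")
  expect_equal(base$ly, 1 + 0.5 + 0.5)
  expect_equal(sc$ly, 1 + 0.5 + 0.25)
})

test_that("the cohort stops at the age cap or at extinction", {
  p <- toy_params(horizon = NULL, start_age = 90, max_age = 100)
  r <- run_cohort(p, "APD")
  expect_equal(r$n_cycles, 10)  # ages 90..99
  p2 <- toy_params(flat_transitions(pd_dead = 0.999), horizon = NULL)
  r2 <- run_cohort(p2, "APD")
  expect_lt(r2$n_cycles, 5)
})

test_that("traces export as tidy tables", {
  p <- toy_params(horizon = 5)
  tt <- trace_table(run_cohort(p, "APD"))
  expect_named(tt, c("cycle", "age", "state", "occupancy"))
  expect_equal(nrow(tt), 6 * 4)
  expect_equal(sum(tt$occupancy), 6, tolerance = 1e-10)
})

test_that("half-cycle correction averages start and end occupancy", {
  tr <- flat_transitions(pd_dead = 0.5)
  p <- toy_params(tr, u_apd = 1, u_capd = 1, horizon = 1)
  p$settings$half_cycle_correction <- TRUE
  r <- run_cohort(p, "APD")
  expect_equal(r$ly, 0.75)  # mean of 1 and 0.5 over the single cycle
})
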