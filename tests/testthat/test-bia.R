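# The ten published yearly patient counts and table cells for 2023-2032.
published_counts <- c(618, 671, 724, 778, 831, 884, 937, 990, 1043, 1051)
published_capd <- c(268, 291, 314, 337, 360, 383, 406, 429, 452, 456)
published_apd <- c(307, 333, 360, 387, 413, 439, 466, 492, 518, 522)
published_inc <- c(39, 42, 46, 49, 53, 56, 59, 63, 66, 66)
published_nbi <- c(63107, 62593, 63536, 62982, 63779, 63348, 62967, 63636,
                   63279, 62797)

test_that("the published budget-impact table is reproduced cell for cell", {
  cfg <- pd_example_bia()
  expect_equal(cfg$counts, published_counts)
  bia <- compute_bia(cfg$counts, cfg)
  expect_equal(bia$year, 2023:2032)
  expect_equal(bia$budget_capd, published_capd)
  expect_equal(bia$budget_apd, published_apd)
  expect_equal(bia$incremental, published_inc)
  expect_equal(bia$nbi_per_patient, published_nbi)
  avg <- attr(bia, "average")
  expect_equal(unname(avg["n_patients"]), 853)
  expect_equal(unname(avg["budget_capd"]), 370)
  expect_equal(unname(avg["budget_apd"]), 424)
  expect_equal(unname(avg["incremental"]), 54)
  expect_equal(unname(avg["nbi_per_patient"]), 63202)
  rep <- bia_report(bia)
  expect_equal(rep$year[nrow(rep)], "Average")
})

test_that("the first projected year adds the incident cases to the stock", {
  # with zero attrition, count(2021) = count(2020) + 61
  cfg <- bia_config(p_kt = 0, p_hd = 0, p_death = 0, incident = 61,
                    years = 2021:2030)
  expect_equal(project_patients(cfg, n_start = 500, n_years = 1), 561)
  # zero incidence and zero attrition leave the population constant
  cfg0 <- bia_config(p_kt = 0, p_hd = 0, p_death = 0, incident = 0)
  expect_equal(project_patients(cfg0, n_start = 500), rep(500, 10))
})

test_that("projection follows the attrition-and-incidence recurrence", {
  cfg <- bia_config(p_kt = 0.079, p_hd = 0.031, p_death = 0.023, incident = 10)
  expect_equal(project_patients(cfg, n_start = 100, n_years = 1),
               100 * 0.867 + 10)  # = 96.7
  # all-age incidence converts through the pediatric and PD proportions
  cfg2 <- bia_config(p_kt = 0, p_hd = 0, p_death = 0, years = 2023:2024)
  out <- project_patients(cfg2, n_start = 0, n_years = 2,
                          all_age_incidence = c(20000, 20000))
  expect_equal(out, cumsum(rep(20000 * 0.004 * 0.76, 2)))
})

test_that("degenerate counts are handled explicitly", {
  cfg <- bia_config(years = 2023:2024)
  bia <- compute_bia(c(0, 10), cfg)
  expect_equal(bia$budget_capd[1], 0)
  expect_equal(bia$budget_apd[1], 0)
  expect_true(is.na(bia$nbi_per_patient[1]))
  expect_false(is.na(bia$nbi_per_patient[2]))
  expect_error(bia_config(p_kt = 0.6, p_hd = 0.3, p_death = 0.2), "sum above 1")
  expect_error(bia_config(cost_capd = -1), "positive")
})

test_that("yearly NBI deviates from the unit-cost difference only by rounding", {
  # unrounded NBI per patient is constant at 496836 - 433641 = 63195 baht
  cfg <- pd_example_bia()
  exact <- compute_bia(cfg$counts, cfg, rounding = "exact")
  expect_equal(exact$nbi_per_patient, rep(496836 - 433641, 10))
  printed <- compute_bia(cfg$counts, cfg, rounding = "printed")
  big <- printed$n_patients >= 500
  expect_true(all(abs(printed$nbi_per_patient[big] - 63195) <= 650))
})

test_that("run_bia uses supplied counts or projects from a starting stock", {
  cfg <- pd_example_bia()
  expect_equal(run_bia(cfg)$n_patients, published_counts)
  cfg$counts <- NULL
  proj <- run_bia(cfg, n_start = 600)
  expect_equal(nrow(proj), 10)
  expect_error(run_bia(bia_config()), "starting count")
})
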