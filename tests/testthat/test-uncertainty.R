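# A two-parameter toy model for tornado verification: CIs only on the APD
# utility and the APD maintenance direct medical cost.
toy_dsa_params <- function() {
  p <- toy_params(u_apd = 0.92, u_capd = 0.88,
                  cost_pd = c(dmc_y1 = 100, dmc_y2plus = 100, dnmc = 0))
  i_u <- which(p$utilities$state == "PD" & p$utilities$arm %in% "APD")
  p$utilities$low[i_u] <- 0.90; p$utilities$high[i_u] <- 0.94
  i_c <- which(p$costs$arm %in% "APD" & p$costs$component == "dmc_y2plus")
  p$costs$value[i_c] <- 150
  p$costs$low[i_c] <- 120; p$costs$high[i_c] <- 180
  validate_params(p)
}

test_that("tornado entries equal brute-force re-evaluation at each bound", {
  p <- toy_dsa_params()
  tor <- one_way_sa(p, discount_range = NULL)
  expect_s3_class(tor, "pd_tornado")
  expect_setequal(tor$id, c("u_APD", "c_APD_dmc_y2plus"))
  # independent brute force: edit the tables directly and recompute
  i_u <- which(p$utilities$state == "PD" & p$utilities$arm %in% "APD")
  for (bound in c("low", "high")) {
    q <- p; q$utilities$u[i_u] <- p$utilities[[bound]][i_u]
    capd <- run_cohort(q, "CAPD"); apd <- run_cohort(q, "APD")
    expect_equal(tor[tor$id == "u_APD", paste0("icer_at_", bound)],
                 (apd$cost - capd$cost) / (apd$qaly - capd$qaly))
  }
  i_c <- which(p$costs$arm %in% "APD" & p$costs$component == "dmc_y2plus")
  for (bound in c("low", "high")) {
    q <- p; q$costs$value[i_c] <- p$costs[[bound]][i_c]
    capd <- run_cohort(q, "CAPD"); apd <- run_cohort(q, "APD")
    expect_equal(tor[tor$id == "c_APD_dmc_y2plus", paste0("icer_at_", bound)],
                 (apd$cost - capd$cost) / (apd$qaly - capd$qaly))
  }
})

test_that("zero-width CIs rank last with zero range", {
  p <- toy_dsa_params()
  i_u2 <- which(p$utilities$state == "PD" & p$utilities$arm %in% "CAPD")
  p$utilities$low[i_u2] <- p$utilities$u[i_u2]
  p$utilities$high[i_u2] <- p$utilities$u[i_u2]
  tor <- one_way_sa(validate_params(p), discount_range = NULL)
  expect_equal(tor$id[nrow(tor)], "u_CAPD")
  expect_equal(tor$range[nrow(tor)], 0)
  expect_true(all(diff(tor$range) <= 0))
})

test_that("PSA sampling recovers means and respects supports", {
  # beta with mean 0.89 and CI (0.85, 0.93): empirical mean of 10,000 draws
  # is within 0.005 of the mean
  p <- toy_params(u_capd = 0.89)
  i <- which(p$utilities$state == "PD" & p$utilities$arm %in% "CAPD")
  p$utilities$low[i] <- 0.85; p$utilities$high[i] <- 0.93
  fits <- pedpdcua:::fit_distributions(validate_params(p))
  expect_named(fits, "u_CAPD")
  expect_equal(fits$u_CAPD$family, "beta")
  draws <- with_seed(99, rbeta(10000, fits$u_CAPD$par1, fits$u_CAPD$par2))
  expect_lt(abs(mean(draws) - 0.89), 0.005)
  expect_true(all(draws >= 0 & draws <= 1))
  # gamma costs never go negative
  pc <- toy_params()
  ic <- which(pc$costs$arm %in% "APD" & pc$costs$component == "dmc_y1")
  pc$costs$low[ic] <- 50; pc$costs$high[ic] <- 150
  fc <- pedpdcua:::fit_distributions(validate_params(pc))
  dc <- with_seed(7, rgamma(5000, shape = fc[[1]]$par1, rate = fc[[1]]$par2))
  expect_true(all(dc >= 0))
  expect_lt(abs(mean(dc) - 100), 2)
})

test_that("an infeasible beta moment fit falls back to uniform with a warning", {
  p <- toy_params(u_capd = 0.98)
  i <- which(p$utilities$state == "PD" & p$utilities$arm %in% "CAPD")
  # CI so wide the implied variance exceeds m(1-m)
  p$utilities$low[i] <- 0.30; p$utilities$high[i] <- 1.0
  expect_warning(fits <- pedpdcua:::fit_distributions(validate_params(p)),
                 "uniform")
  expect_equal(fits$u_CAPD$family, "unif")
})

test_that("parameter sets without CIs are fixed in the PSA", {
  p <- toy_params()  # no CIs anywhere
  psa <- run_psa(p, n_draws = 5, seed = 4)
  expect_equal(ncol(psa$parameter_draws), 0)
  expect_true(all(psa$draws$dcost == psa$base$inc_cost))
  expect_true(all(psa$draws$dqaly == psa$base$inc_qaly))
})

test_that("the PSA is reproducible given its seed", {
  p <- generate_parameter_set(seed = 55, config = list(horizon = 25))
  a <- run_psa(p, n_draws = 15, seed = 123)
  b <- run_psa(p, n_draws = 15, seed = 123)
  expect_identical(a$draws, b$draws)
  expect_identical(a$parameter_draws, b$parameter_draws)
  c <- run_psa(p, n_draws = 15, seed = 124)
  expect_false(identical(a$draws, c$draws))
})

test_that("acceptability probabilities sum to one and obey limits", {
  p <- generate_parameter_set(seed = 71, config = list(horizon = 25))
  psa <- run_psa(p, n_draws = 40, seed = 6)
  cc <- ceac(psa, wtp_grid = seq(0, 4e5, 5e4))
  expect_equal(cc$p_alt + cc$p_ref, rep(1, nrow(cc)))
  expect_true(all(cc$p_alt >= 0 & cc$p_alt <= 1))
  # at wtp 0 the decision is purely about cost
  expect_equal(ceac(psa, wtp_grid = 0)$p_ref,
               mean(psa$draws$dcost > 0) + 0.5 * mean(psa$draws$dcost == 0))
  # force all draws to gain QALYs: P(APD) -> 1 as wtp grows, non-decreasing
  psa$draws$dqaly <- abs(psa$draws$dqaly) + 1e-6
  cc2 <- ceac(psa, wtp_grid = c(0, 1e5, 1e7, 1e12))
  expect_true(all(diff(cc2$p_alt) >= 0))
  expect_equal(cc2$p_alt[nrow(cc2)], 1)
  # default grid includes the Thai threshold
  expect_true(160000 %in% ceac(psa)$wtp)
})

test_that("sampled transition rows are repaired to remain feasible", {
  p <- generate_parameter_set(seed = 31, config = list(horizon = 20))
  with_seed(11, {
    for (k in 1:20) {
      s <- sample_parameters(p)
      tr <- s$params$transitions
      for (arm in c("APD", "CAPD")) for (y in 1:10) for (fr in c("PD", "HD", "KT")) {
        expect_lte(sum(tr$p[tr$arm == arm & tr$year == y & tr$from == fr]),
                   1 + 1e-12)
      }
    }
  })
})
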