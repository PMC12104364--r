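test_that("validation rejects malformed parameter sets with named errors", {
  expect_error(toy_params(flat_transitions(pd_hd = 0.6, pd_kt = 0.3, pd_dead = 0.3)),
               "exit probabilities from PD")
  # unequal PD->KT across arms violates the shared-transplant assumption
  tr <- flat_transitions(pd_kt = 0.05)
  tr$p[tr$arm == "APD" & tr$from == "PD" & tr$to == "KT" & tr$year == 2] <- 0.07
  expect_error(toy_params(tr), "PD->KT")
  expect_error(toy_params(u_apd = 1.2), "utilities")
  expect_error(toy_params(dr_costs = 0.2), "discounting")
  # CI must bracket the point value
  p <- toy_params()
  p$utilities$low[1] <- 0.95; p$utilities$high[1] <- 0.99
  expect_error(validate_params(p), "bracket")
  # mortality must cover every reachable age of a lifetime run
  p <- toy_params(horizon = NULL)
  p$mortality <- p$mortality[p$mortality$age < 50, ]
  expect_error(validate_params(p), "mortality")
  # missing transition rows
  p <- toy_params()
  p$transitions <- p$transitions[-1, ]
  expect_error(validate_params(p), "missing")
})

test_that("packaged fixture carries the published main-text values", {
  p <- pd_example_params()
  u <- p$utilities
  expect_equal(u$u[u$state == "PD" & u$arm %in% "CAPD"], 0.8900)
  expect_equal(u$u[u$state == "PD" & u$arm %in% "APD"], 0.9400)
  expect_equal(p$discounting$costs, 0.03)
  expect_equal(p$discounting$outcomes, 0.03)
  expect_equal(p$settings$wtp, 160000)
  expect_equal(p$settings$start_age, 1L)
  # provenance is tracked row by row; the supplementary slots are synthetic
  expect_false(is_transcribed(p))
  expect_true("main_text" %in% names(provenance_summary(p)))
})

test_that("parameter sets round-trip through JSON and CSV bundles", {
  p <- generate_parameter_set(seed = 101, config = list(horizon = 20))
  tmp <- tempfile(fileext = ".json")
  write_params(p, tmp, format = "json")
  q <- read_params(tmp)
  expect_equal(q$transitions, p$transitions)
  expect_equal(q$costs, p$costs)
  expect_equal(q$utilities, p$utilities)
  expect_equal(q$mortality, p$mortality)
  expect_equal(q$discounting, p$discounting)
  expect_equal(q$settings, p$settings)

  dir <- tempfile()
  write_params(p, dir, format = "csv")
  expect_setequal(list.files(dir),
                  c("transitions.csv", "costs.csv", "utilities.csv",
                    "mortality.csv", "settings.csv"))
  r <- read_params(dir)
  expect_equal(r$transitions$p, p$transitions$p)
  expect_equal(r$costs$value, p$costs$value)
  expect_equal(r$settings, p$settings)
})

test_that("unknown schema and missing files are schema errors", {
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(list(schema = "other"), tmp, auto_unbox = TRUE)
  expect_error(read_params(tmp), "schema")
  expect_error(read_params(tempfile()), "not found")
})

test_that("the parameter registry lists CIs and setters update both arms", {
  p <- generate_parameter_set(seed = 5, config = list(horizon = 15))
  reg <- uncertain_parameters(p)
  expect_true(all(c("u_APD", "u_CAPD", "dr_costs") %in% reg$id))
  expect_true(any(grepl("^p_PDtoKT_y", reg$id)))
  # the shared transplant probability has one entry, set in both arms
  q <- set_parameter(p, "p_PDtoKT_y3", 0.02)
  i <- q$transitions$from == "PD" & q$transitions$to == "KT" & q$transitions$year == 3
  expect_equal(q$transitions$p[i], c(0.02, 0.02))
  # out-of-support values clamp with a warning
  expect_warning(q <- set_parameter(p, "u_APD", 1.4), "clamped")
  expect_equal(q$utilities$u[q$utilities$arm %in% "APD"], 1)
  expect_error(set_parameter(p, "no_such_param", 1), "unknown parameter")
})
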