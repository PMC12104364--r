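# Build small fully-specified parameter sets in code. Probabilities may be
# scalars (constant over years 1-10) or length-10 vectors.

flat_transitions <- function(pd_hd = 0, pd_kt = 0, pd_dead = 0,
                             hd_pd = 0, hd_dead = 0,
                             kt_hd = 0, kt_pd = 0, kt_dead = 0) {
  probs <- list(pd_hd, pd_kt, pd_dead, hd_pd, hd_dead, kt_hd, kt_pd, kt_dead)
  from <- c("PD", "PD", "PD", "HD", "HD", "KT", "KT", "KT")
  to <- c("HD", "KT", "DEAD", "PD", "DEAD", "HD", "PD", "DEAD")
  do.call(rbind, lapply(c("APD", "CAPD"), function(arm) {
    do.call(rbind, lapply(seq_along(from), function(j) {
      data.frame(arm = arm, year = 1:10, from = from[j], to = to[j],
                 p = rep_len(probs[[j]], 10), stringsAsFactors = FALSE)
    }))
  }))
}

toy_params <- function(transitions = flat_transitions(),
                       cost_pd = c(dmc_y1 = 100, dmc_y2plus = 100, dnmc = 0),
                       cost_hd = c(dmc_y1 = 0, dmc_y2plus = 0, dnmc = 0),
                       cost_kt = c(dmc_y1 = 0, dmc_y2plus = 0, dnmc = 0),
                       u_apd = 0.9, u_capd = 0.9, u_hd = 0.7, u_kt = 0.8,
                       mortality_p = 0, dr_costs = 0, dr_outcomes = 0,
                       horizon = 10, start_age = 1, max_age = 100,
                       wtp = 160000, ...) {
  costs <- rbind(
    data.frame(state = "PD", arm = "APD", component = names(cost_pd),
               value = unname(cost_pd), stringsAsFactors = FALSE),
    data.frame(state = "PD", arm = "CAPD", component = names(cost_pd),
               value = unname(cost_pd), stringsAsFactors = FALSE),
    data.frame(state = "HD", arm = NA_character_, component = names(cost_hd),
               value = unname(cost_hd), stringsAsFactors = FALSE),
    data.frame(state = "KT", arm = NA_character_, component = names(cost_kt),
               value = unname(cost_kt), stringsAsFactors = FALSE)
  )
  utilities <- data.frame(
    state = c("PD", "PD", "HD", "KT"),
    arm = c("APD", "CAPD", NA, NA),
    u = c(u_apd, u_capd, u_hd, u_kt), stringsAsFactors = FALSE
  )
  mortality <- data.frame(age = 0:max_age, p = mortality_p,
                          stringsAsFactors = FALSE)
  pd_parameters(transitions = transitions, costs = costs,
                utilities = utilities, mortality = mortality,
                discount_costs = dr_costs, discount_outcomes = dr_outcomes,
                start_age = start_age, max_age = max_age, horizon = horizon,
                wtp = wtp, ...)
}

# Attach a CI to one registry parameter by editing the underlying table.
with_ci <- function(params, table, rows, low, high) {
  col <- switch(table, transitions = "p", costs = "value", utilities = "u")
  params[[table]]$low[rows] <- low
  params[[table]]$high[rows] <- high
  validate_params(params)
}
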