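STATES <- c("PD", "HD", "KT", "DEAD")

#' Build the one-cycle transition matrix for one arm
#'
#' Assembles the 4x4 row-stochastic matrix over states \code{PD}, \code{HD},
#' \code{KT}, \code{DEAD} for a given model year and cohort age. The
#' schedule year is capped at 10 (year-10 probabilities apply thereafter);
#' death probabilities of the alive states are merged with the age-specific
#' background mortality via [combine_mortality()]; each row's
#' stay-probability is the residual after all exits. Failed hemodialysis or
#' transplantation returns to the arm's own PD modality.
#'
#' @param params a \code{pd_params} object.
#' @param arm \code{"APD"} or \code{"CAPD"}.
#' @param model_year model year, 1-based; capped at 10.
#' @param age cohort age (years) during the cycle; must be covered by the
#'   mortality table.
#' @return 4x4 matrix with dimnames \code{PD, HD, KT, DEAD}; rows sum to 1.
#' @export
transition_matrix <- function(params, arm, model_year, age) {
  sched <- schedule_array(params)
  p_bg <- background_mortality(params, age)
  tm_from_schedule(sched[[arm]], min(model_year, 10L), p_bg,
                   params$settings$mortality_rule, arm, age)
}

# Internal: per-arm 10 x 8 numeric matrix of scheduled probabilities,
# columns in PD_TRANSITIONS order. Cached on the params object is not
# possible (immutability), so callers that loop precompute it once.
schedule_array <- function(params) {
  tr <- params$transitions
  out <- list()
  for (arm in params$arms) {
    m <- matrix(NA_real_, nrow = 10, ncol = nrow(PD_TRANSITIONS))
    for (j in seq_len(nrow(PD_TRANSITIONS))) {
      sub <- tr[tr$arm == arm & tr$from == PD_TRANSITIONS$from[j] &
                  tr$to == PD_TRANSITIONS$to[j], ]
      m[sub$year, j] <- sub$p
    }
    colnames(m) <- paste(PD_TRANSITIONS$from, PD_TRANSITIONS$to, sep = "_")
    out[[arm]] <- m
  }
  out
}

background_mortality <- function(params, age) {
  mt <- params$mortality
  i <- match(age, mt$age)
  if (is.na(i)) stop("mortality table does not cover age ", age)
  mt$p[i]
}

# Internal workhorse shared by transition_matrix() and the cycle loop.
tm_from_schedule <- function(sched_arm, year, p_bg, rule, arm, age) {
  p <- sched_arm[year, ]
  d_pd <- combine_mortality(p[["PD_DEAD"]], p_bg, rule)
  d_hd <- combine_mortality(p[["HD_DEAD"]], p_bg, rule)
  d_kt <- combine_mortality(p[["KT_DEAD"]], p_bg, rule)
  m <- matrix(0, 4, 4, dimnames = list(STATES, STATES))
  m["PD", "HD"] <- p[["PD_HD"]]; m["PD", "KT"] <- p[["PD_KT"]]; m["PD", "DEAD"] <- d_pd
  m["HD", "PD"] <- p[["HD_PD"]]; m["HD", "DEAD"] <- d_hd
  m["KT", "PD"] <- p[["KT_PD"]]; m["KT", "HD"] <- p[["KT_HD"]]; m["KT", "DEAD"] <- d_kt
  for (s in c("PD", "HD", "KT")) {
    stay <- 1 - sum(m[s, ])
    if (stay < -1e-9) {
      stop("infeasible transition row: exits from ", s, " exceed 1 after ",
           "background-mortality merge (arm ", arm, ", schedule year ", year,
           ", age ", age, ")")
    }
    m[s, s] <- max(stay, 0)
  }
  m["DEAD", "DEAD"] <- 1
  m
}

#' Run the cohort model for one arm
#'
#' Advances a cohort starting 100\% in the assigned PD modality at
#' \code{start_age} through one-year cycles until the age cap (default 100),
#' an explicit horizon, or cohort extinction (alive fraction below 1e-6).
#' Per cycle, state costs and utilities accrue to the occupancy at the start
#' of the cycle (optionally the half-cycle mean) and are discounted by
#' \eqn{(1+r)^{-t}} with \eqn{t = 0} for the first cycle. First-year versus
#' subsequent-year direct medical costs are selected by time since model
#' start for the PD modality and hemodialysis, and by time since state entry
#' for transplantation (tracked internally through a transplant-year tunnel
#' compartment, since the transplant-year cost differs from maintenance).
#'
#' @param params a \code{pd_params} object.
#' @param arm \code{"APD"} or \code{"CAPD"}.
#' @param scenario \code{"base"} uses the scheduled year-specific
#'   probabilities (year 10 onward constant); \code{"year1_forever"} applies
#'   the year-1 schedule to every cycle.
#' @return object of class \code{pd_arm_result}: discounted and undiscounted
#'   totals (\code{cost}, \code{ly}, \code{qaly}), the cohort trace (matrix
#'   of state occupancy per cycle over \code{PD, HD, KT, DEAD}), and the run
#'   settings.
#' @examples
#' p <- generate_parameter_set(seed = 1)
#' r <- run_cohort(p, "APD")
#' r$qaly
#' @export
run_cohort <- function(params, arm = c("APD", "CAPD"),
                       scenario = c("base", "year1_forever")) {
  arm <- match.arg(arm)
  scenario <- match.arg(scenario)
  st <- params$settings
  sched <- schedule_array(params)[[arm]]
  mt_age <- params$mortality$age
  mt_p <- params$mortality$p
  rule <- st$mortality_rule
  hcc <- st$half_cycle_correction

  cm <- cost_map(params, arm)
  um <- utility_map(params, arm)
  dr_c <- params$discounting$costs
  dr_o <- params$discounting$outcomes

  max_cycles <- st$max_age - st$start_age
  if (!is.null(st$horizon)) max_cycles <- min(max_cycles, st$horizon)

  # internal compartments: PD, HD, KT year-of-entry tunnel, KT established, DEAD
  v <- c(1, 0, 0, 0, 0)
  cost_d <- cost_u <- ly_d <- ly_u <- qaly_d <- qaly_u <- 0
  trace <- matrix(NA_real_, nrow = max_cycles + 1L, ncol = 4L,
                  dimnames = list(NULL, STATES))
  trace[1L, ] <- collapse5(v)
  n_cycles <- 0L

  for (t in seq_len(max_cycles) - 1L) {
    alive <- 1 - v[5L]
    if (alive < 1e-6) break
    age <- st$start_age + t
    year <- if (scenario == "year1_forever") 1L else min(t + 1L, 10L)
    p_bg <- mt_p[match(age, mt_age)]
    m4 <- tm_from_schedule(sched, year, p_bg, rule, arm, age)
    m5 <- expand_tunnel(m4)
    v_next <- as.numeric(v %*% m5)

    occ <- if (hcc) (v + v_next) / 2 else v
    model_year1 <- (t == 0L)
    cyc_cost <- occ[1L] * (if (model_year1) cm$pd_y1 else cm$pd_y2) +
      occ[2L] * (if (model_year1) cm$hd_y1 else cm$hd_y2) +
      occ[3L] * cm$kt_y1 + occ[4L] * cm$kt_y2
    cyc_ly <- sum(occ[1:4])
    cyc_qaly <- occ[1L] * um$pd + occ[2L] * um$hd + (occ[3L] + occ[4L]) * um$kt

    cost_u <- cost_u + cyc_cost
    ly_u <- ly_u + cyc_ly
    qaly_u <- qaly_u + cyc_qaly
    cost_d <- cost_d + cyc_cost / (1 + dr_c)^t
    ly_d <- ly_d + cyc_ly / (1 + dr_o)^t
    qaly_d <- qaly_d + cyc_qaly / (1 + dr_o)^t

    v <- v_next
    n_cycles <- t + 1L
    trace[t + 2L, ] <- collapse5(v)
  }
  trace <- trace[seq_len(n_cycles + 1L), , drop = FALSE]

  structure(list(
    arm = arm, scenario = scenario,
    cost = cost_d, ly = ly_d, qaly = qaly_d,
    cost_undiscounted = cost_u, ly_undiscounted = ly_u,
    qaly_undiscounted = qaly_u,
    trace = trace, n_cycles = n_cycles,
    start_age = st$start_age,
    discounting = params$discounting,
    wtp = st$wtp
  ), class = "pd_arm_result")
}

# 4x4 matrix -> 5x5 with the KT year-of-entry tunnel: entries into KT land
# in the tunnel; tunnel residents exit like KT but their stay-probability
# moves them to established KT.
expand_tunnel <- function(m4) {
  m5 <- matrix(0, 5, 5)
  m5[1L, c(1L, 2L, 3L, 5L)] <- m4["PD", c("PD", "HD", "KT", "DEAD")]
  m5[2L, c(1L, 2L, 3L, 5L)] <- m4["HD", c("PD", "HD", "KT", "DEAD")]
  kt <- m4["KT", ]
  m5[3L, ] <- c(kt[["PD"]], kt[["HD"]], 0, kt[["KT"]], kt[["DEAD"]])
  m5[4L, ] <- c(kt[["PD"]], kt[["HD"]], 0, kt[["KT"]], kt[["DEAD"]])
  m5[5L, 5L] <- 1
  m5
}

collapse5 <- function(v) c(v[1L], v[2L], v[3L] + v[4L], v[5L])

cost_map <- function(params, arm) {
  co <- params$costs
  pick <- function(state, component, use_arm = NA) {
    hit <- co$state == state & co$component == component &
      (if (is.na(use_arm)) is.na(co$arm) else !is.na(co$arm) & co$arm == use_arm)
    co$value[hit]
  }
  list(
    pd_y1 = pick("PD", "dmc_y1", arm) + pick("PD", "dnmc", arm),
    pd_y2 = pick("PD", "dmc_y2plus", arm) + pick("PD", "dnmc", arm),
    hd_y1 = pick("HD", "dmc_y1") + pick("HD", "dnmc"),
    hd_y2 = pick("HD", "dmc_y2plus") + pick("HD", "dnmc"),
    kt_y1 = pick("KT", "dmc_y1") + pick("KT", "dnmc"),
    kt_y2 = pick("KT", "dmc_y2plus") + pick("KT", "dnmc")
  )
}

utility_map <- function(params, arm) {
  ut <- params$utilities
  list(
    pd = ut$u[ut$state == "PD" & !is.na(ut$arm) & ut$arm == arm],
    hd = ut$u[ut$state == "HD" & is.na(ut$arm)],
    kt = ut$u[ut$state == "KT" & is.na(ut$arm)]
  )
}

#' @export
print.pd_arm_result <- function(x, ...) {
  cat(sprintf("Cohort result, %s arm (%s scenario): %d cycles from age %d\n",
              x$arm, x$scenario, x$n_cycles, x$start_age))
  cat(sprintf("  discounted:   cost %15s baht   LY %7.3f   QALY %7.3f\n",
              format(round(x$cost), big.mark = ","), x$ly, x$qaly))
  cat(sprintf("  undiscounted: cost %15s baht   LY %7.3f   QALY %7.3f\n",
              format(round(x$cost_undiscounted), big.mark = ","),
              x$ly_undiscounted, x$qaly_undiscounted))
  invisible(x)
}

#' Export a cohort trace as a long data frame
#'
#' @param result a \code{pd_arm_result}.
#' @return data.frame with columns \code{cycle}, \code{age}, \code{state},
#'   \code{occupancy}, suitable for CSV export.
#' @export
trace_table <- function(result) {
  tr <- result$trace
  n <- nrow(tr)
  data.frame(
    cycle = rep(seq_len(n) - 1L, times = ncol(tr)),
    age = rep(result$start_age + seq_len(n) - 1L, times = ncol(tr)),
    state = rep(colnames(tr), each = n),
    occupancy = as.numeric(tr),
    stringsAsFactors = FALSE
  )
}

#' Plot a cohort trace
#'
#' State-occupancy fractions against cycle for one arm, base graphics.
#'
#' @param x a \code{pd_arm_result}.
#' @param ... passed to \code{matplot}.
#' @export
plot.pd_arm_result <- function(x, ...) {
  graphics::matplot(x = seq_len(nrow(x$trace)) - 1L, y = x$trace, type = "l",
                    lty = 1, lwd = 2, col = c("#1b9e77", "#d95f02", "#7570b3", "grey40"),
                    xlab = "cycle (years)", ylab = "occupancy fraction",
                    main = sprintf("%s arm cohort trace", x$arm), ...)
  graphics::legend("right", legend = colnames(x$trace), lty = 1, lwd = 2,
                   col = c("#1b9e77", "#d95f02", "#7570b3", "grey40"), bty = "n")
  invisible(x)
}
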