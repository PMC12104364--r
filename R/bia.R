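#' Budget-impact configuration
#'
#' Inputs for the ten-year budget-impact projection of adopting APD for all
#' pediatric PD patients, from the government (direct-medical-cost)
#' perspective: annual per-patient costs of each modality, annual attrition
#' probabilities out of the PD population (transplantation, transfer to
#' hemodialysis, death), the proportions converting an all-age ESKD series
#' into pediatric PD patients, incident cases, uptake and projection years.
#'
#' @param cost_capd,cost_apd annual direct medical cost per patient
#'   (baht/year); defaults are the published 433,641 and 496,836.
#' @param p_kt,p_hd,p_death annual attrition probabilities (defaults 0.079,
#'   0.031, 0.023).
#' @param proportion_pediatric proportion of all-age ESKD patients that are
#'   pediatric (default 0.004).
#' @param proportion_pd probability that a pediatric ESKD patient receives
#'   peritoneal dialysis (default 0.76).
#' @param incident incident pediatric PD cases per year; a scalar (applied
#'   to every projected year) or a vector, one per projection step.
#' @param uptake fraction switching to APD in the first year (default 1).
#' @param years calendar years of the projection (default 2023--2032).
#' @return a validated \code{bia_config} object.
#' @export
bia_config <- function(cost_capd = 433641, cost_apd = 496836,
                       p_kt = 0.079, p_hd = 0.031, p_death = 0.023,
                       proportion_pediatric = 0.004, proportion_pd = 0.76,
                       incident = 61, uptake = 1,
                       years = 2023:2032) {
  cfg <- structure(list(
    cost_capd = cost_capd, cost_apd = cost_apd,
    p_kt = p_kt, p_hd = p_hd, p_death = p_death,
    proportion_pediatric = proportion_pediatric,
    proportion_pd = proportion_pd,
    incident = incident, uptake = uptake, years = years
  ), class = "bia_config")
  probs <- c(p_kt, p_hd, p_death, proportion_pediatric, proportion_pd, uptake)
  if (any(probs < 0 | probs > 1)) stop("bia_config: probabilities/proportions must lie in [0, 1]")
  if (p_kt + p_hd + p_death > 1) stop("bia_config: attrition probabilities sum above 1")
  if (cost_capd <= 0 || cost_apd <= 0) stop("bia_config: costs must be positive")
  if (any(incident < 0)) stop("bia_config: incident cases must be non-negative")
  cfg
}

#' Project the pediatric peritoneal-dialysis population
#'
#' Advances a starting patient count year by year:
#' \eqn{n_{y+1} = n_y (1 - p_{KT} - p_{HD} - p_{death}) + incident_{y+1}}.
#' When \code{all_age_incidence} is supplied, incident pediatric PD cases
#' are derived from it as incidence x proportion_pediatric x proportion_pd.
#' Counts are kept unrounded here; rounding to whole patients happens at
#' report time.
#'
#' @param config a \code{bia_config}.
#' @param n_start patient count in the year preceding the first projected
#'   year.
#' @param n_years number of projected years (default
#'   \code{length(config$years)}).
#' @param all_age_incidence optional vector of all-age ESKD incident cases,
#'   one per projected year, overriding \code{config$incident}.
#' @return numeric vector of projected counts, one per projected year.
#' @export
project_patients <- function(config, n_start, n_years = length(config$years),
                             all_age_incidence = NULL) {
  stopifnot(inherits(config, "bia_config"), n_start >= 0, n_years >= 1)
  inc <- if (!is.null(all_age_incidence)) {
    all_age_incidence * config$proportion_pediatric * config$proportion_pd
  } else {
    rep_len(config$incident, n_years)
  }
  if (length(inc) != n_years) stop("need one incident-case value per projected year")
  keep <- 1 - config$p_kt - config$p_hd - config$p_death
  out <- numeric(n_years)
  n <- n_start
  for (i in seq_len(n_years)) {
    n <- n * keep + inc[i]
    if (n < 0) stop("negative projected patient count in year ", config$years[i])
    out[i] <- n
  }
  out
}

#' Compute the budget-impact table
#'
#' Multiplies yearly patient counts by the annual per-patient cost of each
#' modality and tabulates total budgets, the incremental budget of APD over
#' CAPD, and the net budget impact (NBI) per patient, plus an average row.
#' The \code{"printed"} rounding mode reproduces the published table's
#' arithmetic: the two budget columns are rounded to integer millions of
#' baht; the incremental budget is rounded to integer millions from the
#' unrounded difference (so it can differ by 1 from the difference of the
#' printed budget columns); the NBI per patient divides the rounded
#' incremental budget by the patient count; averages are arithmetic means
#' of the yearly rounded values, rounded again. The \code{"exact"} mode keeps everything
#' unrounded (budgets still reported in millions).
#'
#' @param counts yearly pediatric PD patient counts (one per year).
#' @param config a \code{bia_config}.
#' @param rounding \code{"printed"} (default) or \code{"exact"}.
#' @return object of class \code{bia_table}: data.frame with columns
#'   \code{year}, \code{n_patients}, \code{budget_capd},
#'   \code{budget_apd} (million baht), \code{incremental} (million baht),
#'   \code{nbi_per_patient} (baht), plus an \code{average} attribute row. A
#'   year with zero patients reports zero budgets and an undefined
#'   (\code{NA}) NBI.
#' @examples
#' cfg <- bia_config()
#' compute_bia(c(618, 671, 724), bia_config(years = 2023:2025))
#' @export
compute_bia <- function(counts, config, rounding = c("printed", "exact")) {
  rounding <- match.arg(rounding)
  stopifnot(inherits(config, "bia_config"), all(counts >= 0))
  years <- config$years[seq_along(counts)]
  if (length(years) != length(counts)) stop("more counts than configured years")
  n <- if (rounding == "printed") round(counts) else counts
  if (rounding == "printed") {
    b_capd <- round(n * config$cost_capd / 1e6)
    b_apd <- round(n * config$cost_apd / 1e6)
    inc <- round(n * (config$cost_apd - config$cost_capd) / 1e6)
    nbi <- ifelse(n > 0, round(inc * 1e6 / n), NA_real_)
    avg <- c(n_patients = round(mean(n)), budget_capd = round(mean(b_capd)),
             budget_apd = round(mean(b_apd)), incremental = round(mean(inc)),
             nbi_per_patient = round(mean(nbi, na.rm = TRUE)))
  } else {
    b_capd <- n * config$cost_capd / 1e6
    b_apd <- n * config$cost_apd / 1e6
    inc <- b_apd - b_capd
    nbi <- ifelse(n > 0, inc * 1e6 / n, NA_real_)
    avg <- c(n_patients = mean(n), budget_capd = mean(b_capd),
             budget_apd = mean(b_apd), incremental = mean(inc),
             nbi_per_patient = mean(nbi, na.rm = TRUE))
  }
  structure(data.frame(
    year = years, n_patients = n, budget_capd = b_capd, budget_apd = b_apd,
    incremental = inc, nbi_per_patient = nbi
  ), average = avg, rounding = rounding, config = config,
  class = c("bia_table", "data.frame"))
}

#' Run the budget-impact analysis end to end
#'
#' Uses supplied yearly counts when present in the configuration (published-
#' table mode), otherwise projects them from a starting count via
#' [project_patients()], then tabulates budgets via [compute_bia()].
#'
#' @param config a \code{bia_config}, optionally carrying \code{counts}.
#' @param n_start starting count for projection mode.
#' @param ... passed to [compute_bia()].
#' @return a \code{bia_table}.
#' @export
run_bia <- function(config, n_start = NULL, ...) {
  counts <- config$counts
  if (is.null(counts)) {
    if (is.null(n_start)) stop("supply counts in the config or a starting count to project from")
    counts <- project_patients(config, n_start)
  }
  compute_bia(counts, config, ...)
}

#' @export
print.bia_table <- function(x, ...) {
  cat(sprintf("Budget impact of APD vs CAPD, %d years (%s rounding)\n",
              nrow(x), attr(x, "rounding")))
  df <- as.data.frame(x)
  avg <- attr(x, "average")
  df <- rbind(df, data.frame(year = NA, n_patients = avg[["n_patients"]],
                             budget_capd = avg[["budget_capd"]],
                             budget_apd = avg[["budget_apd"]],
                             incremental = avg[["incremental"]],
                             nbi_per_patient = avg[["nbi_per_patient"]]))
  rownames(df) <- c(rep("", nrow(x)), "Average")
  names(df) <- c("year", "patients", "CAPD (M baht)", "APD (M baht)",
                 "incremental (M)", "NBI/patient (baht)")
  print(df, na.print = "")
  invisible(x)
}

#' Budget-impact table with its average row, for export
#'
#' @param x a \code{bia_table}.
#' @return plain data.frame mirroring the published layout, with a final
#'   \code{Average} row.
#' @export
bia_report <- function(x) {
  stopifnot(inherits(x, "bia_table"))
  avg <- attr(x, "average")
  df <- as.data.frame(x)
  df$year <- as.character(df$year)
  rbind(df, data.frame(year = "Average", n_patients = avg[["n_patients"]],
                       budget_capd = avg[["budget_capd"]],
                       budget_apd = avg[["budget_apd"]],
                       incremental = avg[["incremental"]],
                       nbi_per_patient = avg[["nbi_per_patient"]]))
}
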