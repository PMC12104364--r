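#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the full two-arm comparison with each uncertain parameter set in
#' turn to its 95\% CI bounds (the discount rates to a conventional 0--6\%
#' range), all other parameters held at base values, and records the ICER
#' per QALY at each bound. Parameters without a CI are excluded. Entries are
#' sorted by the width of the resulting ICER range, descending, with ties
#' broken by parameter id.
#'
#' @param params a \code{pd_params} object.
#' @param wtp threshold passed through to the comparisons (does not affect
#'   ICERs).
#' @param scenario cohort scenario, see [run_cohort()].
#' @param discount_range DSA range applied to the discount rates; set to
#'   \code{NULL} to exclude them.
#' @return object of class \code{pd_tornado}: a data.frame with columns
#'   \code{id}, \code{low}, \code{high} (parameter bounds),
#'   \code{icer_at_low}, \code{icer_at_high}, \code{range}, plus attribute
#'   \code{base_icer}.
#' @export
one_way_sa <- function(params, wtp = params$settings$wtp,
                       scenario = c("base", "year1_forever"),
                       discount_range = c(0, 0.06)) {
  scenario <- match.arg(scenario)
  reg <- param_registry(params, discount_range = if (is.null(discount_range))
    c(NA_real_, NA_real_) else discount_range)
  reg <- Filter(function(e) !is.na(e$low) && !is.na(e$high), reg)
  if (!length(reg)) stop("one-way sensitivity analysis needs at least one parameter with a CI")

  icer_of <- function(p) {
    cmp <- compare_strategies(run_cohort(p, "CAPD", scenario),
                              run_cohort(p, "APD", scenario), wtp = wtp)
    cmp$icer_qaly
  }
  base_icer <- icer_of(params)
  rows <- lapply(reg, function(e) {
    lo <- icer_of(set_parameter(params, e$id, e$low))
    hi <- icer_of(set_parameter(params, e$id, e$high))
    data.frame(id = e$id, low = e$low, high = e$high,
               icer_at_low = lo, icer_at_high = hi,
               range = abs(hi - lo), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(-df$range, df$id), ]
  rownames(df) <- NULL
  structure(df, base_icer = base_icer, class = c("pd_tornado", "data.frame"))
}

#' @export
print.pd_tornado <- function(x, n = 10, ...) {
  cat(sprintf("One-way sensitivity analysis: %d parameters, base ICER %s baht/QALY\n",
              nrow(x), format(round(attr(x, "base_icer")), big.mark = ",")))
  print.data.frame(utils::head(x, n), row.names = FALSE, digits = 6)
  if (nrow(x) > n) cat("  ...", nrow(x) - n, "more\n")
  invisible(x)
}

#' Tornado diagram
#'
#' Horizontal bars spanning each parameter's ICER range around the base
#' ICER, widest on top, base graphics.
#'
#' @param x a \code{pd_tornado}.
#' @param n number of parameters shown (default 15).
#' @param ... unused.
#' @export
plot.pd_tornado <- function(x, n = 15, ...) {
  d <- utils::head(x, n)
  d <- d[rev(seq_len(nrow(d))), ]
  base <- attr(x, "base_icer")
  xlim <- range(c(d$icer_at_low, d$icer_at_high, base))
  graphics::plot(NULL, xlim = xlim, ylim = c(0.5, nrow(d) + 0.5), yaxt = "n",
                 xlab = "ICER (baht/QALY)", ylab = "", main = "Tornado diagram")
  graphics::segments(pmin(d$icer_at_low, d$icer_at_high), seq_len(nrow(d)),
                     pmax(d$icer_at_low, d$icer_at_high), seq_len(nrow(d)),
                     lwd = 8, col = "#7570b3")
  graphics::abline(v = base, lty = 2)
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$id, las = 1, cex.axis = 0.6)
  invisible(x)
}

# ---- probabilistic sensitivity analysis ----------------------------------

# Internal: fit a sampling distribution to every parameter with a CI.
# Probabilities and utilities get beta, costs gamma, both by method of
# moments with SE = (high - low) / 3.92; an infeasible beta fit (variance
# too large for the mean) falls back to uniform over the CI with a warning.
# Discount rates carry no CI and stay fixed. Returns a list of entries with
# $id, $family, $par1, $par2 and the registry slot info.
fit_distributions <- function(params) {
  reg <- param_registry(params, discount_range = c(NA_real_, NA_real_))
  fits <- list()
  for (e in reg) {
    if (is.na(e$low) || is.na(e$high)) next  # fixed in PSA
    se <- (e$high - e$low) / 3.92
    m <- e$value
    if (se == 0) next
    if (e$kind %in% c("prob", "utility")) {
      v <- se^2
      if (m <= 0 || m >= 1 || v >= m * (1 - m)) {
        warning("beta moment fit infeasible for ", e$id,
                "; falling back to uniform over the CI")
        fam <- "unif"; p1 <- e$low; p2 <- e$high
      } else {
        nu <- m * (1 - m) / v - 1
        fam <- "beta"; p1 <- m * nu; p2 <- (1 - m) * nu
      }
    } else if (e$kind == "cost") {
      if (m <= 0) {
        fam <- "unif"; p1 <- max(e$low, 0); p2 <- e$high
      } else {
        fam <- "gamma"; p1 <- (m / se)^2; p2 <- m / se^2  # shape, rate
      }
    } else {
      next  # rates: fixed in PSA
    }
    fits[[e$id]] <- list(id = e$id, family = fam, par1 = p1, par2 = p2,
                         table = e$table, rows = e$rows)
  }
  fits
}

#' Draw one parameter set for probabilistic sensitivity analysis
#'
#' Samples every uncertain parameter once from its fitted distribution
#' (beta for probabilities and utilities, gamma for costs, method of moments
#' from the point value and 95\% CI with SE = CI width / 3.92; uniform over
#' the CI when a beta fit is infeasible) and returns the modified parameter
#' set. Parameters without a CI are returned unchanged. Draws are
#' independent across parameters and consume the current RNG stream, so
#' results are reproducible under \code{set.seed}.
#'
#' After sampling, any transition row whose exit probabilities sum above 1
#' is rescaled proportionally to restore feasibility.
#'
#' @param params a \code{pd_params} object.
#' @param fits optional precomputed result of the internal distribution
#'   fitting (used by [run_psa()] to avoid refitting each draw).
#' @return a list with \code{params} (the sampled \code{pd_params}) and
#'   \code{draws} (named numeric vector of sampled values).
#' @export
sample_parameters <- function(params, fits = NULL) {
  if (is.null(fits)) fits <- fit_distributions(params)
  draws <- numeric(length(fits))
  names(draws) <- names(fits)
  for (f in fits) {
    val <- switch(f$family,
                  beta = stats::rbeta(1, f$par1, f$par2),
                  gamma = stats::rgamma(1, shape = f$par1, rate = f$par2),
                  unif = stats::runif(1, f$par1, f$par2))
    draws[[f$id]] <- val
    if (f$table == "transitions") {
      params$transitions$p[f$rows] <- val
    } else if (f$table == "costs") {
      params$costs$value[f$rows] <- val
    } else if (f$table == "utilities") {
      params$utilities$u[f$rows] <- val
    }
  }
  params <- repair_exit_sums(params)
  list(params = params, draws = draws)
}

# Internal: proportional rescale of any transition row set whose exits sum
# above 1 after independent sampling.
repair_exit_sums <- function(params) {
  tr <- params$transitions
  for (arm in params$arms) {
    for (y in 1:10) {
      for (fr in c("PD", "HD", "KT")) {
        i <- which(tr$arm == arm & tr$year == y & tr$from == fr)
        s <- sum(tr$p[i])
        if (s > 1) tr$p[i] <- tr$p[i] / s
      }
    }
  }
  params$transitions <- tr
  params
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo simulation over the model's parameter uncertainty: each
#' iteration samples all uncertain parameters once ([sample_parameters()]),
#' runs both arms, and records the incremental cost, life years and QALYs
#' of APD versus CAPD. Deterministic given the seed.
#'
#' @param params a \code{pd_params} object.
#' @param n_draws number of iterations (default 1000).
#' @param seed integer seed.
#' @param scenario cohort scenario, see [run_cohort()].
#' @return object of class \code{pd_psa}: data.frame \code{draws} with
#'   columns \code{draw}, \code{dcost}, \code{dly}, \code{dqaly}; matrix
#'   \code{parameter_draws} (iterations x parameters); the base-case
#'   \code{pd_cea}; \code{n_draws}, \code{seed}, \code{wtp}.
#' @export
run_psa <- function(params, n_draws = 1000, seed = 1L,
                    scenario = c("base", "year1_forever")) {
  scenario <- match.arg(scenario)
  stopifnot(n_draws >= 1)
  fits <- fit_distributions(params)
  base <- compare_strategies(run_cohort(params, "CAPD", scenario),
                             run_cohort(params, "APD", scenario))
  dcost <- dly <- dqaly <- numeric(n_draws)
  pm <- matrix(NA_real_, nrow = n_draws, ncol = length(fits),
               dimnames = list(NULL, names(fits)))
  with_seed(seed, {
    for (i in seq_len(n_draws)) {
      s <- sample_parameters(params, fits)
      if (length(fits)) pm[i, ] <- s$draws
      capd <- run_cohort(s$params, "CAPD", scenario)
      apd <- run_cohort(s$params, "APD", scenario)
      dcost[i] <- apd$cost - capd$cost
      dly[i] <- apd$ly - capd$ly
      dqaly[i] <- apd$qaly - capd$qaly
    }
  })
  structure(list(
    draws = data.frame(draw = seq_len(n_draws), dcost = dcost, dly = dly,
                       dqaly = dqaly),
    parameter_draws = pm,
    base = base, n_draws = n_draws, seed = seed,
    wtp = params$settings$wtp, scenario = scenario,
    arms = c(ref = "CAPD", alt = "APD")
  ), class = "pd_psa")
}

#' @export
print.pd_psa <- function(x, ...) {
  d <- x$draws
  cat(sprintf("PSA: %d draws (seed %d), APD vs CAPD, %s scenario\n",
              x$n_draws, x$seed, x$scenario))
  cat(sprintf("  mean incremental cost %s baht, mean incremental QALY %.3f\n",
              format(round(mean(d$dcost)), big.mark = ","), mean(d$dqaly)))
  q <- mean(d$dcost > 0 & d$dqaly > 0)
  cat(sprintf("  %.0f%% of draws in the higher-cost/higher-QALY quadrant\n", 100 * q))
  cat(sprintf("  P(APD cost-effective at WTP %s) = %.3f\n",
              format(x$wtp, big.mark = ","),
              ceac(x, wtp_grid = x$wtp)$p_alt))
  invisible(x)
}

#' Cost-effectiveness plane
#'
#' Scatter of per-draw incremental QALYs against incremental costs, base
#' graphics, with the WTP threshold line.
#'
#' @param x a \code{pd_psa}.
#' @param ... passed to \code{plot}.
#' @export
plot.pd_psa <- function(x, ...) {
  d <- x$draws
  graphics::plot(d$dqaly, d$dcost, pch = 16, col = grDevices::adjustcolor("#1b6ca8", 0.4),
                 xlab = "incremental QALYs (APD - CAPD)",
                 ylab = "incremental cost (baht)",
                 main = "Cost-effectiveness plane", ...)
  graphics::abline(h = 0, v = 0, col = "grey60")
  graphics::abline(a = 0, b = x$wtp, lty = 2)
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that each arm is the
#' cost-effective choice: the fraction of PSA draws in which its net
#' monetary benefit is strictly the larger, with ties split equally. The two
#' probabilities sum to 1 at every threshold.
#'
#' @param psa a \code{pd_psa}.
#' @param wtp_grid thresholds (baht/QALY); the default spans 0 to 400,000
#'   in steps of 10,000 and always includes 160,000.
#' @return object of class \code{pd_ceac}: data.frame with columns
#'   \code{wtp}, \code{p_alt} (APD), \code{p_ref} (CAPD).
#' @export
ceac <- function(psa, wtp_grid = NULL) {
  stopifnot(inherits(psa, "pd_psa"), psa$n_draws >= 1)
  if (is.null(wtp_grid)) wtp_grid <- sort(unique(c(seq(0, 400000, by = 10000), 160000)))
  d <- psa$draws
  p_alt <- vapply(wtp_grid, function(w) {
    dn <- w * d$dqaly - d$dcost   # NMB(alt) - NMB(ref)
    mean(dn > 0) + 0.5 * mean(dn == 0)
  }, numeric(1))
  structure(data.frame(wtp = wtp_grid, p_alt = p_alt, p_ref = 1 - p_alt),
            arms = psa$arms, class = c("pd_ceac", "data.frame"))
}

#' @export
plot.pd_ceac <- function(x, ...) {
  graphics::plot(x$wtp, x$p_alt, type = "l", lwd = 2, col = "#d95f02",
                 ylim = c(0, 1), xlab = "willingness to pay (baht/QALY)",
                 ylab = "P(cost-effective)",
                 main = "Cost-effectiveness acceptability curve", ...)
  graphics::lines(x$wtp, x$p_ref, lwd = 2, col = "#1b9e77")
  graphics::legend("right", legend = c("APD", "CAPD"), lwd = 2,
                   col = c("#d95f02", "#1b9e77"), bty = "n")
  invisible(x)
}
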