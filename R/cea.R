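#' Compare two strategy arms: incremental cost-effectiveness
#'
#' Computes incremental cost, life years and QALYs of \code{alt} relative to
#' \code{ref} (alt minus ref, from unrounded totals), the ICER per QALY and
#' per life year, dominance labels per effect axis, and cost-effectiveness
#' at the willingness-to-pay threshold. An ICER with a zero incremental
#' effect is reported as undefined (\code{NA}), not as a division error.
#'
#' @param ref reference-arm \code{pd_arm_result} (CAPD in the base case).
#' @param alt alternative-arm \code{pd_arm_result} (APD).
#' @param wtp willingness-to-pay threshold in baht/QALY; defaults to the
#'   threshold stored with the runs.
#' @return object of class \code{pd_cea} with elements \code{ref},
#'   \code{alt} (per-arm totals), \code{inc_cost}, \code{inc_ly},
#'   \code{inc_qaly}, \code{icer_qaly}, \code{icer_ly}, \code{dominance}
#'   (QALY axis), \code{dominance_ly}, \code{cost_effective}, \code{wtp}.
#' @examples
#' p <- generate_parameter_set(seed = 1)
#' compare_strategies(run_cohort(p, "CAPD"), run_cohort(p, "APD"))
#' @export
compare_strategies <- function(ref, alt, wtp = NULL) {
  stopifnot(inherits(ref, "pd_arm_result"), inherits(alt, "pd_arm_result"))
  if (!isTRUE(all.equal(ref$discounting, alt$discounting))) {
    stop("arms were run with different discount settings; compare like with like")
  }
  if (!identical(ref$scenario, alt$scenario)) {
    stop("arms were run under different scenarios")
  }
  if (is.null(wtp)) wtp <- alt$wtp
  dc <- alt$cost - ref$cost
  dly <- alt$ly - ref$ly
  dq <- alt$qaly - ref$qaly
  icer_q <- if (dq == 0) NA_real_ else dc / dq
  icer_l <- if (dly == 0) NA_real_ else dc / dly
  dom <- function(de) {
    if (dc > 0 && de < 0) "dominated"
    else if (dc < 0 && de > 0) "dominant"
    else "none"
  }
  dominance <- dom(dq)
  ce <- dominance == "dominant" ||
    (dc <= 0 && dq >= 0) ||
    (dc > 0 && dq > 0 && icer_q <= wtp)
  structure(list(
    ref = arm_totals(ref), alt = arm_totals(alt),
    inc_cost = dc, inc_ly = dly, inc_qaly = dq,
    icer_qaly = icer_q, icer_ly = icer_l,
    dominance = dominance, dominance_ly = dom(dly),
    cost_effective = ce, wtp = wtp,
    scenario = ref$scenario
  ), class = "pd_cea")
}

arm_totals <- function(r) {
  list(arm = r$arm, cost = r$cost, ly = r$ly, qaly = r$qaly,
       cost_undiscounted = r$cost_undiscounted,
       ly_undiscounted = r$ly_undiscounted,
       qaly_undiscounted = r$qaly_undiscounted)
}

#' Net monetary benefit of one arm
#'
#' \eqn{NMB = WTP \cdot QALY - cost}. For two strategies, the one with the
#' larger NMB at a given threshold is the cost-effective choice.
#'
#' @param result a \code{pd_arm_result}, or a list with elements \code{qaly}
#'   and \code{cost}.
#' @param wtp willingness-to-pay threshold (baht/QALY), non-negative.
#' @return net monetary benefit in baht.
#' @export
net_monetary_benefit <- function(result, wtp) {
  stopifnot(wtp >= 0)
  wtp * result$qaly - result$cost
}

#' @export
print.pd_cea <- function(x, ...) {
  fmtb <- function(v) format(round(v), big.mark = ",", scientific = FALSE)
  cat(sprintf("Cost-utility comparison: %s vs %s (%s scenario)\n",
              x$alt$arm, x$ref$arm, x$scenario))
  cat(sprintf("  %-22s %15s %15s\n", "", x$ref$arm, x$alt$arm))
  cat(sprintf("  %-22s %15s %15s\n", "Total costs (baht)",
              fmtb(x$ref$cost), fmtb(x$alt$cost)))
  cat(sprintf("  %-22s %15.2f %15.2f\n", "Total life years", x$ref$ly, x$alt$ly))
  cat(sprintf("  %-22s %15.2f %15.2f\n", "Total QALYs", x$ref$qaly, x$alt$qaly))
  cat(sprintf("  Incremental costs      %15s\n", fmtb(x$inc_cost)))
  cat(sprintf("  Incremental LYs        %15.2f\n", x$inc_ly))
  cat(sprintf("  Incremental QALYs      %15.2f\n", x$inc_qaly))
  cat(sprintf("  ICER (baht/LY gained)  %15s%s\n",
              if (is.na(x$icer_ly)) "undefined" else fmtb(x$icer_ly),
              if (x$dominance_ly == "dominated") " (Dominated)"
              else if (x$dominance_ly == "dominant") " (Dominant)" else ""))
  cat(sprintf("  ICER (baht/QALY gained)%15s%s\n",
              if (is.na(x$icer_qaly)) "undefined" else fmtb(x$icer_qaly),
              if (x$dominance == "dominated") " (Dominated)"
              else if (x$dominance == "dominant") " (Dominant)" else ""))
  cat(sprintf("  %s at WTP %s baht/QALY\n",
              if (x$cost_effective) "Cost-effective" else "Not cost-effective",
              format(x$wtp, big.mark = ",")))
  invisible(x)
}

#' @export
summary.pd_cea <- function(object, ...) {
  print(object, ...)
}

#' Cost-utility results as a published-style table
#'
#' Lays the comparison out as the familiar results table: per-arm totals,
#' incrementals, and both ICERs, one row per quantity.
#'
#' @param x a \code{pd_cea} object.
#' @param digits rounding for life years/QALYs (default 2, as printed in
#'   published tables); costs and ICERs are rounded to whole baht.
#' @return data.frame with columns \code{result}, \code{CAPD}, \code{APD}
#'   (or the actual arm labels) and \code{incremental}.
#' @export
cea_table <- function(x, digits = 2) {
  stopifnot(inherits(x, "pd_cea"))
  lab_dom <- function(d, v) {
    if (is.na(v)) return("undefined")
    s <- format(round(v), big.mark = "", scientific = FALSE, trim = TRUE)
    if (d == "dominated") paste0(s, " (Dominated)") else s
  }
  data.frame(
    result = c("Total costs (baht)", "Total life years", "Total QALYs",
               "Incremental costs", "Incremental LYs", "Incremental QALYs",
               "ICER (baht/LY gained)", "ICER (baht/QALY gained)"),
    ref = c(round(x$ref$cost), round(x$ref$ly, digits), round(x$ref$qaly, digits),
            NA, NA, NA, NA, NA),
    alt = c(round(x$alt$cost), round(x$alt$ly, digits), round(x$alt$qaly, digits),
            NA, NA, NA, NA, NA),
    incremental = c(NA, NA, NA,
                    round(x$inc_cost), round(x$inc_ly, digits),
                    round(x$inc_qaly, digits),
                    NA, NA),
    note = c(rep("", 6), lab_dom(x$dominance_ly, x$icer_ly),
             lab_dom(x$dominance, x$icer_qaly)),
    stringsAsFactors = FALSE
  ) -> df
  names(df)[2:3] <- c(x$ref$arm, x$alt$arm)
  df
}
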