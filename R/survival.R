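#' Convert an annual probability to an event rate
#'
#' Standard actuarial conversion \eqn{r = -\ln(1 - p) / t} for a probability
#' observed over a period of length \code{t} (in cycles).
#'
#' @param p event probability in \[0, 1\].
#' @param t period length in cycles (default 1).
#' @return instantaneous event rate (per cycle); \code{Inf} when \code{p = 1}.
#' @seealso [rate_to_prob()], [survival_to_cycle_probs()]
#' @export
prob_to_rate <- function(p, t = 1) {
  stopifnot(all(p >= 0 & p <= 1), t > 0)
  -log(1 - p) / t
}

#' Convert an event rate to a per-period probability
#'
#' Inverse of [prob_to_rate()]: \eqn{p = 1 - e^{-r t}}.
#'
#' @param r event rate (per cycle), non-negative; may be \code{Inf}.
#' @param t period length in cycles (default 1).
#' @return probability in \[0, 1\].
#' @export
rate_to_prob <- function(r, t = 1) {
  stopifnot(all(r >= 0), t > 0)
  ifelse(is.infinite(r), 1, 1 - exp(-r * t))
}

#' Derive per-cycle transition probabilities from a survival curve
#'
#' Given annual survival probabilities \eqn{S(t)} for \eqn{t = 0, \dots, T}
#' (with \eqn{S(0) = 1} and \eqn{S} non-increasing), computes for each year
#' the conditional survival \eqn{S(u) = S(t)/S(t-1)}, the per-cycle event
#' probability \eqn{tp(t) = 1 - S(u)}, converts it to a rate
#' \eqn{r = -\ln(1 - tp(t))/\mathrm{cycle}} and back to a probability
#' \eqn{1 - e^{-r \cdot \mathrm{cycle}}}. With one-year cycles the rate
#' round-trip is the identity, so the result equals \eqn{tp(t)}; both steps
#' are nevertheless performed so that other cycle lengths are supported.
#'
#' @param curve numeric vector of survival probabilities \code{S(0..T)};
#'   must start at 1 and be non-increasing.
#' @param cycle cycle length in years (default 1).
#' @return numeric vector of per-cycle event probabilities, one per year
#'   \code{1..T}. A year in which survival reaches exactly zero yields 1.
#' @examples
#' survival_to_cycle_probs(c(1, 0.9, 0.81))  # 0.1, 0.1
#' @export
survival_to_cycle_probs <- function(curve, cycle = 1) {
  validate_survival_curve(curve)
  T <- length(curve) - 1L
  out <- numeric(T)
  for (t in seq_len(T)) {
    s_prev <- curve[t]
    s_now <- curve[t + 1L]
    if (s_prev <= 0) {
      stop("degenerate survival curve: S(", t - 1L, ") = 0 with later years present")
    }
    tp <- 1 - s_now / s_prev
    # tp = 1 exactly => infinite rate; handled explicitly
    if (tp >= 1) {
      out[t] <- 1
    } else {
      r <- prob_to_rate(tp, t = cycle)
      out[t] <- rate_to_prob(r, t = cycle)
    }
  }
  out
}

#' Extrapolate a short survival curve by its year-2 to year-3 decline
#'
#' Observed survival to year 3 is extended to \code{target_year} by applying
#' the year-2 to year-3 survival ratio \eqn{q = S(3)/S(2)} multiplicatively:
#' \eqn{S(t) = S(t-1) \cdot q} for \eqn{t > 3}. The multiplicative (constant
#' conditional survival) reading keeps the curve non-negative on any horizon,
#' unlike an absolute annual decrement.
#'
#' @param curve numeric survival curve \code{S(0..3)} or longer; only
#'   \code{S(2)} and \code{S(3)} determine the extension ratio.
#' @param target_year final year of the returned curve (default 10).
#' @return extended survival curve \code{S(0..target_year)}, non-increasing.
#' @examples
#' extrapolate_survival(c(1, 1, 0.95, 0.90))[5]  # 0.90 * (0.90/0.95)
#' @export
extrapolate_survival <- function(curve, target_year = 10) {
  validate_survival_curve(curve)
  if (length(curve) < 4L) {
    stop("survival curve must be observed to at least year 3 (length >= 4)")
  }
  if (curve[3L] <= 0) stop("degenerate survival curve: S(2) = 0")
  q <- curve[4L] / curve[3L]
  T0 <- length(curve) - 1L
  if (target_year <= T0) return(curve[seq_len(target_year + 1L)])
  ext <- curve[T0 + 1L] * q^seq_len(target_year - T0)
  c(curve, ext)
}

#' Combine a disease-specific and a background death probability
#'
#' Merges a state-specific annual death probability with the age-specific
#' background (all-cause) death probability under independent competing
#' risks: \eqn{1 - (1 - p_{state})(1 - p_{background})}. An alternative
#' \code{"max"} rule, which takes the larger of the two, is available for
#' sensitivity to the merging assumption.
#'
#' @param p_state disease/state-specific annual death probability.
#' @param p_background age-specific background death probability.
#' @param rule \code{"competing_risks"} (default) or \code{"max"}.
#' @return combined annual death probability; always at least the larger of
#'   the two inputs and at most 1.
#' @examples
#' combine_mortality(0.1, 0.2)  # 0.28
#' @export
combine_mortality <- function(p_state, p_background,
                              rule = c("competing_risks", "max")) {
  rule <- match.arg(rule)
  stopifnot(all(p_state >= 0 & p_state <= 1),
            all(p_background >= 0 & p_background <= 1))
  if (rule == "max") {
    pmax(p_state, p_background)
  } else {
    1 - (1 - p_state) * (1 - p_background)
  }
}

# Internal: check S(0) = 1, values in [0,1], non-increasing.
validate_survival_curve <- function(curve) {
  if (!is.numeric(curve) || length(curve) < 2L) {
    stop("survival curve must be a numeric vector S(0..T), T >= 1")
  }
  if (abs(curve[1L] - 1) > 1e-12) stop("survival curve must start at S(0) = 1")
  if (any(curve < -1e-12 | curve > 1 + 1e-12)) {
    stop("survival probabilities must lie in [0, 1]")
  }
  if (any(diff(curve) > 1e-12)) stop("survival curve must be non-increasing")
  invisible(curve)
}
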