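#' Write analysis outputs to CSV/JSON
#'
#' Plain-format report writers for every analysis object: cohort traces,
#' the cost-utility comparison table, tornado entries, PSA draws
#' (cost-effectiveness plane), acceptability-curve points and the
#' budget-impact table. All writers refuse to overwrite an existing file
#' unless \code{force = TRUE}.
#'
#' @param x the object to write: a \code{pd_arm_result}, \code{pd_cea},
#'   \code{pd_tornado}, \code{pd_psa}, \code{pd_ceac} or \code{bia_table}.
#' @param path output file path (\code{.csv}, or \code{.json} for
#'   \code{pd_cea}).
#' @param force overwrite an existing file (default FALSE).
#' @return \code{path}, invisibly.
#' @export
write_report <- function(x, path, force = FALSE) {
  if (file.exists(path) && !force) {
    stop("output file exists (use force = TRUE to overwrite): ", path)
  }
  df <- report_frame(x, path)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    utils::write.csv(df, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

report_frame <- function(x, path) {
  if (inherits(x, "pd_arm_result")) return(trace_table(x))
  if (inherits(x, "pd_cea")) {
    if (grepl("\\.json$", path)) return(unclass(x))
    return(cea_table(x))
  }
  if (inherits(x, "pd_tornado")) return(as.data.frame(x))
  if (inherits(x, "pd_psa")) return(x$draws[, c("draw", "dcost", "dqaly")])
  if (inherits(x, "pd_ceac")) return(as.data.frame(x))
  if (inherits(x, "bia_table")) return(bia_report(x))
  stop("no report writer for class ", paste(class(x), collapse = "/"))
}

#' Run the complete cost-utility pipeline
#'
#' Convenience wrapper running both arms, the comparison, and (optionally)
#' the deterministic and probabilistic sensitivity analyses on one
#' parameter set.
#'
#' @param params a \code{pd_params} object.
#' @param scenario cohort scenario, see [run_cohort()].
#' @param psa_draws PSA iterations (0 to skip the PSA; default 0).
#' @param tornado run the one-way sensitivity analysis (default FALSE).
#' @param seed seed for the PSA.
#' @return list with elements \code{capd}, \code{apd} (arm results),
#'   \code{cea}, and when requested \code{tornado}, \code{psa},
#'   \code{ceac}.
#' @export
run_analysis <- function(params, scenario = c("base", "year1_forever"),
                         psa_draws = 0, tornado = FALSE, seed = 1L) {
  scenario <- match.arg(scenario)
  capd <- run_cohort(params, "CAPD", scenario)
  apd <- run_cohort(params, "APD", scenario)
  out <- list(capd = capd, apd = apd,
              cea = compare_strategies(capd, apd))
  if (tornado) out$tornado <- one_way_sa(params, scenario = scenario)
  if (psa_draws > 0) {
    out$psa <- run_psa(params, n_draws = psa_draws, seed = seed,
                       scenario = scenario)
    out$ceac <- ceac(out$psa)
  }
  out
}
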