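#' Load a packaged reference table
#'
#' The package ships the small reference tables that parameterise the
#' air-quality evaluator: national criterion boundaries per level, the
#' derived cloud-model parameters, the quadratic pseudo-bound regressions
#' that close the open-ended level VI, AHP/entropy criterion weights, and a
#' worked set of nine forecast samples with their published evaluation
#' results. Values are stored exactly as printed in the grading standard
#' (e.g. `13.33`, not `40/3`).
#'
#' @param name One of `"criteria_bounds"`, `"cloud_params"`,
#'   `"pseudo_bounds"`, `"weights"`, `"eval_samples"`, `"eval_results"`.
#'
#' @return A tibble. `criteria_bounds` has columns `criterion`, `level`,
#'   `b_min`, `b_max` (`b_max` is `NA` for the open level VI);
#'   `cloud_params` has `criterion`, `level`, `ex`, `en`, `he`;
#'   `pseudo_bounds` has the quadratic coefficients and the extrapolated
#'   level-VI bound; `weights` has AHP weight `z`, `entropy`, entropy weight
#'   `omega` and combined weight `w`; `eval_samples` holds nine
#'   concentration vectors (cases `A_1` .. `A_9`); `eval_results` their
#'   per-level certainty degrees and final levels.
#'
#' @examples
#' load_fixture("criteria_bounds")
#' load_fixture("weights")
#' @export
load_fixture <- function(name) {
  choices <- c(
    "criteria_bounds", "cloud_params", "pseudo_bounds",
    "weights", "eval_samples", "eval_results"
  )
  if (!is.character(name) || length(name) != 1L || !name %in% choices) {
    abort(paste0(
      "`name` must be one of: ", paste0('"', choices, '"', collapse = ", ")
    ))
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "aerowarn")
  tbl <- tibble::as_tibble(read.csv(path, check.names = FALSE,
                                    stringsAsFactors = FALSE))
  if ("level" %in% names(tbl)) {
    tbl$level <- factor(tbl$level, levels = aq_levels)
  }
  if ("criterion" %in% names(tbl)) {
    tbl$criterion <- factor(tbl$criterion, levels = aq_criteria)
  }
  tbl
}
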