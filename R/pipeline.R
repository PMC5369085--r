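#' Run the full air-quality early-warning pipeline
#'
#' End-to-end orchestration over a set of pollutant series: each series is
#' decomposed and denoised ([ceemd()], [denoise()]), embedded, tuned,
#' forecast one step ahead with intervals ([forecast_pipeline()]), and the
#' per-timestamp forecast vectors across criteria are graded into quality
#' levels by the cloud-model evaluator ([evaluate_air_quality()]). All
#' stochastic stages draw child seeds derived from the single global
#' `seed`, so the report is reproducible.
#'
#' @param data Long tibble with columns `timestamp`, `value`, `criterion`;
#'   evaluation is performed at test timestamps covered by all requested
#'   criteria. Any subset of the six criteria may be supplied; cloud
#'   evaluation requires all six.
#' @param criteria Criteria to process (default: those present in `data`).
#' @param lag,split,ensemble_size,noise_std,tune,tune_pop,tune_iter
#'   Forecasting settings, see [forecast_pipeline()].
#' @param significance Significance levels for prediction intervals.
#' @param evaluate Grade the forecasts with the cloud model? Requires all
#'   six criteria.
#' @param evaluate_actuals Evaluate observed rather than forecast values.
#' @param reps Monte-Carlo repetitions per evaluation.
#' @param seed Global integer seed.
#' @param out_dir Optional directory; when given, per-criterion prediction
#'   CSVs, an evaluation JSON and a manifest JSON are written there.
#' @return An `ews_report`: list with `forecasts` (long tibble across
#'   criteria), `evaluation` (an `aq_evaluation` or `NULL`), `metrics`
#'   (per-criterion accuracy) and `manifest`.
#' @examples
#' \donttest{
#' series <- purrr::map_dfr(c("PM2.5", "PM10"), function(cr)
#'   generate_series(n_hours = 250, criterion = cr, seed = 1))
#' rep <- run_ews(series, ensemble_size = 2, tune = FALSE,
#'                evaluate = FALSE, seed = 1)
#' rep$metrics
#' }
#' @export
run_ews <- function(data,
                    criteria = NULL,
                    lag = 5, split = 0.8,
                    ensemble_size = 200, noise_std = 0.4,
                    tune = TRUE, tune_pop = 20, tune_iter = 40,
                    significance = c(0.05, 0.1, 0.2, 0.4),
                    evaluate = TRUE, evaluate_actuals = FALSE,
                    reps = 2000, seed = 1,
                    out_dir = NULL) {
  stopifnot(all(c("timestamp", "value", "criterion") %in% names(data)))
  criteria <- criteria %||% intersect(aq_criteria, unique(data$criterion))
  if (length(criteria) == 0) abort("No requested criterion found in `data`.")
  if (evaluate && !setequal(criteria, aq_criteria)) {
    abort("Cloud evaluation requires all six criteria; set evaluate = FALSE.")
  }

  seeds <- derive_seeds(seed, length(criteria) + 1L)
  forecasts <- purrr::imap(
    setNames(criteria, criteria),
    function(cr, nm) {
      idx <- match(cr, criteria)
      sub <- dplyr::filter(data, .data$criterion == cr) |>
        dplyr::arrange(.data$timestamp)
      with_stage(paste0("forecast:", cr), forecast_pipeline(
        sub, lag = lag, split = split,
        ensemble_size = ensemble_size, noise_std = noise_std,
        tune = tune, tune_pop = tune_pop, tune_iter = tune_iter,
        significance = significance, seed = seeds[[idx]]
      ))
    }
  )

  fc_long <- purrr::imap_dfr(forecasts, function(fc, cr) {
    dplyr::mutate(fc$forecast, criterion = cr, .before = 1)
  })
  metrics <- purrr::imap_dfr(forecasts, function(fc, cr) {
    dplyr::mutate(glance(fc), criterion = cr, .before = 1)
  })

  evaluation <- NULL
  if (evaluate) {
    value_col <- if (evaluate_actuals) "actual" else "predicted"
    wide <- fc_long |>
      dplyr::select("criterion", "timestamp", dplyr::all_of(value_col)) |>
      tidyr::pivot_wider(names_from = "criterion",
                         values_from = dplyr::all_of(value_col)) |>
      tidyr::drop_na()
    if (nrow(wide) == 0) {
      abort("[evaluate] no common test timestamps across criteria.")
    }
    wide$case <- as.character(wide$timestamp)
    evaluation <- with_stage("evaluate", evaluate_air_quality(
      wide, reps = reps, seed = seeds[[length(seeds)]]
    ))
  }

  manifest <- list(
    criteria = criteria, lag = lag, split = split,
    ensemble_size = ensemble_size, noise_std = noise_std,
    tune = tune, significance = significance, reps = reps,
    seed = seed, package_version = as.character(utils::packageVersion("aerowarn"))
  )

  report <- structure(
    list(forecasts = fc_long, evaluation = evaluation,
         metrics = metrics, manifest = manifest),
    class = "ews_report"
  )
  if (!is.null(out_dir)) write_ews_report(report, out_dir)
  report
}

#' @export
print.ews_report <- function(x, ...) {
  cat(sprintf(
    "<ews_report> %d criteria, %d test predictions%s\n",
    length(unique(x$forecasts$criterion)), nrow(x$forecasts),
    if (is.null(x$evaluation)) "" else
      sprintf(", %d evaluated samples", nrow(x$evaluation))
  ))
  invisible(x)
}

# Write the report artefacts: one predictions CSV per criterion, the
# evaluation table as JSON, and a manifest.
write_ews_report <- function(report, out_dir) {
  rlang::check_installed("jsonlite")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (cr in unique(report$forecasts$criterion)) {
    sub <- dplyr::filter(report$forecasts, .data$criterion == cr)
    utils::write.csv(
      sub, file.path(out_dir, sprintf("predictions_%s.csv", gsub("\\.", "", cr))),
      row.names = FALSE
    )
  }
  if (!is.null(report$evaluation)) {
    jsonlite::write_json(report$evaluation,
                         file.path(out_dir, "evaluation.json"),
                         dataframe = "rows", digits = NA)
  }
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
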