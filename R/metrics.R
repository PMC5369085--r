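#' Point-forecast accuracy metrics
#'
#' Mean absolute error, mean absolute percentage error, root mean square
#' error and goodness of fit between actual and predicted values:
#' `MAE = mean(|y - y'|)`, `MAPE = 100 mean(|y - y'| / |y|)`,
#' `RMSE = sqrt(mean((y - y')^2))`,
#' `R2 = 1 - sum((y - y')^2) / sum((y - mean(y))^2)`.
#' RMSE is reported in concentration units by default; `relative = TRUE`
#' divides each error by its actual value before squaring, giving a
#' unitless relative RMSE.
#'
#' @param data A data frame with `actual` and `predicted` columns, or a
#'   numeric vector of actuals.
#' @param predicted Predictions, when `data` is a vector.
#' @param relative Use the relative (unitless) RMSE variant?
#' @return A one-row tibble with `mae`, `mape` (percent), `rmse`, `r2`
#'   and `n`. With any zero actual the MAPE is `NA` with a warning.
#' @examples
#' point_metrics(tibble::tibble(actual = c(10, 20), predicted = c(12, 16)))
#' @export
point_metrics <- function(data, predicted = NULL, relative = FALSE) {
  if (is.data.frame(data)) {
    stopifnot(all(c("actual", "predicted") %in% names(data)))
    actual <- as.numeric(data$actual)
    predicted <- as.numeric(data$predicted)
  } else {
    actual <- as.numeric(data)
    predicted <- as.numeric(predicted)
  }
  if (length(actual) != length(predicted) || length(actual) < 1) {
    abort("`actual` and `predicted` must be equal-length, nonempty.")
  }
  err <- actual - predicted
  mape <- if (any(actual == 0)) {
    warn("Zero actual value(s): MAPE is undefined and reported as NA.")
    NA_real_
  } else {
    100 * mean(abs(err / actual))
  }
  rmse <- if (relative) {
    if (any(actual == 0)) NA_real_ else sqrt(mean((err / actual)^2))
  } else {
    sqrt(mean(err^2))
  }
  ss_tot <- sum((actual - mean(actual))^2)
  tibble::tibble(
    mae = mean(abs(err)),
    mape = mape,
    rmse = rmse,
    r2 = if (ss_tot > 0) 1 - sum(err^2) / ss_tot else NA_real_,
    n = length(actual)
  )
}

#' Diebold-Mariano forecast comparison test
#'
#' Tests whether two competing forecasts differ in expected loss. With
#' loss differential `V_t = F(e1_t) - F(e2_t)` the statistic is
#' `DM = mean(V) / sqrt(S^2 / t)` with `S^2` the sample variance of `V`;
#' under the null of equal accuracy `DM` is asymptotically standard
#' normal, and the two-sided decision at level `alpha` rejects when
#' `|DM| > z_{alpha/2}`. A positive statistic means the first model's
#' losses exceed the second's. When the loss differential is constant
#' (`S^2 = 0`) the statistic is degenerate and no rejection is reported.
#'
#' @param errors1,errors2 Forecast error series of the two models.
#' @param loss `"absolute"` (default) or `"squared"` loss.
#' @return A one-row tibble: `statistic`, `loss`, `p_value`, `n`,
#'   `degenerate`, and rejection indicators `reject_01`, `reject_05`,
#'   `reject_10` at the 1%, 5% and 10% levels.
#' @examples
#' dm_test(rnorm(100), rnorm(100, sd = 2), loss = "squared")
#' @export
dm_test <- function(errors1, errors2, loss = c("absolute", "squared")) {
  loss <- match.arg(loss)
  e1 <- as.numeric(errors1)
  e2 <- as.numeric(errors2)
  if (length(e1) != length(e2) || length(e1) < 2) {
    abort("Error series must have equal length >= 2.")
  }
  f <- if (loss == "absolute") abs else function(x) x^2
  v <- f(e1) - f(e2)
  s2 <- var(v)
  t_len <- length(v)
  if (s2 == 0) {
    return(tibble::tibble(
      statistic = NA_real_, loss = loss, p_value = NA_real_, n = t_len,
      degenerate = TRUE, reject_01 = FALSE, reject_05 = FALSE,
      reject_10 = FALSE
    ))
  }
  dm <- mean(v) / sqrt(s2 / t_len)
  p <- 2 * pnorm(-abs(dm))
  tibble::tibble(
    statistic = dm, loss = loss, p_value = p, n = t_len,
    degenerate = FALSE,
    reject_01 = abs(dm) > qnorm(0.995),
    reject_05 = abs(dm) > qnorm(0.975),
    reject_10 = abs(dm) > qnorm(0.95)
  )
}
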