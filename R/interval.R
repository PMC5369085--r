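#' Smoother matrix of a fitted LSSVM
#'
#' LSSVM fitted values are exactly linear in the training targets:
#' `yhat = L y`. The smoother matrix `L` is obtained from the bordered
#' dual system — row `i` is the kernel row `[1, k(x_i)]` propagated
#' through the system inverse, with the column acting on the zero
#' right-hand side dropped. Its trace is the effective number of degrees
#' of freedom of the fit and tends to the training size as `gamma` grows
#' (the interpolation limit).
#'
#' @param model An `lssvm_model`.
#' @return An `M x M` matrix `L` with `L %*% model$y` equal to the fitted
#'   values.
#' @seealso [predict_interval()] for the intervals built on it.
#' @export
smoother_matrix <- function(model) {
  stopifnot(inherits(model, "lssvm_model"))
  smoother_rows(model, NULL)
}

# Rows of the linear smoother evaluated at arbitrary inputs: at x,
# yhat(x) = [1, k(x)] A^{-1} (0, y)' = l(x) y.
smoother_rows <- function(model, newdata) {
  Ks <- cross_kernel(model, newdata)
  Z <- cbind(1, Ks)
  # Solve A' W' = Z' so that W = Z A^{-1} (A is symmetric here).
  W <- t(solve(model$A, t(Z)))
  W[, -1L, drop = FALSE]
}

#' Bias and variance estimates for LSSVM predictions
#'
#' Plug-in components of the central-limit-theorem intervals for a linear
#' smoother. The bias of the fit is estimated by double smoothing
#' (`L yhat - yhat`, i.e. applying the smoother to its own fitted values),
#' and the conditional noise variance by smoothing the squared residuals
#' with the same smoother, inflated by the degrees-of-freedom correction
#' `M / (M - trace(L))`. Negative smoothed variances (possible since `L`
#' rows are not a probability weighting) are floored at zero with a
#' warning.
#'
#' @param model An `lssvm_model`.
#' @param newdata Optional matrix of prediction inputs; omitted for the
#'   training points.
#' @param y_obs Optional observed targets for the residual-variance
#'   estimate, defaulting to the model's training targets. When the model
#'   was fitted to a filtered (denoised) series but intervals must cover
#'   the raw observations, pass the raw values here so the filtered-out
#'   noise is counted in the variance.
#' @return A tibble with columns `fit`, `bias` and `variance`, one row per
#'   point.
#' @export
bias_and_variance <- function(model, newdata = NULL, y_obs = NULL) {
  L_new <- smoother_rows(model, newdata)
  yhat_train <- as.numeric(smoother_rows(model, NULL) %*% model$y)
  fit <- as.numeric(L_new %*% model$y)
  bias <- as.numeric(L_new %*% yhat_train) - fit

  y_obs <- y_obs %||% model$y
  if (length(y_obs) != length(model$y)) {
    abort("`y_obs` must match the training size.")
  }
  resid2 <- (y_obs - yhat_train)^2
  M <- length(model$y)
  tr <- sum(diag(smoother_matrix(model)))
  dof_corr <- M / max(M - tr, 1e-8)
  variance <- as.numeric(L_new %*% resid2) * dof_corr
  if (any(variance < 0)) {
    warn("Negative smoothed variance estimates floored at zero.")
    variance <- pmax(variance, 0)
  }
  tibble::tibble(fit = fit, bias = bias, variance = variance)
}

#' Nonsymmetric prediction intervals for an LSSVM forecaster
#'
#' For each point the interval is centred at the bias-corrected prediction
#' `yhat - bias` and extends `z_{a/2}` estimated standard deviations each
#' side, with bias and variance from [bias_and_variance()]. Because the
#' bias correction shifts the centre away from the raw prediction the
#' interval is in general nonsymmetric about `yhat`. Width shrinks as the
#' significance level `a` grows.
#'
#' @param model An `lssvm_model`.
#' @param newdata Prediction inputs (matrix or data frame); omitted for
#'   the training points.
#' @param significance One or more significance levels in (0, 1).
#' @inheritParams bias_and_variance
#' @return A tibble with one row per point and level: `significance`,
#'   `center` (raw prediction), `corrected`, `lower`, `upper`.
#' @examples
#' X <- matrix(seq(0, 1, length.out = 60))
#' m <- lssvm(X, sin(4 * X[, 1]) + rnorm(60, 0, 0.1), sigma = 1, gamma = 50)
#' predict_interval(m, significance = 0.1)
#' @export
predict_interval <- function(model, newdata = NULL, significance = 0.05,
                             y_obs = NULL) {
  if (any(significance <= 0) || any(significance >= 1)) {
    abort("`significance` must lie in (0, 1).")
  }
  bv <- bias_and_variance(model, newdata, y_obs = y_obs)
  purrr::map_dfr(significance, function(a) {
    z <- qnorm(1 - a / 2)
    half <- z * sqrt(bv$variance)
    tibble::tibble(
      significance = a,
      center = bv$fit,
      corrected = bv$fit - bv$bias,
      lower = bv$fit - bv$bias - half,
      upper = bv$fit - bv$bias + half
    )
  })
}

#' Coverage probability and average width of prediction intervals
#'
#' `CP` is the fraction of actual values falling inside their closed
#' interval `[L, U]`; `AW` is the mean interval width. An interval set at
#' significance `a` is declared valid when `CP >= 1 - a`.
#'
#' @param intervals A tibble with `lower`, `upper` and (optionally)
#'   `significance` columns, as returned by [predict_interval()]; scored
#'   per significance level when present.
#' @param actuals Observed values, matching each level's rows in order.
#' @return A tibble with columns `significance` (if available), `cp`,
#'   `aw`, `n` and `valid`.
#' @examples
#' score_intervals(tibble::tibble(lower = c(0, 0), upper = c(2, 4)),
#'                 actuals = c(1, 5))
#' @export
score_intervals <- function(intervals, actuals) {
  stopifnot(is.data.frame(intervals),
            all(c("lower", "upper") %in% names(intervals)))
  if (!"significance" %in% names(intervals)) {
    intervals <- dplyr::mutate(intervals, significance = NA_real_)
  }
  scored <- intervals |>
    dplyr::group_by(.data$significance) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) != length(actuals)) {
        abort("`actuals` length must match the interval rows per level.")
      }
      covered <- actuals >= df$lower & actuals <= df$upper
      tibble::tibble(
        cp = mean(covered),
        aw = mean(df$upper - df$lower),
        n = nrow(df)
      )
    }) |>
    dplyr::ungroup()
  dplyr::mutate(
    scored,
    valid = ifelse(is.na(.data$significance), NA,
                   .data$cp >= 1 - .data$significance)
  )
}
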