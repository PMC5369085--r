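#' Gaussian radial basis kernel
#'
#' `K(x_i, x_j) = exp(-||x_j - x_i||^2 / (2 sigma^2))`, the kernel used
#' throughout the forecaster. Values lie in `(0, 1]` and equal 1 exactly
#' when the inputs coincide.
#'
#' @param xi,xj Numeric vectors of equal length.
#' @param sigma Kernel width, > 0.
#' @return A scalar kernel value.
#' @examples
#' rbf_kernel(c(0, 0), c(1, 1), sigma = 1)
#' @export
rbf_kernel <- function(xi, xj, sigma) {
  check_number(sigma, "sigma", min = 0, strict = TRUE)
  if (length(xi) != length(xj)) abort("`xi` and `xj` must have equal length.")
  exp(-sum((xj - xi)^2) / (2 * sigma^2))
}

# Cross-kernel matrix K[i, j] = k(X[i, ], Y[j, ]).
rbf_kernel_matrix <- function(X, Y, sigma) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), `+`) - 2 * tcrossprod(X, Y)
  exp(-pmax(d2, 0) / (2 * sigma^2))
}

#' Fit a least-squares support vector regression model
#'
#' LSSVM replaces the inequality constraints of support vector regression
#' by equality constraints with squared loss, so the dual problem reduces
#' to one bordered linear system
#' \deqn{\begin{pmatrix} 0 & 1^T \\ 1 & K + I/\gamma \end{pmatrix}
#'       \begin{pmatrix} b \\ \alpha \end{pmatrix} =
#'       \begin{pmatrix} 0 \\ y \end{pmatrix}}
#' in the bias `b` and dual coefficients `alpha`. Predictions at `x` are
#' `b + sum_m alpha_m K(x_m, x)`. Inputs are z-scored with training
#' statistics before kernel evaluation (so `sigma` is expressed in
#' standardised units); targets are left untouched, keeping the fitted
#' values exactly linear in `y`.
#'
#' @param x Training inputs: matrix or data frame, rows = cases.
#' @param y Numeric targets, one per row of `x`.
#' @param sigma Kernel width (> 0), in standardised input units.
#' @param gamma Regularisation (> 0); larger values interpolate harder.
#' @param standardize Z-score the inputs using training statistics?
#' @return An `lssvm_model`: dual coefficients `alpha`, bias `b`, the
#'   training inputs, kernel parameters and scaling. Supports [predict()],
#'   [tidy()] and [glance()].
#' @examples
#' X <- matrix(runif(40), ncol = 2)
#' y <- sin(X[, 1]) + X[, 2]
#' m <- lssvm(X, y, sigma = 1, gamma = 100)
#' glance(m)
#' @export
lssvm <- function(x, y, sigma, gamma, standardize = TRUE) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) abort("`x` and `y` sizes differ.")
  if (nrow(X) < 2) abort("At least 2 training rows are required.")
  check_number(sigma, "sigma", min = 0, strict = TRUE)
  check_number(gamma, "gamma", min = 0, strict = TRUE)

  if (standardize) {
    center <- colMeans(X)
    scale <- apply(X, 2L, sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  } else {
    center <- rep(0, ncol(X))
    scale <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2L, center), 2L, scale, `/`)

  M <- nrow(Xs)
  K <- rbf_kernel_matrix(Xs, Xs, sigma)
  A <- rbind(
    c(0, rep(1, M)),
    cbind(rep(1, M), K + diag(1 / gamma, M))
  )
  rhs <- c(0, y)
  sol <- tryCatch(solve(A, rhs), error = function(e) {
    warn("Singular LSSVM system; using a least-squares solve.")
    qr.solve(qr(A, LAPACK = TRUE), rhs)
  })

  structure(
    list(
      alpha = sol[-1L], b = sol[1L], sigma = sigma, gamma = gamma,
      train_inputs = Xs, center = center, scale = scale,
      y = y, kernel = K, A = A
    ),
    class = "lssvm_model"
  )
}

#' @param object,x An `lssvm_model`.
#' @param newdata Matrix or data frame of prediction inputs; omitted for
#'   fitted values.
#' @param ... Unused.
#' @rdname lssvm
#' @export
predict.lssvm_model <- function(object, newdata = NULL, ...) {
  Ks <- cross_kernel(object, newdata)
  as.numeric(Ks %*% object$alpha + object$b)
}

cross_kernel <- function(model, newdata = NULL) {
  if (is.null(newdata)) return(model$kernel)
  Xn <- as.matrix(newdata)
  storage.mode(Xn) <- "double"
  Xn <- sweep(sweep(Xn, 2L, model$center), 2L, model$scale, `/`)
  rbf_kernel_matrix(Xn, model$train_inputs, model$sigma)
}

#' @rdname lssvm
#' @method tidy lssvm_model
#' @export
tidy.lssvm_model <- function(x, ...) {
  tibble::tibble(term = c("b", paste0("alpha", seq_along(x$alpha))),
                 estimate = c(x$b, x$alpha))
}

#' @rdname lssvm
#' @method glance lssvm_model
#' @export
glance.lssvm_model <- function(x, ...) {
  fitted <- predict(x)
  tibble::tibble(
    n_train = length(x$y), sigma = x$sigma, gamma = x$gamma,
    train_mse = mean((x$y - fitted)^2)
  )
}

#' @export
print.lssvm_model <- function(x, ...) {
  cat(sprintf(
    "<lssvm_model> %d support values, sigma = %.4g, gamma = %.4g\n",
    length(x$alpha), x$sigma, x$gamma
  ))
  invisible(x)
}

#' Build a lagged supervised matrix from a series
#'
#' Turns a univariate series into an autoregressive design: row `t` holds
#' the `lag` previous values and the target is the current value.
#'
#' @param values Numeric series.
#' @param lag Embedding order (number of hourly lags).
#' @return List with matrix `X` (`lag` columns, oldest lag first), target
#'   vector `y`, and `index` giving each target's position in `values`.
#' @export
make_lag_matrix <- function(values, lag = 5) {
  values <- as.numeric(values)
  check_number(lag, "lag", min = 1)
  lag <- as.integer(lag)
  n <- length(values)
  if (n <= lag) abort("Series too short for the requested lag order.")
  idx <- (lag + 1L):n
  X <- vapply(seq_len(lag), function(j) values[idx - (lag + 1L - j)],
              numeric(length(idx)))
  colnames(X) <- paste0("lag", lag:1)
  list(X = X, y = values[idx], index = idx)
}

#' Tune LSSVM hyperparameters with BBODE
#'
#' Searches `(sigma, gamma)` in log10 space with the hybrid
#' biogeography/differential-evolution optimizer, scoring each candidate by
#' the mean squared one-step error on a chronological holdout: the last
#' `holdout` fraction of the training rows (no shuffling, so no leakage
#' from the future).
#'
#' @param x,y Training design and targets (see [make_lag_matrix()]).
#' @param holdout Fraction of rows reserved (chronologically last) for
#'   validation.
#' @param sigma_range,gamma_range Search intervals (natural scale).
#' @param pop_size,max_iter BBODE budget for the search.
#' @param seed Optional integer for a reproducible search.
#' @return List with `sigma`, `gamma`, the validation `mse`, and the
#'   underlying `bbode_result`.
#' @export
tune_lssvm <- function(x, y, holdout = 0.2,
                       sigma_range = c(0.01, 100),
                       gamma_range = c(0.1, 1e6),
                       pop_size = 20, max_iter = 40, seed = NULL) {
  X <- as.matrix(x)
  y <- as.numeric(y)
  M <- nrow(X)
  n_val <- max(1L, floor(holdout * M))
  if (M - n_val < 2) abort("Too few rows to hold out a validation tail.")
  train_i <- seq_len(M - n_val)
  val_i <- (M - n_val + 1L):M

  if (sd(y) == 0) {
    warn("Constant target; returning the midpoint of the search box.")
    return(list(sigma = exp(mean(log(sigma_range))),
                gamma = exp(mean(log(gamma_range))),
                mse = 0, result = NULL))
  }

  objective <- function(p) {
    m <- tryCatch(
      lssvm(X[train_i, , drop = FALSE], y[train_i],
            sigma = 10^p[1], gamma = 10^p[2]),
      error = function(e) NULL
    )
    if (is.null(m)) return(Inf)
    mean((y[val_i] - predict(m, X[val_i, , drop = FALSE]))^2)
  }

  fit <- bbode(objective,
               lower = log10(c(sigma_range[1], gamma_range[1])),
               upper = log10(c(sigma_range[2], gamma_range[2])),
               pop_size = pop_size, max_iter = max_iter, seed = seed)
  list(sigma = 10^fit$par[1], gamma = 10^fit$par[2],
       mse = fit$value, result = fit)
}

#' One-step-ahead forecasting pipeline for a pollutant series
#'
#' The full point-forecasting chain: the series is decomposed by [ceemd()],
#' the first (noise-like) IMF is removed and the series rebuilt from the
#' remaining modes, a lagged design is formed, hyperparameters are tuned on
#' the training portion with [tune_lssvm()], the model is refit on all
#' training rows, and one-step-ahead predictions are made over the test
#' rows using true lagged values (static one-step scheme). Optionally
#' nonsymmetric prediction intervals are attached for each requested
#' significance level (see [predict_interval()]).
#'
#' @param data Tibble with `timestamp` and `value` columns (e.g. from
#'   [generate_series()]), or a numeric vector.
#' @param lag Autoregressive embedding order (hourly lags).
#' @param split Fraction of supervised rows used for training.
#' @param denoise Apply the CEEMD first-mode removal before forecasting?
#' @param ensemble_size,noise_std,max_imfs CEEMD settings, see [ceemd()].
#' @param tune Tune `(sigma, gamma)` with BBODE? With `FALSE` the
#'   `sigma`/`gamma` defaults below are used as-is.
#' @param sigma,gamma Hyperparameters used when `tune = FALSE`.
#' @param tune_pop,tune_iter BBODE budget for tuning.
#' @param significance Optional vector of significance levels for
#'   prediction intervals, each in (0, 1).
#' @param seed Optional integer; drives the CEEMD ensemble and the tuning
#'   search through derived child seeds.
#' @return An `aq_forecast` object: `$forecast` is a tibble with
#'   `timestamp`, `actual`, `predicted` (plus `lower_*`/`upper_*` interval
#'   columns when `significance` is given); `$model`, `$tuning`,
#'   `$decomposition` expose the fitted pieces. [glance()] returns the
#'   point-forecast accuracy metrics on the test rows.
#' @examples
#' x <- generate_series(n_hours = 300, seed = 1)
#' fc <- forecast_pipeline(x, ensemble_size = 2, tune = FALSE, seed = 2)
#' glance(fc)
#' @export
forecast_pipeline <- function(data, lag = 5, split = 0.8, denoise = TRUE,
                              ensemble_size = 200, noise_std = 0.4,
                              max_imfs = 8, tune = TRUE,
                              sigma = 1, gamma = 100,
                              tune_pop = 20, tune_iter = 40,
                              significance = NULL, seed = NULL) {
  parsed <- parse_series_input(data)
  raw <- parsed$value
  timestamp <- parsed$timestamp %||% seq_along(raw)
  if (!is.null(significance) &&
      (any(significance <= 0) || any(significance >= 1))) {
    abort("`significance` levels must lie in (0, 1).")
  }

  seeds <- derive_seeds(seed, 2L)

  # Stage 1: decompose the full series once, drop the first IMF, rebuild.
  work <- if (denoise) {
    dec <- with_stage("ceemd", ceemd(raw, ensemble_size = ensemble_size,
                                     noise_std = noise_std,
                                     max_imfs = max_imfs, seed = seeds[[1]]))
    denoise(dec)$value
  } else {
    dec <- NULL
    raw
  }

  # Stage 2: supervised embedding and chronological split.
  sup <- with_stage("embedding", make_lag_matrix(work, lag = lag))
  M <- length(sup$y)
  n_train <- floor(split * M)
  if (n_train < 10 * lag) {
    abort(sprintf(
      "[embedding] training split leaves %d rows; need >= %d (10 x lag).",
      n_train, 10 * lag
    ))
  }
  train_i <- seq_len(n_train)
  test_i <- (n_train + 1L):M

  # Stage 3: hyperparameter search on the training tail, refit on all
  # training rows.
  tuning <- if (tune) {
    with_stage("tuning", tune_lssvm(
      sup$X[train_i, , drop = FALSE], sup$y[train_i],
      pop_size = tune_pop, max_iter = tune_iter, seed = seeds[[2]]
    ))
  } else {
    list(sigma = sigma, gamma = gamma, mse = NA_real_, result = NULL)
  }
  model <- with_stage("fit", lssvm(
    sup$X[train_i, , drop = FALSE], sup$y[train_i],
    sigma = tuning$sigma, gamma = tuning$gamma
  ))

  # Stage 4: static one-step predictions over the test rows.
  predicted <- with_stage(
    "predict", predict(model, sup$X[test_i, , drop = FALSE])
  )
  fc <- tibble::tibble(
    timestamp = timestamp[sup$index[test_i]],
    actual = raw[sup$index[test_i]],
    predicted = predicted
  )

  if (!is.null(significance)) {
    # the variance estimate uses residuals against the *raw* observations,
    # so intervals cover actual concentrations, not the denoised series
    iv <- with_stage("intervals", predict_interval(
      model, sup$X[test_i, , drop = FALSE], significance = significance,
      y_obs = raw[sup$index[train_i]]
    ))
    for (a in significance) {
      sub <- iv[iv$significance == a, ]
      fc[[sprintf("lower_%g", a)]] <- sub$lower
      fc[[sprintf("upper_%g", a)]] <- sub$upper
    }
  }

  structure(
    list(forecast = fc, model = model, tuning = tuning,
         decomposition = dec, lag = lag, split = split,
         significance = significance),
    class = "aq_forecast"
  )
}

#' @export
print.aq_forecast <- function(x, ...) {
  cat(sprintf(
    "<aq_forecast> %d test predictions (lag %d, sigma = %.4g, gamma = %.4g)\n",
    nrow(x$forecast), x$lag, x$model$sigma, x$model$gamma
  ))
  invisible(x)
}

#' @rdname forecast_pipeline
#' @param x,object An `aq_forecast`.
#' @param ... Unused.
#' @method tidy aq_forecast
#' @export
tidy.aq_forecast <- function(x, ...) x$forecast

#' @rdname forecast_pipeline
#' @method glance aq_forecast
#' @export
glance.aq_forecast <- function(x, ...) {
  point_metrics(x$forecast)
}

#' @rdname forecast_pipeline
#' @method autoplot aq_forecast
#' @export
autoplot.aq_forecast <- function(object, ...) {
  fc <- object$forecast
  p <- ggplot2::ggplot(fc, ggplot2::aes(x = .data$timestamp))
  if (!is.null(object$significance)) {
    a <- min(object$significance)
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data[[sprintf("lower_%g", a)]],
                   ymax = .data[[sprintf("upper_%g", a)]]),
      fill = "steelblue", alpha = 0.25
    )
  }
  p +
    ggplot2::geom_line(ggplot2::aes(y = .data$actual), colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted),
                       colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "concentration (µg/m³)")
}

# ---- internals ---------------------------------------------------------

# Child seeds below 2^31, derived deterministically from a global seed.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list((as.numeric(seed) * 7919 + 104729 * seq_len(n)) %% 2147483629)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[%s] %s", stage, conditionMessage(e)))
  })
}
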