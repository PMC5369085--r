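test_that("the RBF kernel matches its closed form", {
  expect_equal(rbf_kernel(c(1, 2), c(1, 2), sigma = 0.7), 1)
  # squared distance equal to 2 sigma^2 gives exp(-1)
  expect_equal(rbf_kernel(0, 2, sigma = sqrt(2)), exp(-1))
  set.seed(3)
  xi <- rnorm(4); xj <- rnorm(4); s <- runif(1, 0.5, 2)
  expect_equal(rbf_kernel(xi, xj, s), exp(-sum((xj - xi)^2) / (2 * s^2)))
  expect_error(rbf_kernel(1, 2, sigma = 0), "sigma")
  expect_error(rbf_kernel(1, c(1, 2), sigma = 1), "equal length")
})

test_that("kernel matrices are symmetric positive semidefinite", {
  set.seed(4)
  for (i in 1:3) {
    X <- matrix(rnorm(60), ncol = 3)
    K <- aerowarn:::rbf_kernel_matrix(X, X, sigma = runif(1, 0.3, 3))
    expect_equal(K, t(K), tolerance = 1e-12)
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("the dual solve agrees with an independent kernel-ridge oracle", {
  set.seed(5)
  for (i in 1:20) {
    M <- sample(8:20, 1)
    D <- sample(1:4, 1)
    X <- matrix(rnorm(M * D), ncol = D)
    y <- rnorm(M)
    s <- runif(1, 0.5, 3)
    g <- 10^runif(1, 0, 3)
    m <- lssvm(X, y, sigma = s, gamma = g, standardize = FALSE)
    Xnew <- matrix(rnorm(5 * D), ncol = D)
    expect_equal(predict(m, Xnew), oracle_krr_predict(X, y, s, g, Xnew),
                 tolerance = 1e-8)
  }
})

test_that("the interpolation limit reproduces the training targets", {
  set.seed(6)
  X <- matrix(rnorm(20), ncol = 2)
  y <- rnorm(10)
  m <- lssvm(X, y, sigma = 1, gamma = 1e8)
  expect_equal(predict(m), y, tolerance = 1e-4)
})

test_that("a repeated single training point predicts the mean target", {
  X <- matrix(rep(c(0.4, -1), 6), ncol = 2, byrow = TRUE)
  y <- c(1, 2, 3, 4, 5, 6)
  m <- suppressWarnings(lssvm(X, y, sigma = 1, gamma = 1e6,
                              standardize = FALSE))
  expect_equal(predict(m, X[1, , drop = FALSE]), mean(y), tolerance = 1e-6)
})

test_that("predictions are invariant under permutation of training rows", {
  set.seed(7)
  X <- matrix(rnorm(30), ncol = 2)
  y <- rnorm(15)
  perm <- sample(15)
  m1 <- lssvm(X, y, sigma = 1.2, gamma = 50)
  m2 <- lssvm(X[perm, ], y[perm], sigma = 1.2, gamma = 50)
  Xnew <- matrix(rnorm(10), ncol = 2)
  expect_equal(predict(m1, Xnew), predict(m2, Xnew), tolerance = 1e-8)
})

test_that("the lag embedding aligns targets with their true history", {
  lagm <- make_lag_matrix(1:10, lag = 3)
  expect_equal(lagm$y, 4:10)
  expect_equal(lagm$X[1, ], c(lag3 = 1, lag2 = 2, lag1 = 3))
  expect_equal(lagm$index, 4:10)
  expect_error(make_lag_matrix(1:3, lag = 5), "too short")
})

test_that("BBODE tuning beats random hyperparameter draws", {
  set.seed(8)
  x <- generate_series(n_hours = 260, seed = 8)$value
  sup <- make_lag_matrix(x, lag = 5)
  tuned <- tune_lssvm(sup$X, sup$y, pop_size = 10, max_iter = 15, seed = 9)

  M <- length(sup$y)
  n_val <- floor(0.2 * M)
  ti <- seq_len(M - n_val); vi <- (M - n_val + 1):M
  val_mse <- function(s, g) {
    m <- lssvm(sup$X[ti, ], sup$y[ti], sigma = s, gamma = g)
    mean((sup$y[vi] - predict(m, sup$X[vi, ]))^2)
  }
  random_mse <- vapply(1:20, function(i) {
    val_mse(10^runif(1, -2, 2), 10^runif(1, -1, 6))
  }, numeric(1))
  expect_lte(tuned$mse, min(random_mse))
  expect_equal(tuned$mse, val_mse(tuned$sigma, tuned$gamma), tolerance = 1e-10)
})

test_that("tuning recovers a workable model for RBF-generated data", {
  set.seed(10)
  n <- 360
  X <- matrix(runif(2 * n, -2, 2), ncol = 2)
  centers <- matrix(runif(10, -2, 2), ncol = 2)
  f_true <- function(M) {
    apply(M, 1L, function(r) sum(exp(-colSums((t(centers) - r)^2))))
  }
  noise_var <- 0.15^2
  y <- f_true(X) + rnorm(n, 0, sqrt(noise_var))
  train <- 1:300; test <- 301:360
  tuned <- tune_lssvm(X[train, ], y[train], pop_size = 12, max_iter = 30,
                      seed = 11)
  m <- lssvm(X[train, ], y[train], sigma = tuned$sigma, gamma = tuned$gamma)
  mse_test <- mean((y[test] - predict(m, X[test, , drop = FALSE]))^2)
  expect_lte(mse_test, 2 * noise_var)
})

test_that("a constant target short-circuits tuning with a warning", {
  expect_warning(
    out <- tune_lssvm(matrix(rnorm(40), ncol = 2), rep(1, 20)),
    "Constant target"
  )
  expect_equal(out$sigma, 1, tolerance = 1e-12)  # geometric midpoint of box
})

test_that("the pipeline forecasts a deterministic AR(1) almost perfectly", {
  n <- 400
  x <- numeric(n); x[1] <- 50
  for (t in 2:n) x[t] <- 10 + 0.9 * x[t - 1]
  fc <- forecast_pipeline(x, denoise = FALSE, tune = FALSE,
                          sigma = 2, gamma = 1e6)
  expect_lt(glance(fc)$mape, 1)
})

test_that("denoising improves accuracy on trend plus noise", {
  t <- seq_len(500)
  set.seed(12)
  x <- 60 + 15 * sin(2 * pi * t / 120) + rnorm(500, 0, 3)
  fc_den <- forecast_pipeline(x, denoise = TRUE, ensemble_size = 5,
                              tune = FALSE, sigma = 2, gamma = 1e4, seed = 13)
  fc_raw <- forecast_pipeline(x, denoise = FALSE, tune = FALSE,
                              sigma = 2, gamma = 1e4, seed = 13)
  expect_lt(glance(fc_den)$rmse, glance(fc_raw)$rmse)
})

test_that("the pipeline is deterministic given a seed", {
  x <- generate_series(n_hours = 260, seed = 20)
  a <- forecast_pipeline(x, ensemble_size = 2, tune_pop = 6, tune_iter = 8,
                         seed = 21)
  b <- forecast_pipeline(x, ensemble_size = 2, tune_pop = 6, tune_iter = 8,
                         seed = 21)
  expect_identical(a$forecast, b$forecast)
})

test_that("stage failures carry a stage tag", {
  expect_error(forecast_pipeline(1:60, denoise = FALSE, tune = FALSE),
               "\\[embedding\\]")
})
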