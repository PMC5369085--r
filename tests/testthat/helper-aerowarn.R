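# Shared test utilities: independent oracles kept deliberately separate
# from the package's own code paths.

sample_lag1_acf <- function(x) {
  n <- length(x)
  x0 <- x - mean(x)
  sum(x0[-n] * x0[-1]) / sum(x0^2)
}

sample_skewness <- function(x) {
  z <- (x - mean(x)) / sd(x)
  mean(z^3)
}

# Independent kernel-ridge-with-bias solver: eliminates the bias through
# the equality constraint instead of solving the bordered system, and
# builds the kernel entrywise.
oracle_krr_predict <- function(X, y, sigma, gamma, Xnew) {
  M <- nrow(X)
  K <- matrix(0, M, M)
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      K[i, j] <- exp(-sum((X[i, ] - X[j, ])^2) / (2 * sigma^2))
    }
  }
  H <- K + diag(1 / gamma, M)
  Hi1 <- solve(H, rep(1, M))
  Hiy <- solve(H, y)
  b <- sum(Hiy) / sum(Hi1)
  alpha <- Hiy - b * Hi1
  vapply(seq_len(nrow(Xnew)), function(i) {
    k <- vapply(seq_len(M), function(j) {
      exp(-sum((X[j, ] - Xnew[i, ])^2) / (2 * sigma^2))
    }, numeric(1))
    sum(alpha * k) + b
  }, numeric(1))
}

# Coverage of LSSVM prediction intervals on homoscedastic sine-plus-noise
# data, n = 500 per replicate with an interleaved random train/test split.
coverage_replicates <- function(significance, reps = 3, seed = 1) {
  vapply(seq_len(reps), function(r) {
    set.seed(seed + r - 1)
    X <- matrix(runif(500, 0, 10))
    y <- sin(X[, 1]) + rnorm(500, 0, 0.5)
    train <- sample(500, 300)
    test <- setdiff(seq_len(500), train)
    m <- lssvm(X[train, , drop = FALSE], y[train], sigma = 1, gamma = 10)
    iv <- predict_interval(m, X[test, , drop = FALSE],
                           significance = significance)
    score_intervals(iv, y[test])$cp
  }, numeric(1))
}

# Histogram Shannon entropy, coded independently of the package.
oracle_bin_entropy <- function(x, bins) {
  br <- seq(min(x), max(x), length.out = bins + 1)
  counts <- hist(x, breaks = br, plot = FALSE, include.lowest = TRUE)$counts
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}
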