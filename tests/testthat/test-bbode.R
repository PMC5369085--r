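test_that("migration curves hit the prescribed endpoints and midpoints", {
  n <- 10
  for (m in c("cosine", "quadratic", "linear")) {
    r0 <- migration_rates(0, n, model = m)
    rn <- migration_rates(n, n, model = m)
    expect_equal(r0$lambda, 1)
    expect_equal(r0$mu, 0)
    expect_equal(rn$lambda, 0)
    expect_equal(rn$mu, 1)
  }
  # exponential model as printed: endpoints only in the limit
  re <- migration_rates(c(0, n), n, model = "exponential")
  expect_equal(re$lambda, c(1, exp(-1)))
  expect_equal(re$mu, c(exp(-1), 1))

  # quadratic midpoint: (1/2)^2 on both sides
  rq <- migration_rates(5, 10, model = "quadratic")
  expect_equal(rq$lambda, 0.25)
  expect_equal(rq$mu, 0.25)

  # linear rates sum to I when I = E
  rl <- migration_rates(0:10, 10, model = "linear")
  expect_equal(rl$lambda + rl$mu, rep(1, 11))

  expect_error(migration_rates(11, 10), "\\[0, n\\]")
})

test_that("a BBO generation with no active operators leaves the population
          unchanged", {
  set.seed(1)
  pop <- matrix(runif(40, -1, 1), ncol = 2)
  fit <- rowSums(pop^2)
  rates <- tibble::tibble(k = 19:0, lambda = rep(0, 20), mu = rep(1, 20))
  out <- aerowarn:::bbo_generation(
    pop, fit, lower = c(-1, -1), upper = c(1, 1), rates = rates,
    mutation_prob = 0, n_elite = 0,
    eval_fitness = function(X) rowSums(X^2)
  )
  expect_equal(out$pop[order(out$fit), ], pop[order(fit), ])
})

test_that("a DE generation is idempotent on a collapsed population and never
          raises mean fitness", {
  pop <- matrix(rep(c(0.3, -0.2), each = 8), ncol = 2)
  fit <- rowSums(pop^2)
  out <- aerowarn:::de_generation(pop, fit, c(-1, -1), c(1, 1), F = 0.6,
                                  CR = 0.9,
                                  eval_fitness = function(X) rowSums(X^2))
  expect_equal(out$pop, pop)

  set.seed(2)
  pop <- matrix(runif(60, -2, 2), ncol = 3)
  fit <- rowSums(pop^2)
  for (i in 1:5) {
    out <- aerowarn:::de_generation(pop, fit, rep(-2, 3), rep(2, 3), 0.6, 0.9,
                                    function(X) rowSums(X^2))
    expect_lte(mean(out$fit), mean(fit))
    pop <- out$pop; fit <- out$fit
  }
})

test_that("elitism makes the per-generation best monotone nonincreasing", {
  b <- benchmark_function("rastrigin")
  for (alg in list(bbode, bbo)) {
    fit <- alg(b$fn, b$lower, b$upper, dim = 3, pop_size = 20,
               max_iter = 150, vectorized = TRUE, seed = 5)
    expect_true(all(diff(fit$history$best) <= 0))
  }
})

test_that("the optimizer is deterministic given a seed and exact on a
          constant objective", {
  obj <- function(x) sum(x^2)
  a <- bbode(obj, -5, 5, dim = 2, pop_size = 12, max_iter = 60, seed = 3)
  b <- bbode(obj, -5, 5, dim = 2, pop_size = 12, max_iter = 60, seed = 3)
  expect_identical(a$par, b$par)
  expect_identical(a$history, b$history)

  const <- bbode(function(x) 7.5, -1, 1, dim = 2, pop_size = 10,
                 max_iter = 20, seed = 1)
  expect_equal(const$value, 7.5)
})

test_that("non-finite objective values are survived, not propagated", {
  spiky <- function(x) if (abs(x[1]) < 0.5) NaN else sum(x^2)
  fit <- bbode(spiky, -3, 3, dim = 2, pop_size = 12, max_iter = 80, seed = 4)
  expect_true(is.finite(fit$value))
})

test_that("BBODE finds the basin of a shifted 1-D quadratic", {
  hits <- vapply(1:20, function(s) {
    fit <- bbode(function(x) (x - 3)^2, lower = -10, upper = 10, dim = 1,
                 pop_size = 20, max_iter = 200, seed = s)
    abs(fit$par - 3) < 0.1
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("repeated DE generations alone solve the 2-D sphere", {
  best <- vapply(1:20, function(s) {
    set.seed(s)
    pop <- matrix(runif(40, -30, 30), ncol = 2)
    f <- function(X) rowSums(X^2)
    fit <- f(pop)
    for (i in seq_len(500)) {
      out <- aerowarn:::de_generation(pop, fit, c(-30, -30), c(30, 30),
                                      0.6, 0.9, f)
      pop <- out$pop; fit <- out$fit
    }
    min(fit)
  }, numeric(1))
  expect_lt(median(best), 1e-6)
})

test_that("the hybrid at least matches plain BBO on a multimodal benchmark", {
  res_de <- run_benchmark("rastrigin", dim = 2, algorithm = "bbode",
                          runs = 6, max_iter = 400, seed = 50)
  res_bbo <- run_benchmark("rastrigin", dim = 2, algorithm = "bbo",
                           runs = 6, max_iter = 400, seed = 50)
  expect_lte(mean(res_de$best), mean(res_bbo$best))
})

test_that("benchmark functions evaluate to their textbook values", {
  X <- rbind(c(0, 0), c(1, 1))
  expect_equal(benchmark_function("sphere")$fn(X), c(0, 2))
  expect_equal(benchmark_function("rastrigin")$fn(X)[1], 0)
  expect_equal(benchmark_function("griewank")$fn(X)[1], 0)
  expect_equal(benchmark_function("ackley")$fn(X)[1], 0, tolerance = 1e-12)
  expect_equal(benchmark_function("rosenbrock")$fn(rbind(c(1, 1)))[1], 0)
  expect_equal(benchmark_function("schaffer")$fn(rbind(c(0, 0)))[1], 0)
})
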