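#' Standard optimization benchmark functions
#'
#' Returns a matrix-vectorised benchmark objective together with its
#' canonical search box. All functions attain their global minimum 0 at
#' the origin except Rosenbrock (minimum at 1) and Schaffer's F6 sum
#' (minimum 0 at the origin with a characteristic ring of local minima
#' near 9.72e-3 per term).
#'
#' @param name One of `"sphere"`, `"rosenbrock"`, `"rastrigin"`,
#'   `"griewank"`, `"ackley"`, `"schaffer"`.
#' @return A list with `fn` (function of a candidate matrix, rows =
#'   candidates), `lower`, `upper` (scalar box bounds).
#' @examples
#' b <- benchmark_function("sphere")
#' b$fn(matrix(c(0, 0, 1, 2), nrow = 2, byrow = TRUE))
#' @export
benchmark_function <- function(name = c("sphere", "rosenbrock", "rastrigin",
                                        "griewank", "ackley", "schaffer")) {
  name <- match.arg(name)
  switch(name,
    sphere = list(fn = function(X) rowSums(X^2), lower = -30, upper = 30),
    rosenbrock = list(
      fn = function(X) {
        D <- ncol(X)
        a <- X[, -D, drop = FALSE]; b <- X[, -1, drop = FALSE]
        rowSums(100 * (b - a^2)^2 + (1 - a)^2)
      },
      lower = -30, upper = 30
    ),
    rastrigin = list(
      fn = function(X) rowSums(X^2 - 10 * cos(2 * pi * X) + 10),
      lower = -5.12, upper = 5.12
    ),
    griewank = list(
      fn = function(X) {
        D <- ncol(X)
        1 + rowSums(X^2) / 4000 -
          apply(cos(X / rep(sqrt(seq_len(D)), each = nrow(X))), 1L, prod)
      },
      lower = -600, upper = 600
    ),
    ackley = list(
      fn = function(X) {
        D <- ncol(X)
        20 - 20 * exp(-0.2 * sqrt(rowSums(X^2) / D)) +
          exp(1) - exp(rowSums(cos(2 * pi * X)) / D)
      },
      lower = -32, upper = 32
    ),
    schaffer = list(
      # Generalised Schaffer F6: summed over consecutive coordinate pairs.
      fn = function(X) {
        D <- ncol(X)
        a <- X[, -D, drop = FALSE]; b <- X[, -1, drop = FALSE]
        s <- a^2 + b^2
        rowSums(0.5 + (sin(sqrt(s))^2 - 0.5) / (1 + 0.001 * s)^2)
      },
      lower = -100, upper = 100
    )
  )
}

#' Repeated benchmark runs of BBO / BBODE
#'
#' Runs the chosen optimizer `runs` times on a named benchmark function,
#' with run seeds derived from `seed` so that BBO and BBODE can be compared
#' on paired seeds.
#'
#' @param name Benchmark name, see [benchmark_function()].
#' @param dim Problem dimension.
#' @param algorithm `"bbode"` or `"bbo"`.
#' @param runs Number of independent runs.
#' @param seed Base seed; run `r` uses `seed + r`.
#' @param ... Further arguments to [bbode()] / [bbo()] (e.g. `max_iter`).
#' @return A tibble with one row per run (`run`, `seed`, `best`) plus the
#'   algorithm and function labels.
#' @examples
#' run_benchmark("sphere", dim = 2, runs = 2, max_iter = 50, seed = 1)
#' @export
run_benchmark <- function(name, dim, algorithm = c("bbode", "bbo"),
                          runs = 20, seed = 1, ...) {
  algorithm <- match.arg(algorithm)
  bench <- benchmark_function(name)
  opt <- if (algorithm == "bbode") bbode else bbo
  purrr::map_dfr(seq_len(runs), function(r) {
    fit <- opt(bench$fn, lower = bench$lower, upper = bench$upper, dim = dim,
               vectorized = TRUE, seed = seed + r, ...)
    tibble::tibble(
      fn = name, dim = dim, algorithm = toupper(algorithm),
      run = r, seed = seed + r, best = fit$value
    )
  })
}
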