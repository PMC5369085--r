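#' Migration rates for biogeography-based optimization
#'
#' Maps a habitat's species count `k` to its immigration rate `lambda` and
#' emigration rate `mu` under one of four migration curves. In all four,
#' an empty habitat (`k = 0`) has maximal immigration `I` and no
#' emigration, while a saturated habitat (`k = n`) has no immigration and
#' maximal emigration `E`:
#' \describe{
#'   \item{cosine}{`lambda = 0.5 I (1 + cos(k pi / n))`,
#'     `mu = 0.5 E (1 - cos(k pi / n))`}
#'   \item{quadratic}{`lambda = I (k/n - 1)^2`, `mu = E (k/n)^2`}
#'   \item{exponential}{`lambda = I exp(-k/n)`, `mu = E exp(k/n - 1)`
#'     (endpoints attained only in the limit)}
#'   \item{linear}{`lambda = I (1 - k/n)`, `mu = E k/n`}
#' }
#'
#' @param k Species counts, integers in `[0, n]` (vectorised).
#' @param n Maximum species count (population size).
#' @param model Migration curve name.
#' @param I,E Maximum immigration and emigration rates, in `(0, 1]`.
#' @return A tibble with columns `k`, `lambda`, `mu`.
#' @examples
#' migration_rates(0:10, n = 10, model = "cosine")
#' @export
migration_rates <- function(k, n,
                            model = c("cosine", "quadratic", "exponential",
                                      "linear"),
                            I = 1, E = 1) {
  model <- match.arg(model)
  check_number(n, "n", min = 1)
  check_number(I, "I", min = 0, strict = TRUE)
  check_number(E, "E", min = 0, strict = TRUE)
  if (any(k < 0 | k > n)) abort("`k` must lie in [0, n].")
  r <- k / n
  rates <- switch(model,
    cosine = list(lambda = 0.5 * I * (1 + cos(r * pi)),
                  mu = 0.5 * E * (1 - cos(r * pi))),
    quadratic = list(lambda = I * (r - 1)^2, mu = E * r^2),
    exponential = list(lambda = I * exp(-r), mu = E * exp(r - 1)),
    linear = list(lambda = I * (1 - r), mu = E * r)
  )
  tibble::tibble(k = k, lambda = rates$lambda, mu = rates$mu)
}

#' Hybrid biogeography-based optimization with differential evolution
#'
#' Minimises `objective` over a box by biogeography-based optimization
#' (BBO): candidate solutions are habitats whose fitness (habitat
#' suitability) sets probabilistic migration of decision variables from
#' good habitats to poor ones, followed by mutation and elitism. Mutation
#' redraws a variable uniformly within the box at a rank-scaled rate — the
#' worst habitat mutates at `mutation_prob` per variable, the best not at
#' all — mirroring the species-count-probability weighting of classical
#' BBO while protecting refined solutions.
#' In the hybrid (BBODE) variant a differential-evolution generation
#' (DE/rand/1/bin with greedy selection) is additionally applied on every
#' even-numbered iteration, sharpening local exploitation.
#'
#' Habitats are ranked each generation; the best habitat receives the
#' largest species count (lowest immigration, highest emigration) and the
#' worst receives `k = 0`. Emigration sources are drawn by roulette wheel
#' over `mu`, excluding the receiving habitat. All operators clip to the
#' box. Non-finite objective values are treated as worst-possible fitness.
#'
#' @param objective Function mapping a numeric vector of length `D` to a
#'   scalar to minimise. With `vectorized = TRUE` it must accept a matrix
#'   (rows = candidates) and return a vector.
#' @param lower,upper Box bounds, length `D` (or scalars, recycled).
#' @param pop_size Number of habitats (default 50).
#' @param max_iter Number of generations (default 5000).
#' @param n_elite Elites preserved each generation (default 3).
#' @param mutation_prob Per-variable uniform mutation probability
#'   (default 0.4 for the hybrid; plain BBO conventionally uses 0.05).
#' @param de_factor DE difference factor F (default 0.6).
#' @param de_cross DE binomial crossover rate (default 0.9).
#' @param migration_model Migration curve, see [migration_rates()].
#' @param I,E Maximum immigration/emigration rates.
#' @param hybrid_de Apply the DE generation on even iterations? `FALSE`
#'   gives plain BBO.
#' @param vectorized Is `objective` matrix-vectorised?
#' @param seed Optional integer seed; the run is then deterministic.
#'
#' @return A `bbode_result`: list with `par` (best solution), `value`
#'   (best objective), `history` (tibble of per-generation best), counts
#'   and settings. [tidy()] returns the convergence history, [glance()] a
#'   one-row summary, [autoplot()] the convergence curve.
#' @examples
#' fit <- bbode(function(x) sum((x - 3)^2), lower = -10, upper = 10,
#'              dim = 2, pop_size = 20, max_iter = 100, seed = 1)
#' fit$par
#' @param dim Problem dimension; required when `lower`/`upper` are scalars.
#' @export
bbode <- function(objective, lower, upper, dim = NULL,
                  pop_size = 50, max_iter = 5000, n_elite = 3,
                  mutation_prob = 0.4, de_factor = 0.6, de_cross = 0.9,
                  migration_model = "cosine", I = 1, E = 1,
                  hybrid_de = TRUE, vectorized = FALSE, seed = NULL) {
  dim <- dim %||% max(length(lower), length(upper))
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  if (any(upper <= lower)) abort("`upper` must exceed `lower`.")
  if (pop_size <= n_elite || n_elite < 0) {
    abort("`pop_size` must exceed `n_elite` (>= 0).")
  }
  if (mutation_prob < 0 || mutation_prob > 1) {
    abort("`mutation_prob` must be in [0, 1].")
  }
  if (hybrid_de && pop_size < 4) {
    abort("The DE generation requires `pop_size` >= 4.")
  }

  eval_fitness <- function(X) {
    f <- if (vectorized) as.numeric(objective(X)) else
      apply(X, 1L, function(row) as.numeric(objective(row))[1L])
    f[!is.finite(f)] <- Inf
    f
  }

  with_seed_or_stream(seed, {
    P <- pop_size
    pop <- matrix(runif(P * dim, rep(lower, each = P), rep(upper, each = P)),
                  nrow = P)
    fit <- eval_fitness(pop)
    rates <- migration_rates(P - seq_len(P), n = P, model = migration_model,
                             I = I, E = E)
    best_hist <- numeric(max_iter)
    n_evals <- P

    for (gen in seq_len(max_iter)) {
      step <- bbo_generation(pop, fit, lower, upper, rates,
                             mutation_prob, n_elite, eval_fitness)
      pop <- step$pop; fit <- step$fit; n_evals <- n_evals + step$evals
      if (hybrid_de && gen %% 2 == 0) {
        step <- de_generation(pop, fit, lower, upper, de_factor, de_cross,
                              eval_fitness)
        pop <- step$pop; fit <- step$fit; n_evals <- n_evals + step$evals
      }
      best_hist[gen] <- min(fit)
    }

    ib <- which.min(fit)
    structure(
      list(
        par = pop[ib, ], value = fit[ib],
        history = tibble::tibble(iteration = seq_len(max_iter),
                                 best = best_hist),
        n_evals = n_evals, population = pop, fitness = fit,
        settings = list(pop_size = P, max_iter = max_iter, n_elite = n_elite,
                        mutation_prob = mutation_prob, de_factor = de_factor,
                        de_cross = de_cross, migration_model = migration_model,
                        hybrid_de = hybrid_de)
      ),
      class = "bbode_result"
    )
  })
}

#' Plain biogeography-based optimization
#'
#' [bbode()] without the differential-evolution generations and with the
#' conventional low mutation probability; kept as the comparison baseline.
#'
#' @inheritParams bbode
#' @return A `bbode_result`, see [bbode()].
#' @export
bbo <- function(objective, lower, upper, dim = NULL, pop_size = 50,
                max_iter = 5000, n_elite = 3, mutation_prob = 0.05,
                migration_model = "cosine", I = 1, E = 1,
                vectorized = FALSE, seed = NULL) {
  bbode(objective, lower, upper, dim = dim, pop_size = pop_size,
        max_iter = max_iter, n_elite = n_elite,
        mutation_prob = mutation_prob, migration_model = migration_model,
        I = I, E = E, hybrid_de = FALSE, vectorized = vectorized, seed = seed)
}

#' @export
print.bbode_result <- function(x, ...) {
  cat(sprintf(
    "<bbode_result> %s: best value %.6g after %d generations (%d evaluations)\n",
    if (x$settings$hybrid_de) "BBODE" else "BBO",
    x$value, x$settings$max_iter, x$n_evals
  ))
  invisible(x)
}

#' @rdname bbode
#' @param x,object A `bbode_result`.
#' @param ... Unused.
#' @method tidy bbode_result
#' @export
tidy.bbode_result <- function(x, ...) x$history

#' @rdname bbode
#' @method glance bbode_result
#' @export
glance.bbode_result <- function(x, ...) {
  tibble::tibble(
    algorithm = if (x$settings$hybrid_de) "BBODE" else "BBO",
    best = x$value, n_evals = x$n_evals,
    iterations = x$settings$max_iter, pop_size = x$settings$pop_size
  )
}

#' @rdname bbode
#' @method autoplot bbode_result
#' @export
autoplot.bbode_result <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(.data$iteration, .data$best)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generation", y = "best objective value")
}

# ---- generation operators ----------------------------------------------

# One BBO generation: ranked migration, uniform mutation, elitism.
# `rates` holds lambda/mu for k = P-1 (best) .. 0 (worst) in rank order.
bbo_generation <- function(pop, fit, lower, upper, rates,
                           mutation_prob, n_elite, eval_fitness) {
  P <- nrow(pop); D <- ncol(pop)
  ord <- order(fit)
  pop <- pop[ord, , drop = FALSE]
  fit <- fit[ord]
  elite_pop <- pop[seq_len(n_elite), , drop = FALSE]
  elite_fit <- fit[seq_len(n_elite)]

  newpop <- pop
  lambda <- rates$lambda
  mu <- rates$mu

  imm <- matrix(runif(P * D) < lambda, nrow = P)
  if (n_elite > 0) imm[seq_len(n_elite), ] <- FALSE
  idx <- which(imm)
  if (length(idx)) {
    row <- ((idx - 1L) %% P) + 1L
    donors <- sample.int(P, length(idx), replace = TRUE, prob = mu)
    clash <- which(donors == row)
    while (length(clash)) {
      donors[clash] <- sample.int(P, length(clash), replace = TRUE, prob = mu)
      clash <- clash[donors[clash] == row[clash]]
    }
    col <- ((idx - 1L) %/% P) + 1L
    newpop[idx] <- pop[cbind(donors, col)]
  }

  if (mutation_prob > 0) {
    # Rank-scaled mutation rate in Simon's species-probability spirit: the
    # worst habitat is mutated at the nominal rate, the best not at all.
    mrate <- mutation_prob * (seq_len(P) - 1) / (P - 1)
    mut <- matrix(runif(P * D) < mrate, nrow = P)
    midx <- which(mut)
    if (length(midx)) {
      mcol <- ((midx - 1L) %/% P) + 1L
      newpop[midx] <- lower[mcol] +
        runif(length(midx)) * (upper[mcol] - lower[mcol])
    }
  }

  newpop <- clip_box(newpop, lower, upper)
  newfit <- eval_fitness(newpop)

  if (n_elite > 0) {
    worst <- order(newfit, decreasing = TRUE)[seq_len(n_elite)]
    newpop[worst, ] <- elite_pop
    newfit[worst] <- elite_fit
  }
  list(pop = newpop, fit = newfit, evals = P)
}

# One DE/rand/1/bin generation with greedy selection.
de_generation <- function(pop, fit, lower, upper, F, CR, eval_fitness) {
  P <- nrow(pop); D <- ncol(pop)
  r <- distinct_triples(P)
  trial <- pop[r$r1, , drop = FALSE] +
    F * (pop[r$r2, , drop = FALSE] - pop[r$r3, , drop = FALSE])
  cross <- matrix(runif(P * D) < CR, nrow = P)
  jrand <- cbind(seq_len(P), sample.int(D, P, replace = TRUE))
  cross[jrand] <- TRUE
  trial[!cross] <- pop[!cross]
  trial <- clip_box(trial, lower, upper)
  tfit <- eval_fitness(trial)
  better <- tfit < fit
  pop[better, ] <- trial[better, , drop = FALSE]
  fit[better] <- tfit[better]
  list(pop = pop, fit = fit, evals = P)
}

# For each target i, three distinct random indices r1, r2, r3, all != i.
distinct_triples <- function(P) {
  r1 <- sample.int(P, P, replace = TRUE)
  r2 <- sample.int(P, P, replace = TRUE)
  r3 <- sample.int(P, P, replace = TRUE)
  i <- seq_len(P)
  redraw <- function(r, taboo1, taboo2, taboo3) {
    bad <- which(r == taboo1 | r == taboo2 | r == taboo3)
    while (length(bad)) {
      r[bad] <- sample.int(P, length(bad), replace = TRUE)
      bad <- bad[r[bad] == taboo1[bad] | r[bad] == taboo2[bad] |
                   r[bad] == taboo3[bad]]
    }
    r
  }
  r1 <- redraw(r1, i, i, i)
  r2 <- redraw(r2, i, r1, r1)
  r3 <- redraw(r3, i, r1, r2)
  list(r1 = r1, r2 = r2, r3 = r3)
}

clip_box <- function(X, lower, upper) {
  X <- pmax(X, rep(lower, each = nrow(X)))
  pmin(X, rep(upper, each = nrow(X)))
}
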