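#' Extrapolate the open upper bound of the worst quality level
#'
#' The worst air-quality grade has no upper concentration bound; a
#' pseudo-bound is obtained by ordinary least-squares quadratic regression
#' of the lower grades' upper bounds on their level index (1, 2, ...),
#' evaluated one index past the last observed level.
#'
#' @param upper_bounds Increasing positive upper bounds of the closed
#'   levels (typically five values, levels I-V).
#' @return The extrapolated upper bound (scalar).
#' @examples
#' pseudo_bound(c(40, 80, 180, 280, 565))  # 849 for NO2
#' @export
pseudo_bound <- function(upper_bounds) {
  y <- as.numeric(upper_bounds)
  if (length(y) < 3) abort("At least 3 bounds are needed for a quadratic fit.")
  if (any(!is.finite(y)) || any(y <= 0)) abort("Bounds must be positive.")
  x <- seq_along(y)
  fit <- lm(y ~ x + I(x^2))
  unname(predict(fit, data.frame(x = length(y) + 1)))
}

#' Cloud-model parameters from quality-level boundaries
#'
#' Converts per-level concentration intervals `(B_min, B_max]` into normal
#' cloud parameters: expectation `Ex = (B_max + B_min) / 2`, entropy
#' `En = (B_max - B_min) / 3` and hyper-entropy `He = k * En`, where the
#' atomisation factor `k` balances variation against robustness of the
#' Monte-Carlo certainty draws. A missing `b_max` at the highest level is
#' filled by [pseudo_bound()] from the lower levels' upper bounds. The
#' lowest and highest levels are flagged as half clouds (membership
#' saturates at 1 on the closed side of `Ex`).
#'
#' @param bounds A tibble like `load_fixture("criteria_bounds")`: columns
#'   `criterion`, `level`, `b_min`, `b_max`.
#' @param k Atomisation factor (default 0.1).
#' @return A tibble with `criterion`, `level`, `ex`, `en`, `he`,
#'   `half_side` (`"lower"`, `"upper"` or `"none"`).
#' @examples
#' cloud_params(load_fixture("criteria_bounds"))
#' @export
cloud_params <- function(bounds = load_fixture("criteria_bounds"), k = 0.1) {
  check_number(k, "k", min = 0)
  stopifnot(all(c("criterion", "level", "b_min", "b_max") %in% names(bounds)))
  bounds |>
    dplyr::group_by(.data$criterion) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$level)
      n <- nrow(df)
      if (is.na(df$b_max[n])) {
        df$b_max[n] <- pseudo_bound(df$b_max[-n])
      }
      if (any(df$b_max <= df$b_min)) {
        abort("Each level must satisfy b_max > b_min.")
      }
      dplyr::mutate(
        df,
        ex = (df$b_max + df$b_min) / 2,
        en = (df$b_max - df$b_min) / 3,
        he = k * .data$en,
        half_side = dplyr::case_when(
          dplyr::row_number() == 1L ~ "lower",
          dplyr::row_number() == n ~ "upper",
          TRUE ~ "none"
        )
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::select("criterion", "level", "ex", "en", "he", "half_side")
}

#' Certainty degree of an observation under a normal or half cloud
#'
#' The X-condition forward cloud generator: for each repetition an entropy
#' realisation `En' ~ N(En, He^2)` is drawn (redrawn while non-positive)
#' and the membership is `mu = exp(-(x - Ex)^2 / (2 En'^2))`. For a half
#' cloud the membership saturates at 1 on the closed side of `Ex`
#' (`x <= Ex` for the lowest level, `x >= Ex` for the highest — an
#' observation beyond the pseudo-bound is therefore certain to belong to
#' the worst grade).
#'
#' @param x Observed concentration (scalar).
#' @param ex,en,he Cloud parameters.
#' @param half_side `"none"`, `"lower"` or `"upper"`.
#' @param reps Number of Monte-Carlo repetitions.
#' @param seed Optional integer seed.
#' @return A numeric vector of `reps` certainty degrees in `[0, 1]`.
#' @examples
#' mean(certainty(60, ex = 55, en = 13.33, he = 1.33, reps = 1000, seed = 1))
#' @export
certainty <- function(x, ex, en, he, half_side = "none", reps = 1,
                      seed = NULL) {
  check_number(x, "x")
  check_number(en, "en", min = 0, strict = TRUE)
  check_number(he, "he", min = 0)
  if ((half_side == "lower" && x <= ex) ||
      (half_side == "upper" && x >= ex)) {
    return(rep(1, reps))
  }
  with_seed_or_stream(seed, {
    en_prime <- rnorm(reps, en, he)
    bad <- which(en_prime <= 0)
    while (length(bad)) {
      en_prime[bad] <- rnorm(length(bad), en, he)
      bad <- bad[en_prime[bad] <= 0]
    }
    exp(-(x - ex)^2 / (2 * en_prime^2))
  })
}

#' Histogram-entropy criterion weights
#'
#' Data-driven criterion weights from Shannon entropy of binned
#' concentrations. For each criterion the observed range is split into
#' `bins` equal-width intervals, relative frequencies `F_t` give the
#' entropy `e = -sum F_t ln F_t` (with `0 ln 0 = 0`), the normalised
#' entropy is `E = e / ln(bins)`, and the weight is
#' `omega = (1 - E) / (C - sum E)`: criteria whose data are concentrated
#' (low entropy, more informative) receive more weight. When every
#' criterion is maximally entropic the formula degenerates to `0/0` and
#' equal weights `1/C` are returned by symmetry.
#'
#' @param data Long tibble with `criterion` and `value` columns.
#' @param bins Number of equal-width histogram bins (>= 2).
#' @return A tibble with `criterion`, `entropy`, `normalized_entropy` and
#'   `omega` (summing to 1).
#' @export
entropy_weights <- function(data, bins = 10) {
  stopifnot(all(c("criterion", "value") %in% names(data)))
  check_number(bins, "bins", min = 2)
  per <- data |>
    dplyr::group_by(.data$criterion) |>
    dplyr::summarise(entropy = bin_entropy(.data$value, bins),
                     .groups = "drop") |>
    dplyr::mutate(normalized_entropy = .data$entropy / log(bins))
  C <- nrow(per)
  denom <- C - sum(per$normalized_entropy)
  omega <- if (abs(denom) < 1e-12) {
    rep(1 / C, C)
  } else {
    (1 - per$normalized_entropy) / denom
  }
  dplyr::mutate(per, omega = omega)
}

bin_entropy <- function(x, bins) {
  x <- x[is.finite(x)]
  if (length(x) == 0) abort("Empty sample for a criterion.")
  if (diff(range(x)) == 0) return(0)  # fully concentrated: most informative
  cuts <- seq(min(x), max(x), length.out = bins + 1)
  f <- tabulate(findInterval(x, cuts, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = bins)
  p <- f / sum(f)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Combine expert (AHP) and entropy weights
#'
#' The hybrid criterion weight is the normalised product of the expert
#' AHP weight `z` and the data-driven entropy weight `omega`:
#' `W_i = z_i omega_i / sum_j z_j omega_j`.
#'
#' @param z AHP weights (nonnegative), or a data frame with `z` and
#'   `omega` columns (e.g. `load_fixture("weights")`).
#' @param omega Entropy weights; ignored when `z` is a data frame.
#' @return A tibble with `z`, `omega` and the combined weight `w`
#'   (summing to 1); a `criterion` column is carried through when present.
#' @examples
#' combine_weights(load_fixture("weights"))
#' @export
combine_weights <- function(z, omega = NULL) {
  if (is.data.frame(z)) {
    stopifnot(all(c("z", "omega") %in% names(z)))
    tbl <- z[intersect(c("criterion", "z", "omega"), names(z))]
  } else {
    tbl <- tibble::tibble(z = as.numeric(z), omega = as.numeric(omega))
  }
  if (length(tbl$z) != length(tbl$omega)) {
    abort("`z` and `omega` must have equal length.")
  }
  if (any(tbl$z < 0) || any(tbl$omega < 0)) {
    abort("Weights must be nonnegative.")
  }
  prod <- tbl$z * tbl$omega
  if (sum(prod) == 0) abort("All weight products are zero.")
  dplyr::mutate(tbl, w = prod / sum(prod))
}

#' Grade air quality with the cloud-model evaluator
#'
#' For each sample (a vector of six pollutant concentrations) and each
#' quality level, the per-criterion certainty degrees from [certainty()]
#' are combined into the level certainty `U = sum_i W_i mu_i`; the
#' Monte-Carlo mean of `U` over `reps` repetitions is the final certainty
#' degree, and the sample is assigned the level with the largest mean
#' certainty (ties broken toward the worse level as the conservative
#' warning).
#'
#' @param samples A data frame with one column per criterion
#'   (`PM2.5`, `PM10`, `O3`, `CO`, `NO2`, `SO2`) and optionally a `case`
#'   identifier column, e.g. `load_fixture("eval_samples")`; or a named
#'   numeric vector covering the six criteria.
#' @param clouds Cloud parameters per criterion and level, as produced by
#'   [cloud_params()] (defaults to the published parameter table).
#' @param weights Criterion weights `W` in the order of
#'   `clouds`' criteria; defaults to the published entropy-AHP weights.
#' @param reps Monte-Carlo repetitions per sample and level.
#' @param seed Optional integer seed; the evaluation is then deterministic.
#' @return An `aq_evaluation`: tibble with `case`, one certainty column
#'   per level, and `final_level`. [tidy()] returns the long form,
#'   [autoplot()] a per-level certainty chart.
#' @examples
#' evaluate_air_quality(load_fixture("eval_samples")[3, ],
#'                      reps = 200, seed = 1)
#' @export
evaluate_air_quality <- function(samples,
                                 clouds = NULL,
                                 weights = NULL,
                                 reps = 2000,
                                 seed = NULL) {
  clouds <- clouds %||% {
    cp <- load_fixture("cloud_params")
    dplyr::mutate(cp, half_side = dplyr::case_when(
      .data$level == "I" ~ "lower",
      .data$level == "VI" ~ "upper",
      TRUE ~ "none"
    ))
  }
  weights <- weights %||% load_fixture("weights")$w
  check_number(reps, "reps", min = 1)

  if (!is.data.frame(samples)) {
    samples <- tibble::as_tibble(as.list(samples))
  }
  criteria <- as.character(unique(clouds$criterion))
  missing <- setdiff(criteria, names(samples))
  if (length(missing)) {
    abort(paste0("Missing criterion column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (length(weights) != length(criteria)) {
    abort("`weights` must have one entry per criterion.")
  }
  levels_here <- as.character(unique(clouds$level))
  cases <- if ("case" %in% names(samples)) as.character(samples$case) else
    paste0("S_", seq_len(nrow(samples)))

  res <- with_seed_or_stream(seed, {
    purrr::map_dfr(seq_len(nrow(samples)), function(si) {
      u <- vapply(levels_here, function(lv) {
        u_rep <- numeric(reps)
        for (ci in seq_along(criteria)) {
          cl <- clouds[clouds$criterion == criteria[ci] &
                         clouds$level == lv, ]
          mu <- certainty(samples[[criteria[ci]]][si], cl$ex, cl$en, cl$he,
                          half_side = cl$half_side, reps = reps)
          u_rep <- u_rep + weights[ci] * mu
        }
        mean(u_rep)
      }, numeric(1))
      row <- tibble::as_tibble(as.list(u))
      row$case <- cases[si]
      # argmax with ties resolved toward the worse (higher) level
      row$final_level <- levels_here[max(which(u == max(u)))]
      row
    })
  })
  structure(
    dplyr::relocate(res, "case"),
    class = c("aq_evaluation", class(res))
  )
}

#' @rdname evaluate_air_quality
#' @param x,object An `aq_evaluation`.
#' @param ... Unused.
#' @method tidy aq_evaluation
#' @export
tidy.aq_evaluation <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(-c("case", "final_level"),
                        names_to = "level", values_to = "certainty") |>
    dplyr::mutate(level = factor(.data$level, levels = aq_levels))
}

#' @rdname evaluate_air_quality
#' @method autoplot aq_evaluation
#' @export
autoplot.aq_evaluation <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$level, .data$certainty)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$case)) +
    ggplot2::labs(x = "air-quality level", y = "mean certainty degree")
}
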