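#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) by iterative
#' sifting: cubic-spline envelopes are drawn through the local maxima and
#' minima (with mirror extension of two extrema at each boundary to tame end
#' effects), the envelope mean is subtracted, and the process repeats until
#' a Cauchy-type stopping criterion is met. Extraction stops when the
#' residue is monotone (fewer than two interior extrema of either kind) or
#' `max_imfs` modes have been pulled out. The components satisfy the exact
#' reconstruction identity `signal = sum(IMFs) + residue`.
#'
#' @param x A data frame with a numeric `value` column (and optionally a
#'   `timestamp` column, carried through), or a numeric vector.
#' @param max_imfs Maximum number of IMFs to extract.
#' @param stop_threshold Cauchy stopping threshold for sifting: sifting of a
#'   mode ends once the normalised squared change between successive sift
#'   iterates drops below this value.
#' @param max_sift Maximum sift iterations per IMF.
#'
#' @return An object of class `imf_decomposition`: a list with `imfs`
#'   (length-N columns, one per mode, possibly zero columns for a monotone
#'   input), `residue`, `signal` and `timestamp`. Use [tidy()] for a long
#'   tibble and [autoplot()] to plot the components.
#'
#' @seealso [ceemd()] for the noise-assisted ensemble version, [denoise()]
#'   for the first-mode removal filter.
#' @examples
#' t <- seq_len(512)
#' dec <- emd(sin(2 * pi * t / 16) + 0.05 * t)
#' ncol(dec$imfs)
#' max(abs(rowSums(dec$imfs) + dec$residue - dec$signal))
#' @export
emd <- function(x, max_imfs = 8, stop_threshold = 0.2, max_sift = 50) {
  parsed <- parse_series_input(x)
  signal <- parsed$value
  if (length(signal) < 4) abort("`x` must contain at least 4 observations.")
  if (!all(is.finite(signal))) abort("`x` must be finite.")
  check_number(max_imfs, "max_imfs", min = 1)
  check_number(stop_threshold, "stop_threshold", min = 0)
  check_number(max_sift, "max_sift", min = 1)

  n <- length(signal)
  residue <- signal
  imfs <- matrix(numeric(0), nrow = n, ncol = 0)

  while (ncol(imfs) < max_imfs && !is_monotone_mode(residue)) {
    h <- residue
    for (s in seq_len(max_sift)) {
      env <- envelope_mean(h)
      if (is.null(env)) break
      h_new <- h - env
      sd_crit <- sum((h - h_new)^2) / max(sum(h^2), .Machine$double.xmin)
      h <- h_new
      # stop once the change is small AND the mode property (extrema and
      # zero-crossing counts differing by at most one) holds
      if (sd_crit < stop_threshold &&
          abs(count_extrema(h) - count_zero_crossings(h)) <= 1) {
        break
      }
    }
    imfs <- cbind(imfs, h)
    residue <- residue - h
  }
  colnames(imfs) <- if (ncol(imfs)) paste0("imf", seq_len(ncol(imfs))) else NULL

  structure(
    list(
      imfs = imfs, residue = residue, signal = signal,
      timestamp = parsed$timestamp, method = "emd"
    ),
    class = "imf_decomposition"
  )
}

#' Complementary ensemble empirical mode decomposition (CEEMD)
#'
#' Noise-assisted EMD that mitigates mode mixing: for each of
#' `ensemble_size` white-noise realisations a *pair* of contaminated copies
#' of the signal is built (noise added and subtracted), each copy is
#' decomposed by [emd()], and the j-th IMF is averaged over all `2 *
#' ensemble_size` decompositions. Because the noise enters in
#' complementary pairs it cancels exactly in the reconstruction, so
#' `sum(IMFs) + residue` still recovers the input to numerical tolerance.
#' Members whose decomposition yields fewer than `max_imfs` modes are
#' zero-padded before averaging so the ensemble mean is well defined.
#'
#' @inheritParams emd
#' @param ensemble_size Number of noise pairs (the standard setting for
#'   hourly pollutant series is 200).
#' @param noise_std Standard deviation of the added white noise as a
#'   fraction of the signal's standard deviation (standard setting 0.4).
#' @param seed Optional integer for a reproducible ensemble.
#'
#' @return An `imf_decomposition` (see [emd()]); trailing all-zero averaged
#'   modes are dropped.
#' @examples
#' t <- seq_len(256)
#' dec <- ceemd(sin(2 * pi * t / 8) + sin(2 * pi * t / 64),
#'              ensemble_size = 5, seed = 1)
#' @export
ceemd <- function(x, ensemble_size = 200, noise_std = 0.4, max_imfs = 8,
                  stop_threshold = 0.2, max_sift = 50, seed = NULL) {
  parsed <- parse_series_input(x)
  signal <- parsed$value
  check_number(ensemble_size, "ensemble_size", min = 1)
  check_number(noise_std, "noise_std", min = 0)
  n <- length(signal)
  sigma <- noise_std * sd(signal)

  decompose <- function(s) {
    d <- emd(s, max_imfs = max_imfs, stop_threshold = stop_threshold,
             max_sift = max_sift)
    k <- ncol(d$imfs)
    im <- cbind(d$imfs, matrix(0, n, max_imfs - k))
    list(imfs = im, residue = d$residue)
  }

  out <- with_seed_or_stream(seed, {
    acc_imfs <- matrix(0, n, max_imfs)
    acc_res <- numeric(n)
    for (i in seq_len(ensemble_size)) {
      eps <- if (sigma > 0) rnorm(n, 0, sigma) else numeric(n)
      pos <- decompose(signal + eps)
      neg <- decompose(signal - eps)
      acc_imfs <- acc_imfs + pos$imfs + neg$imfs
      acc_res <- acc_res + pos$residue + neg$residue
    }
    list(imfs = acc_imfs / (2 * ensemble_size),
         residue = acc_res / (2 * ensemble_size))
  })

  keep <- which(colSums(abs(out$imfs)) > 0)
  imfs <- out$imfs[, seq_len(max(keep, 0L)), drop = FALSE]
  colnames(imfs) <- if (ncol(imfs)) paste0("imf", seq_len(ncol(imfs))) else NULL

  structure(
    list(
      imfs = imfs, residue = out$residue, signal = signal,
      timestamp = parsed$timestamp, method = "ceemd"
    ),
    class = "imf_decomposition"
  )
}

#' Remove the high-frequency mode from a decomposition
#'
#' The first IMF carries the highest-frequency content, which for hourly
#' pollutant series behaves like measurement noise. The denoised series is
#' the sum of the remaining modes and the residue; adding the first IMF
#' back recovers the full reconstruction.
#'
#' @param decomposition An `imf_decomposition` from [emd()] or [ceemd()].
#' @return A tibble with columns `timestamp` and `value` (the denoised
#'   series). With an empty mode set the residue is returned unchanged.
#' @examples
#' d <- ceemd(generate_series(n_hours = 200, seed = 1),
#'            ensemble_size = 2, seed = 2)
#' denoise(d)
#' @export
denoise <- function(decomposition) {
  stopifnot(inherits(decomposition, "imf_decomposition"))
  k <- ncol(decomposition$imfs)
  value <- decomposition$residue +
    if (k > 1) rowSums(decomposition$imfs[, -1, drop = FALSE]) else 0
  tibble::tibble(
    timestamp = decomposition$timestamp %||% seq_along(value),
    value = as.numeric(value)
  )
}

#' @export
print.imf_decomposition <- function(x, ...) {
  cat(sprintf(
    "<imf_decomposition> %s: %d IMFs + residue over %d observations\n",
    x$method, ncol(x$imfs), length(x$signal)
  ))
  err <- max(abs(rowSums(cbind(x$imfs, x$residue)) - x$signal))
  cat(sprintf("  max reconstruction error: %.3g\n", err))
  invisible(x)
}

#' @rdname emd
#' @param ... Unused.
#' @method tidy imf_decomposition
#' @export
tidy.imf_decomposition <- function(x, ...) {
  comps <- cbind(x$imfs, residue = x$residue)
  tibble::tibble(
    timestamp = rep(x$timestamp %||% seq_along(x$signal), ncol(comps)),
    component = factor(rep(colnames(comps), each = nrow(comps)),
                       levels = colnames(comps)),
    value = as.numeric(comps)
  )
}

#' Plot the components of a decomposition
#'
#' @param object An `imf_decomposition`.
#' @param ... Unused.
#' @return A ggplot with one facet per IMF plus the residue.
#' @method autoplot imf_decomposition
#' @export
autoplot.imf_decomposition <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$timestamp, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$component),
                        scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s decomposition", toupper(object$method)))
}

# ---- internals ---------------------------------------------------------

parse_series_input <- function(x) {
  if (is.data.frame(x)) {
    if (!"value" %in% names(x)) {
      abort("Data-frame input must have a `value` column.")
    }
    list(value = as.numeric(x$value), timestamp = x[["timestamp"]])
  } else if (is.numeric(x)) {
    list(value = as.numeric(x), timestamp = NULL)
  } else {
    abort("`x` must be a data frame with a `value` column or a numeric vector.")
  }
}

# Interior local maxima/minima; ties broken so a flat-topped peak yields a
# single extremum.
local_extrema <- function(x) {
  n <- length(x)
  i <- 2:(n - 1)
  maxima <- i[x[i] > x[i - 1] & x[i] >= x[i + 1] |
                x[i] >= x[i - 1] & x[i] > x[i + 1]]
  minima <- i[x[i] < x[i - 1] & x[i] <= x[i + 1] |
                x[i] <= x[i - 1] & x[i] < x[i + 1]]
  # Collapse runs of equal values flagged at both ends of a plateau.
  list(maxima = maxima[c(TRUE, diff(maxima) > 1)],
       minima = minima[c(TRUE, diff(minima) > 1)])
}

is_monotone_mode <- function(x) {
  ext <- local_extrema(x)
  length(ext$maxima) < 2 || length(ext$minima) < 2
}

# Cubic-spline envelope mean with mirror extension of up to two extrema at
# each end; NULL when an envelope cannot be formed.
envelope_mean <- function(x) {
  ext <- local_extrema(x)
  if (length(ext$maxima) < 2 || length(ext$minima) < 2) return(NULL)
  n <- length(x)
  upper <- spline_envelope(ext$maxima, x[ext$maxima], n)
  lower <- spline_envelope(ext$minima, x[ext$minima], n)
  (upper + lower) / 2
}

spline_envelope <- function(idx, val, n) {
  k <- min(2L, length(idx))
  left_t <- 2 - rev(idx[seq_len(k)])
  left_v <- rev(val[seq_len(k)])
  right_t <- 2 * n - rev(rev(idx)[seq_len(k)])
  right_v <- rev(rev(val)[seq_len(k)])
  f <- splinefun(c(left_t, idx, right_t), c(left_v, val, right_v),
                 method = "fmm")
  f(seq_len(n))
}

count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  sum(diff(s) != 0)
}

count_extrema <- function(x) {
  ext <- local_extrema(x)
  length(ext$maxima) + length(ext$minima)
}
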