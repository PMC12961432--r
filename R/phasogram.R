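#' Phasogram: histogram of pairwise dyad distances
#'
#' For every same-chromosome ordered pair of positions `(i < j)` with
#' `min_lag <= pos_j - pos_i <= max_lag`, the count at that lag is
#' incremented. The periodic peaks of this distance autocorrelation sit at
#' multiples of the nucleosome repeat length. Histograms are computed per
#' chromosome and summed, so cross-chromosome pairs never arise.
#'
#' The default lag window is 50-1200 bp: the lower bound suppresses
#' sub-nucleosomal digestion artifacts, the upper bound keeps at least five
#' periods at ~200 bp spacing. Counting sweeps neighbour ranks of the sorted
#' track, so cost is proportional to the number of pairs within `max_lag`,
#' not to all pairs.
#'
#' @param track A sorted [dyad_track()].
#' @param min_lag,max_lag Inclusive lag window in bp, `1 <= min_lag <= max_lag`.
#' @return A `lag_histogram`: list with `lag` (vector `min_lag:max_lag`),
#'   `count`, and `source` (`"dyad"` or `"start"`).
#' @export
compute_phasogram <- function(track, min_lag = 50, max_lag = 1200) {
  stopifnot(inherits(track, "dyad_track"))
  if (min_lag < 1 || max_lag < min_lag) {
    nrl_validation_error("need 1 <= min_lag <= max_lag")
  }
  min_lag <- as.integer(min_lag); max_lag <- as.integer(max_lag)
  counts <- numeric(max_lag - min_lag + 1L)
  for (ch in names(track$positions)) {
    pos <- track$positions[[ch]]
    if (is.unsorted(pos)) nrl_validation_error(sprintf("track not sorted on %s", ch))
    counts <- counts + pair_lag_counts(pos, min_lag, max_lag)
  }
  new_lag_histogram(min_lag, max_lag, counts, track$source)
}

# Neighbour-rank sweep: rank-d differences of a sorted vector are
# non-decreasing in d pointwise, so once every rank-d difference exceeds
# max_lag no larger rank can contribute.
pair_lag_counts <- function(pos, min_lag, max_lag) {
  n <- length(pos)
  nbins <- max_lag - min_lag + 1L
  counts <- numeric(nbins)
  if (n < 2L) return(counts)
  d <- 1L
  while (d < n) {
    diffs <- pos[(d + 1L):n] - pos[1L:(n - d)]
    if (min(diffs) > max_lag) break
    inwin <- diffs[diffs >= min_lag & diffs <= max_lag]
    if (length(inwin)) {
      counts <- counts + tabulate(as.integer(inwin) - min_lag + 1L, nbins = nbins)
    }
    d <- d + 1L
  }
  counts
}

new_lag_histogram <- function(min_lag, max_lag, counts, source) {
  structure(list(lag = as.integer(min_lag):as.integer(max_lag),
                 count = counts, source = source),
            class = "lag_histogram")
}

#' @export
print.lag_histogram <- function(x, ...) {
  cat(sprintf("<lag_histogram> source=%s, lags %d-%d, %.0f pairs\n",
              x$source, min(x$lag), max(x$lag), sum(x$count)))
  invisible(x)
}

#' Phasogram of fragment start coordinates
#'
#' Identical counting kernel applied to 5' start positions, for
#' single-end-style data where dyads are unknown. A constant start-to-dyad
#' offset cancels in pairwise distances, so the fitted NRL matches the dyad
#' method up to noise from variable fragment lengths.
#'
#' @inheritParams compute_phasogram
#' @param track A [dyad_track()] built by [fragment_starts()].
#' @return A `lag_histogram` with `source = "start"`.
#' @export
compute_start_phasogram <- function(track, min_lag = 50, max_lag = 1200) {
  stopifnot(inherits(track, "dyad_track"))
  track$source <- "start"
  compute_phasogram(track, min_lag, max_lag)
}

#' Smooth a lag histogram
#'
#' Centred moving average with truncated windows at the edges; `window = 1`
#' is the identity. The default 15 bp window used downstream is wide enough
#' to remove 10 bp helical-twist ripple while keeping summit positions to
#' about 1 bp.
#'
#' @param hist A `lag_histogram`.
#' @param window Odd window width in bp.
#' @return A `lag_histogram` with real-valued counts.
#' @export
smooth_histogram <- function(hist, window = 15) {
  stopifnot(inherits(hist, "lag_histogram"))
  new_lag_histogram(min(hist$lag), max(hist$lag),
                    moving_average(hist$count, window), hist$source)
}

#' Detect periodic peak summits in a smoothed phasogram
#'
#' The fundamental period `p` is first taken as the lag of the histogram
#' maximum within `[period_min, period_max]`. For peak order k = 1, 2, ...
#' the summit is the argmax within `[k*p - p/3, k*p + p/3]` (clipped to the
#' histogram range), accepted only if it is a local maximum whose prominence
#' exceeds `min_prominence_frac` of the first peak's height; after each
#' acceptance `p` is re-estimated as the running mean of `summit_k / k`.
#' Ties break toward the smaller lag. Orders whose peak fails acceptance are
#' skipped (gaps are allowed; the regression uses (k, position) pairs).
#'
#' @param hist A smoothed `lag_histogram`.
#' @param period_min,period_max Search window for the fundamental period, bp.
#' @param max_peaks Maximum peak order to attempt.
#' @param min_prominence_frac Required prominence as a fraction of the first
#'   peak height (default 0.02).
#' @param include_first Keep the k = 1 summit in the returned series (it is
#'   the most smoothing-sensitive one; set `FALSE` to drop it from the fit).
#' @return A `summit_series` data frame with columns `k`, `position`,
#'   `height`.
#' @export
detect_summits <- function(hist, period_min = 120, period_max = 250,
                           max_peaks = 10, min_prominence_frac = 0.02,
                           include_first = TRUE) {
  stopifnot(inherits(hist, "lag_histogram"))
  if (period_min >= period_max) nrl_validation_error("need period_min < period_max")
  lags <- hist$lag; values <- hist$count
  lo0 <- max(period_min, min(lags)); hi0 <- min(period_max, max(lags))
  if (lo0 > hi0) nrl_estimation_error("period window outside histogram range")
  s0 <- window_argmax(values, lo0 - lags[1L] + 1L, hi0 - lags[1L] + 1L)
  p_hat <- as.numeric(lags[s0])
  ref_height <- NA_real_
  ks <- integer(); positions <- numeric(); heights <- numeric()
  ratios <- numeric()
  for (k in seq_len(max_peaks)) {
    centre <- k * p_hat
    lo <- max(floor(centre - p_hat / 3), min(lags))
    hi <- min(ceiling(centre + p_hat / 3), max(lags))
    if (lo > max(lags)) break
    if (lo > hi) next
    i_lo <- lo - lags[1L] + 1L; i_hi <- hi - lags[1L] + 1L
    s <- window_argmax(values, i_lo, i_hi)
    if (is.na(s)) next
    half <- as.integer(period_min) %/% 2L
    q <- summit_quality(values, s, s - half, s + half)
    if (is.na(ref_height)) ref_height <- q$height
    if (!q$is_local_max || q$prominence < min_prominence_frac * ref_height) next
    ks <- c(ks, k); positions <- c(positions, lags[s]); heights <- c(heights, q$height)
    ratios <- c(ratios, lags[s] / k)
    p_hat <- mean(ratios)
  }
  if (length(ks) < 3L) {
    nrl_estimation_error(sprintf(
      "insufficient periodicity: %d summit(s) accepted, need at least 3", length(ks)))
  }
  summits <- data.frame(k = ks, position = positions, height = heights)
  if (!include_first) summits <- summits[summits$k != 1L, , drop = FALSE]
  class(summits) <- c("summit_series", "data.frame")
  summits
}

#' Fit the NRL as the slope of summit position on peak order
#'
#' Ordinary least squares of summit position on peak order k, with an
#' intercept (not forced through the origin: the first-peak position can
#' carry a method-dependent offset). The slope is the NRL estimate.
#'
#' @param summits A `summit_series` (or data frame with columns `k`,
#'   `position`), at least 3 rows.
#' @param method Method tag recorded on the estimate: one of
#'   `"dyad_phasogram"`, `"start_phasogram"`, `"fragment_size"`,
#'   `"anchored_profile"`.
#' @return An `nrl_estimate`: `nrl` (slope, bp), `intercept`, `slope_stderr`,
#'   `r_squared`, `n_summits`, `method`, and the summit series used.
#' @export
fit_nrl <- function(summits, method = c("dyad_phasogram", "start_phasogram",
                                        "fragment_size", "anchored_profile")) {
  method <- match.arg(method)
  if (!all(c("k", "position") %in% names(summits))) {
    nrl_validation_error("summits need columns k and position")
  }
  if (nrow(summits) < 3L) {
    nrl_estimation_error(sprintf("need at least 3 summits, got %d", nrow(summits)))
  }
  if (stats::var(summits$k) == 0) nrl_estimation_error("zero variance in peak order")
  fit <- stats::lm(position ~ k, data = summits)
  sm <- suppressWarnings(summary(fit))  # exact fits trigger a spurious warning
  se <- sm$coefficients["k", "Std. Error"]
  if (!is.finite(se)) se <- 0
  structure(list(
    nrl = unname(coef(fit)["k"]),
    intercept = unname(coef(fit)["(Intercept)"]),
    slope_stderr = se,
    r_squared = if (is.nan(sm$r.squared)) 1 else sm$r.squared,
    n_summits = nrow(summits),
    method = method,
    summits = summits
  ), class = "nrl_estimate")
}

#' @export
print.nrl_estimate <- function(x, ...) {
  cat(sprintf("NRL estimate (%s): %.2f bp (+/- %.2f, r^2 = %.4f, %d summits)\n",
              x$method, x$nrl, x$slope_stderr, x$r_squared, x$n_summits))
  invisible(x)
}

#' @exportS3Method base::as.data.frame
as.data.frame.nrl_estimate <- function(x, ...) {
  data.frame(method = x$method, nrl = x$nrl, intercept = x$intercept,
             slope_stderr = x$slope_stderr, r_squared = x$r_squared,
             n_summits = x$n_summits)
}

#' One-call phasogram NRL estimate
#'
#' Convenience pipeline: phasogram, smoothing, summit detection, OLS fit.
#'
#' @inheritParams compute_phasogram
#' @inheritParams detect_summits
#' @param smooth_window Odd smoothing window, bp.
#' @return An `nrl_estimate` (method tag follows the track source).
#' @export
estimate_nrl_phasogram <- function(track, min_lag = 50, max_lag = 1200,
                                   smooth_window = 15, period_min = 120,
                                   period_max = 250, max_peaks = 10,
                                   min_prominence_frac = 0.02,
                                   include_first = TRUE) {
  hist <- compute_phasogram(track, min_lag, max_lag)
  sm <- smooth_histogram(hist, smooth_window)
  summits <- detect_summits(sm, period_min, period_max, max_peaks,
                            min_prominence_frac, include_first)
  fit_nrl(summits, if (track$source == "start") "start_phasogram" else "dyad_phasogram")
}
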