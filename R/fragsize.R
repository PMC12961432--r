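#' Fragment-size histogram
#'
#' Counts fragments per exact 1 bp length in `[1, max_len]` — the sequencing
#' analogue of a gel-electrophoresis ladder, whose mono-, di-, tri-nucleosome
#' bands carry the NRL as the spacing between peak summits. Lengths above
#' `max_len` go into an overflow bucket and are logged.
#'
#' @param fragments Fragment table.
#' @param max_len Largest length tracked at 1 bp resolution (default 2000,
#'   covering ~10-nucleosome spans).
#' @return A `size_histogram`: list with `len` (`1:max_len`), `count`, and
#'   `overflow`.
#' @export
fragment_size_histogram <- function(fragments, max_len = 2000) {
  fragments <- validate_fragments(fragments)
  max_len <- as.integer(max_len)
  lens <- fragments$length
  over <- sum(lens > max_len)
  if (over > 0) nrl_log(sprintf("%d fragment(s) longer than %d counted as overflow", over, max_len))
  counts <- tabulate(as.integer(lens[lens <= max_len]), nbins = max_len)
  structure(list(len = seq_len(max_len), count = counts, overflow = over),
            class = "size_histogram")
}

#' @export
print.size_histogram <- function(x, ...) {
  cat(sprintf("<size_histogram> lengths 1-%d, %.0f fragments (+%d overflow)\n",
              max(x$len), sum(x$count), x$overflow))
  invisible(x)
}

# Ladder summit search shared by the fragment-size and anchored-profile
# estimators: peaks sit at first_summit + (k-1) * period rather than at
# harmonics k * period. The first summit is the argmax in [first_lo,
# first_hi]; the second is searched in [s1 + period_min, s1 + period_max]
# and fixes the initial period; later orders use windows of +/- period/3
# around the extrapolated position, with the period re-estimated as the
# running mean of (s_k - s1)/(k - 1). Acceptance (local maximum, prominence
# >= frac of the first summit height) matches detect_summits, with one
# addition: prominence must also clear `noise_z` robust noise SDs of the
# smoothed signal (estimated from successive differences), so unstructured
# profiles -- e.g. anchors that do not phase nucleosome arrays -- yield no
# summits instead of a ladder of noise bumps.
ladder_summits <- function(values, coords, first_lo, first_hi,
                           period_min, period_max, max_peaks,
                           min_prominence_frac, noise_z = 4,
                           smooth_window = 1) {
  c0 <- coords[1L]
  idx <- function(x) as.integer(x - c0 + 1L)
  # a width-w moving average turns iid noise sd_raw into sd_raw/sqrt(w) while
  # successive differences shrink to sd_raw*sqrt(2)/w; invert that to recover
  # the fluctuation scale of the smoothed signal itself
  noise_sd <- stats::mad(diff(values)) * sqrt(max(smooth_window, 1) / 2)
  min_prom_abs <- noise_z * noise_sd
  lo1 <- max(first_lo, min(coords)); hi1 <- min(first_hi, max(coords))
  if (lo1 > hi1) nrl_estimation_error("first-peak window outside histogram range")
  half <- as.integer(period_min) %/% 2L  # prominence window: centred, ~half period
  s1 <- window_argmax(values, idx(lo1), idx(hi1))
  q1 <- summit_quality(values, s1, s1 - half, s1 + half)
  ref_height <- q1$height
  if (!q1$is_local_max ||
      q1$prominence < max(min_prominence_frac * ref_height, min_prom_abs)) {
    nrl_estimation_error("no acceptable first peak in the ladder window")
  }
  pos1 <- coords[s1]
  ks <- 1L; positions <- pos1; heights <- q1$height
  p_hat <- NA_real_
  spacings <- numeric()
  last_k <- 1L; last_pos <- pos1
  for (k in 2:max_peaks) {
    if (is.na(p_hat)) {
      # period still unknown: widen the search proportionally to the order
      # gap, so a missing di peak does not block the tri peak
      lo <- last_pos + (k - last_k) * period_min
      hi <- last_pos + (k - last_k) * period_max
      if (lo > max(coords)) break
    } else {
      # extrapolate from the last accepted summit: the first-summit position
      # can carry an offset not shared by the rest of the ladder
      centre <- last_pos + (k - last_k) * p_hat
      lo <- floor(centre - p_hat / 3); hi <- ceiling(centre + p_hat / 3)
      if (centre - p_hat / 3 > max(coords)) break
    }
    lo <- max(lo, min(coords)); hi <- min(hi, max(coords))
    if (lo > hi) next
    s <- window_argmax(values, idx(lo), idx(hi))
    q <- summit_quality(values, s, s - half, s + half)
    if (!q$is_local_max ||
        q$prominence < max(min_prominence_frac * ref_height, min_prom_abs)) next
    ks <- c(ks, k); positions <- c(positions, coords[s]); heights <- c(heights, q$height)
    spacings <- c(spacings, (coords[s] - last_pos) / (k - last_k))
    last_k <- k; last_pos <- coords[s]
    # the anchor-to-second spacing absorbs the anchor offset; discount it
    # once later spacings are available
    p_hat <- if (length(spacings) >= 2L) mean(spacings[-1L]) else spacings[1L]
  }
  summits <- data.frame(k = ks, position = positions, height = heights)
  class(summits) <- c("summit_series", "data.frame")
  summits
}

#' Estimate the NRL from the fragment-size distribution
#'
#' Locates the mononucleosome summit as the argmax of the smoothed histogram
#' in `[mono_min, mono_min + period_max]`, then walks the multinucleosome
#' ladder (di-, tri-, ... summits) with the shared summit machinery and fits
#' the NRL as the OLS slope of summit position on peak order.
#'
#' The k-nucleosome band contains one protected footprint plus (k-1) repeat
#' lengths, so the mono band (footprint plus partial linker) carries a
#' different offset than the rest of the ladder. By default the mono summit
#' anchors the ladder and is reported, but is excluded from the regression
#' (`include_mono = FALSE`); the intercept then absorbs the ladder's
#' footprint offset. Set `include_mono = TRUE` to regress through all
#' summits.
#'
#' Sub-mononucleosome lengths (the 50-100 bp linker-fragment peak of
#' ATAC-seq) are excluded via `mono_min`: they reflect inter-nucleosome
#' accessibility, not n-nucleosome protection.
#'
#' @param hist A `size_histogram`.
#' @param mono_min Smallest length considered mononucleosomal (default 120).
#' @param period_min,period_max Allowed peak-to-peak spacing, bp.
#' @param max_peaks Maximum peak order to attempt.
#' @param smooth_window Odd smoothing window, bp.
#' @param min_prominence_frac Prominence threshold as a fraction of the mono
#'   summit height.
#' @param include_mono Include the mono summit in the regression.
#' @return An `nrl_estimate` with `method = "fragment_size"`.
#' @export
nrl_from_size_distribution <- function(hist, mono_min = 120, period_min = 120,
                                       period_max = 250, max_peaks = 10,
                                       smooth_window = 15,
                                       min_prominence_frac = 0.02,
                                       include_mono = FALSE) {
  stopifnot(inherits(hist, "size_histogram"))
  smoothed <- moving_average(hist$count, smooth_window)
  summits <- tryCatch(
    ladder_summits(smoothed, hist$len, mono_min, mono_min + period_max,
                   period_min, period_max, max_peaks, min_prominence_frac,
                   smooth_window = smooth_window),
    nrlfit_estimation_error = function(e) {
      nrl_estimation_error(paste0(
        "insufficient multinucleosome signal: ", conditionMessage(e)))
    })
  fit_set <- if (include_mono) summits else summits[summits$k != 1L, , drop = FALSE]
  if (nrow(fit_set) < 3L) {
    nrl_estimation_error(sprintf(
      "insufficient multinucleosome signal: %d usable summit(s), need 3 (heavily digested or short-read data lack multinucleosome fragments)",
      nrow(fit_set)))
  }
  est <- fit_nrl(fit_set, "fragment_size")
  est$summits <- summits
  est
}
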