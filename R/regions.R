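#' Load labeled regions from a BED4+ file
#'
#' Reads a labeled BED file (label in column 4, e.g. ChromHMM chromatin
#' states, gene bodies, promoter classes) and merges overlapping intervals
#' within each label. Coordinates are 0-based half-open.
#'
#' @param path Path to a BED4+ file (gzip transparent).
#' @return A `region_set`: data.table with columns `chrom`, `start`, `end`,
#'   `label`, merged and sorted within label.
#' @export
load_regions <- function(path) {
  if (!file.exists(path)) nrl_validation_error(sprintf("file not found: %s", path))
  dt <- fread_maybe_gz(path)
  if (nrow(dt) == 0L) nrl_validation_error("no regions in file")
  if (ncol(dt) < 4L) nrl_validation_error("missing label column: BED4+ required")
  region_set(data.frame(chrom = as.character(dt[[1L]]), start = as.numeric(dt[[2L]]),
                        end = as.numeric(dt[[3L]]), label = as.character(dt[[4L]])))
}

#' Build a region set from a data frame
#'
#' @param df Data frame with columns `chrom`, `start`, `end`, `label`.
#' @return A `region_set` with per-label merged intervals.
#' @export
region_set <- function(df) {
  df <- data.table::as.data.table(df)
  if (!all(c("chrom", "start", "end", "label") %in% names(df))) {
    nrl_validation_error("regions need columns chrom, start, end, label")
  }
  if (nrow(df) == 0L) nrl_validation_error("no regions")
  if (any(is.na(df$label) | df$label == "")) nrl_validation_error("empty region label")
  merged <- df[, {
    # min.gapwidth = 0: merge overlapping intervals but keep abutting ones
    # separate -- adjacent intervals are distinct arrays for pair counting
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      chrom, IRanges::IRanges(start = start + 1, end = end)),
      min.gapwidth = 0L)
    list(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1,
         end = as.numeric(GenomicRanges::end(gr)))
  }, by = label]
  merged <- merged[order(label, chrom, start)]
  for (lab in unique(merged$label)) {
    nrl_log(sprintf("label %s: %d merged interval(s)", lab, sum(merged$label == lab)))
  }
  structure(merged[, c("chrom", "start", "end", "label")],
            class = c("region_set", class(merged)))
}

#' Phasogram restricted to one region label
#'
#' Counts only pairs whose both dyads fall within the same merged interval of
#' the label. Cross-interval and cross-boundary pairs are excluded: the NRL
#' is a within-array quantity, and pairs spanning a gap would contribute
#' phantom long lags.
#'
#' @param track A sorted [dyad_track()].
#' @param regions A `region_set`.
#' @param label Label to stratify on.
#' @inheritParams compute_phasogram
#' @return A `lag_histogram`.
#' @export
stratified_phasogram <- function(track, regions, label, min_lag = 50, max_lag = 1200) {
  stopifnot(inherits(track, "dyad_track"))
  sel <- which(regions[["label"]] == label)  # plain which(): avoids data.table
  ivs <- regions[sel]                        # capturing `label` as a column
  if (nrow(ivs) == 0L) nrl_validation_error(sprintf("unknown label: %s", label))
  min_lag <- as.integer(min_lag); max_lag <- as.integer(max_lag)
  counts <- numeric(max_lag - min_lag + 1L)
  for (j in seq_len(nrow(ivs))) {
    pos <- track$positions[[ivs$chrom[j]]]
    if (is.null(pos)) next
    lo <- findInterval(ivs$start[j] - 0.5, pos) + 1L
    hi <- findInterval(ivs$end[j] - 0.5, pos)
    if (hi > lo) counts <- counts + pair_lag_counts(pos[lo:hi], min_lag, max_lag)
  }
  new_lag_histogram(min_lag, max_lag, counts, track$source)
}

# dyads contained in the label's merged intervals (for reporting)
count_contained_dyads <- function(track, ivs) {
  total <- 0L
  for (j in seq_len(nrow(ivs))) {
    pos <- track$positions[[ivs$chrom[j]]]
    if (is.null(pos)) next
    total <- total + sum(pos >= ivs$start[j] & pos < ivs$end[j])
  }
  total
}

#' Per-label NRL estimates
#'
#' Runs the stratified phasogram, smoothing, summit detection and OLS fit for
#' every label of a region set. Labels whose histogram does not support a fit
#' are reported with the failure reason rather than dropped.
#'
#' @param track A sorted [dyad_track()].
#' @param regions A `region_set`.
#' @inheritParams estimate_nrl_phasogram
#' @return A data frame with one row per label: `label`, `nrl`,
#'   `slope_stderr`, `r_squared`, `n_summits`, `n_dyads`, `status` (`"ok"` or
#'   the failure reason).
#' @export
nrl_by_region <- function(track, regions, min_lag = 50, max_lag = 1200,
                          smooth_window = 15, period_min = 120,
                          period_max = 250, max_peaks = 10,
                          min_prominence_frac = 0.02, include_first = TRUE) {
  labels <- unique(regions$label)
  rows <- lapply(labels, function(lab) {
    ivs <- regions[which(regions[["label"]] == lab)]
    n_dyads <- count_contained_dyads(track, ivs)
    res <- tryCatch({
      hist <- stratified_phasogram(track, regions, lab, min_lag, max_lag)
      sm <- smooth_histogram(hist, smooth_window)
      summits <- detect_summits(sm, period_min, period_max, max_peaks,
                                min_prominence_frac, include_first)
      est <- fit_nrl(summits, if (track$source == "start") "start_phasogram" else "dyad_phasogram")
      data.frame(label = lab, nrl = est$nrl, slope_stderr = est$slope_stderr,
                 r_squared = est$r_squared, n_summits = est$n_summits,
                 n_dyads = n_dyads, status = "ok")
    }, nrlfit_error = function(e) {
      data.frame(label = lab, nrl = NA_real_, slope_stderr = NA_real_,
                 r_squared = NA_real_, n_summits = NA_integer_,
                 n_dyads = n_dyads, status = conditionMessage(e))
    })
    res
  })
  do.call(rbind, rows)
}

#' Load anchor points from a BED6 file
#'
#' Anchors (e.g. transcription start sites or TF-binding sites) orient
#' aggregate profiles. The anchor position is the strand-aware biological
#' point: `start` for `+` anchors, `end - 1` for `-` anchors.
#'
#' @param path Path to a BED6 file.
#' @return A data frame with columns `chrom`, `pos`, `strand`.
#' @export
load_anchors <- function(path) {
  if (!file.exists(path)) nrl_validation_error(sprintf("file not found: %s", path))
  dt <- fread_maybe_gz(path)
  if (ncol(dt) < 6L) nrl_validation_error("anchors require BED6 (strand in column 6)")
  strand <- as.character(dt[[6L]])
  if (!all(strand %in% c("+", "-"))) nrl_validation_error("anchor strand must be + or -")
  data.frame(chrom = as.character(dt[[1L]]),
             pos = ifelse(strand == "+", as.numeric(dt[[2L]]), as.numeric(dt[[3L]]) - 1),
             strand = strand)
}

#' Anchored aggregate dyad profile
#'
#' Collects dyad offsets within `[-flank, +flank]` of every anchor; offsets
#' of minus-strand anchors are mirrored (negated), so "downstream" always
#' means the direction the anchor points. Offsets are summed into a 1 bp
#' aggregate dyad-count profile: the average nucleosome landscape around the
#' anchor class. The profile counts dyads, not read pileup, consistent with
#' the dyad-centric estimators.
#'
#' @param track A sorted [dyad_track()].
#' @param anchors Data frame with columns `chrom`, `pos`, `strand`
#'   (see [load_anchors()]).
#' @param flank Half-width of the profile, bp (default 2000, about ten
#'   nucleosomes).
#' @return An `anchor_profile`: list with `offset` (`-flank:flank`), `count`,
#'   `n_anchors`.
#' @export
anchored_profile <- function(track, anchors, flank = 2000) {
  stopifnot(inherits(track, "dyad_track"))
  if (!all(c("chrom", "pos", "strand") %in% names(anchors))) {
    nrl_validation_error("anchors need columns chrom, pos, strand")
  }
  if (!all(anchors$strand %in% c("+", "-"))) {
    nrl_validation_error("anchor strand must be + or -")
  }
  if (nrow(anchors) < 100) {
    nrl_log(sprintf("only %d anchors; aggregate profiles are noisy below ~100", nrow(anchors)))
  }
  flank <- as.integer(flank)
  counts <- numeric(2L * flank + 1L)
  for (i in seq_len(nrow(anchors))) {
    pos <- track$positions[[anchors$chrom[i]]]
    if (is.null(pos)) next
    a <- anchors$pos[i]
    lo <- findInterval(a - flank - 0.5, pos) + 1L
    hi <- findInterval(a + flank + 0.5, pos)
    if (hi < lo) next
    off <- pos[lo:hi] - a
    if (anchors$strand[i] == "-") off <- -off
    counts <- counts + tabulate(as.integer(off) + flank + 1L, nbins = 2L * flank + 1L)
  }
  structure(list(offset = (-flank):flank, count = counts,
                 n_anchors = nrow(anchors)),
            class = "anchor_profile")
}

#' @export
print.anchor_profile <- function(x, ...) {
  cat(sprintf("<anchor_profile> flank %d bp, %d anchors, %.0f dyads\n",
              max(x$offset), x$n_anchors, sum(x$count)))
  invisible(x)
}

#' Estimate the NRL from an anchored profile
#'
#' Detects peak summits on the downstream half of the aggregate profile with
#' the shared ladder machinery (first summit near half a footprint from the
#' anchor, subsequent summits one repeat length apart) and fits the NRL as
#' the OLS slope of summit position on peak order. Peak-based NRL estimation
#' is only reliable near strong phasing anchors; unphased anchors yield no
#' acceptable summits and raise an estimation error.
#'
#' @param profile An `anchor_profile`.
#' @param period_min,period_max Allowed peak spacing, bp.
#' @param max_peaks Maximum peak order to attempt.
#' @param smooth_window Odd smoothing window, bp.
#' @param min_prominence_frac Prominence threshold as a fraction of the
#'   first summit height.
#' @return An `nrl_estimate` with `method = "anchored_profile"`.
#' @export
nrl_from_profile <- function(profile, period_min = 120, period_max = 250,
                             max_peaks = 10, smooth_window = 15,
                             min_prominence_frac = 0.02) {
  stopifnot(inherits(profile, "anchor_profile"))
  down <- profile$offset >= 0
  values <- moving_average(profile$count[down], smooth_window)
  summits <- ladder_summits(values, profile$offset[down], 0, period_max,
                            period_min, period_max, max_peaks,
                            min_prominence_frac, smooth_window = smooth_window)
  if (nrow(summits) < 3L) {
    nrl_estimation_error(sprintf(
      "insufficient downstream summits (%d); anchors may not phase nucleosome arrays",
      nrow(summits)))
  }
  fit_nrl(summits, "anchored_profile")
}
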