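# Internal helpers shared across estimators.

#' @importFrom data.table data.table fread fwrite setDT := .N .SD
#' @importFrom stats lm coef rnorm rpois rgeom runif var ave setNames mad sd median
NULL

# Condition constructors: validation errors for bad inputs, estimation errors
# for data that cannot support an NRL fit. Both inherit from "nrlfit_error"
# so callers (and the CLI) can distinguish them from programming errors.
nrl_validation_error <- function(msg) {
  stop(errorCondition(msg, class = c("nrlfit_validation_error", "nrlfit_error")))
}

nrl_estimation_error <- function(msg) {
  stop(errorCondition(msg, class = c("nrlfit_estimation_error", "nrlfit_error")))
}

nrl_log <- function(...) {
  message("[nrlfit] ", ...)
}

# Centred moving average with truncated windows at the edges; window must be
# odd so the kernel is symmetric. Shared by histogram smoothing, the
# fragment-size ladder and the anchored profile.
moving_average <- function(x, window) {
  if (length(window) != 1L || is.na(window) || window < 1 || window %% 2 == 0) {
    nrl_validation_error("smoothing window must be a single odd integer >= 1")
  }
  window <- as.integer(window)
  if (window == 1L) return(as.numeric(x))
  n <- length(x)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, as.numeric(x)))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# argmax over values[sel]; ties broken toward the smaller index (which.max).
window_argmax <- function(values, lo, hi) {
  lo <- max(lo, 1L)
  hi <- min(hi, length(values))
  if (lo > hi) return(NA_integer_)
  lo + which.max(values[lo:hi]) - 1L
}

# Summit acceptance used by every peak-based estimator: the candidate must be
# a local maximum of the smoothed signal, and its prominence (height above
# the higher of the two flanking minima within [lo, hi], normally a window
# centred on the summit and about half a period wide) must exceed the
# caller's threshold. Degenerate flat windows yield zero prominence and are
# rejected.
summit_quality <- function(values, s, lo, hi) {
  n <- length(values)
  lo <- max(lo, 1L)
  hi <- min(hi, n)
  height <- values[s]
  is_local <- s > 1L && s < n && values[s] >= values[s - 1L] && values[s] >= values[s + 1L] &&
    (values[s] > values[s - 1L] || values[s] > values[s + 1L])
  left_min <- if (s > lo) min(values[lo:(s - 1L)]) else height
  right_min <- if (s < hi) min(values[(s + 1L):hi]) else height
  prominence <- height - max(left_min, right_min)
  list(height = height, prominence = prominence, is_local_max = is_local)
}

# Per-chromosome reproducible seeding: streams are derived from the base seed
# and a small integer offset so generation order across chromosomes does not
# matter. Offsets stay small to keep derived seeds well below 2^31.
with_stream <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed((as.integer(seed) + as.integer(offset)) %% 2000000011L)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

# '#'-prefixed header lines carrying the effective configuration; every TSV
# report written by the toolkit is self-describing and byte-reproducible
# (no timestamps).
# fread with transparent gzip support via a base connection (fread's own gz
# path needs an optional package; readLines handles gz natively).
fread_maybe_gz <- function(path, ...) {
  if (file.size(path) == 0L) return(data.table::data.table())
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, open = "rt")
    on.exit(close(con))
    lines <- readLines(con)
    if (length(lines) == 0L) return(data.table::data.table())
    data.table::fread(text = lines, header = FALSE, sep = "\t", fill = TRUE,
                      showProgress = FALSE, ...)
  } else {
    data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                      showProgress = FALSE, ...)
  }
}

report_header <- function(params, inputs = character()) {
  lines <- c(
    sprintf("# nrlfit %s", as.character(utils::packageVersion("nrlfit"))),
    vapply(names(params), function(k) {
      sprintf("# %s = %s", k, paste(format(params[[k]], trim = TRUE), collapse = ","))
    }, character(1))
  )
  if (length(inputs)) {
    sums <- tools::md5sum(inputs)
    lines <- c(lines, sprintf("# input %s md5 = %s", names(sums), unname(sums)))
  }
  unname(lines)
}

write_report <- function(df, path, params = list(), inputs = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(report_header(params, inputs), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    body <- do.call(paste, c(lapply(df, function(col) {
      if (is.double(col)) formatC(col, format = "g", digits = 10) else as.character(col)
    }), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}
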