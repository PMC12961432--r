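# Independent oracles, deliberately naive implementations kept separate from
# the package's own code paths.

# Quadratic all-pairs lag counting (only usable on small tracks).
allpairs_lag_counts <- function(positions_by_chrom, min_lag, max_lag) {
  counts <- numeric(max_lag - min_lag + 1L)
  for (pos in positions_by_chrom) {
    n <- length(pos)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        lag <- abs(pos[j] - pos[i])
        if (lag >= min_lag && lag <= max_lag) {
          counts[lag - min_lag + 1L] <- counts[lag - min_lag + 1L] + 1
        }
      }
    }
  }
  counts
}

# Closed-form OLS slope and intercept.
ols_fit <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Direct truncated-window moving average (loop form).
box_smooth <- function(x, window) {
  h <- (window - 1) %/% 2
  vapply(seq_along(x), function(i) {
    mean(x[max(1, i - h):min(length(x), i + h)])
  }, numeric(1))
}

# Synthetic phasogram comb: Gaussian bumps on a flat background.
gaussian_comb <- function(min_lag, max_lag, centres, sd = 15, height = 100,
                          background = 5) {
  lags <- min_lag:max_lag
  counts <- rep(background, length(lags))
  for (c0 in centres) counts <- counts + height * exp(-(lags - c0)^2 / (2 * sd^2))
  nrlfit:::new_lag_histogram(min_lag, max_lag, counts, "dyad")
}
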