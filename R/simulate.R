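#' Simulation configuration for synthetic nucleosome arrays
#'
#' Defines the generative model used to validate every NRL estimator by
#' parameter recovery. Arrays of nucleosomes restart at random boundaries
#' (Poisson process with rate `boundary_rate`, plus each chromosome start);
#' within an array, nucleosome i sits at
#' `boundary + floor(footprint/2) + (i-1) * true_nrl + N(0, jitter_sd)`.
#' Jitter is applied independently per nucleosome (no cumulative drift).
#' Dyads closer than one footprint after jitter (steric clash) are resolved
#' by discarding the later one.
#'
#' Fragment digestion: with probability `1 - multi_frac` a mononucleosome
#' fragment is emitted, centred on a uniformly chosen dyad with length
#' `N(frag_len_mean, frag_len_sd)` clipped to at least `0.8 * footprint`;
#' otherwise a multinucleosome fragment spans k >= 2 consecutive dyads of one
#' array (k = 2 + geometric(multi_decay)), from `floor(footprint/2)` before
#' the first dyad to `ceiling(footprint/2)` after the last.
#'
#' @param genome Named numeric vector of chromosome lengths in bp, or a data
#'   frame with columns `chrom` and `length`.
#' @param true_nrl True nucleosome repeat length in bp (> `footprint`).
#' @param footprint Protected nucleosome footprint in bp (default 147).
#' @param jitter_sd Gaussian positional noise per nucleosome, bp (default 20,
#'   typical fuzziness of bulk mammalian nucleosome maps).
#' @param boundary_rate Expected array boundaries per bp (default 1/50000).
#' @param frag_len_mean,frag_len_sd Mononucleosome fragment length model, bp.
#' @param multi_frac Fraction of fragments spanning k >= 2 nucleosomes.
#' @param multi_decay Geometric parameter for k (larger = shorter spans).
#' @param n_fragments Number of fragments to emit (per label in
#'   [simulate_state_mixture()]).
#' @param seed Mandatory integer seed; identical configurations give
#'   byte-identical output.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(genome, true_nrl, footprint = 147, jitter_sd = 20,
                       boundary_rate = 1 / 50000, frag_len_mean = 167,
                       frag_len_sd = 15, multi_frac = 0.3, multi_decay = 0.5,
                       n_fragments = 100000, seed) {
  if (is.data.frame(genome)) {
    g <- stats::setNames(as.numeric(genome$length), as.character(genome$chrom))
  } else {
    g <- genome
  }
  if (is.null(names(g)) || anyDuplicated(names(g)) || any(g <= 0)) {
    nrl_validation_error("genome must be uniquely named chromosome lengths > 0")
  }
  if (missing(seed) || is.na(seed)) nrl_validation_error("seed is mandatory")
  if (true_nrl <= footprint) {
    nrl_validation_error(sprintf("true_nrl (%g) must exceed the footprint (%g)",
                                 true_nrl, footprint))
  }
  if (jitter_sd < 0) nrl_validation_error("jitter_sd must be >= 0")
  if (multi_frac < 0 || multi_frac >= 1) nrl_validation_error("need 0 <= multi_frac < 1")
  if (multi_decay <= 0 || multi_decay > 1) nrl_validation_error("need 0 < multi_decay <= 1")
  structure(list(genome = g, true_nrl = true_nrl, footprint = as.integer(footprint),
                 jitter_sd = jitter_sd, boundary_rate = boundary_rate,
                 frag_len_mean = frag_len_mean, frag_len_sd = frag_len_sd,
                 multi_frac = multi_frac, multi_decay = multi_decay,
                 n_fragments = as.integer(n_fragments), seed = as.integer(seed)),
            class = "sim_config")
}

# One chromosome (or labeled interval): boundaries, phased ladders, jitter,
# steric-clash resolution. Positions are relative to offset 0 .. length.
simulate_array_chrom <- function(len, nrl, footprint, jitter_sd, boundary_rate) {
  n_b <- stats::rpois(1L, boundary_rate * len)
  bounds <- sort(unique(c(0, floor(runif(n_b) * len))))
  seg_start <- bounds
  seg_end <- c(bounds[-1L], len)
  seg_len <- seg_end - seg_start
  half_lo <- footprint %/% 2L
  half_hi <- footprint - half_lo
  m <- ifelse(seg_len >= footprint, floor((seg_len - footprint) / nrl) + 1, 0)
  m <- as.integer(m)
  if (sum(m) == 0L) {
    return(list(pos = numeric(), array = integer(), boundaries = bounds))
  }
  arr <- rep.int(seq_along(m), m)
  idx <- sequence(m) - 1L
  pos_true <- rep.int(seg_start + half_lo, m) + idx * nrl
  pos <- round(pos_true + stats::rnorm(length(pos_true), 0, jitter_sd))
  ord <- order(pos)
  pos <- pos[ord]; arr <- arr[ord]; pos_true <- pos_true[ord]
  keep <- pos >= 0 & pos < len
  pos <- pos[keep]; arr <- arr[keep]; pos_true <- pos_true[keep]
  # steric clash: iteratively drop the later dyad of any pair closer than one
  # footprint (within or across arrays); terminates because each pass strictly
  # shrinks the track
  repeat {
    if (length(pos) < 2L) break
    tight <- which(diff(pos) < footprint)
    if (!length(tight)) break
    drop <- unique(tight + 1L)
    pos <- pos[-drop]; arr <- arr[-drop]; pos_true <- pos_true[-drop]
  }
  list(pos = pos, pos_true = pos_true, array = arr, boundaries = bounds)
}

#' Simulate ground-truth nucleosome dyad positions
#'
#' Draws array boundaries and phased nucleosome ladders per chromosome (each
#' chromosome uses its own random stream derived from `seed` + chromosome
#' index, so results do not depend on generation order).
#'
#' @param config A [sim_config()].
#' @return A `sim_dyads` object: `$track` (a [dyad_track()] of realised
#'   dyads), `$truth` (data.table `chrom`, `pos`, `pos_true`, `array`),
#'   `$boundaries` (data.table `chrom`, `pos`), and `$config`.
#' @export
simulate_dyad_positions <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  chroms <- names(config$genome)
  parts <- lapply(seq_along(chroms), function(i) {
    with_stream(config$seed, i, {
      sim <- simulate_array_chrom(config$genome[[i]], config$true_nrl,
                                  config$footprint, config$jitter_sd,
                                  config$boundary_rate)
      list(
        truth = data.table::data.table(chrom = chroms[i], pos = sim$pos,
                                       pos_true = sim$pos_true, array = sim$array),
        bounds = data.table::data.table(chrom = chroms[i], pos = sim$boundaries)
      )
    })
  })
  truth <- data.table::rbindlist(lapply(parts, `[[`, "truth"))
  bounds <- data.table::rbindlist(lapply(parts, `[[`, "bounds"))
  structure(list(
    track = dyad_track(data.frame(chrom = truth$chrom, pos = truth$pos), "dyad"),
    truth = truth, boundaries = bounds, config = config
  ), class = "sim_dyads")
}

#' @export
print.sim_dyads <- function(x, ...) {
  cat(sprintf("<sim_dyads> true_nrl=%g, %d dyads, %d boundaries\n",
              x$config$true_nrl, nrow(x$truth), nrow(x$boundaries)))
  invisible(x)
}

#' Simulate sequencing-like fragments from a dyad landscape
#'
#' Emulates partial chromatin digestion: a mix of mononucleosome fragments
#' and multinucleosome fragments spanning consecutive dyads of one array (see
#' [sim_config()] for the model). Exactly `config$n_fragments` fragments are
#' emitted, allocated across chromosomes proportionally to their dyad counts;
#' each chromosome draws from its own seed-derived stream.
#'
#' @param dyads A `sim_dyads` object from [simulate_dyad_positions()], or a
#'   bare [dyad_track()] (then each chromosome is treated as one array).
#' @param config The same [sim_config()].
#' @return A fragment `data.table` (`chrom`, `start`, `end`, `length`).
#' @export
simulate_fragments <- function(dyads, config) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(dyads, "sim_dyads")) {
    truth <- dyads$truth
  } else if (inherits(dyads, "dyad_track")) {
    truth <- data.table::rbindlist(lapply(names(dyads$positions), function(ch) {
      data.table::data.table(chrom = ch, pos = dyads$positions[[ch]], array = 1L)
    }))
  } else {
    nrl_validation_error("dyads must be a sim_dyads or dyad_track object")
  }
  if (nrow(truth) == 0L) nrl_validation_error("no dyads to sample fragments from")
  chroms <- sort(unique(truth$chrom))
  n_dyads <- vapply(chroms, function(ch) sum(truth$chrom == ch), numeric(1))
  alloc <- floor(config$n_fragments * n_dyads / sum(n_dyads))
  rem <- config$n_fragments - sum(alloc)
  if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1L
  half_lo <- config$footprint %/% 2L
  half_hi <- config$footprint - half_lo
  n_trunc <- 0L
  parts <- lapply(seq_along(chroms), function(i) {
    ch <- chroms[i]
    n <- alloc[i]
    if (n == 0L) return(NULL)
    pos <- truth$pos[truth$chrom == ch]
    arr <- truth$array[truth$chrom == ch]
    chrom_len <- unname(config$genome[ch])
    if (is.na(chrom_len)) chrom_len <- max(pos) + config$true_nrl
    with_stream(config$seed, 1000L + i, {
      is_multi <- runif(n) < config$multi_frac
      n_mono <- sum(!is_multi)
      start <- numeric(n); end <- numeric(n)
      if (n_mono > 0L) {
        di <- sample.int(length(pos), n_mono, replace = TRUE)
        len <- pmax(round(rnorm(n_mono, config$frag_len_mean, config$frag_len_sd)),
                    ceiling(0.8 * config$footprint))
        start[!is_multi] <- pos[di] - len %/% 2
        end[!is_multi] <- start[!is_multi] + len
      }
      n_multi <- sum(is_multi)
      if (n_multi > 0L) {
        first <- sample.int(length(pos), n_multi, replace = TRUE)
        k <- 2L + stats::rgeom(n_multi, config$multi_decay)
        # last dyad index of each array, aligned to `first`
        arr_last <- ave(seq_along(pos), arr, FUN = max)
        last <- pmin(first + k - 1L, arr_last[first])
        n_trunc <<- n_trunc + sum(first + k - 1L > arr_last[first])
        start[is_multi] <- pos[first] - half_lo
        end[is_multi] <- pos[last] + half_hi
      }
      start <- pmax(start, 0)
      end <- pmin(end, chrom_len)
      keep_len <- pmax(end - start, 1)
      data.table::data.table(chrom = ch, start = start, end = start + keep_len)
    })
  })
  if (n_trunc > 0L) {
    nrl_log(sprintf("%d multinucleosome span(s) truncated at array ends", n_trunc))
  }
  frags <- data.table::rbindlist(parts)
  frags$length <- frags$end - frags$start
  frags[]
}

#' Simulate a chromatin-state mixture with per-label NRLs
#'
#' Each labeled interval is simulated as an independent set of nucleosome
#' arrays with its own true NRL (the interval start acts as an array
#' boundary), emulating region-stratified chromatin such as ChromHMM states.
#' `base_config$n_fragments` fragments are emitted per label, split across a
#' label's intervals proportionally to interval length.
#'
#' @param states Data frame with columns `chrom`, `start`, `end`, `label`,
#'   `true_nrl`; intervals must not overlap across or within labels.
#' @param base_config A [sim_config()] supplying all other parameters (its
#'   `true_nrl` is ignored in favour of the per-label values).
#' @return A list: `$fragments`, `$regions` (labeled BED-like table),
#'   `$truth` (per-label table with `label`, `true_nrl`, `n_dyads`),
#'   `$dyads` (combined [dyad_track()] of ground-truth dyads).
#' @export
simulate_state_mixture <- function(states, base_config) {
  stopifnot(inherits(base_config, "sim_config"))
  states <- data.table::as.data.table(states)
  needed <- c("chrom", "start", "end", "label", "true_nrl")
  if (!all(needed %in% names(states))) {
    nrl_validation_error("states need columns chrom, start, end, label, true_nrl")
  }
  if (any(states$true_nrl <= base_config$footprint)) {
    nrl_validation_error("every label's true_nrl must exceed the footprint")
  }
  ov <- states[order(chrom, start)]
  bad <- ov[, any(start[-1L] < end[-.N]), by = chrom]$V1
  if (any(bad)) nrl_validation_error("state intervals overlap")

  frag_parts <- list(); dyad_parts <- list(); truth_rows <- list()
  labels <- unique(states$label)
  for (li in seq_along(labels)) {
    lab <- labels[li]
    ivs <- states[states$label == lab]
    lens <- ivs$end - ivs$start
    n_per <- floor(base_config$n_fragments * lens / sum(lens))
    rem <- base_config$n_fragments - sum(n_per)
    if (rem > 0) n_per[seq_len(rem)] <- n_per[seq_len(rem)] + 1L
    lab_dyads <- 0L
    for (j in seq_len(nrow(ivs))) {
      cfg <- base_config
      cfg$true_nrl <- ivs$true_nrl[j]
      cfg$genome <- stats::setNames(lens[j], ivs$chrom[j])
      cfg$n_fragments <- as.integer(n_per[j])
      cfg$seed <- as.integer((base_config$seed + 7919L * li + j) %% 2000000011L)
      sim <- simulate_dyad_positions(cfg)
      frags <- simulate_fragments(sim, cfg)
      frags$start <- frags$start + ivs$start[j]
      frags$end <- frags$end + ivs$start[j]
      frag_parts[[length(frag_parts) + 1L]] <- frags
      dyad_parts[[length(dyad_parts) + 1L]] <- data.table::data.table(
        chrom = ivs$chrom[j], pos = sim$truth$pos + ivs$start[j])
      lab_dyads <- lab_dyads + nrow(sim$truth)
    }
    truth_rows[[li]] <- data.table::data.table(label = lab,
                                               true_nrl = ivs$true_nrl[1L],
                                               n_dyads = lab_dyads)
  }
  frags <- data.table::rbindlist(frag_parts)
  dyads_dt <- data.table::rbindlist(dyad_parts)
  list(
    fragments = frags[],
    regions = states[, c("chrom", "start", "end", "label")],
    truth = data.table::rbindlist(truth_rows),
    dyads = dyad_track(data.frame(chrom = dyads_dt$chrom, pos = dyads_dt$pos), "dyad")
  )
}
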