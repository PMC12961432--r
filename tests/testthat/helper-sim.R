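# Shared fixture builders: everything is generated in code at test time.

write_bed3 <- function(df, path = tempfile(fileext = ".bed")) {
  writeLines(sprintf("%s\t%d\t%d", df$chrom, df$start, df$end), path)
  path
}

write_bedpe <- function(mates, path = tempfile(fileext = ".bedpe")) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%d\tfrag\t0\t+\t-",
                     mates$chrom1, mates$start1, mates$end1,
                     mates$chrom2, mates$start2, mates$end2), path)
  path
}

# Default desk-scale simulation used by several tests: mononucleosome
# fragments over 5 Mb, enough coverage for sub-bp phasogram summits.
desk_sim <- function(true_nrl = 185, jitter_sd = 20, multi_frac = 0,
                     n_fragments = 2e5, genome_mb = 5, seed = 101) {
  cfg <- sim_config(genome = c(chr1 = genome_mb * 1e6), true_nrl = true_nrl,
                    jitter_sd = jitter_sd, multi_frac = multi_frac,
                    n_fragments = n_fragments, seed = seed)
  sim <- simulate_dyad_positions(cfg)
  frags <- suppressMessages(simulate_fragments(sim, cfg))
  list(config = cfg, sim = sim, fragments = frags)
}

mono_dyads <- function(fixture) {
  compute_dyads(suppressMessages(filter_by_length(fixture$fragments, 100, 200)))
}

random_track <- function(n, span = 20000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dyad_track(sort(sample.int(span, n, replace = TRUE)))
}
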