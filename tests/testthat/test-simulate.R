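test_that("zero-jitter arrays form the deterministic phased lattice", {
  cfg <- sim_config(genome = c(chr1 = 1000), true_nrl = 190, jitter_sd = 0,
                    boundary_rate = 0, n_fragments = 10, seed = 1)
  sim <- simulate_dyad_positions(cfg)
  # boundary at 0, footprint 147: dyads at floor(147/2) + (i-1)*190
  expect_equal(sim$truth$pos, c(73, 263, 453, 643, 833))
  expect_equal(unique(sim$truth$array), 1L)
})

test_that("mean within-array neighbour spacing matches the configured NRL", {
  cfg <- sim_config(genome = c(chr1 = 4e6), true_nrl = 185, jitter_sd = 10,
                    n_fragments = 10, seed = 11)
  sim <- simulate_dyad_positions(cfg)
  expect_gt(nrow(sim$truth), 1e4)
  sp <- sim$truth[, diff(pos), by = c("chrom", "array")]$V1
  sem <- sd(sp) / sqrt(length(sp))
  # +1 bp allowance: steric-clash resolution discards the closest spacings,
  # which biases the realised mean up by ~NRL * clash rate (<1% at this
  # jitter level)
  expect_lt(abs(mean(sp) - 185), 3 * sem + 1)
})

test_that("identical configs give identical dyads and byte-identical BED", {
  cfg <- sim_config(genome = c(chr1 = 5e5, chr2 = 3e5), true_nrl = 190,
                    n_fragments = 5000, seed = 77)
  a <- simulate_dyad_positions(cfg)
  b <- simulate_dyad_positions(cfg)
  expect_identical(a$truth, b$truth)
  fa <- suppressMessages(simulate_fragments(a, cfg))
  fb <- suppressMessages(simulate_fragments(b, cfg))
  pa <- tempfile(fileext = ".bed"); pb <- tempfile(fileext = ".bed")
  write_fragments(fa, pa); write_fragments(fb, pb)
  expect_identical(readBin(pa, "raw", file.size(pa)),
                   readBin(pb, "raw", file.size(pb)))
})

test_that("steric clashes are resolved and spacing grows with true_nrl", {
  cfg <- sim_config(genome = c(chr1 = 2e6), true_nrl = 160, jitter_sd = 30,
                    n_fragments = 10, seed = 3)
  sim <- simulate_dyad_positions(cfg)
  expect_true(all(sim$truth[, diff(pos), by = c("chrom")]$V1 >= 0))
  expect_true(all(sim$truth[, diff(pos), by = c("chrom", "array")]$V1 >= 147))

  means <- vapply(c(167, 185, 200, 212), function(nrl) {
    cfg <- sim_config(genome = c(chr1 = 2e6), true_nrl = nrl, jitter_sd = 10,
                      n_fragments = 10, seed = 5)
    s <- simulate_dyad_positions(cfg)
    mean(s$truth[, diff(pos), by = c("chrom", "array")]$V1)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("fragment digestion model emits the configured mixture", {
  fx <- desk_sim(true_nrl = 190, multi_frac = 0, n_fragments = 2e4,
                 genome_mb = 2, seed = 21)
  expect_equal(nrow(fx$fragments), 2e4)  # conservation
  # all mononucleosomal: unimodal length histogram near frag_len_mean
  expect_lt(max(fx$fragments$length), 260)
  expect_equal(as.numeric(median(fx$fragments$length)), 167, tolerance = 0.02)

  # zero jitter: a k-nucleosome fragment spans floor(fp/2) before the first
  # dyad to ceiling(fp/2) after the last -> length k*190 - 43
  cfg <- sim_config(genome = c(chr1 = 1e5), true_nrl = 190, jitter_sd = 0,
                    boundary_rate = 0, multi_frac = 0.9, multi_decay = 0.999,
                    n_fragments = 500, seed = 8)
  sim <- simulate_dyad_positions(cfg)
  frags <- suppressMessages(simulate_fragments(sim, cfg))
  multi <- frags$length[frags$length > 260]
  expect_true(all(multi %% 190 == (2 * 190 - 43) %% 190))
  expect_true(any(multi == 337))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(genome = c(chr1 = 1e5), true_nrl = 140, seed = 1),
               "exceed the footprint")
  expect_error(sim_config(genome = c(chr1 = 1e5), true_nrl = 190),
               "seed")
  expect_error(sim_config(genome = c(chr1 = -5), true_nrl = 190, seed = 1),
               "genome")
  expect_error(sim_config(genome = c(chr1 = 1e5), true_nrl = 190, seed = 1,
                          multi_frac = 1), "multi_frac")
})

test_that("state mixtures carry per-label lattices and reject overlaps", {
  states <- data.frame(chrom = "chr1", start = c(0, 50000),
                       end = c(50000, 100000), label = c("A", "B"),
                       true_nrl = c(180, 195))
  base <- sim_config(genome = c(chr1 = 1e5), true_nrl = 190, jitter_sd = 0,
                     boundary_rate = 0, multi_frac = 0, n_fragments = 500,
                     seed = 13)
  mix <- suppressMessages(simulate_state_mixture(states, base))
  expect_equal(nrow(mix$fragments), 1000)  # n_fragments per label
  # zero jitter: per-label neighbour spacing is exactly the label's NRL
  posA <- mix$dyads$positions$chr1[mix$dyads$positions$chr1 < 50000]
  posB <- mix$dyads$positions$chr1[mix$dyads$positions$chr1 >= 50000]
  expect_true(all(diff(posA) == 180))
  expect_true(all(diff(posB) == 195))
  expect_equal(mix$truth$true_nrl, c(180, 195))

  bad <- states; bad$start[2] <- 40000
  expect_error(suppressMessages(simulate_state_mixture(bad, base)), "overlap")
})

test_that("a single whole-genome label degenerates to the plain simulator", {
  states <- data.frame(chrom = "chrZ", start = 0, end = 2e5, label = "all",
                       true_nrl = 188)
  base <- sim_config(genome = c(chrZ = 2e5), true_nrl = 188, jitter_sd = 10,
                     n_fragments = 2000, seed = 31)
  mix <- suppressMessages(simulate_state_mixture(states, base))
  expect_equal(nrow(mix$fragments), 2000)
  expect_equal(mix$truth$n_dyads, length(mix$dyads$positions$chrZ))
})
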