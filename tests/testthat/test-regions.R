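test_that("labeled BED regions are merged per label", {
  p <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tActive", "chr1\t150\t300\tActive",
               "chr1\t400\t500\tHeterochromatin"), p)
  rs <- suppressMessages(load_regions(p))
  act <- rs[which(rs$label == "Active")]
  expect_equal(nrow(act), 1)
  expect_equal(act$start, 100)
  expect_equal(act$end, 300)
  expect_equal(sort(unique(rs$label)), c("Active", "Heterochromatin"))

  empty <- tempfile(fileext = ".bed"); file.create(empty)
  expect_error(load_regions(empty), "no regions")
  p3 <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200", p3)
  expect_error(load_regions(p3), "label")
})

test_that("stratified phasograms count only same-interval pairs", {
  track <- dyad_track(c(100, 290, 480, 5000, 5190))
  rs <- suppressMessages(region_set(data.frame(chrom = "chr1", start = 0,
                                               end = 1000, label = "X")))
  h <- stratified_phasogram(track, rs, "X", 1, 1000)
  expect_equal(h$count[h$lag == 190], 2)
  expect_equal(h$count[h$lag == 380], 1)
  expect_equal(sum(h$count), 3)  # the 5000s are outside the interval

  # dyads in adjacent intervals of the same label never pair
  rs2 <- suppressMessages(region_set(data.frame(
    chrom = "chr1", start = c(0, 500), end = c(500, 1000), label = "Y")))
  h2 <- stratified_phasogram(dyad_track(c(480, 520)), rs2, "Y", 1, 1000)
  expect_equal(sum(h2$count), 0)

  expect_error(stratified_phasogram(track, rs, "nope", 1, 1000), "unknown label")
})

test_that("per-label pair counts are a subset of the unstratified phasogram", {
  tr <- random_track(400, span = 30000, seed = 14)
  parts <- data.frame(chrom = "chr1", start = c(0, 10000, 20000),
                      end = c(10000, 20000, 30001),
                      label = c("a", "b", "c"))
  rs <- suppressMessages(region_set(parts))
  whole <- compute_phasogram(tr, 50, 1200)
  strat <- Reduce(`+`, lapply(c("a", "b", "c"), function(l) {
    stratified_phasogram(tr, rs, l, 50, 1200)$count
  }))
  expect_true(all(strat <= whole$count))  # boundary-crossing pairs are lost
  expect_true(sum(strat) <= sum(whole$count))
})

test_that("two-state mixtures resolve per-label NRLs in the right order", {
  states <- data.frame(chrom = c("chrA", "chrB"), start = 0, end = 1.5e6,
                       label = c("Active", "Polycomb"), true_nrl = c(180, 195))
  base <- sim_config(genome = c(chrA = 1.5e6, chrB = 1.5e6), true_nrl = 190,
                     jitter_sd = 20, multi_frac = 0, n_fragments = 8e4,
                     seed = 41)
  mix <- suppressMessages(simulate_state_mixture(states, base))
  track <- mono_dyads(mix)
  rep <- suppressMessages(nrl_by_region(track, region_set(mix$regions)))
  expect_equal(rep$status, c("ok", "ok"))
  expect_lt(abs(rep$nrl[rep$label == "Active"] - 180), 1.5)
  expect_lt(abs(rep$nrl[rep$label == "Polycomb"] - 195), 1.5)
  # active-like state strictly shorter, non-overlapping 2*stderr intervals
  a <- rep[rep$label == "Active", ]; b <- rep[rep$label == "Polycomb", ]
  expect_lt(a$nrl + 2 * a$slope_stderr, b$nrl - 2 * b$slope_stderr)
})

test_that("labels that cannot support a fit are reported, not dropped", {
  track <- dyad_track(c(100, 290, 480, 670))
  rs <- suppressMessages(region_set(data.frame(
    chrom = c("chr1", "chr9"), start = c(0, 0), end = c(1000, 1000),
    label = c("ok-ish", "empty"))))
  rep <- suppressMessages(nrl_by_region(track, rs))
  expect_equal(nrow(rep), 2)
  row_empty <- rep[rep$label == "empty", ]
  expect_true(is.na(row_empty$nrl))
  expect_match(row_empty$status, "insufficient periodicity")
  expect_equal(row_empty$n_dyads, 0)
})

test_that("a single whole-genome label equals the unstratified estimate", {
  fx <- desk_sim(true_nrl = 188, n_fragments = 1e5, genome_mb = 3, seed = 47)
  track <- mono_dyads(fx)
  rs <- suppressMessages(region_set(data.frame(chrom = "chr1", start = 0,
                                               end = 3e6, label = "all")))
  rep <- suppressMessages(nrl_by_region(track, rs))
  whole <- estimate_nrl_phasogram(track)
  expect_equal(rep$nrl, whole$nrl, tolerance = 1e-10)
})

test_that("anchored profiles recover phased-lattice spacing exactly", {
  cfg <- sim_config(genome = c(a = 5000, b = 5000, c = 5000, d = 5000),
                    true_nrl = 190, jitter_sd = 0, boundary_rate = 0,
                    multi_frac = 0, n_fragments = 400, seed = 51)
  sim <- simulate_dyad_positions(cfg)
  anchors <- data.frame(chrom = c("a", "b", "c", "d"), pos = 0, strand = "+")
  prof <- suppressMessages(anchored_profile(sim$track, anchors, 2000))
  est <- nrl_from_profile(prof, smooth_window = 1)
  expect_equal(est$nrl, 190, tolerance = 1e-8)
  expect_equal(est$summits$position[1:3], c(73, 263, 453))
  expect_equal(est$method, "anchored_profile")
})

test_that("minus-strand anchors mirror offsets and strand flips reverse", {
  track <- dyad_track(list(chr1 = c(927, 1500)))
  minus <- data.frame(chrom = "chr1", pos = 1000, strand = "-")
  prof <- suppressMessages(anchored_profile(track, minus, 600))
  # dyad at p - 73 contributes offset +73 for a minus-strand anchor
  expect_equal(prof$count[prof$offset == 73], 1)
  expect_equal(prof$count[prof$offset == -500], 1)

  tr2 <- random_track(200, span = 8000, seed = 52)
  anc <- data.frame(chrom = "chr1", pos = c(2000, 5000), strand = c("+", "-"))
  flipped <- anc; flipped$strand <- c("-", "+")
  p1 <- suppressMessages(anchored_profile(tr2, anc, 700))
  p2 <- suppressMessages(anchored_profile(tr2, flipped, 700))
  expect_equal(p1$count, rev(p2$count))
})

test_that("unphased anchors yield no acceptable profile summits", {
  fx <- desk_sim(true_nrl = 190, n_fragments = 3e4, genome_mb = 2, seed = 53)
  set.seed(60)
  anchors <- data.frame(chrom = "chr1",
                        pos = sort(sample.int(2e6 - 4000, 300)) + 2000,
                        strand = "+")
  prof <- anchored_profile(mono_dyads(fx), anchors, 2000)
  expect_error(nrl_from_profile(prof), class = "nrlfit_estimation_error")
})
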