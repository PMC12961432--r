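---
title: "Estimating nucleosome repeat lengths with nrlfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating nucleosome repeat lengths with nrlfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrlfit)
```

## The quantity and the model

Nucleosomes protect ~147 bp of DNA and are separated by linkers of roughly
10–100 bp. The nucleosome repeat length (NRL) is the genomic distance
between the centres (dyads) of two neighbouring nucleosomes. In sequencing
data from MNase digestion, Tn5 tagmentation or apoptotic cfDNA
fragmentation, the protected fragments carry this spacing in two ways:

1. **Pairwise distances.** If dyads sit, on average, one NRL apart within
   regular arrays, the histogram of pairwise dyad distances (the
   *phasogram*) has peaks at lags NRL, 2·NRL, 3·NRL, …
2. **Fragment sizes.** Partial digestion leaves fragments spanning k
   consecutive nucleosomes, of length ≈ 147 + (k − 1)·NRL, producing the
   familiar mono/di/tri ladder of sizes.

Every estimator in the package reduces to one regression: detect the peak
summits \(x_k\) of a suitable distribution, then fit
\(x_k = a + \mathrm{NRL}\cdot k\) by ordinary least squares over peak order
\(k\). The slope is the estimate; its standard error, \(r^2\) and the
number of summits are reported as diagnostics. The intercept is always
kept: the first-peak position can carry a method-dependent offset (most
visibly in the fragment-size ladder, where every band contains one
footprint), and forcing the line through the origin would fold that offset
into the slope.

The assumptions are mild but worth stating: nucleosome spacing is locally
stationary within the region analysed (mixtures of very different NRLs
blur the higher-order peaks); dyads are estimated well by fragment
midpoints, which requires a mononucleosome-sized fragment population; and
periodicity extends over at least three resolvable peak orders.

## The estimators

**Dyad phasogram** (`compute_phasogram()` → `smooth_histogram()` →
`detect_summits()` → `fit_nrl()`, or `estimate_nrl_phasogram()` in one
call). Dyads are fragment midpoints, `floor((start + end) / 2)` — the floor
makes the coordinate deterministic and integral. Pairs are counted per
chromosome for every ordered pair within the lag window, so
cross-chromosome pairs never arise. The counting kernel sweeps neighbour
ranks of the sorted position vector and stops as soon as the closest
remaining rank exceeds the maximum lag, so cost is proportional to the
number of in-window pairs rather than all pairs; the test suite holds it
against a quadratic all-pairs oracle on hundreds of random tracks.

**Start phasogram** (`compute_start_phasogram()`): identical kernel on 5′
starts, for single-end-style inputs. A constant start-to-dyad offset
cancels in pairwise distances, so the slope is unchanged; variable fragment
lengths only widen the peaks. On a common simulation the two routes agree
within a couple of bp, with the dyad route the more precise.

**Fragment-size ladder** (`nrl_from_size_distribution()`): the smoothed
length histogram is searched for the mononucleosome summit in
`[mono_min, mono_min + period_max]`, then the di-, tri-, … summits are
walked with windows extrapolated from the last accepted summit. `mono_min`
defaults to 120 bp, which excludes the sub-nucleosomal ATAC-seq peak
(50–100 bp linker fragments reflecting inter-nucleosome accessibility, not
n-nucleosome protection).

One design choice deserves emphasis. The k-nucleosome band sits at
147 + (k − 1)·NRL, a line of slope NRL with offset 147 − NRL, whereas the
mononucleosome band sits at footprint plus *partial* linker (~167 bp in
typical MNase digests) — a *different* offset. Regressing through the mono
summit therefore biases the slope by several bp when only a handful of
peaks are detectable. The package consequently uses the mono summit only to
anchor the ladder and excludes it from the regression by default
(`include_mono = FALSE`, mirrored by the `include_first` flag of the
phasogram route). With the mono point excluded, a zero-jitter simulation
recovers the configured NRL exactly. Users who want the classical
all-bands regression can set `include_mono = TRUE`.

**Anchored profile** (`anchored_profile()` + `nrl_from_profile()`): dyad
offsets within ±`flank` of each anchor are aggregated (minus-strand anchors
mirrored) and the downstream summit ladder is fitted. The default flank of
2000 bp covers roughly ten nucleosomes, the typical extent of well-phased
arrays next to strong boundaries such as CTCF sites. Peak-based NRL
estimation is unreliable away from strong anchors — fuzzy positioning means
peak calling recovers only a fraction of nucleosomes — which is why the
package offers peak spacing *only* in anchored form and otherwise relies
on phasograms.

**Region stratification** (`nrl_by_region()`): per-label phasograms count
only pairs whose both dyads lie in the *same merged interval* of a label.
Counting any pair "inside the label" would admit phantom lags across gaps
between intervals; the NRL is a within-array quantity. Intervals are merged
with `GenomicRanges::reduce(min.gapwidth = 0)`, so overlapping intervals
fuse but abutting ones stay distinct. Labels that cannot support a fit are
reported with the failure reason rather than dropped.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `min_lag` | 50 | bp | suppresses sub-nucleosomal digestion artifacts |
| `max_lag` | 1200 | bp | ≥ 5 peak orders at ~200 bp spacing |
| `smooth_window` | 15 | bp | removes the 10 bp helical-twist ripple of linker quantisation while keeping ~1 bp summit accuracy |
| `period_min`, `period_max` | 120, 250 | bp | brackets every NRL reported across species (154–240 bp) |
| `max_peaks` | 10 | – | upper bound on regression orders; the lag window is usually the binding constraint |
| `min_prominence_frac` | 0.02 | – | summit acceptance, as a fraction of the first peak height |
| `mono_min` | 120 | bp | smallest length considered mononucleosomal |
| `flank` | 2000 | bp | anchored-profile half-width, ~10 nucleosomes |
| length filter | 100–200 | bp | mononucleosome fraction for dyad methods (footprint ± partial linker) |

Summit acceptance combines three rules: the candidate must be a local
maximum; ties break toward the smaller lag; and its prominence — height
above the higher of the two flanking minima within half a period of the
summit — must exceed `min_prominence_frac` of the first peak. The ladder
detectors add a noise floor: prominence must also clear four robust
standard deviations of the smoothed signal, estimated from successive
differences and rescaled for the smoothing window. Without that floor, a
structureless profile (e.g. anchors that do not phase any arrays) would
yield a ladder of noise bumps; with it, such inputs raise an estimation
error instead of returning a number.

Degenerate inputs are errors, not guesses: fewer than three accepted
summits ("insufficient periodicity" / "insufficient multinucleosome
signal"), unsorted tracks, even smoothing windows, inverted coordinate
ranges, and BEDPE mates on different chromosomes (rejected with a warning)
all stop early with a typed condition.

## The simulator

`simulate_dyad_positions()` draws array boundaries as a Poisson process
(default rate 1/50 000 bp, plus every chromosome start) and places
nucleosome i of an array at
`boundary + floor(147/2) + (i − 1)·true_nrl + N(0, jitter_sd)`, truncated
at the next boundary. Jitter is independent per nucleosome — there is no
cumulative drift, unlike a true statistical-positioning model, which makes
higher-order phasogram peaks unrealistically sharp; this is sufficient for
estimator validation but flattering to real data. The default
`jitter_sd = 20` bp reflects the positional fuzziness typical of bulk
mammalian nucleosome maps. Dyads closer than one footprint after jitter
(steric clash) are resolved by discarding the later one, preserving sorted,
physically plausible tracks; at default jitter this removes a few percent
of dyads and biases the realised mean spacing up by under 1%, which the
phasogram slope — anchored at peak *positions*, not mean spacings — does
not inherit.

`simulate_fragments()` emits exactly `n_fragments` records: with
probability `1 − multi_frac` a mononucleosome fragment centred on a
uniformly chosen dyad with length N(167, 15) clipped at 0.8 footprints,
otherwise a fragment spanning k ≥ 2 consecutive dyads (k = 2 + geometric
(`multi_decay`)), from `floor(147/2)` before the first dyad to
`ceiling(147/2)` after the last — so a zero-jitter k-fragment has length
k·NRL − (NRL − 147), e.g. 337 bp for k = 2 at NRL 190. Spans that would
cross an array end are truncated and logged.
`simulate_state_mixture()` simulates each labeled interval with its own
NRL and emits `n_fragments` *per label* (matching how per-state analyses
are benchmarked), split across a label's intervals by length.

Reproducibility: every chromosome (and every state interval) draws from a
stream derived from the seed plus a fixed offset, so generation order does
not matter and identical configurations give byte-identical BED output.

What the simulator does *not* model: DNA sequence (no MNase/Tn5 cleavage
preference, no GC bias), digestion-level effects, fragile nucleosomes,
cumulative positional drift within arrays, single-cell sparsity. Passing
recovery tests therefore demonstrates estimator correctness under an ideal
generative model, not robustness to every experimental artifact of real
MNase-seq or ATAC-seq libraries.

## Validation scale

The package's own test suite validates each estimator by parameter
recovery at desk scale, chosen to mirror realistic fragment densities while
keeping the default run fast: the headline check simulates a 20 Mb genome
with true NRL 185 bp, jitter 20 bp and 1.3 million mononucleosome fragments
— 0.065 fragments/bp, the density of ~200 million paired-end reads on a
3.1 Gb genome — and requires the dyad-phasogram estimate to land within
1 bp of the truth. Cross-method agreement (fragment-size vs dyad phasogram,
within 2 bp) is checked at the same density with half multinucleosome
fragments; stratification is checked on a two-state 180/195 bp mixture with
10⁵ fragments per state, requiring each label within 1.5 bp and the
active-like state strictly shorter. `scripts/acceptance.R` re-runs the
headline experiment end to end from a single seed.

## Known limitations

* Phasogram summits are argmaxima of a smoothed histogram, quantised to
  1 bp; sub-bp precision comes entirely from averaging across peak orders
  in the regression.
* The estimators assume one dominant repeat length per analysed stratum;
  a strong mixture produces broadened peaks and a density-weighted
  compromise slope rather than two numbers. Use region stratification to
  separate such populations.
* The fragment-size route needs multinucleosome fragments; fully digested
  (mono-only) libraries correctly fail with an estimation error rather
  than an extrapolated value.
* BAM/CRAM input is out of scope; convert alignments to BED3/BEDPE
  intervals first (e.g. with `bedtools bamtobed`).
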