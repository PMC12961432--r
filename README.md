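# nrlfit

Estimation of the **nucleosome repeat length (NRL)** from sequenced DNA
fragment data (MNase-seq, ATAC-seq, cell-free DNA).

Chromatin packs DNA into nucleosomes — ~147 bp wrapped around a histone
octamer — separated by linkers of roughly 10–100 bp. The NRL is the genomic
distance between the centres (*dyads*) of two neighbouring nucleosomes;
linker length is NRL − 147 bp. The NRL varies between species, cell types,
chromatin states, and changes in differentiation, cancer and ageing, so
estimating it accurately from sequencing data is a recurring task in
epigenomics. `nrlfit` provides the standard estimators behind those
analyses, together with a ground-truth simulator for validating them.

## Methods

All estimators reduce to the same regression: find the periodic peak summits
*x*₁ < *x*₂ < … of a suitable distance distribution and fit

&nbsp;&nbsp;&nbsp;&nbsp;*x*ₖ = *a* + NRL · *k* + εₖ

by ordinary least squares over peak order *k*. The slope is the NRL; the
intercept absorbs any method-dependent offset of the first peak.

* **Dyad phasogram** — each paired-end fragment's midpoint estimates a
  nucleosome dyad; the histogram of pairwise same-chromosome dyad distances
  (the phasogram, an autocorrelation of dyad positions) has peaks at
  multiples of the NRL. This is the most precise route: at the fragment
  density of ~200 million paired-end reads on a human genome it recovers a
  known NRL to well under 1 bp.
* **Start phasogram** — the same kernel on fragment 5′ starts, for
  single-end-style data where dyads are unknown.
* **Fragment-size ladder** — the fragment-length distribution of partially
  digested chromatin shows mono-, di-, tri-nucleosome peaks, the sequencing
  analogue of a gel-electrophoresis ladder; summit spacing gives the NRL.
  Works on raw ATAC-seq and cfDNA fragment sizes.
* **Anchored profile** — the aggregate dyad profile around phasing anchors
  (TSSs, TF-binding sites) has peaks one NRL apart; reliable only near
  strong anchors, which is why the package restricts peak-based estimation
  to anchored profiles.
* **Region stratification** — per-label phasograms over chromatin-state
  style annotations, counting only dyad pairs inside the same merged
  interval, yield per-state NRLs (active chromatin short, repressed
  chromatin long).

The simulator generates boundary-phased nucleosome arrays with configurable
true NRL, 147 bp footprints, positional jitter, per-state NRL mixtures, and
a digestion model emitting mono- and multinucleosome fragments, so every
estimator is testable by parameter recovery without external downloads.

## Worked example

```r
library(nrlfit)

cfg <- sim_config(genome = c(chr1 = 5e6), true_nrl = 192, jitter_sd = 20,
                  multi_frac = 0.4, n_fragments = 3e5, seed = 42)
sim   <- simulate_dyad_positions(cfg)
frags <- simulate_fragments(sim, cfg)

mono  <- filter_by_length(frags, 100, 200)   # mononucleosome fraction
track <- compute_dyads(mono)
estimate_nrl_phasogram(track)
#> NRL estimate (dyad_phasogram): 192.31 bp (+/- 0.78, r^2 = 0.9999, 6 summits)

nrl_from_size_distribution(fragment_size_histogram(frags))
#> NRL estimate (fragment_size): 191.60 bp (+/- 0.14, r^2 = 1.0000, 4 summits)
```

Both estimators recover the configured 192 bp repeat length to within a
fraction of a base pair: the slope (`nrl`) is the NRL in bp, `+/-` is the
regression standard error of the slope, and `n_summits` is the number of
periodic peak summits entering the fit. The phasogram summits sit near
multiples of 192 (191, 386, 573, 773, 963, 1151), and the fragment-size
ladder near 147 + (k−1)·192.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/nrlfit simulate --genome chr1:5000000 --true-nrl 192 \
    --n-fragments 300000 --seed 42 --out frags.bed
Rscript inst/cli/nrlfit phasogram --fragments frags.bed --out run1
Rscript inst/cli/nrlfit report    --fragments frags.bed --out run1
```

Outputs are tab-separated with `#`-prefixed headers recording the toolkit
version, every effective parameter and input checksums, so identical
command lines give identical bytes.

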