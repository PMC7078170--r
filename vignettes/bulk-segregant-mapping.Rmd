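---
title: "Mapping a dominant locus by bulked-segregant sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a dominant locus by bulked-segregant sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bulkmap)
```

## The design

An F2 population from two inbred parents segregates 3:1 for a dominant
monogenic trait. Two DNA pools are built from phenotype extremes — a
dominant-class bulk and a recessive-class bulk — and sequenced. Away from the
causal locus the two pools are random draws from the same population and
their allele frequencies agree; at the locus, phenotype selection forces the
recessive bulk to be homozygous for the recessive-parent allele while the
dominant bulk is 1/3 AA : 2/3 Aa. `bulkmap` scores that contrast per site,
smooths it along the genome, calls candidate regions, and then narrows the
interval with individual marker genotypes.

## Model and statistics

With `rho_X` reads supporting the dominant-parent allele and `rho_x` the
recessive-parent allele in a pool, the pool's **SNP-index** is
`rho_X / (rho_X + rho_x)` — the dominant-parent allele read fraction. We fix
this orientation for both pools so that

\[
\Delta = \mathrm{index}_{\mathrm{dom}} - \mathrm{index}_{\mathrm{rec}}
\]

is positive at the causal locus. The expected index of the dominant bulk at a
fully linked site is \(\tfrac13 \cdot 1 + \tfrac23 \cdot \tfrac12 =
\tfrac23\) and of the recessive bulk is 0, so the theoretical F2 threshold is
\(\Delta = 2/3\), printed as 0.67 (`theoretical_delta_threshold()` derives it
from the genotype-class proportions and also covers codominant-extreme
AA-vs-aa bulks, threshold 1, and unselected bulks, threshold 0).

The **ED statistic** is the Euclidean distance between the two pools'
frequency vectors over the two alleles,
\(\mathrm{ED} = \sqrt{(f_Y-f_G)^2 + ((1-f_Y)-(1-f_G))^2}\), which for
biallelic sites collapses to \(\sqrt{2}\,|\Delta|\) — an identity the test
suite asserts at every site. ED is raised to the 4th power before smoothing
(configurable); since no theory fixes an ED cutoff, `ed_threshold()` offers
an empirical genome-wide quantile (default 0.99) or a median + k·MAD rule.

## The simulator

`simulate_f2()` draws each individual as two independent gametes. Meiosis
follows the Haldane model: crossover counts are Poisson with mean
(genetic length in cM)/100, positions are uniform in genetic coordinates
with linear cM–bp interpolation, and there is no interference — the simplest
model consistent with single-locus linkage analysis, and exactly the model
under which `haldane_r()`, \(r = (1 - e^{-2d/100})/2\), converts map distance
to recombination fraction. The tests verify that simulated gametes reproduce
both the Poisson crossover mean and `haldane_r()` itself.

Pooled sequencing is modelled post-variant-calling: per site the bulk's true
allele frequency is the mean member dosage, depth is Poisson(`mean_depth`),
and dominant-allele reads are Binomial with success probability
\(f(1-e) + (1-f)e\), where `e` is a symmetric per-read error rate. Raw read
simulation, alignment and variant calling are deliberately out of scope; the
simulator emits the allele-count tables a caller would.

Defaults mirror a realistic cucurbit study and are fixed once: 11
chromosomes of 26–35 Mb (≈330 Mb), 2.5 cM/Mb (≈830 cM total, in the range of
published watermelon maps), n = 1106 plants, bulks of 30 + 30, mean depth
29×, error rate 0.01, and the causal locus 0.5 Mb from the top of
chromosome 4 — a terminal position, so one side of the fine-mapped interval
is expected to be the chromosome end. SNP density defaults to 30 sites/Mb,
a down-sample of the >100k genome-wide SNPs a real parental comparison
yields; it keeps a full pipeline run around a second while leaving hundreds
of sites per chromosome for the scan.

What the simulator does *not* emulate: linked selection elsewhere in the
genome, depth heterogeneity beyond Poisson (GC bias, mapping bias),
allele-specific mapping error, mis-called variants, or phenotyping error
(available via `pheno_error`, default 0). Passing tests therefore show the
statistics behave correctly under the design's own assumptions, not that any
particular real dataset is clean.

## Filtering, smoothing and calling

`filter_sites()` applies the pre-association rules: per-bulk depth ≥ 5
(applied to each bulk — stricter than a combined-depth reading and standard
in pooled mapping), removal of sites monomorphic across both pools, an
optional parental homozygous-different check, and an optional external site
whitelist standing in for a caller-consensus step. Filtering is idempotent
and monotone in the depth cutoff, both asserted as properties.

`smooth_track()` uses a deterministic sliding-window mean (default 1 Mb
window, 10 kb step, tricube weighting optional) rather than loess: it is
exactly reproducible, cheap at genome scale via cumulative sums, and its
behaviour at chromosome ends is transparent (windows are clipped). Windows
with fewer than `min_sites` (default 10) informative sites are reported as
missing rather than fitted from noise. `call_regions()` takes maximal runs
of windows at or above the threshold, merges runs separated by at most
`merge_gap_bp`, and reports each region's leftmost peak. When nothing
reaches the threshold the top sub-threshold peak is still reported — in this
design the Δ scan frequently peaks just under 0.67 (read error alone pulls
the expected observed Δ at the locus down to about
\(\tfrac23(1-2e) - e \approx 0.65\) at e = 0.01, and windowed smoothing adds
a small linkage decay), so the near-miss is informative, not a failure mode.
For the same reason the suite checks the locus-window Δ against 2/3 with a
tolerance of three standard errors of a single-run estimate across seeds.

## Fine-mapping

`count_recombinants()` scores, for a dominant trait: recessive-class plants
with marker dosage ≥ 1, and dominant-class plants with dosage 0. Both rules
can be switched off independently (dominant-class carriers are individually
uninformative on the proximal side; the homozygous-recessive dominant plants
still count). `recessive_class_r()` estimates the marker–locus recombination
fraction from the recessive class alone, whose causal genotype is known;
it converges to `haldane_r(d)` and flags estimates above 0.5 as likely
mis-orientation. `refine_interval()` performs exclusion mapping: the
interval is bounded by the nearest recombinant-bearing marker on each side,
or by the chromosome terminus when a side has none; zero-recombinant markers
lie inside. Genotyping error is not modelled in the exclusion logic (marker
calls are assumed clean), but `max_recombinants` allows k-recombinant
tolerance. On error-free simulated data the true locus provably lies in the
interval, and adding markers can only shrink it — both tested.

## Segregation and pigments

`chisq_ratio_test()` tests observed dominant:recessive counts against a
Mendelian ratio. The Yates continuity correction is on by default for this
1-df goodness-of-fit test; for the canonical 818:288 vs 3:1 example the
corrected statistic is 0.583 and its p-value 0.445 (uncorrected: 0.638,
p = 0.425). A published figure of "P = 0.583" for these counts coincides
with the corrected *statistic*, not a tail probability; the package always
reports both so the two cannot be conflated. `chi2_sf()` provides the
upper-tail probability via the erfc closed form at 1 df and the regularized
upper incomplete gamma otherwise, and is cross-checked against numerical
quadrature in the tests.

`pigment_concentrations()` applies the Lichtenthaler equations for 100%
acetone — the coefficient set defined at 663.2/646.8/470 nm, the wavelengths
these assays are read at — even when the nominal extractant is an
acetone–ethanol mix; the coefficients are an argument for other solvent
systems. Results are in µg/mL of extract scaled by volume/mass to µg per g
fresh weight; small negative carotenoid values (noise near zero in
chlorophyll-rich extracts) are floored at 0 with a warning.

## Numerical and design choices

* Quantile thresholds use R's default type-7 linear interpolation
  (documented because the 0.99 quantile of small window sets depends on it).
* Peak positions break ties leftmost (`which.max`).
* All randomness flows through explicit seeds; every simulation output is
  bit-for-bit reproducible given (configuration, seed), and the pipeline
  report omits wall-clock timings so reruns are byte-identical.
* Zero-depth sites yield missing indices, never division errors; an all-zero
  table returns an empty track with a warning.
* The test suite runs the full study-scale design (11 chromosomes,
  n = 1106, 30+30 bulks, 29× depth) for 20 mapping replicates and 20 null
  replicates, plus n = 5000 for the estimator-consistency check; the whole
  suite completes in about a minute on one core.

## Limitations

Single biallelic causal locus only; no multi-allelic sites; no per-SNP
p-values or multiple-testing machinery (the design's threshold is
theoretical); no genetic-map construction or multipoint likelihood — the
fine-mapping step is single-locus exclusion, as in the marker-assisted
narrowing it models.
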