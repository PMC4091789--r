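---
title: "Methods: profile smoothing, bound-region calling and state comparison for tiling-array ChIP-chip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profile smoothing, bound-region calling and state comparison for tiling-array ChIP-chip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilechip)
library(dplyr)
```

## The problem

Tiling-array ChIP-chip interrogates a genome with short probes (~25-mers)
at near-regular spacing (~36 bp on the *Drosophila* tiling design). Each
hybridization yields one intensity per probe per sample; an experiment
pairs replicate ChIP hybridizations with matching chromatin-input
hybridizations. The biological questions `tilechip` addresses are those
raised by the genomics of the Pho repressive complex: where do PHO, PHOL
and SFMBT bind; how does binding strength relate to the recognition motif
at TSS-proximal sites versus Polycomb response elements (PREs); and does
PhoRC binding at a PRE drop when the element switches from the repressed
to the active chromatin state.

## Signal model and smoothing

The per-probe signal is the ratio of the *mean* ChIP intensity across
replicates to the *mean* input intensity (ratio of means, not mean of
ratios — with two replicates of each, averaging before dividing weights
the replicates by their input intensity and is the convention matching
"average ChIP to average Input"). Probes with zero mean input are
undefined and stay undefined: no stage imputes.

Ratios are smoothed with a trimmed mean over a sliding 675 bp window:

* A probe's *position* is its midpoint (`start + length/2`); the window is
  `[mid − 337.5, mid + 337.5]`, closed on both ends. The choice of
  midpoint over probe start is symmetric and affects nothing at regular
  spacing; it is the package's convention wherever a probe needs a point
  position.
* Windows holding fewer than 10 probes with defined ratios give an
  undefined smoothed value. At 36 bp spacing a full window holds ~19
  probes, so the rule mainly blanks array gaps and chromosome ends.
* The trim fraction (share of values dropped from each tail before
  averaging, `floor(trim * n)` values per tail) defaults to 0.10 — the
  conventional "trimmed mean" default; it is exposed as a parameter
  because the procedure itself does not force a value.

## Background adjustment and bound-region calling

The background cutoff is `mean + 3·SD` over all defined smoothed values,
genome-wide. Subtracting it and zeroing negatives yields the adjusted
profile. Two conventions are deliberate:

* **Sample SD** (n−1 denominator) — the default in mainstream statistical
  environments.
* The profile that is thresholded *and* the profile that supplies peak
  strengths is the smoothed profile. Using one profile throughout is
  self-consistent; mixing smoothed thresholds with raw peak values would
  make the strength scale depend on a quantity the caller never sees.

Bound regions are maximal clusters of above-zero features in which the
distance from each feature to its nearest above-zero neighbour — measured
midpoint to midpoint — does not exceed 500 bp. Clusters whose genomic span
(first-probe start to last-probe end) is shorter than 360 bp, the estimated
ChIP resolution, are dropped. Within a region, every window of 6
consecutive supporting features is evaluated and the one with the highest
mean smoothed ratio becomes the binding peak; its mean is the binding
strength. Ties take the leftmost window (deterministic output); regions
with fewer than 6 features use the whole region (the 360 bp filter makes
this rare at production spacing). Rankings by strength are stable: ties
keep genomic order.

A property worth recording: raising the SD multiplier does **not**
monotonically reduce the number of called regions. A stricter cutoff can
cut one long cluster into two shorter clusters that both clear 360 bp, so
the count can locally rise. What is monotone — and what the test suite
checks — is the set of above-cutoff probes, the total called coverage, and
the nesting of every stricter-cutoff region inside some looser-cutoff
region.

## Overlap curves

Overlap-versus-strength curves recompute, on a decreasing grid of retained
fractions (default 5% steps from 100% down to 5%), the fraction of the top
`ceil(f·N)` sites whose span intersects a reference interval by at least
1 bp. Overlap is counted per site, not per base pair, matching axes that
read "% overlap of binding sites". The overlap predicate's minimum width
is configurable. An empty site set is an error rather than a silent zero,
to surface upstream failures. Interval arithmetic is 0-based half-open
throughout (BED native); 1-based inputs are converted on read.

## Motif scoring

PWMs are estimated from user-supplied aligned occurrences with a
per-base pseudocount (default 0.5): `p = (count + c) / (n + 4c)`. Motif
*discovery* is out of scope — occurrence alignment comes from an external
finder. Scanning slides a 14 bp window one base at a time over the
±200 bp sequence around each peak center, scores each window as the summed
log₂ odds of its bases against a uniform background, does the same for the
reverse strand, and keeps the single best score per site (forward strand,
then smallest offset, on ties). Ambiguous bases contribute the background
odds (score 0) rather than −∞, so repeat-masked sequence stays scoreable.
GCCAT core counting takes every perfect match of the pentamer and of its
reverse complement, overlaps allowed — PHO binds double-stranded DNA, so a
core on either strand is a core; a forward-only mode exists.

Strength-binned summaries rank sites by binding strength and cut them into
equal-count bins (bin 1 strongest; remainders join the strongest bins —
the placement has to go somewhere and the strong tail is the focus of the
analysis). Per-bin 95% CIs come from a seeded percentile bootstrap (1000
resamples): the CI method is not forced by the procedure, and the seeded
bootstrap is distribution-free and reproducible. Trend tests between bins
use the two-sided Wilcoxon rank-sum test, exact by enumeration of rank
assignments for combined sizes ≤ 12 and the tie-corrected normal
approximation (with continuity correction) beyond.

## The two-state comparison

The adjusted average binding signal of a PRE is the mean of all defined
smoothed values within a 500 bp window centered on its PHO peak, minus the
genome-wide mean of the same profile (the background signal, computed once
per profile). Adding a constant to a profile therefore changes nothing.
The paired test across PREs is the Wilcoxon signed-rank test with the
classic conventions: zero differences dropped, absolute differences
mid-ranked, `W+` the sum of positive-difference ranks. For n ≤ 20 the
p-value is exact — all `2^n` sign assignments of the observed (possibly
tied) ranks are enumerated — otherwise the tie-corrected normal
approximation with continuity correction applies.

The default alternative is one-sided, active < repressed. This sidedness
is an inference, but a tightly constrained one: eight concordant
reductions give an exact one-sided p of `1/256 = 0.0039…` and seven of
eight with the smallest-magnitude discordance give `2/256 = 0.0078…`,
which are the only conventions under which the pair of printed values
0.004 and 0.008 can both arise from eight pairs.

## The synthetic generator

The generator exists so that every stage is testable end to end without
array downloads. It emulates:

* probes of length 25 at 36 bp spacing; two ChIP and two *matching* input
  replicates — each ChIP value is its matching input draw times the
  enrichment times multiplicative lognormal noise
  (`Input ~ lognormal(log 500, σ)`, `ChIP = Input · (1 + Σ aₛK) ·
  lognormal(0, σ)`), so at σ = 0 the probe ratio equals the enrichment
  exactly;
* localized enrichment spread by a triangular kernel of half-width 500 bp
  (the fragment-size / ChIP-resolution scale; a Gaussian kernel is
  available by config);
* two planted site classes: **TSS-class** sites embed a sequence sampled
  from the PWM, with amplitude log-linearly coupled to that instance's
  score (`a = a₀·2^{β(s − E[s])}·lognormal(0, σ_a)`, defaults a₀ = 8,
  β = 0.3, σ_a = 0.1 — the simplest monotone coupling that reproduces the
  motif-tracks-strength contrast); **PRE-class** sites embed 1–3 perfect
  GCCAT cores and draw amplitude independently of sequence
  (lognormal(log 8, 0.6));
* a default GC fraction of 0.41 (the fly genome-wide value) and mandatory
  seeding — every random draw flows through one seeded generator, so runs
  are bit-reproducible.

What the generator does *not* emulate: probe-sequence hybridization bias,
cross-hybridization, copy-number variation, mappability. Tests passing on
synthetic data therefore validate the *procedures* (recovery, calibration,
coupling contrasts), not robustness to array artifacts.

## Numerical behavior and calibration

Problem sizes in the shipped tests were chosen to exercise each claim at
desk scale: oracle equivalence uses hundreds of random small profiles and
sequences; site recovery uses one 2 Mb simulation with 20 planted sites at
σ = 0.1 (≥95% of sites with amplitude ≥ 5 recovered with peak centers
within one probe spacing); the motif-coupling contrast uses 200 TSS-class
and 160 PRE-class sites; the two-state null calibration uses 200 noise
realizations over 8 PREs.

Two calibration findings are worth stating because they shape the test
design:

* **Null call rate.** Under a zero-site null the smoothed profile is
  strongly autocorrelated (neighbouring windows share ~18 of 19 probes),
  so the rare exceedances of the μ + 3σ cutoff arrive in excursions that
  occasionally span 360 bp. The expected false-call rate at σ = 0.1 is
  just under 1 per Mb, but single 2 Mb realizations fluctuate between 0
  and ~2.5 per Mb; the calibration test therefore measures the mean over
  five seeded nulls.
* **Background coupling.** The adjusted average binding signal subtracts a
  genome-wide background estimated from the same profile. If the
  simulated genome carries too few background probes (tens of kb for
  eight PREs), the sampling noise of that shared background couples the
  eight paired differences and makes the signed-rank null conservative.
  The two-state simulations therefore use a 150 kb genome, where the
  background estimate is effectively noise-free relative to the 500 bp
  window means — which is also the realistic regime, since real profiles
  estimate background over the whole ~120 Mb genome.

Other numerical choices: window membership uses a small absolute tolerance
(10⁻⁹ × window) so probes exactly on a closed window edge are included
regardless of floating-point representation; exact-test tail comparisons
use the same tolerance against mid-ranks; TSS windows are clipped at
chromosome starts (whether the original analysis clipped is unstated;
clipping is the only behavior that keeps coordinates valid).

## Limitations

The package starts from probe-level ratio tables: CEL parsing and
between-array normalization (RMA/quantile) are upstream and out of scope.
Motif discovery, logo rendering and FDR-style significance for region
calls are not provided — the caller is the bespoke cutoff/gap/span
procedure, reproduced faithfully rather than replaced by a model-based
peak caller. Expression handling covers the activity thresholds (RPKM ≥
300, RMA > 6) and TSS windows, not read mapping or quantification.
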