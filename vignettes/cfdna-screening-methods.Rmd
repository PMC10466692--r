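---
title: "Methods: extended cfDNA prenatal screening in cfscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: extended cfDNA prenatal screening in cfscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfscreen)
```

# The problem

Extended non-invasive prenatal testing (NIPT-PLUS) screens maternal plasma
cell-free DNA (cfDNA) for fetal chromosomal abnormality. Plasma cfDNA is a
mixture: a maternal background plus a minority fraction — the *fetal
fraction* (ff) — shed by placental trophoblast. Sequencing reads are counted
in genomic windows; a chromosome present in three copies in the placenta
raises its read share by about `ff/2`, and a sub-chromosomal duplication or
deletion shifts the local read depth by `ff/2` (fetal heterozygous event) or
`(1-ff)/2` to `1/2` (maternal event). Screening is therefore a problem of
detecting small shifts in noisy count ratios, and its two systematic failure
modes are biological: *confined placental mosaicism* (the placenta carries
an abnormality the fetus does not — false positives) and *fetal/placental
mosaicism at low grade* (the shift is diluted below threshold — false
negatives).

`cfscreen` implements the full computational stack: a synthetic
maternal-plasma cohort generator with separate maternal, placental and fetal
compartments; equal-read windowing and least-squares GC correction;
per-chromosome Z-score aneuploidy calling against a euploid reference panel;
least-squares changepoint segmentation with a dynamic threshold for CNVs,
with fetal/maternal origin attribution; dual fetal-fraction estimation
(chrY-based and a seqFF-style short-fragment regression) with a 3.5% lower
detection limit; and screening-versus-diagnostic concordance metrics,
including packaged count fixtures for the published comparison tables.

# The simulator

## Compartments

A simulated pregnancy (`sim_sample_spec()`) carries three genomes: maternal,
placental (trophoblast) and fetal. The plasma signal is generated from the
*placental* compartment mixed with the maternal background,

$$r_i \;=\; (1-\mathrm{ff})\,\frac{m_i}{2} \;+\;
  \mathrm{ff}\,\frac{(1-\pi)\,b_i + \pi\,k_i}{2},$$

where $m_i$ is the maternal copy number in bin $i$, $b_i$ the sex-typical
placental base copy number, $k_i$ the placental event copy number and $\pi$
the placental mosaic fraction. The diagnostic ground truth
(`truth_to_diagnostic()`) is rendered from the *fetal* compartment only.
This separation is not plumbing: it is what makes confined placental
mosaicism produce screening-positive/diagnosis-negative pairs and low-grade
mosaicism produce the reverse, without any special-casing in the callers
(both are checked in the test suite as emergent behaviour).

## Reduced genome and noise model

The genome is GRCh37 scaled down 20-fold and tiled with 50-kb bins
(`synthetic_genome()`, ~3,100 bins), so a full sample simulates in
milliseconds while relative chromosome sizes stay realistic. Expected bin
intensities are `depth * gc_effect(gc_i) * r_i`, renormalised to sum exactly
to `depth`; counts are drawn negative-binomially with dispersion 0.01
(variance $\mu + 0.01\mu^2$; Poisson optional). Overdispersion at this level
is what real plasma libraries show after GC correction, and it deliberately
stresses the callers: the per-bin coefficient of variation has a 10% floor
no depth can beat.

Default depth is 8.5 million reads — the production assay's average
effective volume of uniquely mapped reads. Scaling depth down with the
genome would make per-chromosome fractions several-fold noisier than the
assay being emulated; keeping the assay's read budget on the reduced genome
reproduces its operating point (trisomy 21 crossing the threshold across
the typical clinical fetal-fraction range, while a 13–14% mosaic trisomy 21
at typical ff is still missed).

Fetal fractions are drawn from Beta(3, 10) truncated to [0.042, 0.883]
(mean ≈ 0.23), matching the clinical range of roughly 4–88% with its
observed centre. Fragment lengths are modelled as truncated normals on
[50, 250] bp — maternal N(166, 18), fetal N(143, 18) — and only their
100–150 bp class probabilities enter the simulation: each bin's short
count is binomial with a success probability interpolating between the
maternal (≈0.19) and fetal (≈0.64) class probabilities by the locally
fetal-derived share. A small chrY mapping-noise floor (`y_background`,
5e-4 of reads) gives female-fetus samples the realistic non-zero chrY
signal the chrY estimator must see through.

## What the generator does not emulate

No read-level artefacts (mappability, duplicates, alignment error), no
per-bin fixed effects beyond the linear GC model (real genomes have
residual bin-specific bias that production pipelines remove with per-bin
panels), no maternal malignancy or twin pregnancies, and GC bias is linear
by default (a quadratic misspecification mode exists for robustness tests).
Passing tests therefore show the *method logic* is correct at a realistic
operating point — not that the pipeline is validated on real plasma.

# Normalisation

`relative_reads()` divides window counts by their mean (mean exactly 1);
`fit_gc()` is ordinary least squares of the relative read number on window
GC; `correct_gc()` divides by the fitted value and renormalises.
Multiplicative (rather than additive) correction preserves positivity and
scale invariance. A single division leaves a residual OLS slope of order
`sd/sqrt(n)`, so the correction iterates divide-refit-renormalise until the
refitted slope is below 1e-8; this makes the correction idempotent and the
post-correction slope exactly zero at working precision. Fitted values are
clamped at 1e-6 (flagged) to protect against pathological fits.

`make_windows()` builds equal-read windows from fine-bin expected counts:
windows are allocated to chromosomes by largest-remainder rounding of the
chromosome masses (at least one each, never spanning a boundary) and cut at
the cumulative-mass quantiles, so window masses are equal within one
fine-bin quantum.

# Aneuploidy calling

Per-chromosome corrected read fractions are standardised against a euploid
reference panel: $z_c = (x_c - \mu_c)/\sigma_c$, positive at $|z_c| \ge 3$.
Trisomy 21/18/13 and rare autosomal trisomies use the identical rule.

**Finite-panel calibration.** With $\mu_c, \sigma_c$ estimated from an
$n$-sample panel, the naive statistic is $\sqrt{1+1/n}\,t_{n-1}$, whose
$|z|\ge 3$ tail at $n = 50$ is ~0.0046, not the nominal
$2\Phi(-3) = 0.0027$. `build_panel()` therefore stores
$\sigma_c = s_c \sqrt{1+1/n}\; q_{t_{n-1}}(\Phi(3))/3$ — the raw SD inflated
so that the 3-SD rule attains its nominal normal false-positive rate. The
raw SD is kept alongside. The null-calibration test measures the rate
marginally over the panel draw (several independent panels), because a
single panel realisation conditions the rate on that panel's estimation
errors.

**Sex chromosomes.** chrY presence is decided against a self-calibrated
background (`calibrate_y_reference()`); with chrY material present, the chrX
Z is taken against the male-typical expectation $\mu_X(1-\mathrm{ff}/2)$.
The decision table: no Y and $z_X \le -3$ → 45,X; no Y and $z_X \ge 3$ →
47,XXX; Y present and $z_X \ge 3$ → 47,XXY; Y present and the chrY share at
least 1.5 times the single-Y expectation for the measured ff → 47,XYY. The
ff used here is the chrY-*independent* (seqFF) estimate: an XYY doubles the
chrY-based estimate and would otherwise corrupt both the male-X expectation
and the single-Y yardstick. Below the 3.5% ff limit the sample is a
no-call.

**CNV/aneuploidy disambiguation.** A large called CNV inflates its own
chromosome's fraction (mimicking trisomy) and, through renormalisation,
deflates every other chromosome's. `screen_sample()` therefore calls CNVs
first, masks maternal-scale segments (|deviation| ≥ 0.25 over ≥ 10 bins,
covering < 80% of their chromosome) back to diploid before the Z pass, and
subjects any remaining aneuploidy call on a CNV-bearing chromosome to a
remainder test: the call survives only if the *uncalled* part of the
chromosome also deviates (or the segments cover ≥ 80% of it — a fractured
whole-chromosome shift). Only clearly non-fetal dosage is masked because
masking noise-selected segments would under-disperse the sample relative to
the unmasked panel.

# CNV segmentation

The segmenter is least-squares changepoint detection, implemented as
grow-then-prune binary splitting: the sum-of-squared-error-minimising split
is applied recursively down to the minimum segment size (3 bins); the split
tree is then pruned bottom-up, a split surviving when its full-span
left/right mean contrast exceeds $z_t$ standard errors or when surviving
structure below depends on it; a final pass merges weakest-first any
adjacent consolidated segments whose contrast has dropped below $z_t$, and
re-locates each surviving boundary to the SSE-optimal split of its flanking
pair. Growing before testing prevents an interior event being diluted in
its parent's mean (which stalls literal retained-split recursion); pruning
by contrast collapses uniform shifts — whole-chromosome aneuploidy — into a
single segment instead of shredding them.

The *dynamic threshold* is the calling rule: a segment becomes a
duplication/deletion call when $|\bar{r} - 1| \ge z_t\,\hat\sigma/\sqrt{L}$
(reported as `segment_z`), with $\hat\sigma$ the scaled median absolute
deviation of first differences (robust to the segments themselves), plus a
deviation floor of 0.015 (just under the smallest fetal signal at the ff
detection limit, 0.035/2) and a 3-bin minimum. Segments spanning ≥ 90% of a
chromosome belong to the aneuploidy caller. On chrX the sex-typical male
level `1 - ff/2` is divided out first; chrY is excluded from interval
calling (its dosage drives the karyotype logic).

A per-segment 3-SD rule over ~3,000 windows is a scan statistic: selection
makes a handful of noise segments per euploid genome clear it (measured ~5,
mostly sub-Mb). `segmentation_config(multiplicity_adjust = TRUE)` optionally
Bonferroni-divides the nominal level over each chromosome's candidate
segments, which brings the euploid spurious-call rate down to
~0.0027/chromosome at the cost of sensitivity to small fetal events; it is
off by default because the 3-SD operating point is the one the size-trend
behaviour is defined at.

`segment_exact()` is the exhaustive minimal-SSE dynamic program
($O(kn^2)$), used as the independent oracle: on strong-step instances the
recursive segmenter matches it exactly in ~97% of cases, the residual being
the textbook non-optimality of greedy splitting (a 3-bin noise sliver
clearing the contrast rule spends a segment the DP places better).

**Origin attribution** (`infer_origin()`): expected deviations are `ff/2`
(fetal heterozygous), `(1-ff)/2` (maternal, not inherited) and `1/2`
(maternal, inherited); the observed deviation is classified to the nearest,
the two maternal variants collapsing to one class. When the fetal and
maternal expectations are closer than twice the segment's standard error,
or at an exact tie, the origin is indeterminate.

# Fetal-fraction estimation

**chrY route**: `ff_y = (y - y_0)/(y_1 - y_0)` with `y` the observed chrY
read fraction, `y_0` the female background and `y_1` the pure-male
reference, both measured from the simulator's own syntheses so the package
is self-calibrating; undefined within the noise margin of background
(female fetus).

**seqFF route**: ridge-regularised least squares (penalty 1e-3 on
standardised features) of known ff on three sample-level features — the
genome-wide short-fragment (100–150 bp) proportion, count-weighted mean GC
and log total fragments. The named features pin down the "GC content, read
number and other indicators" of the original description. Rank-deficient
calibrations fall back, flagged, to the short-fragment proportion alone.

**Combination**: with male evidence the two routes are averaged; otherwise
seqFF stands alone (the chrY route is undefined for female fetuses). The
averaging rule is the package's choice — only "combined" is specified
upstream. A combined estimate below 0.035 flags the sample as a screening
no-call.

# Concordance

`parse_iscn()` reads the microarray result dialect
`arr[GRCh37] <bands>(<start>_<end>)×<cn>` with thousands separators, mosaic
ranges (`×2–3`, en dash, hyphen or underscore), an `hmz` homozygosity
token, whole-karyotype tokens (45,X / 47,XXY / …) and bare trisomy tokens.
Printed coordinates are 1-based inclusive and convert internally to 0-based
half-open (BED-compatible); sizes are printed-coordinate differences, so
the canonical sizing arithmetic is reproduced exactly. An interval covering
≥ 90% of its chromosome's callable (array-covered) length classifies as
whole-chromosome aneuploidy; acrocentric p-arms are excluded from the
callable span.

Matching (`match_calls()`): aneuploidies by chromosome, sex-chromosome
karyotypes by token identity, CNVs by sign plus reciprocal overlap ≥ 25%
(configurable). Unmatched screening calls are FP, unmatched diagnostic
findings FN; deletions < 0.5 Mb and duplications < 1 Mb fall under the
microarray selection floor and are excluded rather than counted FN; regions
of homozygosity are never screenable. Metrics are
`sensitivity = 100·detected/diagnostic-positive`,
`PPV = 100·confirmed/screen-positive`, `miss = 100 - sensitivity`, with 95%
intervals by Wilson score with continuity correction by default (method
configurable). The intervals printed in the source tables are not
reproduced by any standard method we tried and are deliberately not a
target. The packaged fixtures under `inst/extdata/` transcribe the
published count tables; `build_report()` recomputes every rate from the
counts at run time.

# Problem sizes and reproducibility

The test and acceptance experiments use, as the package's own design: a
1/20-scale genome with 50-kb bins; 50-sample reference panels (25 for unit
tests); 5 × 1,000 euploid samples for null calibration; 100 male samples
for chrY recovery and 100/50 train/test for seqFF; 100 random instances for
the segmentation oracle; 60 replicates per size for the CNV size trend; and
30 replicates per mosaicism mechanism. Every stochastic step is seeded
(`with_seed()`, `child_seed()`), so identical inputs give bit-identical
outputs; `scripts/acceptance.R` re-derives every reported quantity from a
single command-line seed.

# Known limitations

- The dispersion floor of the reduced-genome noise model caps small-CNV
  sensitivity below what a 300,000-window production pipeline achieves;
  size-trend results are therefore read as a direction, not as clinical
  sensitivities.
- Greedy binary segmentation is near- but not exactly DP-optimal (~3% of
  strong-step instances differ by a noise sliver).
- At the default 3-SD dynamic threshold the euploid genome carries a few
  spurious sub-Mb segment calls (scan-statistic selection); the
  multiplicity-adjusted mode trades them against small-event sensitivity.
- The chrX logic models whole-chromosome dosage and large X deletions; no
  attempt is made to reproduce vendor-specific X-isochromosome or partial-X
  reporting.
- CMA itself is not modelled — diagnostic truth is rendered directly from
  the fetal compartment with the mosaic-range (`×2–3`) reporting convention
  and the 100-kb interpretation floor.
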