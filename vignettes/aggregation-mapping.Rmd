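---
title: "Quantifying and mapping protein-aggregation phenotypes with aggscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and mapping protein-aggregation phenotypes with aggscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggscan)
```

## Overview

`aggscan` implements the quantitative core of a natural-variation screen for
modifiers of polyglutamine (polyQ) protein aggregation: automated counting of
fluorescent aggregates (foci) in micrographs of yeast expressing a GFP-tagged
polyQ reporter, a single-marker linkage scan over a laboratory x vineyard
haploid cross with a permutation-based false discovery rate, and
size-distribution statistics for aggregates in human cells. Because the kind
of raw data this pipeline consumes (proprietary-format micrographs, cross
genotypes from earlier studies) is rarely redistributable, the package also
ships first-class synthetic-data generators with known ground truth; every
claim the test suite makes is checked against truth that was planted, not
assumed.

This vignette records the models, the tunable parameters and their defaults,
the numerical choices, and what the synthetic data does and does not emulate.

## The imaging model

A `micrograph` is an intensity matrix plus a physical scale (µm/pixel). The
scale matters because the classification rule at the heart of the assay is
physical: segmented GFP objects with equivalent diameter
$d_\mathrm{eq} = 2\sqrt{A/\pi} \le 2\,\mu m$ are counted as punctate foci
(aggregates); larger objects are diffuse cytoplasmic fluorescence. The
equivalent-diameter convention is our choice — "diameter" is otherwise
ill-defined for an irregular segmented object.

Processing of one field proceeds in four steps.

**Cell detection** (`detect_cells`). Slightly off-focus DIC renders cells as
bright blobs. We binarise with a locally adaptive rule — foreground iff
$I > \mu_w + k\,\sigma_w + c$, with $\mu_w,\sigma_w$ the mean and population
sd over a square window — fill holes, label connected components, and keep
components whose area lies in `[min_cell_area, max_cell_area]`
(defaults 3–80 µm², generous bounds around a 4 µm yeast cell). The window
defaults to ~8 µm (about two cell diameters) so that the local statistics
see mostly background; `k` defaults to 1 for the DIC channel. The small
absolute margin $c$ (`min_contrast`, 2 intensity units) exists purely for
degenerate inputs: in a noise-free image the pure rule would segment
arbitrarily faint smoothing tails, because $\sigma_w \to 0$. Cells touching
the image border are kept by default (`exclude_border` flips this); dropping
them would bias counts in dense fields.

**High-pass filtering and foci detection** (`highpass_puncta_filter`,
`detect_foci`). The high-pass filter is a difference of scales: the image
minus a Gaussian smoothing of itself at `highpass_scale` (default 0.8 µm),
negatives clipped. A sub-resolution spot passes nearly unchanged while a
feature broader than the scale is attenuated toward zero, so thresholding the
filtered image (same locally adaptive rule, offset `puncta_offset_k`) isolates
puncta. Components are assigned to the cell containing their centroid (the
tie-break for a focus straddling two masks) and filtered by the 2 µm rule.

One numerical subtlety: an aggressive threshold carves only the bright core
out of a broad blob, so the *thresholded* component of an oversize object can
measure under 2 µm. We therefore size each candidate at **half maximum** of
its high-pass response — the half-max extent of a smooth peak is independent
of the threshold level — which restores the true width of broad objects and
keeps the focus/diffuse dichotomy a genuine partition.

**Fluorescence classification and diffuse intensity** (`detect_diffuse`). A
cell is fluorescent iff the low-pass-smoothed GFP signal (scale
`lowpass_scale`, default 1 µm) exceeds `fluor_threshold` over at least half
of its mask, or the cell contains a focus. This operational definition is
ours; the alternative of thresholding mean intensity is more fragile to
partial-cell masks. The diffuse mean intensity is the raw GFP mean over the
cell mask with focus pixels excluded (dilated by 2 px so Gaussian tails do
not leak in); a cell that is entirely foci reports NA.

**The statistic** (`percent_foci`). The per-field phenotype is
$100 \cdot n_\mathrm{foci}/n_\mathrm{fluorescent}$: dividing by fluorescent
(not all) cells standardises away expression differences between strains and
experiments. A field with no fluorescent cells yields NA — propagating
"undefined" rather than 0 avoids dragging strain means toward zero.
`aggregate_replicates` averages replicate fields per strain, excluding (and
counting) undefined replicates. `diffuse_vs_foci_correlation` reports the
Pearson correlation between strain-mean diffuse intensity and percent-foci;
a small value supports the claim that expression level does not drive the
aggregation phenotype. (Pearson is our choice; nothing downstream depends on
the correlation flavour.)

**Calibration** (`calibrate_thresholds`). Thresholds are set on a
high-aggregating positive-control field, mirroring the practice of tuning an
imaging pipeline on a control and then freezing it. Two rules, both
deterministic given the control:

* `fluor_threshold` is the Otsu split (two-class minimum within-class sum of
  squares) of the *per-cell median* low-pass GFP intensities. Per-cell
  medians give two clean populations — background-level and diffusely
  fluorescent cells — that a pixelwise quantile rule does not, because focus
  signal bleeding into the low-pass image skews the upper pixel quantiles.
  The control must contain both populations; if the two classes are not
  separated by at least 20% of the background class (a control with no
  fluorescent cells), calibration refuses to proceed.
* `puncta_offset_k` is the largest offset at which the control's foci count
  stays within 5% of its plateau, where the plateau is the longest run of
  near-constant counts over an offset grid after a 3-point running median
  (which removes single-offset flickers). The count-vs-offset curve drops
  sharply when real foci start being lost; stopping at the high end of the
  plateau maximises specificity while retaining sensitivity. A control with
  on the order of 100 cells gives a stable plateau; very small controls make
  the 5% band sub-integer and the choice noisy.

For human-cell data, `max_project` collapses a z-stack by per-pixel maximum,
`segment_aggregates` segments the projection (adaptive threshold with a
window of a third of the image side, since aggregates are much larger than
yeast puncta), and `bin_aggregate_sizes` bins areas at 50 µm² — areas exactly
at the cutoff count as "large", a boundary convention we fixed since the
binning rule itself does not dictate one. `rank_sum_test` computes the
Mann-Whitney U from joint midranks; the two-sided p is exact by enumeration
whenever the number of group assignments is at most $\binom{16}{8}$ (which
covers both samples ≤ 8 as well as every split with $n_1+n_2 \le 12$), and a
tie- and continuity-corrected normal approximation otherwise. The exact
two-sided convention counts assignments with $|U - n_1 n_2/2|$ at least the
observed distance, which makes identical samples give exactly p = 1.

## The linkage model

Genotypes are biallelic (laboratory = 0, vineyard = 1) over haploid
segregants with chromosome/position metadata.

**Marker QC** (`prune_markers`). Three rules, applied in this order:
markers with fewer than two genotyped strains are unusable; within each
chromosome a greedy left-to-right pass computes R² (squared Pearson
correlation over pairwise-complete strains) between the current marker and
the next and, when R² > 0.90, removes the *earlier* member of the pair — so
a block of correlated markers collapses to its last member; then markers
with more than one missing entry or minor-allele frequency below 25% are
removed. Every removal is logged with its reason, and counts always balance
(kept + removed = total). Under linkage-decaying correlation the surviving
adjacent pairs provably satisfy R² ≤ 0.90; with adversarial (non-monotone)
correlation structure a single greedy pass cannot guarantee it, but meiotic
genotypes are Markov along the chromosome and decay monotonically. An
alternative mode (`compare = "last_retained"`) drops the candidate instead
and keeps the first member of a block; which end of a block survives is the
only difference, and the default honours "remove the earlier member".

**The scan** (`linkage_scan`). Per marker: drop strains missing that
genotype, regress phenotype on the 0/1 allele code by least squares, report
the two-sided p for slope = 0 from the t distribution with $n-2$ df. With a
binary predictor this is algebraically the pooled two-sample t-test, which
the test suite verifies to $10^{-10}$ against `t.test`. The implementation
is closed-form and vectorised across markers (cross-products with a
missingness mask), so one scan of 1000 markers x 200 strains takes
milliseconds — which is what makes the permutation FDR cheap. Monomorphic
markers and zero-variance phenotypes are flagged undefined, never silently
dropped. Strain-mean phenotypes are used (replicate-level regression would
require a mixed model and the replicate counts here are small).

**Permutation FDR** (`permutation_fdr`). Phenotype values are shuffled
across strains — genotypes, and hence linkage disequilibrium, stay fixed —
the scan is re-run per shuffle, and
$\mathrm{FDR}(t) = \overline{\#\{p_\mathrm{perm} \le t\}} / \#\{p_\mathrm{real} \le t\}$.
The threshold grid defaults to the sorted observed p-values, making the FDR
step function exact without arbitrary gridding. Undefined markers are
excluded from both numerator and denominator so the two counts stay
comparable; a threshold with zero real hits reports NA, not 0/0. Counting
uses a $10^{-9}$ relative tolerance at the threshold: p-values that are
equal in exact arithmetic (symmetric permutations) can differ by one ulp,
and a hit must not fall off the boundary for that reason. For tiny instances
an explicit permutation matrix can be supplied, which is how the suite
checks the table against exhaustive enumeration.

**Variance explained and peaks** (`variance_explained`, `call_peaks`).
R² of the least-squares fit on the named markers, jointly (additive with
intercept; collinear sets are handled by a rank-revealing fit with the rank
reported) and singly, all on the strains complete at every named marker — so
single and joint values are comparable and the joint R² is never below the
best single one. Peak calling takes the largest p threshold whose FDR is at
or below the ceiling and collapses each within-chromosome run of adjacent
significant markers to its best marker; an unreachable ceiling yields an
empty call set, not an error.

## What the synthetic data emulates

`simulate_cross` draws each chromosome as a two-state Markov chain: first
marker a fair coin, allele switching between adjacent markers with
probability `recomb_prob` (0 = complete linkage, 0.5 = free recombination),
entries masked missing at `missing_rate`. This reproduces the three
properties the scan and QC actually exploit — 0.5 marginal allele
frequencies, geometrically decaying within-chromosome LD, independent
chromosomes — and nothing else: there is no interference, no real
recombination map (none is published for the motivating cross, so the
switch probability is a free knob, default 0.1 per interval), and positions
sit on a uniform 5 kb grid because the scan uses only marker order.

`simulate_phenotypes` is the additive model
$y = \mathrm{baseline} + \sum_j e_j\,[x_j = \mathrm{L}] + \varepsilon$,
clamped to [0, 100] because the phenotype is a percentage. A strain missing
a QTL genotype receives no contribution from that locus (dropping the strain
instead would couple simulator sample size to the QTL list; the scan handles
missingness itself). Since alleles are fair Bernoulli draws, an effect $e$
contributes variance $e^2/4$, so effects can be chosen to hit any target
single-locus R² exactly in expectation — the tests plant expected R² of 0.38
and 0.16 this way at n = 500 and demand recovery within ±0.05. With one
laboratory-increasing and one vineyard-increasing allele the four two-locus
classes straddle both parental values: transgressive segregation, checked by
enumeration in the noiseless case. Default conditions (baseline 6%, effects
of a few points, residual sd 2%) put simulated segregants in roughly a
0.2–22% phenotype range with negligible clamping.

`render_field` draws ellipsoidal cells (hard fill, then a 2 px Gaussian edge
blur standing in for defocus) as bright blobs in the DIC proxy and as
diffuse fill in fluorescent cells in the GFP channel, plants each focus as
an isotropic Gaussian whose full width at half maximum equals its planted
diameter (analytically checkable: a 1 µm focus at 0.2 µm/px has a 5 px
half-max width), and adds white Gaussian noise. Field layouts come from
`simulate_field_truth`, which places cells on a jittered grid so that
arbitrarily dense fields never produce touching cells. Default intensities
(background 100, cell +300, diffuse +150, focus peak +600, detector units)
give peak-SNR 5 at noise sd 120, the noise level the accuracy tests run at.
The renderer deliberately omits real optics — no PSF, no shading, no
photon-counting noise, no touching or budding cells, no fluorescence
bleed-through — so a passing suite demonstrates that the *algorithms* meet
their contracts on images satisfying their assumptions, not that the
pipeline segments any particular real microscope's output. On real data the
locally adaptive parameters and the calibration control would do the
adapting; the contracts (2 µm dichotomy, undefined-propagation,
DC-invariance, foci ⊆ fluorescent) are unchanged.

`render_aggregate_field` places non-overlapping filled disks with requested
physical areas (bounded rejection sampling; an impossible request errors)
and returns the true label map, giving the morphology statistics a pixel-
exact oracle: one 50 µm² disk at 0.26 µm/px must segment to ≈740 px.

## Reproducibility choices

Every stochastic operation takes an explicit seed and restores the caller's
RNG state; identical seeds give bit-identical outputs, which the suite
asserts. `run_pipeline` expands one global seed into fixed per-stage
substreams so a stage can be re-run alone and reproduce itself. All tables
are plain TSV with `#key=value` metadata headers carrying the seed, package
version and a hash of the scientific configuration (the output path is
excluded from the hash so relocated runs stay comparable); images are 16-bit
TIFF with a JSON sidecar for the µm/pixel scale (TIFF round-trips integer
intensities exactly; PNG is accepted on input). The problem sizes used by
the test suite and the acceptance script — 50 small random datasets for the
t-test equivalence, 200 strains x 1000 markers for null calibration, 20
seeds of 500 strains x 296 markers for QTL recovery, ten 210-cell fields at
SNR 5 for imaging accuracy — are the package's chosen validation conditions:
large enough that the binomial and Monte-Carlo tolerances quoted above are
meaningful, small enough to run in about a minute total.

## Known limitations

* The DIC proxy is "cells are bright"; real off-focus DIC has shear
  artefacts the detector has never seen.
* Calibration assumes the control contains both fluorescent and
  non-fluorescent cells and on the order of a hundred cells; tiny or
  saturated controls fail loudly rather than mis-calibrating silently.
* The scan is single-marker and additive: no interval mapping, epistasis,
  dominance (the cross is haploid) or covariates.
* The greedy pruning invariant (surviving adjacent R² ≤ 0.90) is guaranteed
  only under monotone LD decay, which meiotic data satisfies.
* `percent_foci` treats a cell with one focus and a cell with ten
  identically, by design — the assay's readout is the fraction of cells
  aggregating, not aggregate load.
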