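---
title: "Methods: bimodal single-cell protein dynamics and cell fate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bimodal single-cell protein dynamics and cell fate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bimodyn)
```

## The problem

Drugs kill some cancer cells and spare genetically identical siblings. One
route to understanding this stochastic outcome is dynamic proteomics:
time-lapse fluorescence microscopy of clonal cell lines in which one protein
per clone carries an endogenous YFP tag, alongside a constitutive red
nuclear-enriched marker used for segmentation and tracking. After drug
addition, some tagged proteins behave *bimodally* — their level rises in one
subpopulation of cells and falls in another, starting around 12 h after
treatment — and membership in these subpopulations can correlate with
whether a cell eventually dies or survives.

bimodyn re-implements the full analysis chain for such experiments: image
analysis of two-channel movies, per-cell slope statistics that define
bimodality, and the downstream fate, mitosis-timing, profile and heatmap
analyses. Because raw movies of this kind are rarely shared, the package
also contains a first-class synthetic-data generator that produces both
trajectory tables and rendered movies with complete ground truth; every
stage of the pipeline is tested against that ground truth.

## The bimodality procedure

For every cell of a clone, the trajectory of total YFP signal is reduced to
interval slopes between consecutive time points inside a late analysis
window, by default 12 h to 20 h after drug addition. At 30-min sampling the
closed window holds exactly 17 time points and therefore 16 consecutive
slopes; for gap-free uniform sampling the mean of those slopes telescopes to
the endpoint slope \((y_{17}-y_1)/8\,\mathrm{h}\), an identity the test
suite checks to \(10^{-10}\) relative error. Cells are then split by the
sign of their central slope (mean by default, median available); exact zero
slopes join the non-increasing group, a measure-zero tie under continuous
noise but fixed for reproducibility.

A clone enters testing only if both sign groups hold at least `n_min = 10`
cells. For eligible clones the two groups' central-slope distributions are
compared with three tests — two-sided Welch *t*, two-sample
Kolmogorov–Smirnov, and Mann–Whitney — and Benjamini–Hochberg correction at
FDR \(q = 0.1\) is applied across eligible clones separately for each test
family (a pooled variant over all \(3m\) p-values is available). A clone is
called bimodal when it is eligible, all three raw p-values fall below
\(\alpha = 0.05\), and all three survive BH.

Two caveats are intentional. First, the sign-split-then-test construction
is anti-conservative by design — the groups are defined on the tested
variable — so the effective filter is the eligibility rule; we implement the
procedure as defined and do not "fix" it. Second, the Welch *t* reference
distribution is not the permutation null: at group sizes near 15 its
p-values deviate from a permutation oracle by a small systematic bias
(\(\sim 0.003{-}0.006\) at mid-range p), which is larger than Monte-Carlo
error at \(10^5\) permutations. The exact KS and Mann–Whitney p-values *are*
permutation p-values and match the oracle to Monte-Carlo error. The package
ships the oracle (`permutation_test_triple()`) so users can reproduce this
comparison.

Cells that die before the window opens, or retain fewer than two usable
samples inside it, are dropped from slope analysis — a dying cell cannot
contribute a 12–20 h slope. Missing in-window samples are bridged with the
actual time gap in the slope denominator; nothing is imputed.

## Fate, mitosis timing, profiles, heatmaps

`fate_screen()` repeats the three-test consensus per bimodal clone with
cells grouped by fate: died versus survived at the end of the movie, with
tracks lost earlier treated as censored and excluded. A clone significant in
all three tests (raw \(p < \alpha\), BH-passing across the analysed clones)
gets a direction determined by which fate group has the larger median
central slope. Fate groups smaller than 10 cells (mirroring the eligibility
rule; configurable) mark the clone underpowered.

`mitosis_death_analysis()` bins cells by whether any detected mitosis
occurs within the first 12 h and reports killed fractions with binomial
standard errors \(\sqrt{\hat p(1-\hat p)/n}\) and a two-proportion
chi-square test (continuity-corrected) — the test is not part of the
original procedure but gives the comparison a testable contract. The default
binning follows the figure-caption convention (mitosis-in-first-12-h versus
not, which places never-dividing cells in the late bin); a strict alternative
keeps only cells with an observed late mitosis.

`classify_mean_profile()` labels a clone's cell-averaged trajectory as
`up`, `down` or `down_up` from the signs of its net changes over
\([0, 12\,\mathrm{h}]\) and \([12\,\mathrm{h}, \mathrm{end}]\). Changes are
normalised by the trajectory's range rather than its starting level so the
label is invariant under positive affine transformations \(y \mapsto ay+b\);
a dead-band of \(\varepsilon = 5\%\) of the range absorbs flat wiggle, and
profiles flat within the band default to `down`.

`normalize_dynamics_matrix()` z-scores each protein's mean trajectory (zero
variance rows become zero and are flagged), and `cluster_order()` orders
rows by average-linkage hierarchical clustering on correlation distance —
metric and linkage are unstated in the source procedure; correlation
distance matches the "similar dynamics adjacent" intent and average linkage
is the common default for expression heatmaps.

## The image-analysis chain

The red channel drives segmentation. After flat-field and background
correction, each frame is smoothed (Gaussian, \(\sigma = 2\) px), nuclei are
thresholded with global Otsu and split by a distance-transform watershed,
and debris below 50 px² is discarded. Cell bodies are obtained from a lower
threshold (0.4 × Otsu) region-grown from the nuclei by seeded propagation,
so every nucleus lies in exactly one cell. When no flat-field image is
supplied, the illumination field is estimated as a smoothed 8 × 8-tile low
quantile of the temporal median image — a blurred median alone fails when
cells barely move, because normalising by the mean of a mostly-background
image amplifies the cells into the "illumination" estimate.

Tracking reads the movie end-to-start and greedily links each cell to the
detection in the previous frame minimising Euclidean centroid distance plus
`attr_weight` (10 px per log-unit) times the absolute change in log total
YFP; links beyond `max_link_px = 50` px are refused. The cost is a linear
combination because the source procedure names "closest centroid, and other
attributes like protein levels" without a functional form; greedy matching
in increasing cost order is the simplest faithful reading and is documented
as such. Two tracks merging backward onto one detection mark a candidate
mitosis at the merge frame.

Phenotypes use two morphology features per detection: roundness
\(4\pi A/P^2\) with the perimeter measured on the 8-connected contour using
Vossepoel–Smeulders step weights (0.980/1.406) — the naive boundary-pixel
count makes even discs exceed 1 — and the nuclear-to-cytoplasm red contrast.
Death is called at the first frame where the cell is round
(roundness ≥ 0.9) *and* its contrast has collapsed below 0.6 × the track's
baseline, sustained three frames or followed by track termination; "envelope
breakdown" is not operationalised in the source, so the contrast collapse is
this package's proxy for it. Mitosis is confirmed when a backward merge
coincides with parent rounding within ±2 frames and no earlier death call.
The thresholds are calibrated on the synthetic renderer (see below) and are
exposed in the configuration.

`quantify_tracks()` emits each track's total (summed) cell YFP per frame —
the sum rather than the mean is used because it is robust to the
halving-at-division convention — and `nuclear_cytoplasmic_ratio()` reports
the N/C intensity ratio with a fold-change translocation flag.

## What the synthetic generator emulates — and what it does not

`simulate_clone()` produces trajectories with the qualitative structure of
the real experiments: ~30-min sampling over 24 h, a shared drift before a
12 h divergence point, a rising and a falling subpopulation in bimodal
clones, multiplicative log-normal measurement noise, death times from
Normal(15 h, 3 h) truncated to (12 h, 24 h] (the "15 ± 3 h" observation
read as mean ± SD — the source does not define the ±, and this reading is a
recorded decision), fate probabilities coupled to the subpopulation, and
Poisson-process mitoses that halve the level of the single followed lineage.
Samples at or after death are *missing*, not zero, because segmentation
loses dying cells; that convention flows through the whole pipeline.

Defaults define the study conditions used by the tests: 200 cells per
clone, baseline 1000 fluorescence units, `noise_sd = 0.1`, post-switch
slopes ±45 units/h in bimodal clones, mitosis rate 0.3/day. With these
values the per-cell mean-slope estimate has a standard deviation of roughly
18–21 units/h, so the ±45 separation is about 4–5 noise-SD. Unimodal clones
in a screened panel decline at 30 units/h, which puts a cell's probability
of showing a positive slope near \(10^{-3}\): the 10-cell eligibility rule
then excludes essentially all of them, as in the real procedure where
eligibility is the effective filter. The panel generator makes
`round(frac_bimodal * n_clones)` clones bimodal (25 of 100 at the default
fraction, matching the scale of the original screen) with per-clone seeds
derived from one master seed.

The within-cell noise magnitude and the piecewise-linear trajectory shape
are not stated anywhere in the source; they are calibrated only to the
qualitative published trajectory shapes. Cell-to-cell variation ("about
two-fold around the mean") is available as `cell_level_sd` — implemented as
an additive whole-curve offset so that configured slopes remain exact — but
defaults to 0 so that the generator's countable contracts (exact slopes at
zero noise) hold at the defaults. Real data differ in ways the generator
does not model: trajectories are not piecewise-linear, noise is not
time-independent, division is not a clean halving, and segmentation errors
are not independent of cell state. Passing the recovery tests therefore
shows the *procedure* is implemented correctly and is well-calibrated on
data satisfying its assumptions — not that it would achieve the same
sensitivity on real movies.

`render_movie()` draws each cell as an elongated elliptical cytoplasm
(semi-axis 18 px, axis ratio 2.8) with a brighter elliptical nucleus, moving
by a bounded random walk with pairwise repulsion; mitosis is rendered as
rounding for two frames followed by a split into two daughters, death as
rounding with partial contrast collapse (nucleus 0.48, cytoplasm 0.34
versus the normal 1.0/0.25) for two lingering frames, then disappearance.
Poisson shot noise (400 photons per intensity unit) and Gaussian read noise
are added after optical blur (\(\sigma = 1\) px). These defaults were chosen
together with the segmentation defaults so that global Otsu lands on the
nucleus–cytoplasm boundary rather than the background–foreground boundary,
normal cells segment at roundness ≈ 0.74–0.89 while rounded cells measure
≈ 0.95–1.05 (ε above 1 reflects discretisation), and a dying cell's contrast
falls to ≈ 0.45–0.55 of baseline while its nucleus stays segmentable. A
fully collapsed contrast would be more dramatic but would make the dying
cell invisible to the Otsu step, so nothing could ever detect the death
morphology — the partial collapse is the renderer analogue of the early
phase of envelope breakdown.

## Numerical choices and degenerate inputs

* Blank frames make Otsu degenerate; segmentation returns empty masks with
  a warning rather than an error.
* Both-constant samples with equal means define the *t* p-value as 1
  (different means: 0).
* Zero-variance rows of the dynamics matrix z-score to zeros and are
  flagged; `cluster_order()` places them last.
* Empty cytoplasm compartments give missing N/C ratios, logged.
* All times in public tables are decimal hours; frame-index/hour conversion
  is confined to the imaging layer, with pixel centres at integer
  coordinates and frame 0 at the first time point.
* One master seed drives everything; per-clone and per-stage seeds are
  derived by a stable polynomial hash kept below \(2^{31}\), so reruns are
  byte-identical.

## Problem sizes used by the tests

The packaged test-suite and the acceptance script run at deliberately
desk-sized conditions chosen to estimate each property with adequate
precision: \(10^4\) random trajectories for the telescoping identity, 1000
random p-vectors for the BH equivalence, 1000 null replicates for test
calibration, a 100-clone × 200-cell panel for bimodality recovery, a
40-clone coupled panel with 1000 label permutations for fate control, three
rendered 12-cell, 49-frame movies for the imaging chain, and a 161/120-cell
pool for the mitosis-timing estimator.

## Known limitations

* The generator's trajectory model is phenomenological; no drug
  pharmacokinetics or mechanism-specific biology is modelled.
* The imaging chain is 2-D, single-position, without drift correction,
  deconvolution or learning-based segmentation; the cytoplasm boundary from
  a second threshold on the nuclear marker is an interpretation, as the
  source does not state how the cytoplasm was delimited.
* Movie-quality filtering of real screens (the step that discards clones
  with unusable movies) is a manual judgement and is out of scope.
* The Welch *t* versus permutation-null bias discussed above is inherent to
  the parametric test at these group sizes.
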