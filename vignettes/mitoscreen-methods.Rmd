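---
title: "mitoscreen: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mitoscreen: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Tandem-tag mitophagy reporters fuse EGFP and mCherry to a mitochondrial
matrix protein. At cytosolic pH both fluorophores emit, so the mitochondrial
network appears yellow; once a mitochondrion is delivered to an acidic
lysosome the EGFP is quenched while mCherry persists, so mitolysosomes
appear as red-only puncta. Counting and sizing those red-only structures per
cell, across thousands of cells per well and hundreds of wells per screen,
turns a qualitative colour change into a quantitative mitophagy readout.
`mitoscreen` implements that computation — calibration, per-pixel ratio
scoring, structure detection, per-cell and per-well statistics, hit calling —
together with a morphology classifier, object-level variants for tissue
imaging, colocalization and interaction-network profiling, and a synthetic
scene generator that provides ground truth for every stage.

## The ratio model

Let $g$ and $r$ be background-corrected green and red intensities. Because
acquisition gains differ between channels, a weight $w$ is first estimated on
*non-mitophagy-inducing control* fields so that mitochondrial pixels are
balanced:

$$\hat w = \operatorname{median}\left\{\, g_i / r_i \;:\; i \in
\text{control mitochondrial pixels} \,\right\}$$

The per-pixel score is then

$$\rho_i = \frac{g_i}{\hat w\, r_i},$$

which is $\approx 1$ on healthy yellow network, $<1$ where red dominates,
and $<0.5$ where red is more than twice as bright as green — the criterion
for a *true* red-only structure. Connected components of
$\{\rho < 0.5\}$ within the mitochondrial-signal mask, at least
`min_structure_area` pixels in size, become structure records, each assigned
to a cell; red-only area and structure count are accumulated per cell.

**Orientation of the ratio.** The protocol this reimplements describes the
score verbally as red divided by green, yet attaches the semantics "~1 is
yellow", "<1 means red stronger than green", and "<0.5 means red twice as
bright as green". Those three statements are only mutually consistent if the
quotient is green over (weighted) red, so that is what `compute_ratio_map()`
computes. We chose the semantics over the literal wording; nothing else in
the pipeline depends on the orientation because calibration makes the two
formulations exact reciprocals.

The median is used for $\hat w$ because controls are never perfectly free of
mitophagy: a small population of quenched pixels drags a mean but not a
median. If more than 15% of control mitochondrial pixels fall below half of
the upper-decile ratio level, calibration warns about a bimodal control — the
signature of mitophagy contamination in the supposed negative control.

Key numerical guards:

* pixels whose weighted red signal is below 1% of its own 99th percentile
  are excluded from classification (`intensity_floor_frac`); ratio of noise
  over noise is meaningless,
* division results that are non-finite are flagged, never propagated,
* a global rescale of the red channel by any $g > 0$ cancels exactly after
  recalibration; the acceptance suite checks that red-only area per cell
  moves by less than 1% for $g \in \{0.5, 1, 2\}$.

## Segmentation

Nuclei are smoothed (Gaussian, $\sigma = 2$ px), Otsu-thresholded, split by
a watershed on the smoothed Euclidean distance transform seeded at distance
maxima, and filtered at `nuclei_min_area` (40 px at the simulated scale).
Cell territories are a generalized Voronoi tessellation: every pixel joins
the nearest nucleus (multi-source growth over the distance transform), with
an optional intensity-weighted watershed variant. The source protocol never
states how cells were delineated for the per-cell statistic; nearest-nucleus
propagation is the standard high-content choice when no membrane stain is
available, and the choice is exposed in `seg_config(cell_assignment = )`.
Mitochondrial signal is segmented from the red channel (the pH-stable tag
marks both network and mitolysosomes) by Otsu or a fixed threshold.

Background correction defaults to a grayscale opening with a flat square
window (van Herk running min/max, radius 25 px $\gg$ structure width)
followed by a light blur of the background estimate — the flat-element
analogue of rolling-ball subtraction. The protocol mentions only
"background noise reduction"; the method and radius are configurable.

## From cells to screen calls

Per well, the screen statistic is the mean red-only area per cell (structure
counts are carried alongside; area is the default because figure legends
quote "red area per cell"). Wells below `qc_min_cells` — default 1000, the
stated screen minimum — are flagged and excluded. Each well is normalised to
the mean of the non-targeting (siNT) control wells of the same plate and
treatment arm, and centred so the control sits at 0:
$\text{fold} = \bar x_{\text{well}} / \bar x_{\text{siNT}}$,
$\text{centered} = \text{fold} - 1$.

Significance is one-way ANOVA-style many-to-one comparison against siNT
with Dunnett familywise adjustment. The adjusted $p$ is the tail
probability of the maximum absolute $t$ statistic across comparisons; we
compute it by seeded Monte Carlo (default $10^5$ resamples of the shared
control mean, per-group means, and pooled $\chi^2$ variance), which
reproduces the equicorrelated multivariate-$t$ structure without quadrature
and is checkable against a brute-force oracle at higher resolution. With a
single comparison the statistic degenerates and the exact pooled two-sample
$t$ $p$-value is returned. The replicate unit is the plate, following the
"n = … plates" convention of screen reporting.

Deconvolution hit calling: a target is confirmed when at least two of its
three oligos are individually significant *with the same direction*.
Direction concordance is our stated decision — the source text says only
"modulated", but every highlighted target moved one way across its oligos —
and the rule is tested exhaustively over all $3^3$ outcome combinations.

## Morphology classifier

Per-cell shape features of the green-channel network: component count, mean
and median component area, total area, mean form factor
($4\pi A / P^2$ with a 4-direction Crofton perimeter; clamped to 1),
mean eccentricity (second central moments), mean solidity (area over
convex-hull area), skeleton length per unit area (Zhang–Suen thinning),
largest-component fraction, and network compactness. The original feature
set (a CellProfiler selection) is not printed anywhere, so this is a stated
superset of standard shape descriptors.

The classifier is a 200-tree random forest (stratified bootstrap per class,
Gini splits, $\sqrt{p}$ features per node) trained on labelled fragmented
versus tubular populations — in the original, DRP1- and OPA1-depleted
cells; here, generator classes. Labels are bound to generator phenotypes,
not to siRNA names, because the source's own description of which siRNA
yields which phenotype is internally inconsistent between sections; the
mapping is the caller's. A stratified 25% holdout yields the per-class
accuracy that mirrors the reported "confusion matrix > 0.90 per phenotype";
the third, clumped phenotype is generated for robustness tests but is not a
trained class, matching the original two-bin design. The forest is
implemented in-package because the execution environment guarantees no
random-forest library; it is deliberately small and deterministic given the
seed.

## Object-level and organism-level variants

For tissue sections the ratio is integrated per structure rather than per
pixel: an object is red-only when
$\sum g / (\hat w \sum r) < 0.5$ over its pixels. The section readout is
the mean red-only count over four 250×250 px grids; window placement is
uniform over all positions fully inside the region of interest,
non-overlapping, seed-controlled, with random restarts before declaring a
region infeasible (the source states the grid count and size but no
placement rule). For discrete-mitochondria tissues the readout is the
percentage of red puncta lacking green colocalization; "lacking" is an
overlap below 25% of punctum area — the source states no cutoff, so the
value is an exposed parameter. The whole-tissue green/red integrated ratio
and the Manders coefficient (fraction of a channel's intensity inside a
reference mask) complete the colocalization toolkit.

## Interaction-network profiles

Candidate genes are profiled by where their direct interaction partners
live: for each compartment, the percentage of first-shell interactors
annotated to it, against a screen-wide baseline that is the unweighted mean
of per-gene percentages over all screened genes with at least one
interactor. MITAB-style tables are reduced to a simple graph (uppercase
symbols, first parsable `locuslink:` alias wins, self-loops dropped,
unordered duplicates merged, all removals counted). We profile direct
interactors rather than whole connected components — the source mentions
both readings; first-shell percentages are the ones its figure annotates
with interactor counts. No enrichment $p$-values are computed because the
source reports descriptive percentages only.

## The synthetic world

`generate_field()` renders what the scoring stage assumes: per-cell
mitochondrial networks (dilated persistent random walks for tubular,
scattered small ellipses for fragmented, nucleus-packed fragments for
clumped), red-only puncta planted at a per-cell Poisson rate with a 2 px
guard ring so planted counts remain resolvable after blur, a green/red
intensity ratio of `redonly_ratio = 0.2` inside puncta (quenching as a
single multiplicative drop — the reporter literature treats the quench as
essentially binary), a red-channel gain of 1.5 so that calibration is
always exercised, background at 120 counts, a Gaussian PSF of
$\sigma = 0.8$ px, Poisson shot noise and Gaussian read noise
(sd 15), all under one seed with bit-identical reproducibility.

Stated-world defaults that the source does not pin down numerically, chosen
once: base signal 2000 counts (mid-range for a 16-bit camera at moderate
exposure), cell radius 24 px and nucleus radius 6 px (U2OS-like at ×20,
~0.3 µm/px), mitolysosome radius 1.8–2.6 px (sub-micron organelles),
control-arm rate 0.3 puncta/cell and a DFP induction factor of 8 (strong
induction over a low basal rate, matching the qualitative contrast of
control versus treated reporter images), per-cell brightness jitter ±20%.
Plate layouts carry planted multiplicative effects; the screen's own "35
fields of view per well" is the layout default in documentation, with
simulations scaled down and the field count always explicit.

What the generator does *not* emulate: spectral bleed-through, 3-D PSFs,
photobleaching, focus drift, cell crowding and overlap, autofluorescence,
or live-cell dynamics. A green test therefore establishes that the
*computations* are correct on images satisfying the model's assumptions —
not that the pipeline is robust to every artefact of real microscopy.
Conversely the planted quantities (counts, areas, rates, class labels,
interaction profiles) are exact, which is precisely what desk verification
needs.

## Verification strategy

Every operation with a closed-form or countable answer is tested against an
independent brute-force oracle (pixel loops for Manders and integrated
ratios, pair-dedup recounts for MITAB, direct means for well aggregation,
raw-data Monte Carlo for Dunnett). Generator-facing operations are tested
against planted ground truth. The acceptance suite runs the six package
criteria at stated scales: classifier per-class holdout accuracy ≥ 0.90 on
≥ 200 cells/class; per-well recovery correlation ≥ 0.95 with an 80%
suppression recovered at −0.8 ± 0.1; gain invariance < 1%; Dunnett
familywise error 0.05 ± 0.01 over $10^4$ null plates and $k=1$ exactness to
$10^{-6}$; oracle equivalences; and the exhaustive deconvolution truth
table. `scripts/acceptance.R` recomputes the reported classifier accuracy
from scratch at every run.

## Known limitations

* Segmentation is 2-D, classical (threshold + watershed), and tuned to the
  synthetic scale; real data will need `seg_config` adjustment.
* The Dunnett adjustment is Monte Carlo: adjusted $p$-values carry
  $O(B^{-1/2})$ noise (default $B = 10^5$, i.e. ±0.002 near $p = 0.05$).
* The TIFF layer covers uncompressed single-channel baseline files only.
* The random forest is adequate for ~10 features and a few thousand cells;
  it is not a general-purpose learner.
* Structure detection near the PSF scale undercounts merged puncta; the
  generator's guard ring documents (not hides) that resolution limit.
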