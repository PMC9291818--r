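---
title: "Quantifying dual stable-isotope NanoSIMS images of mycorrhizal tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dual stable-isotope NanoSIMS images of mycorrhizal tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isopixel)
```

## The measurement and its model

NanoSIMS raster-scans a Cs+ primary beam over a resin-embedded tissue
section and counts sputtered secondary ions per species per pixel. In a
dual 13C/15N pulse-chase labelling of an ectomycorrhizal root tip, the
channels of interest are the diatomic carbon species 12C12C- and 13C12C-,
the nitrogen-bearing species 12C14N- and 12C15N-, monatomic carbon, 31P-
and secondary electrons.

**Carbon isotope fraction.** C2- ions pair two carbon atoms. If atoms pair
independently with a 13C atom fraction $p_C$, the emission probabilities are
$(1-p_C)^2$ for 12C12C- and $2p_C(1-p_C)$ for 13C12C- (13C13C- is not in the
detector configuration). The ratio

$$\mathrm{at\%}^{13}C = 100\cdot\frac{^{13}C^{12}C^-}{2\cdot{}^{12}C^{12}C^- + {}^{13}C^{12}C^-}$$

inverts this model exactly: substituting the expectations gives
$2p(1-p)/(2(1-p)^2 + 2p(1-p)) = p$, an algebraic identity the test suite
asserts. Under non-independent pairing the estimator is a slight
underestimate; we deliberately retain the field's formula rather than
"improving" it.

**Nitrogen isotope fraction.**
$\mathrm{at\%}^{15}N = 100\cdot{}^{12}C^{15}N^-/({}^{12}C^{15}N^- + {}^{12}C^{14}N^-)$.

**Structural signal.** The total CN- image used to visualise anatomy is
corrected for the carbon labelling:
$({}^{12}C^{14}N^- + {}^{12}C^{15}N^-)(1 + R)$ with
$R = {}^{13}C^{12}C^-/(2\cdot{}^{12}C^{12}C^-)$.

**Uncertainty and masking.** Counts are Poisson; at% standard errors come
from first-order (delta-method) propagation, e.g.
$\mathrm{SE}(b/(a+b)) = \sqrt{ab/(a+b)^3}$. Pixels whose ratio denominator
falls below `min_counts` (default 10 counts) are masked rather than imputed
— a ratio of a handful of counts is numerically explosive and
scientifically empty. The threshold trades coverage against variance; at
the instrument's CN- count rates it masks essentially only resin and
background.

**APE.** Atom percent excess subtracts the at% measured on an unlabelled
control section (`control_reference`), globally or per tissue class. APE is
stored signed; display conventions may floor at zero, the data never do.

## Regions of interest and the ratio-of-sums estimator

ROI compositions average species intensities over the ROI's pixels first
and then apply the at% formulas (equivalently: ratios of summed counts).
This "ratio of sums" estimator is additive under ROI merges and much less
biased at low counts than averaging per-pixel ratios; the mean-of-ratios
variant is exposed only for cross-checks, and a hand-computable example in
the tests shows where the two disagree. Tissue summaries report n, mean,
RSD (SD/mean), min and max per tissue x compartment; single-ROI groups get
RSD 0 by convention with a degeneracy flag.

## Mosaics and the N2-adsorption screen

Tiles are stitched by the nearest-tile-centre rule with ties broken toward
the earlier acquisition. Overlapping acquisitions of an already-sputtered
surface are not independent Poisson replicates, so overlap pixels are never
averaged or summed; non-overlap pixels are copied verbatim, making per-tile
count sums conserved (a tested invariant). With the published geometry —
4 x 4 tiles of 512 px / 70 µm and a 20 µm overlap — the overlap is 146 px
and the canvas 1610 px (~220 µm); the acquisition's stated total of
200 x 200 µm is kept as metadata rather than silently reconciled, and the
tile size (reported in places as 50 µm) is configurable with 70 µm as the
default.

Re-measuring an area can deposit adsorbed N2 of natural isotopic
composition, depressing measured at%15N there. `adsorption_qc` compares
each re-measured strip against an equal-width interior band of the same
tile with a one-sided Wilcoxon rank-sum test and flags a strip only when
the depression is both significant (default alpha 0.01) and larger than a
practical threshold (default 5% relative). Pre-sputtered tiles — the
published remedy — are exempt.

The detector's operating characteristics (>= 90% detection of the default
30% injected depression, <= 5% false flags) are established on homogeneous
enrichment phantoms (`uniform_scene_truth`), where the only noise is
counting noise. This is a deliberate choice, and a known limitation: on a
fully tissue-structured scene, cell-to-cell enrichment variation (RSDs near
or above 1) and radial tissue gradients produce strip/band differences of
the same order as the artifact itself, which no label-free strip-versus-band
comparison can separate from a genuine step. The QC therefore always
reports effect sizes and group means alongside flags so that structured
scenes can be judged by eye, exactly as the original diagnosis was made.

## Segmented regression of the C–N coupling

The spatial coupling of APE15N on APE13C across ROIs is biphasic: steep at
low 13C enrichment, flat (or declining) above a breakpoint. `fit_segmented`
fits the continuous two-segment model

$$y = b_0 + a_{low}x + (a_{high} - a_{low})\,(x - BP)_+$$

by profiling the residual sum of squares over 200 breakpoint candidates in
the interior 5–95% quantile range of x (boundary breakpoints are
degenerate), refining the best candidate by iterative linearisation
(gap-variable update) to a 1e-8 tolerance, and polishing with a bracketed
1-D minimisation. Existence of the breakpoint is tested first with a
Davies-type bound on the supremum of the hinge-term t-statistic over
candidate breakpoints; when not significant at alpha = 0.05 the model falls
back to a plain linear fit with the `kink` flag unset — an honest answer
for data that carry no kink. SE(BP) is a nonparametric bootstrap (default
999 resamples, seeded, reproducible); a delta-method SE is not reported
because the profile RSS is only piecewise smooth in BP. "Total" R² is that
of the full segmented fit; low/high R² are per-segment sub-fits, a
documented reading of a summary convention the source material leaves
implicit.

Model selection compares {linear, log-x, log-y, log-log, segmented} by
AIC/BIC. Log-transformed responses are made comparable on the original
scale with the change-of-variable correction
$\log L_y = \log L_{\log y} - \sum \log y$; both corrected and uncorrected
criteria are reported and selection uses the corrected values by default,
with ties broken toward fewer parameters. The segmented candidate counts 5
parameters (intercept, two slopes, breakpoint, residual SD).

Spearman correlations use mid-ranks for ties; the p-value is an exact
permutation enumeration (in C, all n! arrangements) for n <= 10 and the t
approximation otherwise. Line scans aggregate 3 pixels per data point by
default, matching the published profiles, with distances in µm.

## What the synthetic scenes emulate — and what they do not

`generate_root_tip_scene` builds a stylised cross-section: concentric rings
(vascular core, endodermis, cortex, Hartig net, mantle) with a per-tissue
square cell lattice separating cell walls from lumina, and external hyphae
as annulus-wall/disc-lumen discs scattered outside the mantle. Hyphal
geometry is stylised by design: no published geometric model exists, and
rings plus lattice are sufficient to exercise the CW/L statistics and the
two radial patterns. Per cell, APE13C is drawn from a right-skewed
lognormal (most cells barely enriched, matching the reported
three-quarters-below-0.12 skew) and APE15N follows the tissue's biphasic
model plus Gaussian noise. A configurable fraction of hyphae carries the
"wall-co-located" high-enrichment pattern (13C and 15N peaked together in
the outer ring); the rest carry the "centre-15N" pattern (15N in the
lumen, little 13C). A small hot-spot fraction multiplies hyphal draws by a
lognormal factor.

Counts are simulated per pixel and species as independent Poisson draws
from the pairing/split models above, scaled by per-tissue emission rates
(cell walls denser than lumina), dwell time (default 13.5 ms) and
accumulated planes. The adsorption artifact, when enabled, adds
natural-abundance CN- counts at a configurable fraction of the native CN
rate (default 3/7, i.e. a 30% proportional at%15N depression where
enrichment is high) to pixels covered by earlier tiles.

Real NanoSIMS data differ in ways the generator does not model:
instrumental mass fractionation, quasi-simultaneous arrival and dead-time
losses, beam drift, topography, and genuinely irregular cell morphology.
Passing tests therefore demonstrate that the estimators and the pipeline
are correct under the stated counting model — not that the instrument
corrections are unnecessary on real data.

The root-system-scale generator draws per-side segment records from the
published per-side linear models of APE15N on APE13C with residual noise
calibrated in closed form so the population R² matches the published value
($\sigma = \mathrm{sd}(\mu)\sqrt{(1-R^2)/R^2}$). The APE13C distribution is
lognormal with mean 0.84 (amended) / 0.79 (unamended), the values implied
by the published side means through the fitted lines; with the amended
model 0.25x − 0.06 this reproduces the published segment mean APE15N of
0.15 and an SD near 0.16 without further tuning. Root tips are lognormal
with median 0.003 and a very heavy tail (sdlog 3), matching the reported
"most near zero, few large" pattern. Segment dry masses (the weighted-mean
weights; the weighting variable is not named in the source and dry mass is
the natural choice) are lognormal around 15 mg.

For breakpoint-recovery simulations, `simulate_coupling_rois` draws APE13C
from a lognormal(log 0.3, 1.6) truncated at 4.04 — right-skewed, spanning
the observed fungal cell-wall range and keeping the 1.93 breakpoint inside
the interior quantile search window — with R²-calibrated noise around the
published two-segment model (slopes 7.77 / −1.50, n = 1118).

## Pipeline, reproducibility and problem sizes

`run_pipeline` executes scene → counts → mosaic → maps → QC → ROI stats →
segmented fits → root-system table → per-side stats, validating stage
dependencies before touching any file. One global seed deterministically
derives per-stage seeds (`derive_seed`), every output is checksummed into a
JSON manifest, and identical configs give byte-identical runs. Stacks are
stored as multi-page 32-bit TIFF with a JSON sidecar (0-based, row-major,
origin top-left pixel-centred coordinates; stage offsets in µm via the
pixel size); float maps use an affine 32-bit encoding whose quantisation
(~6e-8 at%) is far below counting noise; vendor formats are out of scope
behind this documented conversion contract.

Default problem sizes are chosen so the full suite runs in well under a
minute of CPU: pipeline demonstrations use 2 x 2 mosaics of 96 px tiles;
phantom studies 70–128 px canvases; recovery studies use the published
sample sizes (n = 1118 ROIs; 35/32 segments) with 100–200 replicates.
Larger canvases change nothing but runtime; the estimators operate per
pixel or per ROI.

## Known limitations

* The adsorption QC is characterised on phantoms; on structured tissue its
  flags are conservative by design and should be read together with the
  reported effect sizes.
* The pairing formula assumes independent atom pairing; the control-based
  APE calibration absorbs a constant bias but not a coverage-dependent one.
* Hyphal and cell geometry is stylised; morphometric conclusions should
  not be drawn from synthetic scenes.
* The breakpoint bootstrap resamples ROIs independently, ignoring any
  spatial autocorrelation between neighbouring ROIs of one section.
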