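---
title: "Quantification methods: duplex stability and replication kinetics of modified cytosines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods: duplex stability and replication kinetics of modified cytosines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modkin)
```

# Scope

Cytosine methylation (5mC) stabilizes the DNA double helix; its oxidation
products — above all 5-hydroxymethylcytosine (5hmC) — revert or even invert
that stabilization. A stiffer, higher-melting duplex is harder for the
replication machinery to unwind, so the modification state of DNA feeds
through to helicase and polymerase speed, replication fork progression and
S-phase timing. `modkin` implements the quantification layer of the assay
family used to measure this chain of effects:

1. **HRM melting analysis** — melting temperature (Tm) of modified
   templates from SYBR-green fluorescence ramps;
2. **high-content imaging** — rule-based nucleus/chromocenter segmentation
   and intensity quantification;
3. **RPA accumulation kinetics** — a coefficient-of-variation statistic as
   a live-cell helicase-speed proxy;
4. **DNA fiber combing** — replication fork speed from dual-pulse track
   lengths;
5. **cell-cycle kinetics** — doubling times and S-phase substage durations;
6. **gel densitometry** — band integration and ratio normalization for the
   in vitro polymerization, exonuclease, MNase and reconstituted-replication
   assays;
7. **shared statistics** — the two-group tests and boxplot conventions used
   throughout.

Every assay has a seeded synthetic generator that records its ground truth
(`SimTruth`), so each stage is validated by parameter recovery rather than
by fixtures.

# Melting analysis

## Model

The generators produce two-state melts on the instrument ramp (50–90 °C in
0.1 °C steps):

$$F(T) = b_0 + b_1 T + a\,\theta(T) + \varepsilon,\qquad
  \theta(T) = \frac{1}{1 + e^{(T - T_m)/w}},$$

with additive Gaussian noise. $\theta$ is the fraction of intact duplex; the
transition width defaults to $w = 1$ °C. Default Tm values
(`default_tm_config()`: base 78.0 °C; shifts +1.2 for 5mC, −0.8 for 5hmC,
−0.9 for 5caC, −2.0 for 5fC) are *nominal*: they reproduce the qualitative
stability ordering Tm(5fC) < Tm(5hmC) ≈ Tm(5caC) < Tm(C) < Tm(5mC) and are
config-exposed, never presented as measured values. Sequence-level
(nearest-neighbour) thermodynamics is out of scope.

## Procedure and numerical choices

`normalize_melt()` fits linear pre- and post-melt baselines on the outer 10%
of the grid at each end (the published normalization does not state its
windows; 10% is our default) and rescales to the duplex fraction, clipping
to [0, 1]. Baselines that cross or coincide within the grid — to a relative
tolerance of $10^{-9}$ — mark a degenerate, non-melt curve and are rejected.

`derivative_melt()` averages technical replicates point-wise *before*
differentiation (the reported curves are derivatives of the normalized mean
of technical replicates) and applies a Savitzky–Golay order-3 filter with an
11-point (1.1 °C) window, sign-flipped so melting is a positive peak.

`call_tm()` locates the global maximum of $-dF/dT$ on the grid, ties broken
toward the lowest temperature, with the smoothing margin excluded from the
search and boundary maxima flagged as edge calls. Because the grid argmax of
a smoothed noisy derivative jitters by several grid steps even at 1%
fluorescence noise (the logistic derivative is nearly flat within ±0.3 °C of
its peak), the reported Tm is by default refined to sub-grid precision as
the intensity-weighted centroid of the contiguous derivative region above
half the peak height. The two-state derivative is symmetric about Tm, so the
centroid is unbiased; in practice it recovers true Tm to well within one
0.1 °C grid step at the 1% noise scale. `refine = "none"` gives the literal
grid argmax.

`compare_tm_groups()` reports pairwise mean ΔTm with equal-variance
Student's t-tests on per-replicate Tm calls.

# High-content imaging

Nuclei are segmented in the DAPI channel (Otsu threshold by default,
config-exposed), connected-component labelled, and filtered by the analysis
rule: roundness > 0.8, nuclear area 60–300 µm², no image-border contact.
Roundness is fixed as $4\pi A / P^2$ (the commercial software's definition
is unpublished). The perimeter $P$ is the chain-code length of the traced
8-connected contour times the standard 0.95 smooth-shape correction, which
reproduces analytic ellipse perimeters to 1–2%; roundness is clipped at 1.

Chromocenters are DAPI-bright pixels above a spot threshold (default:
per-nucleus mean + 2 SD) inside a nucleus mask; spots outside every nucleus
are never reported. Intensity sums are raw (whether the original pipeline
background-subtracts its sums is unstated; a background term can be
supplied). Expression binning uses half-open intervals with the lower bound
inclusive — 0–100 (a), 100–500 (b), 500–1000 (c), 1000–2000 (2), 2000–3000
(3), >3000 (4) — since the printed bounds overlap at the joints. The
DAPI-standard-deviation decondensation proxy uses the *population* SD of
nuclear pixels. Fields are 2-D; confocal stacks are assumed
maximum-projected upstream (documented simplification).

The synthetic nucleus field renders ellipses, one per non-overlapping grid
cell, with deliberate fractions clearly passing or clearly failing each
filter (area 80–260 µm² and near-circular vs. 25–45 µm², 330–420 µm²,
aspect ratio ≥ 2.5, or centred on the field edge). The margins around the
filter thresholds are generator design, not tuning: they guarantee the
pixel-level measurement and the analytic truth table agree on every filter
verdict, which is exactly what the recovery tests assert. Real chromatin
texture, optics and PSF blur are not emulated, so passing these tests shows
the *rules* are implemented correctly, not that segmentation would be this
clean on microscope data.

# RPA accumulation kinetics

Under aphidicolin, polymerases stall but the helicase keeps unwinding;
ssDNA-bound RPA accumulates at replication foci and the nuclear RPA signal
becomes more textured. The statistic is the coefficient of variation

$$c_V = \sigma / \mu$$

over all nuclear-mask pixels of a frame (population σ; the original
analysis does not state the σ convention, we fix the population form for
determinism). Trajectories are normalized to the pretreatment frame,
$c_V(t)/c_V(0)$, so every trajectory is anchored at exactly 1, and the
accumulation slope is the OLS coefficient of $c_V^{\mathrm{norm}}$ against
time restricted to 0–20 min (identical to "rise over run" of the fitted
line; the window avoids later plateau phases).

The generator renders a disk nucleus with Gaussian foci (σ = 2 px) whose
amplitude grows linearly, $I(t) = I_0 (1 + r t)$, over a constant diffuse
background $B$ with Gaussian read noise. Because the focal pattern $G$ is
fixed in time, pixel values are $B + s(t) G(x)$ and the cV has the closed
form

$$c_V(t) = \frac{s(t)\,\mathrm{sd}(G)}{B + s(t)\,\overline{G}},$$

exposed as `expected_cv_norm()` — the independent oracle for slope-recovery
tests. The normalized curve is mildly concave, so the fitted 0–20 min slope
sits slightly below $r$ (e.g. 0.042/min at $r = 0.05$/min under the default
$B = I_0 = 100$); recovery is asserted against the closed-form expected
slope, and rank recovery of $r$ across trajectories is essentially perfect.
Whether the published cV used full z-stacks or a projection is unstated; we
compute it on single 2-D frames and reuse the pretreatment mask.

# DNA fiber combing

Tracks are tables of ordered IdU/CldU segment lengths. A track is
*progressing* iff a CldU segment directly follows an IdU segment and the IdU
signal is "clear" — operationalized as IdU length ≥ 1 µm (the original
threshold is unstated; config-exposed). Only progressing tracks yield a
fork speed:

$$\mathrm{RFS} = \frac{\ell_{\mathrm{CldU}}\ [\mu m] \times 2\ [kb/\mu m]}
 {t_{\mathrm{pulse}}\ [min]},$$

with the combing calibration 1 µm = 2 kb and a 15 min default pulse.
Summaries report median/quartiles per genotype and Mann–Whitney contrasts.
The generator draws speeds from a truncated normal (v > 0; mean 1.5 kb/min,
SD 0.3 as a realistic mammalian fork-speed scale) and a 10% mean shift
between genotypes mirrors the reported effect direction; at n = 300 per
group the Mann–Whitney test detects it in essentially every seeded repeat.

# Cell-cycle kinetics

The printed growth-rate expression $\log_2(n_x/n_0)/t$ is doublings per
hour; its reciprocal is reported as the doubling time in hours — the only
reading consistent with multiplying doubling time by phase occupancy.
`doubling_time()` offers the endpoint form and (default) the regression
form, $1/\mathrm{slope}$ of $\log_2(\mathrm{count})$ vs. time, which is
robust to count noise; the two agree exactly on clean exponentials.
Substage durations are doubling time × occupancy fraction, so durations
over all categories partition the doubling time exactly. The substage
vocabulary defaults to stages I–V plus non-S and mitosis (the final label
of the printed staging scheme is a typographical artifact; the number of
substages is config, not guessed). Growth noise is multiplicative
mean-one lognormal, the natural model for count data.

# Densitometry

Lanes are 1-D migration/intensity profiles with named half-open band
windows. Band quantification is trapezoidal integration on the native grid
(no peak fitting) minus a background term: `"linear-endpoints"` (default)
integrates the straight line through the two window-end anchors, each
estimated as the mean of the three outermost points (robust for sloped,
noisy gel backgrounds and exact for linear ones); `"flat"` uses the window
minimum. The original ImageJ background variant is unstated, so both
dialects are provided. Negative net areas clip to 0 with a flag.
Assay-level quantities: ratio-to-control series, the MNase
DNA~monomer~/DNA~total~ ratio (raw integrals, monomer window over whole
lane), the ±DDK replication signal (net area below the end-labelling band,
+DDK minus matched −DDK, normalized to the dC template), and transcript
intensities normalized to a reference full-length signal. Synthetic lanes
are Gaussian bands (integral = specified area) whose windows span ±4σ, so
window truncation contributes < 0.01% bias.

# Statistics

`compare_groups()` implements the two reported tests: the classical
equal-variance two-sample t (Welch behind a flag; whether the original
t-tests were Welch is unstated) and Mann–Whitney–Wilcoxon with mid-ranks,
exact for n ≤ 20 without ties, otherwise the normal approximation with
continuity correction. Both are delegated to the standard R implementations
and hold their nominal 5% level to within Monte-Carlo error at n = 50.
No multiple-testing correction is applied: pairwise p-values are reported
as-is, matching the reporting convention. `summarize_distribution()` fixes
the quartile convention to linear interpolation (type 7) and whiskers to the
most extreme points within 1.5 × IQR of the quartiles.

# Problem sizes and reproducibility

All randomness flows through a single integer seed per generator call; there
is no hidden global state. The default validation sizes — 100 seeds × 4
replicates for Tm recovery, 20 trajectories for slope ranking, 200 repeats
of n = 300/group for fork-speed discrimination, 20 seeded fields of 24
nuclei for the segmentation/truth-table comparison, and 10⁴ null
replicates for test calibration — were chosen so each recovery estimate's
Monte-Carlo error is small against the property being asserted while the
whole suite stays interactive. `scripts/acceptance.R` re-runs the same
computations from scratch for any seed.

# Known limitations

* Generators emulate the *statistical* structure of each readout, not its
  physics: no optics/PSF, no chromatin texture, no gel smile or lane
  distortion, no fiber breakage. Recovery tests therefore validate the
  quantification logic, not robustness to real-world artefacts.
* Tm values are nominal; predicting sequence-specific (salt-corrected) Tm
  is out of scope.
* Image analysis is strictly 2-D and rule-based; no machine-learned
  segmentation.
* Fiber analysis takes track tables as the canonical input; image-to-track
  extraction is not part of the pipeline.
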