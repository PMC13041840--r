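---
title: "p_BOLD: separating BOLD from net-magnetization fluctuations in multi-echo fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{p_BOLD: separating BOLD from net-magnetization fluctuations in multi-echo fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pboldqa)
```

## The problem

An fMRI timeseries mixes two very different kinds of fluctuation. BOLD
contrast — the signal neuroscience cares about — acts through the transverse
relaxation rate R2\* (= 1/T2\*), so its imprint on the measured signal grows
with the echo time TE. Artifacts that change the net magnetization S_o
(head motion, irregular-TR saturation in cardiac-gated protocols, hardware
instabilities) shift the signal by the same *relative* amount at every TE.
Multi-echo acquisitions sample several TEs per repetition and therefore
carry enough information to ask, per scan: *is this data dominated by BOLD
or by S_o fluctuations?* `pboldqa` answers with a single number, p_BOLD in
[0, 1], plus companion QA metrics (TSNR, background thermal noise).

## Signal model

Assuming mono-exponential decay, the gradient-echo signal at voxel x, time
t and echo time TE_i is

S(x, t, TE_i) = S_o(x, t) · exp(−R2\*(x, t) · TE_i) + n(x, t).

Writing S_o and R2\* as temporal means plus deviations (Δρ = ΔS_o/S̄_o,
ΔR2\*) and linearizing for small fluctuations, the signal in
signal-percent-change (SPC) units is

S_{x,i}(t) ≈ Δρ_x(t) − ΔR2\*_x(t) · TE_i.

The Δρ term is TE-independent; the ΔR2\* term scales with TE. Two
consequences for functional connectivity (FC) between regions x and y
computed *across* echoes:

* **Pearson correlation** is invariant to the (positive) per-series scaling
  that TE induces, so FC_r is echo-pair independent in *both* regimes —
  correlation cannot separate them.
* **Covariance** is echo-pair independent only when Δρ dominates; when
  ΔR2\* dominates, C(S_{x,i}, S_{y,j}) ∝ TE_i · TE_j.

## The metric

For a *quadruple* of echo pairs ((TE_i,TE_j), (TE_k,TE_l)) every edge (x, y)
of a parcellation becomes a point whose coordinates are the two across-echo
covariances. S_o-dominated edges land on the identity line; BOLD-dominated
edges land on the zero-intercept line of slope m = TE_k·TE_l/(TE_i·TE_j).
Per edge we compute the Euclidean distances d_So and d_BOLD to the two
lines, label the edge 1 if it is closer to the BOLD line by more than a
tolerance δ, 0 if closer to the S_o line by more than δ, and 0.5 otherwise,
and weight it by its distance to the origin (near-origin edges cannot
discriminate). The quadruple's p_BOLD is the weighted mean label. The scan
value averages all quadruples — Ne(Ne+1)/2 pairs give
P(P−1)/2 quadruples, 15 for three echoes — weighted by the chord distance
2·R·sin(θ/2) (R = 0.5) between the two lines, which is how separable the
hypotheses are for that TE combination.

### Parameters that matter

* **δ (delta), default 1e-3** — the tie band on the distance difference, in
  covariance units of percent-SPC (so, percent²). Its effect is
  scale-dependent: halving the fluctuation amplitude quarters all
  covariances while δ stays put. It is exposed as a parameter for exactly
  that reason.
* **R (chord_radius), default 0.5** — only re-weights quadruples relative
  to one another; any common rescaling cancels in the weighted mean.
* **coverage threshold, default 0.95 (inclusive)** — ROIs with less than
  95% of their voxels inside the field-of-view mask are dropped before
  extraction, since partially covered ROIs have depressed means and
  distorted covariances.
* **symmetrize (off)** — the cross-echo covariance matrix is asymmetric
  (C[x,y; TE_1,TE_2] ≠ C[y,x; TE_1,TE_2]); by default the strictly upper
  triangle of the raw matrix is used, matching the procedure's "top
  triangle" phrasing. The flag averages C with its transpose first. On
  simulated data the difference is small (tested < 0.1).

### Units: percent, not fractional

SPC is defined here as 100·(S − S̄)/S̄. The fractional convention would be
mathematically equivalent *except* that δ and R are fixed constants on the
percent scale: with ~1% fluctuations, fractional-scale covariances are
~1e-4, every edge would fall inside the δ = 1e-3 tie band, and the metric
would degenerate to 0.5 everywhere. On the percent scale typical
within-network covariances are order 0.1–1, commensurate with both δ and
the R = 0.5 chord circle. This was a genuinely open interpretation; the
percent reading is the only one that keeps the published constants
meaningful, so the package adopts it throughout and documents SPC outputs
as percent.

### The printed labelling rule

The source formula for the preference label, read literally, assigns 1 when
the edge is *farther* from the BOLD line (d_BOLD > d_So + δ), which
contradicts the metric's meaning and every regime prediction (pure-S_o data
would score ≈ 1). The package default is closer-line-wins, with the tie
label 0.5 when |d_So − d_BOLD| ≤ δ; the literal orientation is available
behind `literal_eq14 = TRUE` for comparison, never silently.

### Numerical choices

* Edges are the strictly upper triangle (diagonal excluded): variances are
  not connections.
* Within a quadruple, the pair with the smaller TE product is placed on the
  x-axis so m ≥ 1. Swapping the axes reflects every point across y = x and
  inverts m, which leaves d_So, d_BOLD, the label, the weight and hence the
  quadruple p_BOLD unchanged (tested to 1e-12), so the canonicalization is
  harmless.
* θ = |arctan(m) − π/4|; with m ≥ 1 the absolute value is redundant but
  kept for safety.
* A quadruple with equal TE products (m = 1, possible with ≥ 4 echoes)
  gets chord weight 0 and simply drops out of the average; a quadruple
  whose edge weights are all zero is undefined (NA) and is excluded rather
  than imputed, with a warning.
* Covariance uses the sample (Nt − 1) denominator and re-removes temporal
  means even from SPC inputs to bound floating-point drift.
* Zero-variance series yield NA correlations with a warning, never a
  silent 0.

## What the simulator emulates — and what it does not

`simulate_fluctuations()` draws Δρ and ΔR2\* as *independent* zero-mean
Gaussian processes sharing an inter-ROI covariance proportional to a target
network matrix (default: 5 equal blocks, within-block covariance 0.8, none
between — a stereotyped resting-state block structure). `bold_fraction`
fixes, at the reference echo (the second TE, where scan quality is
conventionally reported), the share of fluctuation variance carried by the
R2\* route; the total amplitude defaults to `spc_sigma = 1` (1% of mean
signal), typical of ROI-level resting-state data. The standardized draws
depend only on the seed, so sweeping `bold_fraction` under one seed
compares like with like — which is why the monotonicity test can demand
*strict* increase.

Defaults follow a realistic 3-echo 3T protocol: TEs 13.9/31.7/49.5 ms,
Nt = 500, 50 ROIs. Voxel-level synthesis
(`synthesize_voxel_scan`) evaluates the *nonlinear* decay model with
baseline S̄_o = 1000 and R2\* = 1/40 per ms (T2\* = 40 ms, cortical gray
matter at 3T) and adds Gaussian thermal noise. `apply_tr_jitter` emulates
cardiac gating through a single-compartment T1 steady-state factor
(1 − e^(−TR_t/T1))/(1 − e^(−TR_nom/T1)) − 1 added to Δρ, identical across
echoes — an emulation of the saturation mechanism, not a Bloch simulation.

Not emulated: spatial autocorrelation and draining-vein geometry,
motion-induced spin-history effects, physiological (cardiac/respiratory)
quasi-periodicity, Rician noise statistics (thermal noise is Gaussian; the
linearized theory treats noise as negligible, and the thermal-noise
estimator is additionally characterized on a folded-Gaussian background,
where it recovers sd·√(1 − 2/π)). A green simulation test therefore
establishes that the implementation realizes the theory's predictions, not
that the metric is robust to every failure mode of real data.

## QA companions

* **TSNR**: voxel-wise temporal mean / temporal sd (sample sd). Residual
  inputs get their mean map added back first, so TSNR is always computed on
  detrended data; the summary is the median over the mask, and the
  second-echo median is highlighted.
* **Thermal noise**: the spatial sd over object-free background voxels,
  computed per volume and averaged over time (per-volume computation
  resists slow drifts; the alternative pooled reduction was the open
  choice). Background voxels have temporal mean ≤ 2 (scanner units,
  exposed as `bg_mean_max`) in *every* echo and at most 20 exactly-zero
  timepoints in *any* echo (`max_zero_count`, an absolute count by
  definition, hence also exposed).

## Known limitations

* δ is a fixed additive tolerance on a scale-dependent quantity; comparing
  p_BOLD across datasets with very different fluctuation amplitudes
  requires care (or per-dataset δ).
* The NIfTI layer is a deliberate minimal subset (NIfTI-1, common dtypes,
  sform/qform, gzip) validated against nibabel; exotic files belong in a
  converter first.
* No preprocessing is performed or replicated here: the package scores
  whatever it is given. Scores on raw versus denoised data answer different
  questions.
* ROI-level simulation validates the metric's theory; it does not certify
  behavior on empirical scanner data, which requires real multi-echo
  acquisitions.
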