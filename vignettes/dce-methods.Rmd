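---
title: "Methods: from SPGR signal to follicular vascular phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from SPGR signal to follicular vascular phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovadce)
```

## The problem

During each reproductive cycle only a few ovarian follicles — the dominant
follicles (DF) — are selected for ovulation; the rest (subordinate
follicles, SF) regress. Dominance is accompanied by remodeling of the
vascular network confined to the theca layer around the avascular,
fluid-filled antrum. Dynamic contrast-enhanced MRI with a slowly
extravasating macromolecular agent (an albumin–GdDTPA conjugate of roughly
82 kDa) can resolve this remodeling as three voxel-wise quantities:

* **fBV** — fractional blood volume, the fraction of a voxel occupied by
  plasma carrying the agent;
* **PS** — permeability surface area product (min⁻¹), the rate at which
  agent leaks out of the vasculature, normalized to blood concentration;
* **late enhancement** — the signed rate of concentration change long
  after injection (mM/min), which is positive in DF antra (slow
  interstitial convection of extravasated agent into the cavity) and
  zero-to-negative in SF antra (plateau followed by clearance).

The package implements the full chain from raw spoiled gradient-echo
(SPGR) signal to these maps, the ROI statistics built on them, and a
digital phantom that validates every stage by parameter recovery.

## Signal model and relaxometry

The steady-state SPGR signal at flip angle $\alpha$ and repetition time
$TR$ is

$$I(\alpha) = M_0 \sin\alpha \; \frac{1 - E}{1 - \cos\alpha\, E}, \qquad
  E = e^{-TR \cdot R_1},$$

where $M_0$ absorbs spin density, coil sensitivity and the fixed-TE
$T_2^*$ weighting — the package does not model $T_2^*$ separately. The
pre-contrast relaxation rate $R_{1,\mathrm{pre}}$ and $M_0$ are fitted per
voxel from a variable flip-angle (VFA) set — by default the schedule
5°, 15°, 30°, 50°, 70° at $TR = 10$ ms — by nonlinear least squares.

Numerically, `fit_r1_vfa()` runs a damped Gauss–Newton
(Levenberg–Marquardt) iteration *simultaneously over all voxels*: the
$2 \times 2$ normal equations have a closed-form solution per voxel, so
the whole volume is fitted with vectorized array arithmetic rather than a
per-voxel solver loop. The iteration is seeded by the classical
linearization (regressing $I/\sin\alpha$ on $I/\tan\alpha$, whose slope is
$E$), which is exact on noiseless data, and $R_1$ is constrained to
$[0.05, 20]$ s⁻¹. After convergence the amplitude is closed with the
exact linear least-squares $M_0$ given $R_1$. Voxels whose maximum VFA
signal falls below a floor (default 2% of the volume's 99th-percentile
signal — an arbitrary but echoed masking rule) or whose fit fails are
flagged invalid, never raised as errors.

Post-contrast $R_1(t)$ comes from the ratio of each dynamic frame to the
pre-contrast image at the same flip angle (15° by default, taken from the
VFA set). Since $M_0$ cancels in the ratio, the inversion is closed-form
(`invert_r1_post()`); ratios that would push $E_{\mathrm{post}}$ outside
$(0,1)$ are non-physical and yield `NA`. Concentration follows from the
agent's longitudinal relaxivity $r_1$ (measured per batch; a required
input, units mM⁻¹s⁻¹):

$$c(t) = \frac{R_{1,\mathrm{post}}(t) - R_{1,\mathrm{pre}}}{r_1}.$$

Negative concentrations produced by noise are deliberately retained —
clamping at zero would bias ROI histograms and regression slopes.

## Kinetic maps

For a macromolecular agent the tissue concentration over the first
quarter hour is well approximated as linear in time:
$c(t) \approx fBV \cdot c_{b}(t) + PS \cdot c_{b0} \cdot t$. Per voxel,
`fit_vascular_params()` regresses $c(t)$ on $t$ over the **early window**
(default the first 15 min post-injection, frames selected by
closed-interval membership of their nominal times) and normalizes by the
initial blood concentration $c_{b0}$:

$$fBV = \frac{\hat c(0)}{c_{b0}}, \qquad PS = \frac{\widehat{dc/dt}}{c_{b0}}.$$

$c_{b0}$ is a per-dataset scalar, either supplied explicitly or estimated
by `estimate_blood_reference()` as the $t = 0$ extrapolation of the
early-window regression of a blood-pool ROI mean. The one-minute bolus is
treated as instantaneous — an approximation that matters only below the
first frame time. No non-negativity constraint is applied to fBV or PS;
negative estimates are QC-flagged (`qc_negative`).

The **late window** (default 25–35 min) yields the signed late
enhancement rate as a per-voxel OLS slope (`fit_late_enhancement()`).
Before late-rate mapping, `apply_spike_threshold()` excludes voxels whose
concentration exceeds 10 mM in any frame — an observation-cleaning rule
targeting reconstruction spikes, intentionally *not* applied to the
fBV/PS fit — and reports the excluded fraction, expected to be well under
5% of ROI voxels.

## ROI statistics and the DF/SF rule

`roi_histogram()` bins a map over a stated range — conventionally
0–0.1 (or 0–0.5) for fBV and 0–0.02 min⁻¹ for PS, in 50 bins —
left-closed/right-open with the last bin closed; out-of-range voxels are
counted, never dropped, so counts plus out-of-range always equal the
number of valid ROI voxels. Percentages use that same denominator
(invalid voxels are tracked separately as `n_missing`).
`compare_histograms()` runs a two-sided Student's t-test per bin on the
per-subject percent values, unpaired or paired. No multiple-testing
correction is applied by default — the per-bin $p < 0.05$ convention is
preserved — but any `p.adjust` method can be requested and is recorded in
the output. Zero-variance bins are flagged degenerate rather than
crashing. `aggregate_subject()` averages the two ovaries of an animal so
each animal contributes one value, and `compare_roi_groups_paired()` is
the paired t-test on matched per-subject means with explicit handling of
the zero-variance degenerate case ($p = 1$ for identical groups, flagged).

`classify_follicle()` encodes the discrimination rule: a follicle ROI
with **low PS and positive late enhancement** is called DF; **high PS
with zero-or-negative late enhancement** is called SF; anything else is
indeterminate. No absolute PS cutoff exists for this rule, so
`classify_follicles()` defaults the threshold to the median ROI-mean PS
across the candidate follicles of a dataset — a within-cohort separation
— with the late threshold at 0 mM/min; both thresholds are echoed in
every call so classifications are reproducible.

## The digital phantom

`build_phantom()` realizes an ovary-like geometry on a grid (default
64³ voxels of 0.117 × 0.117 × 0.5 mm): spherical follicles placed by
rejection sampling (bounded retries, whole-configuration restarts, then a
geometry error), each an avascular antrum (fBV = 0) wrapped in a
vascularized shell of configurable thickness; corpus-luteum (CL) objects
are filled spheres with elevated fBV; a small corner block with fBV = 1
serves as the blood-pool reference. Compartment ground truth:

| compartment | fBV | PS (min⁻¹) | late rate (mM/min) | R1pre (s⁻¹) |
|---|---|---|---|---|
| stroma | 0.02 | 0.005 | +0.0025 | 0.70 |
| DF shell | 0.04 | 0.002 | +0.001 | 0.75 |
| SF shell | 0.04 | 0.010 | −0.003 | 0.75 |
| CL body | 0.15 | 0.002 | +0.001 | 0.80 |
| DF antrum | 0 | 0.0005 | +0.020 | 0.35 |
| SF antrum | 0 | 0.004 | −0.003 | 0.35 |
| blood pool | 1.00 | 0 | 0 | 0.45 |

These are stated study conditions, not measured values: DF shells are
tight (low PS) and SF shells leaky, with equal fBV, so the discriminating
signal is permeability; the CL has markedly higher blood volume at
DF-like permeability; SF compartments plateau early then clear shallowly
enough that concentration never goes negative by 35 min. Plasma
concentration defaults to a constant 1 mM over the 35-min follow-up —
appropriate for an 82-kDa agent whose circulation half-life far exceeds
the experiment — with a monoexponential option for robustness tests. The
dose-to-molarity conversion for the real agent is not derivable from mass
concentration alone, hence the configurable round 1 mM default.

`simulate_concentration()` applies the linear early model and hands over
to each compartment's late rate at 20 min through a linear cross-fade
over 18–22 min: the analysis windows end at 15 and start at 25 min, so
the cross-fade shape between them is immaterial to recovery while keeping
every voxel's time course continuous. `simulate_acquisition()` pushes
truth through the SPGR equation (VFA set at $R_{1,\mathrm{pre}}$; dynamic
frames at $R_{1,\mathrm{pre}} + r_1 c(t)$, ~2-min cadence over 35 min)
and adds seeded noise last, on *signal* rather than concentration:
Gaussian by default, Rician optionally, with standard deviation expressed
as a fraction of the peak noiseless dynamic signal. At the SNRs of
interest (> 20) the Rician mean shift is below 0.5% of signal, which the
test suite verifies on a constant-signal phantom.

What the phantom does **not** emulate: realistic (non-spherical) anatomy,
partial-volume mixing at compartment boundaries, motion, B1
inhomogeneity, slice-profile effects, or a measured arterial input
function. Passing recovery tests therefore demonstrates the correctness
of the estimation chain under its own model assumptions — not robustness
to the physiological and hardware confounds of in-vivo data.

## Validation problem sizes

The shipped tests and the acceptance script validate with: noiseless VFA
inversion on 400 voxels over $R_1 \in [0.2, 5]$ s⁻¹ (max relative error
at solver precision, ~10⁻¹⁴); closed-form post-contrast inversion vs. a
bracketed root-finder on 60 seeded conditions (agreement ~10⁻¹³); full
noiseless 64³-phantom recovery of fBV and PS on theca-shell voxels (max
relative error < 10⁻³, achieved ~10⁻¹³); ROI-mean bias < 5% at 1%
Gaussian noise (achieved < 1.1% across seeds); DF/SF classification on
24³ two-follicle phantoms — 100% correct noiseless and ≥ 90% across 50
seeded replicates at 2% noise (achieved 100%); and 200-replicate power of
the paired PS comparison at $n = 5$ pairs with DF 40% below SF under 10%
noise (≥ 95%, achieved ~99.5%).

## Numerical and design choices

* **Units** are normalized at the boundary (`acq_params()`): TR seconds,
  times minutes, $R_1$ s⁻¹, PS min⁻¹, concentration mM. Configs accept
  `tr_ms`.
* **Frame selection** uses closed intervals on nominal frame times;
  shrinking the early window on exactly-linear data leaves fBV/PS
  unchanged (tested).
* **Determinism**: all stochastic steps (geometry, noise, Monte-Carlo
  studies) are seeded; reruns of the pipeline on identical inputs write
  byte-identical files, which the suite checks by checksum.
* **fBV histogram range**: both conventional ranges (0–0.1 and 0–0.5)
  are supported; the range used is echoed in the result object.
* **Mixed-effects group models** (treatment fixed; animal and ovary
  random) are deliberately out of scope as bespoke code: per-animal
  aggregation plus paired t-tests are implemented here, and an
  `lme4::lmer(value ~ group + (1 | animal))` call on the per-ovary table
  is the documented route for users who need the random-effects
  formulation.

## Limitations

The analysis assumes the early time course is linear — valid for slowly
extravasating macromolecular agents, not for low-molecular-weight
contrast media, which need compartmental (Tofts-type) modeling that this
package intentionally omits. The blood reference is a per-dataset scalar;
per-voxel input functions, deconvolution and flow estimation are out of
scope. ROI masks are taken as given: no registration or segmentation is
performed.
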