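# ovadce

Quantitative DCE-MRI mapping of ovarian follicular vasculature with a
macromolecular contrast agent.

In each reproductive cycle only a few ovarian follicles — the dominant
follicles (DF) — are selected for ovulation, while subordinate follicles
(SF) regress. Selection is accompanied by remodeling of the capillary
network in the theca layer that surrounds the avascular antrum. Dynamic
contrast-enhanced MRI with a slowly extravasating albumin–GdDTPA
conjugate resolves this remodeling voxel by voxel, and `ovadce`
implements the complete analysis chain for such data, aimed at
researchers quantifying vascular function in small-animal DCE-MRI.

## The model

Pre-contrast T1 is mapped from variable flip-angle (VFA) spoiled
gradient-echo images via the SPGR signal equation

    I(α) = M0 · sin α · (1 − E) / (1 − cos α · E),   E = exp(−TR · R1),

fitted per voxel by a vectorized Levenberg–Marquardt solver. Post-contrast
R1(t) follows in closed form from the ratio of each dynamic frame to the
matching-flip-angle pre-contrast image (M0 cancels), and concentration
from the agent's relaxivity: c(t) = (R1post(t) − R1pre) / r1.

Linear regression of c(t) then yields three maps:

- **fBV** = ĉ(0) / cb0 — fractional blood volume, the early-window
  intercept extrapolated to injection time, normalized to the initial
  blood concentration;
- **PS** = (dc/dt)_early / cb0 (min⁻¹) — permeability surface area
  product, the early accumulation rate normalized the same way
  (early window: first 15 min post-injection);
- **late enhancement rate** (mM/min) — the signed OLS slope over
  25–35 min, after excluding voxels spiking above 10 mM; positive in DF
  antra (continued accumulation), zero-to-negative in SF antra (plateau
  then clearance).

ROI tooling includes 50-bin fixed-range histograms with per-bin t-tests,
per-animal averaging of paired ovaries, paired group comparisons, and the
two-parameter DF/SF classification rule (low PS + positive late
enhancement ⇒ DF; high PS + non-positive late enhancement ⇒ SF). A
digital ovary phantom with known ground truth (vascularized shells around
avascular antra, filled corpora lutea, a blood-pool reference block)
validates every stage by parameter recovery; see the methods vignette
(`vignettes/dce-methods.Rmd`) for the full account.

## Worked example

Simulate a noisy two-follicle phantom, run the full pipeline, and
classify the follicles:

```r
library(ovadce)

acq <- acq_params(flip_angles = c(5, 15, 30, 50, 70), tr_ms = 10,
                  frame_times = seq(1, 35, by = 2), relaxivity_r1 = 3.3)
spec <- phantom_spec(grid_shape = c(32, 32, 32), n_follicles = 2,
                     follicle_kinds = c("DF", "SF"), radius_range = c(4, 5),
                     noise_sigma = 0.01, seed = 42)
truth <- build_phantom(spec)
sim <- simulate_acquisition(truth, simulate_concentration(truth), acq)

cfg <- as_pipeline_config(list(
  acquisition = list(tr_ms = 10, flip_angles_deg = c(5, 15, 30, 50, 70),
                     dynamic_flip_angle_deg = 15,
                     frame_times_min = sim$dynamic$frame_times,
                     relaxivity_per_mM_s = 3.3)))
res <- run_pipeline(cfg, vfa = sim$vfa, dynamic = sim$dynamic,
                    blood_roi = truth$label_volume == 3)
res
#> DCE-MRI pipeline result
#>   cb0: 1.01483 mM; valid voxels: 32768; spike-excluded fraction: 0.0000
#>   ovary means: fBV 0.0223, PS 0.00490 min^-1, late rate 0.00253 mM/min

classify_follicles(res$vmaps, list(f1 = truth$follicle_id == 1,
                                   f2 = truth$follicle_id == 2))
#> $f1
#> follicle_call f1: DF (mean PS 0.00146 min^-1 vs 0.00464; mean late rate 0.00784 mM/min vs 0.00000)
#> $f2
#> follicle_call f2: SF (mean PS 0.00782 min^-1 vs 0.00464; mean late rate -0.00297 mM/min vs 0.00000)
```

The blood reference extrapolated from the phantom's blood-pool block
(1.015 mM) recovers the simulated 1 mM injection concentration to 1.5%
despite 1% acquisition noise; the DF is called by its low permeability
(0.0015 min⁻¹, below the cohort-median threshold 0.0046) together with
positive late antral enhancement, the SF by the opposite pattern.
`run_pipeline(..., out_dir = "maps/")` additionally writes the fBV / PS /
late-rate NIfTI maps, QC masks, histogram CSVs and a JSON provenance
report. A thin command-line wrapper for simulation and pipeline runs is
installed at `inst/cli/ovadce.R`.

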