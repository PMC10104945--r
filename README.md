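# tdistrain

Automated myocardial deformation imaging from colour tissue Doppler (TDI)
recordings of the left ventricle, with a synthetic phantom for validation.

## What it does, and for whom

Strain echocardiography quantifies regional myocardial function: a
normally contracting segment shortens about 18% in systole (strain
-18%), while ischemic segments shorten less and often keep shortening
*after* aortic valve closure (post-systolic shortening, a marker of
ischemia). TDI measures tissue velocity along the ultrasound beam at high
frame rates, but reading its deformation curves by hand is slow and
operator-dependent. This package implements a fully automated TDI
pipeline, intended for researchers developing or evaluating automated
strain analysis:

1. mid-wall contours traced in the three standard apical views (A4C, A2C,
   APLAX) are **tracked** through the cardiac cycle using the along-beam
   velocity field (explicit Euler, bilinear resampling);
2. assuming a 60° rotation between views, the six tracked walls are
   interpolated circumferentially by **periodic cubic splines** into a 3D
   mesh; **aortic valve closure (AVC)** is detected as the smallest
   reconstructed cavity volume;
3. the **AHA 16-segment model** is applied (apex-most quarter of the
   apical third discarded), and per segment the strain rate
   `SR = (v_far − v_near)/L` is integrated into Lagrangian strain
   `ε(t) = exp(∫₀ᵗ SR dτ) − 1`, smoothed over 5 frames;
4. peaks are extracted in guarded windows — peak systolic strain over
   `[cycleStart, AVC)`, peak systolic SR over `[8%, 50%)` of systole,
   post-systolic peak over `[AVC + 90 ms, mid-diastole)` — and the
   **post-systolic index** is

   `PSI = 100 · (peak cycle strain − end-systolic strain) / peak cycle strain`;

5. strain below −25% or above +5% is flagged as noise and an area
   fraction of noisy myocardium is reported; segment values are averaged
   into LAD/CX/RCA **coronary territories** and global values (GLS), and a
   cohort layer evaluates occlusion discrimination by rank AUC (bootstrap
   CI) and Welch's t-test.

A synthetic left-ventricle phantom (half-ellipsoid geometry, prescribed
segmental strain curves, Doppler beam projection, Gaussian velocity noise,
reverberation bands) generates complete three-view studies with ground
truth, so the entire chain is testable without clinical data. See the
methods vignette (`vignettes/tdi-strain-methods.Rmd`) for the full model
account.

## Worked example

```r
library(tdistrain)

# a noiseless phantom with an ischemic LAD territory:
# LAD segments shorten to only -8% and show 8% post-systolic shortening
study  <- generatePhantom(phantomConfig(noiseSd = 0),
                          ischemicKinematics("LAD"))
report <- runPipeline(study, pipelineConfig())
report
#> StudyReport
#>   GLS -13.5 %  global SR -0.65 1/s  global PSI 19.1 %  noise area 0.0 %
#> CardiacTiming: cycle [1000, 2000) ms, AVC 1350 ms (systole 350 ms), mid-diastole 1675 ms

territoryTable(report)
#>   territory peakSystolicStrain peakSystolicSR      psi n
#> 1       LAD          -7.590143     -0.3548223 50.98948 6
#> 2        CX         -17.118589     -0.8342537  0.00000 5
#> 3       RCA         -17.092805     -0.8330590  0.00000 5
```

The LAD territory is recovered at about −7.6% strain with PSI ≈ 51%
(ground truth from the prescribed curves: −8% and 50%), while the
non-ischemic territories sit near −17% with PSI 0 — the slight
underestimation versus the prescribed −18% is the beam-angle dependence
inherent to TDI, reproduced by design. Detected AVC (1350 ms) equals the
phantom's true valve closure. A cohort-level evaluation:

```r
co <- runCohort(nNormal = 30, nOccluded = 10, culprit = "LAD", seed = 1)
subset(co$evaluation, metric %in% c("strain_LAD", "psi_LAD"))
#>       metric auc ciLo ciHi        t            p meanOccluded    meanOpen
#> 1 strain_LAD   1    1    1 121.6396 2.089945e-22    -7.573382 -17.3438992
#> 3    psi_LAD   1    1    1 122.5490 6.425127e-16    52.928028   0.1948417
```

Command-line use (`exec/tdistrain`): `tdistrain phantom --out DIR`,
`tdistrain analyze --study DIR --out DIR`, `tdistrain evaluate`,
`tdistrain validate`, with `--config FILE` for a JSON pipeline
configuration and `--version`.

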