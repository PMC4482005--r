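# fallwav

Wavelet-based fall detection from body-worn tri-axial accelerometry.

Automatic fall detectors for older adults must tell the brief, violent
signature of an impact apart from the everyday transients of walking,
sitting down, or bumping into things. `fallwav` implements a
pattern-matching approach to this problem: instead of thresholding simple
impact statistics, it learns a *prototype fall* from training data and
scores every recording by its similarity to that prototype under a
continuous wavelet transform (CWT).

The package is aimed at researchers in wearable sensing and digital health
who want a self-contained, testable reference implementation of the
adapted-wavelet similarity feature, its classic baselines, and a
cross-validated ROC evaluation — plus a seeded simulator so the entire
pipeline runs without access to (rare, sensitive) real-world fall
recordings.

## The method

All analysis operates on the acceleration sum vector
`SV(t) = sqrt(ax² + ay² + az²)` in units of g, which rests near 1 g and
shows, during a fall, a dip toward free fall followed by a sharp impact
peak and damped ringing.

1. **Prototype (model fitting).** For each training fall, the 2-s window of
   SV centered on its global peak is extracted; the windows are averaged
   sample-wise into the mean fall pattern. The pattern is converted into an
   *adapted mother wavelet* Ψ_fall on [0, 1]: mean-subtracted, end-tapered,
   constrained to zero integral (wavelet admissibility) and unit L2 norm.
2. **Similarity score.** A recording is scanned; every sample with
   SV > 1.5 g seeds a candidate 2-s window. For each candidate the CWT
   coefficients

   C(a, b) = (1/√a) ∫ SV(t) Ψ_fall((t − b)/a) dt

   are evaluated on the restricted box a ∈ [1.5 Fs, 2.5 Fs] (the prototype
   spans 2 s, so a self-similar input matches at a = 2 Fs) and
   b ∈ [0.5 Fs, 1.5 Fs] (near the window center, avoiding border effects).
   The feature is the maximum coefficient over all candidates, clipped at
   zero; recordings that never cross the trigger score exactly 0.
3. **Baselines.** UPV (upper peak value, the SV maximum) and LPV (lower
   peak value, the free-fall minimum just before the peak).
4. **Evaluation.** Stratified 10-fold cross-validation with per-fold
   refitting of Ψ_fall; fold ROCs averaged vertically on a specificity grid
   of step 0.001; AUC, the maximum Youden index (sensitivity +
   specificity − 1) with its operating point, false-alarm rates, and paired
   exact Wilcoxon signed-rank comparisons with Bonferroni correction.

## Worked example

```r
library(fallwav)

# a synthetic study: 29 one-minute falls, 200 active ADLs, 100 Hz
ds <- simulate_dataset(sim_config(seed = 1))

fw <- fall_wavelet(ds)      # fit the prototype on the falls
fw
#> Adapted fall wavelet
#>   trained on 29 fall(s), 2-s peak-centered windows @ 100 Hz
#>   conversion: direct, 200 grid points on [0,1]

predict(fw, ds$recordings[[1]])    # wavelet similarity of one recording
#> [1] 5.91482

ev <- evaluate_features(ds, n_folds = 10, seed = 1)
ev
#> Cross-validated fall-detection evaluation (10 folds, seed 1)
#>   wavelet AUC 0.907 [0.815, 0.998] | max YI 0.733 [0.649, 0.971] | sens 73.3% spec 100.0%
#>   upv     AUC 0.820 [0.687, 0.953] | max YI 0.633 [0.550, 0.910] | sens 73.3% spec 90.0%
#>   lpv     AUC 0.790 [0.692, 0.888] | max YI 0.483 [0.535, 0.772] | sens 68.3% spec 80.0%
#>   paired Wilcoxon (Bonferroni m = 2 per metric):
#>     wavelet vs upv (auc): p = 0.01562 *
#>     wavelet vs lpv (auc): p = 0.03906
#>     wavelet vs upv (yi): p = 0.03125
#>     wavelet vs lpv (yi): p = 0.09375
```

The wavelet similarity separates falls from daily activities better than
either impact-magnitude baseline: its cross-validated AUC is 0.907 against
0.820 (UPV) and 0.790 (LPV), and at its best operating point (maximum
Youden index) it detects 73% of falls while rejecting every ADL in this
simulated cohort. `plot(ev)` draws the three averaged ROC curves;
`plot(fw)` shows the averaged fall pattern and the adapted wavelet.

A command-line interface wraps the same functions:

```sh
Rscript -e 'fallwav::fallwav_cli()' simulate --n-falls 29 --n-adls 200 --seed 1 --out data/
Rscript -e 'fallwav::fallwav_cli()' build-wavelet --manifest data/manifest.csv --out wavelet/
Rscript -e 'fallwav::fallwav_cli()' score --manifest data/manifest.csv --wavelet wavelet/wavelet.csv --out scores/
Rscript -e 'fallwav::fallwav_cli()' evaluate --manifest data/manifest.csv --seed 1 --out eval/
```

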