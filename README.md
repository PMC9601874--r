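# wscec

Training-free classification of single-lead ECG heartbeats by the
**Wasserstein scalar curvature** of their local-covariance point clouds.

## The problem

Automated arrhythmia screening usually means either hand-crafted signal
features or a trained network. `wscec` takes a third route aimed at small,
imbalanced cohorts: it computes a *geometric invariant* of each beat and
classifies by fixed rectangles in a two-dimensional feature plane — no
training samples, no fitted weights, every step a closed-form computation.

## The method

For a denoised 300-sample beat $T$ at 360 Hz:

1. **Sliding-window FFT embedding.** Windows of length $l = 10$, step
   $\tau = 1$; window $k$ maps to
   $\frac{2}{l}(a_0^k, a_1^k, b_1^k) \in \mathbb{R}^3$, where
   $C_j = a_j + i b_j$ are its DFT coefficients. The beat becomes an
   ordered cloud of 289 points.
2. **Local Gaussian statistics.** Each point is replaced by the
   unnormalised scatter of its $k = 20$ nearest neighbours,
   $\Sigma_i = \sum_j (N_{ij}-\mu_i)^\top(N_{ij}-\mu_i)$, yielding a point
   cloud on the SPD manifold.
3. **Bures–Wasserstein scalar curvature.** On $\mathrm{SPD}(n)$ with the
   optimal-transport metric
   $g_W|_S(X,Y) = \frac12\mathrm{tr}(\Gamma_S[Y]X)$
   ($S\Gamma_S[Y]+\Gamma_S[Y]S = Y$), the scalar curvature at each scatter
   matrix is a spectral invariant with
   $0 < \rho(S) < 3n(n-1)/\lambda_{\min 2}(S)$ and
   $\rho(cS)=\rho(S)/c$. It magnifies the fine local structure of the
   cloud: fast QRS sweeps give large scatters and small curvature.
4. **Histogram dispersion.** The curvature sequence is binned with width
   $m$ up to a ceiling $b = \min(\max \rho(T_s),\, 3d(d-1)/\epsilon)$ fixed
   once from a standard normal beat $T_s$ ($= 200$ at the defaults
   $d = 3$, $\epsilon = 0.09$). A beat is summarised by
   $(\mathrm{cur}_1, \mathrm{cur}_2)$: the median of the in-range
   curvatures and a corrected standard deviation of the histogram columns.
5. **Symptom-domain partition.** Fixed rectangles in the
   $(\mathrm{cur}_1, \mathrm{cur}_2)$ plane assign
   normal / atrial-abnormal / ventricular-abnormal / bundle-branch-block /
   unclassified, with fine labels (`N`, `A.P.`, `V.F.`, `F.V.N.`,
   `P.V.C.`, `L.B.B.B.`, `R.B.B.B.`) where subdomain boxes do not overlap.

The package also ships the preprocessing chain (zero-phase Butterworth
low-pass at 50 Hz, adaptive R-peak search, beat segmentation), a
brute-force curvature oracle used to validate the closed form, a seeded
synthetic PQRST generator for seven rhythm classes, and per-class
TPR/NRR/PPV/F1 scoring.

## Worked example

Classify 20 synthetic normal beats and compare their dispersion with a
widened-QRS (left bundle-branch-block-like) batch:

```r
library(wscec)
batch <- function(cl) lapply(1:20, function(i) generate_beat(beat_spec(cl, seed = i)))
normal <- run_wscec(batch("N"))
lbbb   <- run_wscec(batch("L.B.B.B."))
print(normal)
#> Curvature-dispersion classification of 20 beats (b = 200):
#>
#>               normal ventricular_abnormal
#>                   19                    1
#> Classification metrics over 20 beats:
#>                 class original_size classified_size intersection tpr nrr ppv
#>                normal            20              19           19  95  NA 100
#>  ventricular_abnormal             0               1            0  NA  95   0
#>     f1
#>  97.44
#>   0.00
```

The ceiling `b = 200` is the analytic cap $3d(d-1)/\epsilon$: the standard
beat's flat stretches contain degenerate neighbourhoods whose curvature
exceeds it. 19 of 20 normal beats land in the normal box. The directional
structure the method rests on — transverse dispersion shrinks and
longitudinal dispersion grows as the QRS widens — shows directly:

```r
mean(normal$features$cur1); mean(lbbb$features$cur1)
#> [1] 35.0   # normal
#> [1] 27.3   # widened QRS
mean(normal$features$cur2); mean(lbbb$features$cur2)
#> [1] 1.42
#> [1] 3.91
```

Absolute synthetic dispersion values are not expected to match the default
domain boxes, which reflect a clinical-recording calibration; see the
vignette (`vignettes/curvature-dispersion.Rmd`) for what the generator does
and does not emulate, and `read_partition()` for recalibrated boxes.

A continuous record goes through `preprocess_signal()` first, or use the
thin CLI in `inst/cli/wscec`:

```sh
Rscript inst/cli/wscec synth --classes N:50,L.B.B.B.:20 --seed 7 --out synthdir
Rscript inst/cli/wscec run --input synthdir/record.csv --fs 360 --out outdir
```

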