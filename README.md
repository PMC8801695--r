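# kernelconvert

Deep-learning reconstruction-kernel conversion for quantitative chest CT.

## The problem

CT raw data become images through a reconstruction kernel. Sharp kernels
(FC51-style) enhance edges for visual reading at the cost of noise; soft
kernels (FC13-style) suppress both and are what density-based
quantification needs. Many archives keep only the sharp-kernel thin-slice
series, so standard quantitative indices cannot be computed reliably from
what remains:

* **LAV%** — emphysema low-attenuation volume: lung voxels < −950 HU;
* **IMAT%** — intramuscular adipose tissue: muscle voxels < −30 HU;
* **CAC volume** — coronary calcium: coronary-ROI voxels > 130 HU × voxel
  volume.

`kernelconvert` converts sharp-kernel volumes into soft-kernel-like
volumes (and the reverse) by paired image-to-image translation, for
researchers who need to reuse archived sharp-kernel CT in quantitative
studies.

## The method

Matched slice pairs (every other 0.5 mm sharp slice aligned to each 1.0 mm
soft slice by nearest physical location) train a residual
encoder–bottleneck–decoder network: three stride-2 down-sampling layers,
nine residual bottleneck blocks, three up-sampling layers with additive
skip connections, instance normalisation and ReLU after every convolution
except the last, and a final arctan activation that confines the output to
the model's HU window. Training minimises the combination of the absolute
and the squared errors, `L = mean|ŷ − y| + mean((ŷ − y)²)`, in a
normalised space where `[window_lo, window_hi] → [−1, 1]`.

Because conversion accuracy deteriorates in the mid-HU band
(−200..200 HU), a second *partial* model is trained on the same pairs
truncated to −300..300 HU, and the final image is a HU-dependent weighted
sum

```
I_final(x) = w · I_partial(x) + (1 − w) · I_full(x)
```

where `w` is 1 on [−170, 170] HU, 0 outside [−230, 230], and linear on the
60-HU ramps. Conversion error is judged against the scanner's own
inter-scan variability, measured from six repeated phantom scans
(deviations of each scan from the voxelwise mean), profiled in HU bands
[−1000,−600), [−600,−200), [−200,200), [200,600), [600,1000) and
[−1000,1000). Classical Gaussian- and median-filter conversions
(parameters calibrated by MSE grid search on the training pairs) serve as
baselines, and agreement of LAV%/IMAT%/CAC between converted and
ground-truth images is summarised by Bland–Altman bias and 95% limits of
agreement.

A synthetic paired-kernel simulator (thorax-like piecewise-constant
phantoms; soft kernel = 1.5 mm FWHM Gaussian smoothing + 4 HU noise; sharp
kernel = radial high-boost filter `1 + 1.5 (f/f_Nyq)²` + 10 HU noise;
repeated phantom scans) makes the whole pipeline trainable and testable
with no external data. See the methods vignette
(`vignettes/kernel-conversion-methods.Rmd`) for design details and
limitations.

## Worked example

Desk-scale end-to-end run (a few minutes on one CPU):

```r
library(kernelconvert)

ds <- simulate_dataset(sim_config(n_train = 20, n_val = 6,
                                  shape = c(8, 64, 64), seed = 1))
bundle <- train_pipeline(ds, network_config(base_channels = 8),
                         train_config(epochs = 10, seed = 0))
glance(bundle$models$full)
#> # A tibble: 1 × 6
#>   id    window_lo window_hi n_parameters epochs final_loss
#> 1 full      -2048      1500       716065     10    0.00809

report <- run_validation(bundle, ds)
dplyr::filter(report$band_errors, band %in% c("[-1000,-600)", "[-200,200)"),
              method %in% c("sharp", "full_dnn", "full_1_partial")) |>
  dplyr::select(band, method, n, median, q1, q3)
#>   band         method             n  median     q1    q3
#> 1 [-1000,-600) sharp          81442 -6.71   -32.8   8.69
#> 2 [-200,200)   sharp          69133 -1.72   -23.9  16.0
#> 3 [-1000,-600) full_dnn       81442 -1.79    -7.47  4.19
#> 4 [-200,200)   full_dnn       69133 -0.0197  -5.36  5.28
#> 5 [-1000,-600) full_1_partial 81442 -1.79    -7.47  4.19
#> 6 [-200,200)   full_1_partial 69133  0.359   -3.57  4.44
```

Reading this: the raw sharp-vs-soft differences in the lung band spread
over roughly ±30 HU (quartiles −32.8 to 8.7); the converted image narrows
that to −7.5..4.2 HU, and fusing in the partial model tightens the
mid-band spread further (IQR 8.0 vs 10.6 HU for the full model alone) —
the region-wise fusion is doing its job. The phantom inter-scan
variability in the lung band is ±2.5 HU (quartiles), the scanner's
intrinsic noise floor that conversion error is compared against.

```r
report$bland_altman
#>   index_name     method            bias loa_lo loa_hi     n
#> 1 LAV%           full_1_partial -0.344  -0.848  0.160     6
#> 2 IMAT%          full_1_partial -0.0667 -0.841  0.708     6
#> 3 CAC_volume_mm3 full_1_partial 26.7    -7.25  60.6       6
```

LAV% on converted images is within half a percentage point of the
ground-truth soft images (bias −0.34%, limits of agreement −0.85..0.16%),
IMAT% within a tenth of a point, and CAC volume biased by ~27 mm³ —
agreement of the same character as reported for patient cohorts at full
scale. `report$dice` and `report$dice_tests` compare low-attenuation-mask
Dice overlap against the Gaussian, median, and raw-sharp baselines with
Bonferroni-corrected paired t-tests.

A thin command-line wrapper over the same functions ships in
`inst/cli/kernelconvert` (subcommands `simulate`, `train`, `convert`,
`quantify`, `validate`).

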