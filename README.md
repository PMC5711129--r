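# dosewarp

4D deformable dose accumulation for respiratory-phase radiotherapy.

## The problem

Liver SBRT plans are conventionally evaluated in 3D: a single static dose
distribution, computed on a static planning image, is summarised by DVH
metrics as if the anatomy never moved. But the liver moves and deforms
with every breath, carrying a steep, inhomogeneous dose gradient through
the tissue. A quasi-4D evaluation estimates the dose each tissue element
actually accumulates: the dose delivered in each respiratory phase of a
4D CT is warped back to a common reference anatomy (end-expiration)
through deformable image registration (DIR) and averaged with equal
weights,

    D_4D(x) = (1/10) * sum_k  D_k( x + u_k(x) ),

where `u_k` is the displacement field from the reference anatomy into
phase `k`. Comparing `D_4D` with the static dose shows how strongly 3D
planning overestimates target coverage and homogeneity and underestimates
dose to the surrounding healthy liver.

`dosewarp` is for medical-physics researchers who want that pipeline as
inspectable, tested R code: a deformable digital liver phantom with
analytic ground-truth displacement fields, multi-resolution Horn–Schunck
optical-flow registration (Rcpp core), DVF-based dose warping and
equal-weighted path-integrated accumulation (including the reduced phase
subsets p = 2, 3, 5even, 5odd), and the standard plan-quality metrics:

* `Dx` — minimum dose to the hottest x% of a structure (D2, D50, D95, D98),
* `HI = D2 / D98` — homogeneity index (1 = perfectly homogeneous),
* `BED_i = n d_i (1 + d_i / (alpha/beta))` — DVH-based biologically
  effective dose (alpha/beta = 10 Gy for tumour, 2 Gy for liver),
* `r3D = sqrt(SI^2 + AP^2 + LR^2)` — tumour centroid motion magnitude.

Volumes, masks and vector fields are read and written as NRRD / MetaImage.

## Worked example

A down-scaled study (40^3 voxels at 4 mm, 8 mm superior–inferior motion)
runs in seconds; the default `study_config()` reproduces the full
reference conditions (96^3 at 3 mm, lesion-E motion, 42 Gy in 6
fractions).

```r
library(dosewarp)
spec <- phantom_spec(shape = c(40, 40, 40), spacing = c(4, 4, 4),
                     body_radii = c(70, 62, 74), liver_radii = c(40, 32, 36),
                     liver_center = c(5, 0, 5), tumor_center = c(5, 0, 20),
                     tumor_radius = 13)
cfg <- study_config(spec = spec,
                    motion = motion_model(amplitude = c(1, 1.5, 8)),
                    seed = 1)
report <- run_study(cfg)
report
#> <study_report>
#>   grid 40x40x40, seed 1
#>   oracle: 88.4% of liver voxels within 0.84 Gy of the analytic 4D dose
#>   3D vs 4D differences:
#> # A tibble: 5 × 8
#>   structure    dmean_pct_diff d2_pct_diff d98_pct_diff bed_mean_pct_diff hi_3d
#>   <chr>                 <dbl>       <dbl>        <dbl>             <dbl> <dbl>
#> 1 GTV                   0.123    0.000166         1.18             0.184  1.00
#> 2 ITV                   3.84     0.000403        34.1              5.40   1.00
#> 3 PTV                   8.17     0.000883        63.6             10.9    1.33
#> 4 GTV+5mm               0.740    0.000562        -7.59             1.14   1.27
#> 5 normal_liver         -5.99     4.86            -8.09            -1.77  15.6
```

Reading the output: the static 3D calculation overstates the PTV mean
dose by 8.2% and its near-minimum dose D98 by 64%, because tissue at the
field edge spends part of the breathing cycle outside the high-dose
region; the GTV itself is essentially unaffected (0.1%). The normal liver
(liver minus GTV) receives 6.0% *more* mean dose than the static plan
claims (`dmean_pct_diff` is (3D − 4D)/4D). `glance(report)` gives the
one-row headline, `tidy(report)` the long metric table, and
`autoplot(report)` the 3D-vs-4D DVH overlay.

Convergence of reduced-phase accumulation towards the full 10 phases:

```r
subset_convergence_study(report)
#> # A tibble: 8 × 4
#>   subset structure    n_phases max_abs_deviation_pct
#>   <chr>  <chr>           <int>                 <dbl>
#> 1 p2     PTV                 2                10.5
#> 2 p2     normal_liver        2                 1.37
#> 3 p3     PTV                 3                 4.68
#> 4 p3     normal_liver        3                 2.05
#> 5 p5even PTV                 5                 2.04
#> 6 p5even normal_liver        5                 0.560
#> 7 p5odd  PTV                 5                 2.09
#> 8 p5odd  normal_liver        5                 0.465
```

Three phases already approximate the 10-phase DVH within ~5% over the
D98–D50 range; two phases do not.

Individual stages are exposed directly: `generate_phase_ct()` /
`generate_phase_masks()` / `generate_static_dose()` (phantom),
`register_volumes()` (DIR), `warp_dose()` / `accumulate_dose()` /
`average_intensity_projection()` (accumulation), `compute_dvh()` /
`dose_metrics()` / `bed_from_dvh()` (metrics), and
`ground_truth_accumulated_dose()` (the analytic oracle every estimate is
benchmarked against). See the methods vignette
(`vignettes/quasi4d-dose-accumulation.Rmd`) for the model, the phantom's
design and its fidelity gaps, and every numerical convention.

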