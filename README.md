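# thyroscint

Quantification of technetium-99m pertechnetate thyroid uptake from
planar gamma-camera images, for nuclear-medicine physicists and
methodologists who want the full chain — image counts → uptake
parameters → reference-range classification → concordance statistics —
as reproducible, scriptable code.

Three uptake parameters are computed per study:

* **TcTU** (quantitative): the percentage of the net injected activity
  accumulated in the thyroid,

  `TcTU(%) = 100 · (C_T − (C_B/S_B)·S_T) / (A_net(t_img) · f · D)`,

  with `C_T`, `C_B` the thyroid/background ROI counts, `S_T`, `S_B`
  their areas in cm², `A_net` the pre-minus-post syringe assay decayed
  to imaging time (leakage-subtracted), `f` the camera calibration
  factor (counts·s⁻¹·MBq⁻¹) and `D` the acquisition duration.
* **UR** (semiquantitative): the thyroid-to-background concentration
  ratio `UR = (C_T/S_T)/(C_B/S_B)`.
* **CUR**: UR corrected for functional gland size against a
  standardized (control-mean) thyroid area `S_T1`,
  `CUR = UR · S_T/S_T1`. UR overestimates uptake in small glands and
  underestimates it in large ones; CUR removes this area dependence
  and tracks TcTU almost perfectly.

Around the estimators the package provides mean ± 1.96 SD reference
ranges with three-class labeling (decreased/normal/increased),
concordance tables between the semiquantitative and TcTU classes with
likelihood-ratio (G) and Pearson chi-square tests, weighted
least-squares regression with standardized coefficients, the
Mann-Whitney U test with tie-corrected Z, a synthetic Poisson phantom
and cohort generator with exact ground truth, a plain-text image/ROI
format, and a `thyroscint` command-line pipeline
(`simulate` / `quantify` / `classify` / `compare` / `run`).

## Worked example

Generate one synthetic control-like study (148 MBq injected, imaged
300 s at 20 min, 22.06 cm² gland with true TcTU 2.17%) and quantify it:

```r
library(thyroscint)

ph <- generate_phantom(phantom_spec(seed = 7))
quantify_study(ph$image, ph$truth$thyroid_mask, ph$truth$background_mask,
               record = ph$truth$record, calib = ph$truth$calib)
#>      C_T    S_T   C_B   S_B    UR   CUR  TcTU
#> 1 108884 22.106 10809 9.225 4.204 4.212 2.158
```

The thyroid ROI collected 108,884 counts over 22.1 cm²; the estimated
TcTU of 2.158% recovers the simulated 2.17% within Poisson noise, and
UR ≈ CUR ≈ 4.2 because this gland sits at the standard size.

Run the whole pipeline on a 389-subject synthetic clinic cohort:

```r
report <- run_pipeline(run_config(seed = 1))
report$concordance$UR$summary
#>   stratum   n concordant     rate
#> 1   small 102         56 54.90196
#> 2  normal 162        148 91.35802
#> 3   large 125        101 80.80000
#> 4 overall 389        305 78.40617
report$concordance$CUR$summary
#>   stratum   n concordant     rate
#> 1   small 102         94 92.15686
#> 2  normal 162        161 99.38272
#> 3   large 125        119 95.20000
#> 4 overall 389        374 96.14396
```

UR agrees with the TcTU class for only 55% of small-gland subjects
(misreading decreased uptake as normal, and normal as increased) and
81% of large-gland subjects (the opposite directions), while CUR stays
above 92% everywhere — the size-correction at work. The same pipeline
is available from the shell:

```sh
thyroscint run --seed 1 --out results/
```

See `vignettes/thyroid-uptake-quantification.Rmd` for the model,
parameter meanings, phantom assumptions and design decisions.

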