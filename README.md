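# coroflow

Personalized aortic pressure waveforms and hyperemic coronary
flow–perfusion modelling in R.

`coroflow` predicts the two clinical endpoints of functional coronary
assessment — **fractional flow reserve (FFR)** on the epicardial arteries
and **myocardial blood flow (MBF)** in the tissue — from routine *resting*
clinical measures only: age, sex, height, weight, heart rate, brachial
systolic/diastolic pressure, and left ventricular mass. No invasive
measurement and no stress imaging are needed; drug-induced (adenosine)
hyperemia is modelled, not measured.

The chain, end to end:

1. **Waveform synthesis.** Closed-form regressions turn the patient
   record into the timings and pressures of a four-phase aortic-root
   waveform (cubic systolic upstroke with a prescribed 75 mmHg/s shoulder
   slope, augmentation parabola peaking at the central systolic pressure,
   dicrotic-notch parabola, linear diastolic decay). An *effective
   pressure* variant removes 70 % of the aortic value during ejection to
   mimic systolic impediment of coronary flow, recovers the aortic curve
   through isovolumic relaxation, and closes the cycle through a 50 ms
   isovolumic-contraction segment.
2. **Hyperemia mapping.** Frozen linear maps send resting heart rate and
   pressures to their adenosine-stress values; the estimation procedure
   (interquartile-range cleaning with strict 0.5·IQR fences, then least
   squares) is reproducible on synthetic paired data from the built-in
   cohort generator.
3. **Perfusion.** A three-compartment Darcy model (small arteries,
   arterioles, capillaries) on a voxelized myocardial slab, solved by
   cell-centered finite volumes and sparse Cholesky, with a *blinded*
   resting calibration: one conductance scale factor is bisected until
   the resting model delivers 1 mL/min per gram of tissue.
4. **Tree and FFR.** A Poiseuille resistive surrogate of the coronary
   tree (stenoses as narrowed segments in series) is coupled to the
   perfusion model through an exact affine interface solve; hyperemia
   dilates the epicardial radii by 1.225 and the microvascular
   conductances by 4. FFR is the pressure ratio to the inlet at the
   peak-diastolic instant; MBF is the beat-averaged capillary drainage.

All computation is deterministic: identical inputs and seeds reproduce
byte-identical artifacts. Results are tibble-first, with `tidy()`,
`glance()` and `autoplot()` methods on the waveform, cleaning, Darcy,
network, beat and FFR objects.

## Worked example

```r
library(coroflow)

p <- patient_record(age = 60, sex = "male", height = 175, weight = 75,
                    hr = 70, p_sys = 120, p_dia = 80, lv_mass = 160)

wp <- derive_waveform_params(p)
wp[, c("t_period", "t_sh", "t_peak", "t_i", "t_notch",
       "p_peak", "p_sh", "p_notch", "p_i")]
#> # A tibble: 1 × 9
#>   t_period  t_sh t_peak   t_i t_notch p_peak  p_sh p_notch   p_i
#>      <dbl> <dbl>  <dbl> <dbl>   <dbl>  <dbl> <dbl>   <dbl> <dbl>
#> 1    0.857 0.112  0.168 0.259   0.336    110  103.    98.2  92.0
```

The central systolic peak is the brachial value minus the male 10 mmHg
brachial-to-aortic drop; the shoulder sits at one third and the peak at
one half of the end of systole. The hyperemic state of the same patient:

```r
rest_to_stress(p)[, c("state", "hr", "p_sys", "p_dia")]
#> # A tibble: 1 × 4
#>   state     hr p_sys p_dia
#>   <chr>  <dbl> <dbl> <dbl>
#> 1 stress  90.4  119.  79.6
```

The full pipeline — waveforms, resting calibration on the default
20 × 20 × 10 slab of 2 mm voxels, dilation, stress scaling, one coupled
beat at `dt = 1e-3` s, FFR/MBF report:

```r
run <- run_pipeline(p)
run
#> <coroflow_run> patient P1
#>   FFR landmarks: LAD 0.994, LCX 0.995, RCA 0.994
#>   mean MBF 380.3 mL/min/100g, inflow 1.412 mL/beat, diastolic fraction 0.73
#>   calibration lambda 0.3162 (rest inflow 0.9982 mL/min/g)
```

A healthy tree yields landmark FFR values near unity; adding a stenosis
lowers them:

```r
sten <- tibble::tibble(segment_id = "LAD1",
                       radius_reduction_frac = 0.6, length_frac = 0.5)
run_s <- run_pipeline(p, tree = default_coronary_tree(stenoses = sten))
```

Waveforms can be inspected directly:

```r
par  <- build_aortic_waveform(wp)
peff <- build_effective_waveform(par)
plot_waveforms(par, peff)          # ggplot2 overlay of one beat
```

See `vignette("methods")` (source in `vignettes/methods.Rmd`) for the
model equations, every parameter choice, and the numerical methods.

## Testing

The package ships a `testthat` (edition 3) suite including independent
dense oracles for both the Darcy and the network solver and an
end-to-end acceptance file:

```r
testthat::test_dir("tests/testthat", package = "coroflow",
                   load_package = "installed")
```

## Scope

`coroflow` is a desk-scale surrogate: a synthetic slab rather than a
segmented ventricle, a seven-segment tree rather than patient 3D
geometry, quasi-static hemodynamics, and spatially constant perfusion
parameters. Endpoints that require patient imaging are out of scope.
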