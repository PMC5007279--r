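# spinehough

Operator-independent segmentation and FDG-PET quantification of the
spinal cord on whole-body PET/CT.

The spinal cord is a thin, curved structure that routine whole-body
FDG-PET/CT reads almost never quantify: manual delineation over dozens
of axial slices is slow and operator-dependent. `spinehough` automates
the whole chain for anyone who needs cord metabolism from standard
scans — nuclear-medicine and neuroimaging researchers studying motor
neuron disease, myelopathy, or cord physiology. The only manual input
is three axial plane indices (occipital skull border, caudal C7,
caudal D12).

## The method

On every axial CT slice, a generalized Hough transform detects two
algebraic curves:

* the **spinal canal** as the two-parameter curve with three
  convexities

  C(a,b): (x² + y²)³ = (a(x² + y²) − b(x³ − 3xy²))²,

  polar form r(θ) = a / (1 + b·cos 3θ) — a rounded triangle matching
  the canal profile;

* the **spinal cord** inside it as the four-parameter axis-aligned
  ellipse b²(x − c)² + a²(y − d)² = a²b².

Canny edge points each cast one vote for every cell of the discretized
parameter space (cell side 0.02 in a canal-centered working frame)
whose curve passes within the cell's half-side tolerance band; the
accumulator maximum identifies the curve. The fitted curves are
rasterized to nested binary masks (cord ⊆ canal), multiplied against
the coregistered PET volume, and summarized as liver-normalized
standardized uptake values (NSUV). The whole-cord value is the
volume-weighted mean

SC_NSUV = (C_NSUV · V_cervical + D_NSUV · V_dorsal) / (V_cervical + V_dorsal).

The chain is fully deterministic: identical inputs give bit-identical
masks and reports. A digital phantom module generates coregistered
CT/PET pairs with analytic ground truth (three-convexity canal,
elliptical cord, 4 mm FWHM PET blur) and a cohort simulator draws
case/control uptake distributions, so everything is testable without
patient data.

## Worked example

Generate the default digital phantom, segment it, and quantify the
uptake:

```r
library(spinehough)

ph <- generate_phantom(phantom_truth(noise_sd = 0),
                       shape = c(64, 64, 60), spacing = c(1, 1, 2))
segdef <- partition_segments(ph$ct, occiput = 3, c7 = 23, d12 = 50)
cfg <- seg_config(cord_lower = c(0.02, 0.02, -0.1, -0.1),
                  cord_upper = c(0.40, 0.40,  0.1,  0.1))
seg <- segment_volume_run(ph$ct, segdef, cfg)
seg
#> <segmentation result>  48/48 slices fitted
#> # A tibble: 2 x 4
#>   segment  n_slices canal_volume_ml cord_volume_ml
#>   <chr>       <int>           <dbl>          <dbl>
#> 1 cervical       20            48.0           2.41
#> 2 dorsal         28            67.3           3.39

liver <- liver_suv_sphere(ph$pet, ph$truth_record$liver_center_vox,
                          ph$subject, diameter_mm = 12)
rep <- uptake_report(seg, ph$pet, ph$subject, liver, subject_id = "phantom01")
rep
#> <uptake report>  liver SUV 1.864, whole-cord NSUV 0.826
#> # A tibble: 2 x 5
#>   segment  canal_nsuv cord_nsuv canal_volume_ml cord_volume_ml
#>   <chr>         <dbl>     <dbl>           <dbl>          <dbl>
#> 1 cervical      0.632     0.946            48.0           2.41
#> 2 dorsal        0.617     0.740            67.3           3.39
```

Every slice was fitted; the per-slice parameters land within one
accumulator cell of the phantom's ground truth. The cord NSUVs (0.946
cervical, 0.740 dorsal, against true values 0.99 and 0.72) carry the
expected partial-volume bias of a ~4–8 mm structure imaged at 4 mm
FWHM; the volume-weighted whole-cord NSUV (0.826) sits within 1 % of
its ground truth. `tidy(seg)` returns the per-slice fit table,
`glance(rep)` the one-row summary, and `autoplot()` draws
parameter-stability and NSUV plots. `run_pipeline()` drives the same
chain from NIfTI files and a YAML config (see
`inst/scripts/spinehough` for the command-line wrapper), writing masks
aligned to the input grid, a per-slice fit table, and the uptake
report.

Cohort-level helpers reproduce the desk-scale statistics around the
method: `dichotomize_fifth_decile()` (median split, lower
interpolation), `mortality_by_nsuv_group()` (deaths and rates per
group), and `compare_groups()` (two-sample comparison).

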