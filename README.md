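# sstmorph

3D cross-sectional morphometry of avian **sperm storage tubules (SSTs)**
from light-sheet (SPIM) image volumes.

SSTs are blind-ended epithelial tubules in the utero-vaginal junction of the
avian oviduct. Punctate autofluorescent granules in the tubule epithelium
outline each SST in label-free light-sheet stacks of live tissue, which
makes their 3D shape measurable — but only if every cross-section is taken
*normal to the local tube direction*, because SSTs follow convoluted paths
and oblique cuts overestimate diameter. This package implements that
pipeline end to end, for morphologists working on sperm storage and for
anyone measuring tubular structures in 3D fluorescence volumes:

* **tracegeom** — average two traced sides of a tubule into a luminal
  centerline, parameterize by arc length, sample N equidistant points
  (default 10, first at the orifice), estimate local directions;
* **obliqueslice** — extract 2D sections at arbitrary angles by trilinear
  interpolation, with a deterministic in-plane frame and validity mask;
* **morphometry** — per section, measure the major/minor axis diameters
  `d1 >= d2` of the region enclosed by autofluorescence
  (Otsu threshold → component at centre → hole fill → moment-equivalent
  ellipse), giving mean diameter `(d1 + d2)/2` and circularity `d1/d2`;
* **ssstats** — linear mixed-effects models of the repeated measures:

  `mean_diameter ~ distance + distance² + total_length + (1 | bird)`

  `circularity ~ total_length + (d1+d2) + distance + (d1+d2):distance + (1 | bird)`

  fitted by REML with in-package Satterthwaite t/df/p and
  Nakagawa–Schielzeth marginal/conditional r²; plus the linear
  lumen-vs-outer-diameter scaling used to predict lumen calibre at the
  orifice;
* **synthgen** — a generator of SPIM-like volumes (punctate epithelial
  shell around a dark lumen, Poisson + Gaussian noise), side traces, and
  cohort measurement tables with known ground truth, so every stage is
  verifiable without the original raw images;
* **cli_io** — `simulate` / `measure` / `stats` / `all` subcommands, TIFF +
  SWC/CSV + JSON/YAML I/O, and a reproducibility manifest per run.

## Worked example

Render a synthetic 150 µm tubule with the default morphology (orifice
10.1 µm, widest section 16.4 µm at the midpoint, ellipticity 1.6), trace it
with 0.5 µm jitter, and measure it back:

```r
library(sstmorph)
cl   <- make_centerline(seed = 1, total_length = 150, tortuosity = 0.25)
cfg  <- render_config(volume_shape = c(200, 120, 60),
                      voxel_spacing = c(1, 1, 1.5), seed = 1)
cl   <- center_in_volume(cl, cfg)
ren  <- render_sst(sst_geometry(cl), cfg)
tr   <- simulate_side_traces(ren$ground_truth, jitter_sd = 0.5, seed = 2)
rec  <- measure_sst(ren$volume, tr$side_a, tr$side_b)
round(rec$measurements[, c("s_um", "d1_um", "d2_um", "mean_diameter_um")], 2)
#>      s_um d1_um d2_um mean_diameter_um
#> 1    0.00 13.22  6.91            10.07
#> 2   18.06 15.77  9.72            12.75
#> 3   36.11 18.93 11.06            15.00
#> 4   54.17 20.32 11.67            15.99
#> 5   72.22 20.99 12.71            16.85
#> 6   90.28 20.96 12.65            16.80
#> 7  108.33 20.33 12.06            16.20
#> 8  126.39 18.76 10.95            14.86
#> 9  144.44 16.39  9.49            12.94
#> 10 162.50 12.58  7.30             9.94
```

The measured profile recovers the constricted orifice (10.1 µm generated,
10.07 measured), the mid-tubule maximum (16.4 generated, 16.85 measured)
and the narrow blind end. Fitting the diameter model on a simulated
10-bird cohort:

```r
tab <- make_measurement_table(seed = 1)
fit_diameter_model(tab, distance = "normalized")
#> <sst_model_fit> mean_diameter ~ distance + distance^2 + total_length + (1 | bird) (100 obs, 10 birds)
#>          term    estimate     se       t   df        p
#>   (Intercept)  14.8070000 6.4760  2.2870  8.3 5.04e-02
#>      distance  17.0690000 4.3940  3.8840 88.0 1.98e-04
#>    distance^2 -17.5820000 4.2300 -4.1560 88.0 7.48e-05
#>  total_length  -0.0084939 0.0203 -0.4185  8.0 6.87e-01
#> random effects: bird intercept SD 3.608, residual SD 3.795
#> r2 marginal 0.0925, conditional 0.5234
```

The significant negative quadratic distance term is the statistical
signature of the tubule shape: constricted at the orifice, widest near the
middle; total length has no effect. Note the Satterthwaite df separate
within-bird terms (~88) from between-bird terms (~8).

The same pipeline from the shell:

```sh
Rscript inst/cli/sstmorph all --out runs/demo --seed 1
```

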