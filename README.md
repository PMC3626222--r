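# holofilter

Three-dimensional shift-invariant pattern recognition for digital
holographic microscopy, in R.

## The problem

A coherent (holographic) microscope records the complex amplitude of a
monochromatic field in a single plane.  Because such a field obeys the
Helmholtz equation, that one plane determines the whole volume: the
angular-spectrum method propagates each plane-wave component
(k<sub>x</sub>, k<sub>y</sub>) by the pure phase
exp(+j2πz·k<sub>z</sub>), with
k<sub>z</sub> = √((n/λ)² − k<sub>x</sub>² − k<sub>y</sub>²).  This gives
holographic instruments an enormous effective depth of field — and
creates the problem this package addresses: finding and classifying
small objects (e.g. one bacterial species among another) anywhere in
that reconstructed volume, regardless of lateral position and depth.

The key identity exploited throughout: a monochromatic field's 3D
spectrum lives on a spherical shell, so a general 3D correlation filter
applied to it has only **2D** degrees of freedom, and one plane of the
3D correlation is a 2D circular correlation of the reconstructed plane
with a single spectral kernel H(k<sub>x</sub>, k<sub>y</sub>):

R<sub>Z</sub> = F⁻¹[ U · H\* · exp(+j2πZ·k<sub>z</sub>) ].

On top of this the package implements a trainable **nonlinear filter
cascade** — correlation layers with compact trainable spectral supports,
pointwise cubic thresholds a·x³ + b·x² + c·x + d acting on complex
values, and a squared-modulus readout — optimised by simulated annealing
of the peak-weighted squared-error objective

E = Σ<sub>ij</sub> (R<sub>ij</sub> − O<sub>ij</sub>)² +
n·Σ<sub>j</sub> (R<sub>1j</sub> − O<sub>1j</sub>)²,

where the desired output O is a unit delta for in-class references and
zero for out-of-class ones.  A synthetic two-class scenario (rod-shaped
scatterers of slightly different sizes, off-axis hologram simulation and
demodulation, volumetric peak detection) provides an end-to-end
demonstration.

## Worked example

Train the scaled two-class rod classifier, add the cubic decision layer,
and run detection on a synthetic 32 × 32 µm scene containing 6 target
and 4 non-target rods at random 3D positions:

```r
library(holofilter)

cl  <- train_rod_classifier(seed = 7)     # 6+6 references, 16x16x8 volumes
cl
#> <rod_classifier>
#> <trained_filter> E: 4692.11 -> 2629.23 over 36000 moves
#>   discrimination ratio: 1.452

cl2 <- add_sharpening_layer(cl)           # all-pass layer with T(x) = x^3
cl2$evaluation
#> <filter_evaluation> discrimination ratio 3.06

thr <- calibrate_threshold(cl2$evaluation)   # 0.1314

scfg  <- optical_config(pixel_pitch = 0.25, nx = 128, ny = 128)
scene <- random_scene(6, 4, scfg, z_range = c(-3, 3), seed = 7)
res   <- run_pipeline(scene, cl2$model, seq(-4, 4, by = 0.25), threshold = thr)
res$report
#> <detection_report> 6 detection(s) above 0.1314
#> # A tibble: 6 x 7
#>     x_um   y_um  z_um score    ix    iy    iz
#>    <dbl>  <dbl> <dbl> <dbl> <int> <int> <int>
#> 1   8.25  -4.5   2.75 0.614    98    47    28
#> 2  -1.25  -9.25 -1.75 0.492    60    28    10
#> 3  -2.75 -10.8  -2.5  0.487    54    22     7
#> 4 -11.2   -1.25 -0.75 0.325    20    60    14
#> 5 -13.8   13.5   1.25 0.303    10   119    22
#> 6  -5.75  14     4    0.262    42   121    33
```

Reading the numbers: annealing lowers the training error E from 4692 to
2629; the linear layer separates the classes by a factor 1.45 (minimum
in-class peak over maximum out-of-class output), and the cubic decision
layer widens that to 3.06, leaving room for a threshold (the geometric
midpoint, 0.131).  The pipeline then detects exactly the six target rods
— each detection's (x\_um, y\_um, z\_um) lands on a planted target-class
rod to sub-pixel lateral accuracy — with no false detections on the four
non-target rods.  `plot_projection(res$output, res$report)` displays the
max-z projection with detections overlaid; `autoplot(cl$trained)` shows
the annealing trace.

A thin command-line surface over the same functions lives at
`inst/cli/holo3d.R` (subcommands `simulate`, `reconstruct`, `train`,
`apply`, `detect`, `pipeline`).

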