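# lamellaR

Quantitative image analysis of T cell:antigen-presenting-cell (APC)
conjugates — the immunological synapse — for R.

When a primed T cell couples to an APC, fluorescently tagged signaling
sensors redistribute into a small set of recurring interface geometries:
a central signaling complex, a peripheral ring, cortical (diffuse)
accumulation, a transient large invagination, small one-sided protrusions,
and a transient, actin-associated *lamellum* spanning the whole interface
and reaching micrometers into the T cell. lamellaR implements the
measurement battery used to characterize these structures, for
microscopists and quantitative immunologists who want the analyses as
tested, scriptable R functions:

* **Pattern classification** — segments the two cells, builds an
  interface-anchored coordinate frame (depth `δ` into the T cell, radial
  position `ρ`), detects accumulation >40% above the cellular background,
  and assigns one of six mutually exclusive patterns per cell couple per
  timepoint; tabulates percentage occurrence and per-interval change across
  populations of couples.
* **Interface morphometry** — arc-length/chord ratio `L/D` of the
  undulating membrane from EM or live midplane contours, area extrapolation
  `(L/D)^2`, and tight-contact length (membrane stretches < 20 nm apart).
* **Actin structure scoring** — full-width-half-maximum (FWHM) line scans
  perpendicular and parallel to the interface; depth/width ratio and
  intensity/area of elongated structures.
* **Depth-intensity profiles** — box-scan slab averages into the T cell,
  for the full interface, its center (middle 50% of the diameter) or
  periphery (outer 25% each side), relative-to-maximum or %-above-background.
* **Colocalization & clusters** — Pearson and intensity-weighted Manders
  coefficients over linear-threshold masks; 3D connected-component cluster
  detection with interface distances read off the APC channel half-maximum.
* **FRAP kinetics** — trace normalization and Levenberg–Marquardt fitting of
  `Y(t) = (Ymax − Ymin)(1 − e^{−kt}) + Ymin`, with `t½ = ln 2 / k` and the
  mobile fraction `(Ymax − Ymin)/(1 − Ymin)`; classic fitted-model interface
  (`print`, `coef`, `predict`, `fitted`, `residuals`, `plot`).
* **Population statistics** — pooled two-proportion z-test, mean ± s.e.m.,
  average-linkage clustering of sensor timecourses on correlation distance,
  and lamellal-dominance summaries.
* **Synthetic data with ground truth** — seed-deterministic generators for
  every input the pipeline consumes: conjugate movies with pattern
  templates, undulating contour pairs, STED-like structure images, FRAP
  traces, correlated two-channel volumes, planted cluster fields. Every
  estimator in the package is validated against these truths in the test
  suite.

## Worked example

Generate a synthetic conjugate movie with a known lamellal pattern,
classify it, and measure the structure:

```r
library(lamellaR)

sc <- gen_cell_couple_stack(scene_spec("lamellum", seed = 42))
res <- classify_frame(sc$stack)
res$label
#> [1] "lamellum"
res$region
#> <accumulation_region> 468 voxels, f = 1.75, c = 0.90, rho_bar = 0.65, d = 2.75 um
res$frame
#> <interface_frame> D = 7.28 um, normal (0.00, 0.00, 1.00) [z,y,x]
```

The detected region spans the interface diameter (`c = 0.90`) at
1.75-fold over the cellular background and extends 2.75 µm into the T cell
— the lamellal geometry (full coverage, depth ≥ 1.5 µm).

Interface undulation, from a generated early-stage contour pair:

```r
g <- gen_interface_contours(preset = "em_early", seed = 0)
interface_length_diameter(g$tcell)
#> <interface_morphometry> L = 16.800 um, D = 8.000 um, L/D = 2.100 (area fold 4.41)
```

The membrane is 2.1-fold longer than the straight interface diameter;
extrapolated isotropically, a ~4.4-fold membrane area increase at the
contact. FRAP recovery of a lamellal sensor:

```r
tr <- gen_frap_trace(k_per_s = log(2) / 1.3, noise_sd = 0.03, seed = 1)
fit_recovery(tr$trace)
#> <frap_fit> k = 0.5089 /s, t1/2 = 1.362 s, mobile fraction = 0.692
#>   Ymin = 0.523, Ymax = 0.853, RSS = 0.0813
```

An end-to-end demonstration over all modules, with CSV/JSON outputs and a
provenance record:

```r
out <- run_pipeline(run_config(seed = 1L, out_dir = "results"))
```

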