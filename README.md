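# synapseQuant

Quantification of B cell immune-synapse fluorescence microscopy, with a
synthetic-microscopy generator that makes every measurement stage testable
against known ground truth.

## What it measures, and for whom

When B cells engage antigen (Ag) on a surface or an antigen-presenting
cell, BCR signaling drives actin-dependent spreading, centripetal
(retrograde) actin flow, and the coalescence of BCR–Ag microclusters into a
central supramolecular activation cluster (cSMAC). Labs studying this
biology quantify it from multi-channel fluorescence images and TIRF
time-lapse movies. `synapseQuant` packages that workflow as tested R
functions:

* **Spreading area** — Otsu segmentation of the F-actin channel, largest
  component, hole filling; area = pixel count × pixel size².
* **Radial intensity profiles** — per-cell mean intensity in 1-px concentric
  annuli, normalized to the per-cell maximum (value) and to the cell edge
  (radius); population curves smoothed by fixed-span local regression with a
  between-cell standard error band.
* **Retrograde-flow velocimetry** — kymographs along a sampling line
  (bilinear interpolation, odd perpendicular width); track velocity
  `|Δx| · px · 1000 / (Δt_frames · interval)` in nm/s, plus an automated
  correlation-based slope estimator for benchmarking; per-condition medians
  and percent reduction versus control.
* **Microcluster / cSMAC analysis** — rolling-ball background subtraction
  (exact grayscale opening with a spherical element, default radius 10 px),
  exact Otsu thresholding, 8-connected components filtered at
  area > 0.05 µm², per-cluster integrated intensities and fractions;
  **cSMAC call**: > 90% of clustered Ag intensity in at most two clusters;
  **signal amplification**: clustered pCD79 / clustered Ag per cell.
* **Statistics** — ROUT robust outlier flagging at a target false-discovery
  rate (default Q = 1%), exact-when-possible Mann–Whitney U, paired t
  tests, per-experiment percent-of-control normalization, densitometry
  ratios, median/IQR summary tables.
* **Synthetic microscopy** — spreading cells (peripheral actin ring +
  interior GMFγ peak), synapse frames with designed cluster fractions and a
  designed pCD79:Ag ratio, and flow movies translating at a known nm/s,
  all imaged through a blur → Poisson → Gaussian-read-noise → clip camera
  model with explicit seeds and bit-reproducible output.

## Worked example

Design a synapse with three clusters holding 40/30/30% of the Ag intensity
(no cSMAC: the top two clusters hold only 70%) and a designed pCD79:Ag
ratio of 0.5, image it through the camera model, and run the full
quantification:

```r
library(synapseQuant)

truth <- synapse_truth(centers = rbind(c(30, 30), c(62, 58), c(34, 68)),
                       ag_intensities = c(4e4, 3e4, 3e4),
                       pcd79_per_ag = 0.5)
sim <- simulate_synapse_frame(truth, camera_model(), seed = 42)
q <- quantify_synapse_frame(sim$frame)
q$clusters$Ag
#> cluster_set: 3 clusters, total clustered intensity 71466.4
#>   id n_px area_um2 intensity  fraction
#> 1  1   45     0.45  30056.98 0.4205750
#> 2  2   37     0.37  20526.94 0.2872251
#> 3  3   37     0.37  20882.48 0.2922000
q$csmac
#> cSMAC call: no cSMAC (>90% of Ag in 3 clusters)
q$amplification
#> [1] 0.4998557
```

The measured fractions recover the designed 0.40/0.30/0.30 split, the cell
is correctly called cSMAC-negative, and the per-cell amplification ratio
recovers the designed 0.5. The same pattern scales up: a movie translating
at a true 100 nm/s is recovered by the kymograph estimator to within a
fraction of a percent:

```r
mv <- simulate_flow_movie(flow_movie_truth(v_true_nm_s = 100),
                          camera_model(), seed = 7)
ky <- extract_kymograph(mv$movie, c(4, 24, 124, 24), width_px = 3)
estimate_kymograph_velocity(ky)
#> [1] 99.9961
```

An end-to-end demo over two cohorts (control vs knockdown conditions
differing in coalescence, flow speed and amplification ratio) is available
as `run_quantification(run_config(mode = "synthetic", pixel_size_um = 0.1,
seed = 1))`; it writes per-cell CSV tables, a summary JSON with per-condition
cSMAC percentages, median velocities and percent reduction, and a log, all
byte-reproducible under a fixed seed.

## Layout

```
R/                  measurement stages, generator, statistics, pipeline
src/                compiled kernels: ball morphology, Gaussian blur,
                    connected components, hole filling
tests/testthat/     unit, property and end-to-end recovery tests with
                    brute-force pixel-loop oracles
scripts/acceptance.R  ground-truth recovery report (see above)
vignettes/          methods vignette: models, parameters, design choices
```
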