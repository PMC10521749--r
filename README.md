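# tomocyte

Label-free profiling of single white blood cells (WBCs) from 3D
refractive index (RI) tomograms, for researchers working with optical
diffraction tomography (ODT) of hematologic samples. A reconstructed RI
tomogram is both a morphological and a biochemical measurement: the
nonaqueous (mostly protein) content raises the refractive index linearly
over the medium,

    n = n0 + α·C        (α = 0.2 mL/g, the refractive index increment)

so thresholding and integrating the volume yields six single-cell
parameters — cellular volume *V* (fL), surface area *S* (µm²),
sphericity π^⅓·(6V)^⅔ / S, protein density (g/dL), dry mass (pg,
1 g/mL = 1 pg/fL) and mean RI — with the exact identities
dry mass = pd/100 × V and mean RI = n0 + α·pd/100.

The package provides, as one coherent toolchain:

* **Tomogram I/O** — multi-page 32-bit float TIFF + JSON metadata
  sidecar (pitch is mandatory, never defaulted), CSV dataset manifests
  with seeded, stratified 7:1:2 train/val/test splitting.
* **Synthetic phantom generator** — spheroid single-cell RI volumes with
  exact analytic ground truth, per-class distributions parameterized by
  published bone-marrow WBC statistics (B/T lymphocytes, monocytes,
  myelocytes), mean-RI-preserving nuclear compartment, seeded and
  bitwise reproducible per cell.
* **Morphometry** — RI-threshold segmentation (largest 26-connected
  component), marching-tetrahedra surface area on a smoothed component
  indicator, and the six parameters above with QC flags.
* **Classifiers** — a DS–US–DS 3D convolutional network (batch norm,
  leaky rectifier, 3D conv, max pooling; nearest-neighbour upsampling
  with residual refinement; 1×1×1 conv head with global average
  pooling), trained with ADAM, cross-entropy, per-step learning-rate
  decay and label-preserving augmentation — implemented end to end in
  this package (C++ kernels, finite-difference-verified backprop); a 2D
  baseline on maximum-intensity projections / synthetic phase /
  amplitude proxies; five classical baselines on the six features
  (one-vs-one SVM committee with ECOC voting, KNN k=5, LDA, Gaussian
  naive Bayes, Gini decision tree).
* **Learned-feature visualization** — features tapped at the last layer
  of the second downsampling block, embedded in 2D with an in-package
  UMAP implementation (seed-deterministic), plus silhouette scoring.
* **End-to-end benchmark** — one command from phantom cohort to a
  model-comparison table with resolved config, hashes and logs,
  byte-identical on rerun.

## Worked example

Generate one myelocyte-like phantom with known truth and measure it:

```r
library(tomocyte)
spec <- defaultClassSpecs(gridShape = "fit", noiseSdRi = 0)$My
cell <- generateCell(spec, seed = 7)
cell$tomogram
#> Tomogram 'My_0001': 96 x 96 x 96 voxels (z,y,x)
#>   pitch (um): 0.2 x 0.2 x 0.2 | medium RI: 1.3370 | RI range: [1.3370, 1.3788]

round(cell$truth[, -(1:2)], 4)       # analytic ground truth
#>   volume_fl surface_area_um2 sphericity  pd_gdl dry_mass_pg mean_ri
#> 1  425.3428          355.085     0.7703 19.7149     83.8558  1.3764

round(profileCell(cell$tomogram)[, -1], 4)   # measured from the voxels
#>   volume_fl surface_area_um2 sphericity dry_mass_pg  pd_gdl mean_ri
#> 1   425.584         358.3863     0.7635     83.8986 19.7138  1.3764
```

The drawn cell is an oblate spheroid whose volume (425.3 fL) and
sphericity (0.770) were sampled from the myelocyte distributions; the
measured volume agrees to 0.06%, the mesh surface area to 0.9%, and
protein density / dry mass / mean RI satisfy their algebraic identities
(the truth columns are ordered slightly differently: `pd_gdl` before
`dry_mass_pg`). A full classification experiment is one call:

```r
specs <- defaultClassSpecs()          # common 112^3 grid, 0.2 um pitch
cfg <- experimentConfig(specs, nPerClass = 12, seed = 1,
                        outDir = "bench")
res <- runBenchmark(cfg)              # phantoms -> features -> 5 ML models
res$comparison                        #   -> 2D CNN -> 3D CNN -> embedding
```

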