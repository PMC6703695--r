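# nucridge

3D nucleus instance segmentation for fluorescence microscopy images of
**nuclear-envelope** staining (LaminB1 and similar reporters), written
for the crowded regimes — embryonic epithelia, stacked layers, dense
cultures — where nucleoplasmic-stain thresholding merges touching
nuclei.

## The method

The envelope appears in every z plane as a thin bright **ridge** closing
around each nucleus. `nucridge` segments it per plane and reassembles
instances in 3D:

1. **Ridge enhancement** — the response is the negative-eigenvalue
   magnitude of the scale-normalised Hessian of Gaussian
   (a second-order steerable ridge detector); the tangent comes from
   the complementary eigenvector; non-maximum suppression across the
   normal thins the response to 1-px crest curves.
2. **Seeding** — thresholded local maxima of a Difference-of-Gaussian
   band-pass of the envelope intensity.
3. **Tree-structured ridge tracing** — from each seed two ridge
   polylines ("ridglets") grow in opposite directions, always stepping
   to the brightest admissible neighbour; children spawn at
   obstructions and junctions. Each ridglet ends with one stop code
   (origin closure O, self-loop L, tree crossing C/CP/P, distance D,
   intensity drop I, sharp turn T).
4. **Shape selection** — every leaf pair closes into a candidate
   contour; candidates are rasterised, described by intensity and
   chain-code curvature features, and ranked by a Gaussian naive Bayes
   classifier trained on a handful of annotated shapes; winners are
   reconciled to pixel disjointness per plane.
5. **3D linkage** — accepted areas connect across planes under
   centroid-distance and overlap gates; Jaccard-index arbitration
   resolves merge/split ambiguities (dividing a co-section between its
   partners when the union fits better); edges are consumed in
   descending JI to label instances, under min/max volume constraints.
6. **Refinement** — stacked pairs split at the peak of the axial
   centre-to-rim intensity-ratio profile; laterally fused pairs at the
   peak of the centroid-displacement profile; volumes are
   morphologically smoothed.

A benchmarking module classifies every instance of a test segmentation
against ground truth (accurate / merge / miss / split / spurious),
computes precision, recall and F-measure, and writes colour-coded 3D
error maps. A synthetic scene generator renders envelope-labelled
ellipsoidal nuclei with exact ground truth and controlled degradations
(noise, z resampling, bit-depth reduction), so the whole pipeline is
testable without any external data.

## Worked example

```r
library(nucridge)

# a synthetic scene: 6 sparse nuclei with exact ground-truth labels
sc <- generate_scene(scene_spec(n_nuclei = 6, field_um = c(40, 40, 24),
                                mode = "sparse", seed = 7))

# bootstrap a training set from a small annotated scene, harvesting
# candidate shapes at three noise levels so one classifier serves a
# range of image qualities
tsc <- generate_scene(scene_spec(n_nuclei = 8, field_um = c(45, 45, 26),
                                 mode = "touching", seed = 21))
pars <- seg_params(seed_threshold = 300)
tabs <- lapply(c(0, 0.12, 0.25) * 2850, function(sd) {
  ti <- add_noise(tsc$intensity, sd, seed = 31)
  make_training_table(ti, tsc$labels, pars,
                      n_per_class = 10, planes = seq(3, 23, by = 3))
})
cl <- train_classifier(do.call(rbind, tabs))

res <- segment(sc$intensity, pars, cl)
head(res$table, 3)
#>   id      x_um     y_um      z_um volume_um3 plane_min plane_max mean_intensity
#> 1  1 29.770139 23.60933  8.163537     412.75         3        13       1419.503
#> 2  2 16.092649 29.51007  8.531722     248.25         6        11       1385.498
#> 3  3  8.299595 10.63386 13.367915     494.00         9        19       1343.927

benchmark_segmentation(sc$labels, res$labels)
#> BenchmarkReport: 6 GT / 6 test instances
#>    accurate=6 merge=0 miss=0 split=0 spurious=0
#>   precision=1.0000 recall=1.0000 F=1.0000 mean JI(accurate)=0.7058
```

Each row of `res$table` is one nucleus: centroid in micrometres, volume
in µm³, plane span, mean envelope intensity. The benchmark report
counts instance-level errors against the ground truth; here all six
nuclei are exclusive mutual-majority matches (accurate), and the mean
Jaccard overlap of the matched pairs is 0.71 (the traced contours sit
on the envelope mid-line, slightly inside the ground-truth solids).

A command-line front end (`inst/cli/nucridge.R`) exposes `segment`,
`train`, `benchmark` and `simulate` for shell use.

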