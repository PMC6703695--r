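---
title: "Segmenting nuclei in 3D from nuclear-envelope staining: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting nuclei in 3D from nuclear-envelope staining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucridge)
```

## The problem

In crowded tissues (embryonic epiblast, stacked epithelia, dense cell
culture) nuclei touch, overlap in z, and vary widely in shape, so the
classical route to nucleus instance segmentation — threshold a
nucleoplasmic stain, then cut the blob apart — fails exactly where the
biology is interesting. `nucridge` instead segments the *nuclear
envelope* (e.g. a LaminB1 label): a thin bright shell whose 2D
cross-sections are closed ridges. Each z plane is processed as a 2D
problem — enhance ridges, trace them, close them into candidate
contours, rank the candidates — and the accepted 2D areas are then
linked across planes into 3D instances, where information from
neighbouring planes corrects residual 2D mistakes.

## The per-plane model

**Ridge enhancement.** The envelope cross-section is a curvilinear
ridge a few pixels wide. The ridge strength at each pixel is the
magnitude of the negative eigenvalue of the scale-normalised Hessian of
Gaussian at scale `ridge_scale` (px); the ridge tangent is the
complementary eigenvector. This second-order filter is the standard
reproducible realisation of a steerable ridge detector. Because the
response involves only second derivatives, adding a constant offset to
the image changes nothing, and scaling intensities scales the response
linearly — the basis of the bit-depth invariance discussed below. The
response field is thinned to one-pixel crest curves by non-maximum
suppression across the local normal (`ridge_nms()`); the tracer
operates on these crests.

**Optional smoothing.** For very noisy data the working image can be
pre-smoothed (`smoothing_sigma` > 0). Smoothing is 3D: each plane is
first averaged with its two z neighbours (weights 1-2-1) and then
blurred in-plane. The z average matters: in-plane blurring is partly
redundant with the Gaussian already inside the ridge filter (both are
linear), whereas adjacent planes of a z-stack are structurally almost
identical, so averaging them suppresses noise that no in-plane filter
can reach while barely distorting geometry. Shape features are always
measured on the same working image the detector sees, normalised by
the bit-depth range so that one trained classifier serves 8-, 12- and
16-bit data alike.

**Seeding.** Starting points are local maxima of a
Difference-of-Gaussian band-pass (`dog_sigma_small` <
`dog_sigma_large`, px) of the envelope intensity, thresholded at
`seed_threshold` (intensity units). The threshold is deliberately the
one "knob" that tracks image quality: it is the only parameter that
needs retuning when bit depth changes, and its default here (300 for
the 12-bit synthetic scenes) is chosen to sit well above the
DoG response of pixel noise at the noise levels the robustness
analysis uses, while the envelope response is several times larger.

**Tree-structured tracing.** From each seed (snapped to the strongest
crest pixel in a 5x5 window) two ridglets grow in opposite directions,
each repeatedly stepping to the brightest admissible 8-neighbour.
A step may not reverse by more than 90 degrees (that would jump across
the ridge rather than follow it), and one-pixel crest gaps are bridged
by a two-pixel forward probe. A ridglet ends with exactly one stop
code: loop closure at the root (O), loop onto its own path (L, with
the re-entry pixel recorded so the enclosed loop is still usable as a
candidate), meeting its own tree (C), a parent crossing point (CP) or
the path to its parent (P), cumulative length beyond
`max_trace_distance` (D), response below `intensity_drop_fraction`
times the root response (I — relative, hence invariant to global
intensity scaling), or a net turn of more than `sharp_turn_max_angle`
degrees over `turn_window` steps (T; the *signed* sum is used so the
+-45-degree zigzag of a digitised curve cancels instead of
accumulating). Child ridglets spawn where a trace was obstructed and at
path pixels where a strong unclaimed ridge meets the path (envelope
junctions); spawn pixels are recorded as crossing points. Growth is
capped at `branch_depth` generations and 16 ridglets per tree, which
keeps trees shallow, terminating and cheap even on noise webs.

**Candidate shapes and features.** Every unordered pair of leaves
proposes a closed contour: the two root-to-leaf paths, closed by the
shortest pixel segment between the leaf termini. Walks that touch
themselves are repaired by excising the sub-loop between the two visits
of a repeated pixel (the contour closes at the self-intersection);
whatever remains must be a simple closed 8-connected chain or the pair
is dropped silently. Contours are rasterised (outline = chain,
interior = the complement region not 4-connected to the outside;
area = |outline| + |interior| throughout). Each candidate is described
by 13 features: outline and interior intensity mean and SD, their
ratio, area, perimeter, circularity 4&pi;A/P&sup2;, convex and concave
outline fractions, and a three-bin histogram of chain-code turn
magnitudes (0, 45, >= 90 degrees). Convexity is decided on the net turn
over a 5-pixel window, calling a pixel convex/concave only when that
net turn reaches 90 degrees — digitisation wobble therefore counts as
straight.

**Ranking.** A Gaussian naive Bayes classifier, trained on annotated
candidate shapes (valid nucleus sections vs internuclear gaps, merged
pairs, off-target blobs), scores every candidate; the winner per tree
is the highest posterior above `posterior_cutoff` (0.5). Winners from
different trees in one plane are reconciled greedily by descending
posterior — near-ties (2% bins) resolve toward the larger shape so a
full envelope beats the two halves a crossing wall can offer — with
>50%-overlapping duplicates discarded and lesser overlaps trimmed to
pixel disjointness.

Training rows are bootstrapped from an annotated (or synthetic) pair of
intensity and label images: the candidate stages run as usual and each
candidate is labelled by its Jaccard overlap with the reference areas
(>= 0.7 valid, <= 0.3 invalid). In sparse scenes almost no invalid
candidates arise, so valid contours are additionally re-measured at
translated off-nucleus positions to provide genuine negative rows.

## Linking 2D areas into 3D nuclei

Accepted areas become nodes of a directed graph. An edge `a@p -> b@q`
(q > p) requires `q - p <= max_jump` planes, centroid distance at most
`max_intercentroid_distance` (um; default 8, which must exceed the
centroid shift a merged co-section has against its true partners —
about one nucleus radius), and an overlap fraction of at least
`overlap_threshold` (by default the larger of the two per-area
fractions; a `min` dialect is selectable). A target already linked to a
nearer upstream plane receives no longer-jump edges.

Competing links are arbitrated with the Jaccard index: wherever one
area holds several in-edges (or out-edges) from the same plane, the JI
between that area and the *union* of its competitors is compared with
the best single-partner JI. If the union wins, the area is a
co-section of several nuclei and is divided between the partners by
nearest-centroid pixel assignment; otherwise only the best edge
survives. Groups resolve in descending union-JI order, so when both
sides of an area are ambiguous the stronger side dictates the outcome.
This is the step that rescues a plane where two touching nuclei were
accidentally traced as one: its correct neighbours above and below
carve the merged area in two.

Surviving edges are consumed in descending JI (ties: lower plane, lower
id); each edge propagates an instance ID or mints one, chains meeting
later are united, and the result is a set of per-instance plane stacks.
Volumes below `min_volume` (um^3) or spanning fewer than `min_span`
occupied planes are discarded — a single-plane detection is almost
always an artifact, since any real nucleus several micrometres across
spans multiple optical sections — and volumes above `max_volume` are
kept but flagged for splitting.

## Post-hoc refinement

Two axial profiles diagnose under-segmentation:

* **Intensity ratio (IR)** — per plane, mean intensity over the central
  region (within half the equivalent radius of the centroid) divided by
  the mean over the rim pixels. Mid-nucleus planes of a shell-labelled
  nucleus sit far below 1; the interface plane of two stacked nuclei is
  envelope material through the centre and jumps to about 1 or above.
  A volume is cut at an interior IR peak that exceeds both flanking
  minima by `ir_prominence` (default 1.5); the peak plane joins neither
  half. Clean nuclei are safe because their high-IR planes are the
  axial tips, which are never interior peaks.
* **Centroid displacement (CD)** — the xy distance (um) between
  consecutive plane centroids. A laterally fused pair shows an isolated
  CD peak at the junction; the cut requires the peak to exceed
  `cd_prominence` (default 3) times the median CD *and* an absolute
  floor of `cd_min_peak_px` pixels, so the digitisation jitter of a
  straight stack (median CD near 0) can never trigger a split. A
  steadily drifting (helical) volume has no isolated peak and is left
  alone.

Splits are binary and iterate until stable, so three stacked nuclei
resolve in two passes. Both halves must satisfy `min_volume` or the
cut is refused.

Finally each volume is smoothed morphologically: tips are extended by a
doubly-eroded cap where the terminal area exceeds 60% of its
neighbour (abrupt truncation artifacts — for a small nucleus whose top
and bottom sections were not traced this recovers a substantial part of
the volume), then a 3D closing-then-opening with a one-voxel cross
(z arms dropped when dz exceeds twice the xy pixel) removes
single-plane spikes. Closing-then-opening is an idempotent
morphological filter, so smoothing twice changes nothing beyond the
first pass; a guard reverts the filter (not the deliberate tip caps)
if it would move the voxel count by more than 20%.

## Benchmarking

`match_instances()` compares a segmentation with ground truth under a
mutual-majority rule: a GT-test pair is a candidate match when their
overlap exceeds half of each instance's volume. Several GT instances
whose majority cover is the same test instance are a *merge*; one GT
majority-covering two or more test instances is a *split*; an exclusive
mutual pair is *accurate*; remaining GT are *misses* and uninvolved
test instances *spurious*. Precision is accurate / all test instances,
recall accurate / all GT, F their harmonic mean. A Jaccard-cut dialect
(`rule = "jaccard"`) is available because the matching rule used by
comparable benchmarking tools varies. The whole classification is
validated in the test suite against a brute-force re-statement of the
rule on random toy volumes, and error maps (accurate/merge/split/
spurious/miss codes) can be written as label TIFFs.

## The synthetic scene generator

`generate_scene()` renders rotated ellipsoids as a bright shell
(`shell_um` thick, by thresholding the implicit ellipsoid coordinate)
around a dimmer interior on a dark background, with exact ground-truth
labels (full solids; contested voxels go to the nearest surface).
Crowding modes: `sparse` (separated), `touching` (surfaces may abut and
share boundary voxels), `stacked` (pairs along z) and `offset_fused`
(pairs along z with a lateral offset). Degradations reproduce the
robustness axes at desk scale: clipped additive Gaussian noise
(`add_noise`), axial intensity falloff `exp(-lambda z)`, plane
decimation to a coarser z step (`resample_z`), and linear bit-depth
conversion (`reduce_bit_depth`).

Default study conditions, fixed before any benchmarking and used by
`scripts/acceptance.R`: 12-bit intensities with shell 3000, interior
600, background 150; nuclei with mean semi-axis 3.5-5 um and per-axis
anisotropy 0.8-1.25; shell thickness 1 um; voxels 0.5 x 0.5 x 1 um.
The evaluation scene packs 50 touching nuclei into 100 x 100 x 40 um;
the training scene packs 8 touching nuclei into 45 x 45 x 26 um; a
classifier is trained once on candidate shapes harvested from the
training scene rendered at noise levels 0, 12 and 25% of the
shell-background contrast (10 valid + 10 invalid rows per level), so
the same model serves the whole image-quality sweep.

What the generator does *not* emulate: optical PSF anisotropy and
z-blur, chromatic or depth-dependent aberrations, texture inside
nuclei, autofluorescent debris, and envelope invaginations. Passing
the synthetic benchmarks therefore demonstrates the algorithmic
machinery (tracing, ranking, linkage, refinement, benchmarking) under
controlled geometry and noise, not performance on any particular
microscope's data, for which the classifier should be retrained on a
few annotated shapes from that data.

## Numerical choices and degenerate inputs

* Gaussian kernels are sampled to 6 sigma and normalised; the
  second-derivative kernel is shifted to exact zero DC so constants map
  to exactly zero response. Borders are handled by symmetric padding.
* Tie-breaks are fixed everywhere (clockwise neighbour scan from the
  previous direction; lexicographically smallest pixel of a maxima
  plateau; lower plane then lower id for equal JI), so identical inputs
  give identical outputs, independent of worker count or plane order.
* A seed on zero response yields an empty tree, not an error; a
  contour whose interior is empty is dropped; an empty candidate list
  simply records the seed as missed (code M).
* Images larger than memory are processed through the plane accessor
  (`read_volume(..., stream = TRUE)`); the streamed and in-memory paths
  are byte-identical by construction and by test.
* Time series are segmented frame by frame, in any order, with memory
  bounded by one frame.

## Parameters at a glance

| parameter | unit | default | role |
|---|---|---|---|
| `ridge_scale` | px | 1.5 | envelope half-thickness for the ridge filter |
| `dog_sigma_small`, `dog_sigma_large` | px | 1.5, 3 | seed band-pass |
| `seed_threshold` | intensity | 300 | seed gate; the image-quality knob |
| `smoothing_sigma` | px | 0 (off) | optional 3D pre-smoothing for very noisy data |
| `min_span` | planes | 2 | minimum occupied planes per emitted volume |
| `intensity_drop_fraction` | — | 0.08 | trace stop relative to root response |
| `sharp_turn_max_angle` | deg | 150 | net-turn stop over `turn_window` = 5 steps |
| `max_trace_distance` | px | 300 | trace length cap |
| `max_intercentroid_distance` | um | 8 | linkage centroid gate |
| `overlap_threshold` | fraction | 0.35 | linkage overlap gate |
| `max_jump` | planes | 2 | widest plane gap a link may span |
| `min_volume`, `max_volume` | um^3 | 40, 2000 | emitted volume constraints |
| `ir_prominence`, `cd_prominence` | — | 1.5, 3 | split peak prominence |
| `posterior_cutoff` | — | 0.5 | classifier acceptance |

## Known limitations

* Tracing operates on the pixel grid; no sub-pixel localisation.
* The greedy JI-ordered linkage is the method — no global optimisation
  over the link graph is attempted.
* At noise beyond roughly half the shell-background contrast the
  per-plane stage degrades faster than the 3D linkage can repair;
  recovering that regime requires the 3D pre-smoothing plus a
  classifier retrained with a few shapes annotated at that quality,
  and the refreshed pipeline still sits a few points below its
  clean-image accuracy.
* Very flat nuclei spanning fewer than about 3 planes cannot profit
  from the axial profiles and are linked on overlap alone.
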