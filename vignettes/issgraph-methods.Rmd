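---
title: "Graph-based ISS decoding and spatial compartment analysis: methods"
author: "issgraph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based ISS decoding and spatial compartment analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the numerical choices made where the
design was open, and what the synthetic-data tests do and do not demonstrate
about real data.

## The measurement model

Targeted in situ sequencing reads barcodes of length $n$ over $\{A,C,G,T\}$
directly in tissue. Each targeted transcript is converted into a rolony — a
rolling-circle amplified DNA ball of roughly 1 µm — that emits one
diffraction-limited spot per sequencing cycle in the base channel of its
current barcode letter, and in the general ("anchor") stain channel in every
cycle. The decoding problem is to link spots across cycles into per-rolony
paths and read off the channel letters, in the presence of:

* **spectral bleed-through** — a fraction of each spot's intensity appears
  in a neighbouring channel, creating duplicate detections;
* **residual registration error** — a spot's position wanders by a fraction
  of a pixel between cycles even after alignment;
* **autofluorescent background and sensor noise** — spurious local maxima
  that a generous detection threshold necessarily admits.

## Normalization and tiling

For every cycle and anchor/base channel, `estimate_normalization()` samples
`n_patches` (default 50) random square patches (default 128 px) and sets

* background = mean over patches of the patch intensity **mode** (binned:
  width 1 for integer data, 256 equal bins otherwise — a mode is undefined
  for continuous values);
* signal = the 99th percentile over patches of the per-patch 98th intensity
  percentile.

`normalize_stack()` maps background to 0 and signal to 1 linearly, clipping
below 0 and retaining values above 1 (bright spots may exceed the robust
signal estimate). Normalization is estimated per whole image and is
overridable per tile; `tile_stack()` partitions a slide into non-overlapping
tiles for memory-bounded processing, and `refine_alignment()` provides a
translation-only FFT cross-correlation touch-up of each cycle against a
reference cycle's anchor (whole-slide multiresolution registration is
assumed done upstream).

Two properties of this estimator matter in practice and are deliberately
surfaced rather than hidden:

* A channel whose image carries (almost) no real spots has its "signal"
  estimated at a noise quantile; the channel then normalizes noise to order
  one. A constant channel raises a *degenerate channel* error. This is why
  barcode panels should be **channel-balanced** — `design_codebook()`
  constructs panels whose letter usage is even at every cycle position, the
  way practical panels are designed.
* With sparse spots the signal estimate sits in the spot intensity mid-tail
  rather than at peak level, so normalized spot peaks land around 1–3 and
  the noise floor around 0.02–0.04. The detection threshold default below
  is chosen relative to that scale.

## Spot detection and merging

`detect_candidates()` applies a white top-hat filter (disk radius 2 px, the
typical rolony radius at 20× magnification) and then the **h-maxima
transform**: the morphological reconstruction by dilation of $f-h$ under
$f$ suppresses every regional maximum whose dynamic is below $h$; the
surviving maximum plateaus become signal candidates. The default $h = 0.2$
keeps a ≥5× margin below the faintest simulated spots while sitting above
the noise-prominence band of the normalization described above — a generous
threshold in the sense that real spots are essentially never rejected, with
residual noise removed downstream by the probability model. No installed R
package provides grayscale reconstruction, so it is implemented in-package
(vectorized parallel dilation with exact convergence); the test suite
checks it against an independent sequential-scan reconstruction on 100
random images.

Candidate positions are refined to sub-pixel precision with an
intensity-weighted centroid over a 5×5 window. This is standard spot
localization practice, and it is load-bearing here: with integer plateau
coordinates, registration jitter plus quantization pushes true inter-cycle
distances onto and past the connection thresholds ($d = 2.0$ exactly at a
strict $d_{th} = 2$), losing ~10% of rolonies.

`merge_channels()` groups, within one cycle, candidates from different
channels whose rounded positions coincide or are 4-adjacent (transitively),
keeping the highest-intensity member and recording the suppressed ones —
these are the *competitors* of the per-base quality below. Intensity ties
keep the lexicographically smallest (channel, x, y) for determinism.

## Signal probability

Each candidate receives a probability $p$ of being true signal from its
5×5 normalized intensity window. The default model is a ridge-regularized
logistic regression on the 25 pixels plus four summary features; the
architecture is deliberately pluggable (any object with a
`predict_window_prob()` method), because the decoding equations consume
only $p$. Training examples are **nominated by the detector** and labelled
by ground-truth proximity: spurious-but-real fluorescent spots count as
*signal* (separating rolonies from spurious signal is the graph's and the
codebook's job, not the window classifier's), bleed-through twins are
ambiguous and dropped, and the noise class is drawn from detector false
alarms nominated at a more generous threshold (default $h = 0.08$) so that
borderline noise peaks are represented. The reported AUC is 5-fold
cross-validated; an in-sample AUC with 29 features is optimistic (~0.67 on
permuted labels). Probabilities are clamped to $[10^{-6}, 1]$ so node
weights stay finite.

Because the classifier consumes *normalized* intensities, a model should be
applied to data normalized under comparable conditions (field size and spot
density); the packaged helpers train on a simulation matching the target
conditions.

## Graph decoding

Candidates become split D-nodes: an in/out pair joined by an edge of weight
$w_i = -\log p_i$. Candidates of different cycles closer than $d_{th}$
(default 2 px) are linked, and the connected components of that graph are
the decoding units. Within each component, additional *forced* edges join
unconnected candidates of consecutive cycles closer than $d_{max}$ (default
3 px); links between non-consecutive cycles are then removed; inter-cycle
edges carry $w_{ij} = -\log\left(\frac{1}{1 + k\,d_{ij}}\right)$ with
$k = 1$ by default. A source feeds all first-cycle nodes and all last-cycle
nodes drain into a sink at zero cost.

With unit capacity on every node (via its internal edge) and every
inter-cycle edge, a feasible flow decomposes into node-disjoint
source–sink paths, each visiting one candidate per cycle. The solver finds
the **maximum flow of minimum cost** by successive shortest-path
augmentation (Bellman–Ford on the residual network, since residual arcs
carry negative costs); with non-negative original costs each augmentation
maintains cost-optimality for its flow value, so the final flow is the
largest set of disjoint barcode paths at least total cost. Near-ties are
resolved toward the first-found path under a fixed edge ordering, making
results run-to-run deterministic. Components that do not span all cycles
yield no reads — a complete barcode needs one base per cycle.

The test suite and the acceptance script verify optimality against
exhaustive enumeration of node-disjoint path sets on hundreds of random
small graphs; the packaged `worked_example_fixture()` realizes the canonical
14-detection worked example (two components; three paths decoding TAGT,
GCAC, GCAG past two low-probability noise detections). The fixture's
numeric positions and probabilities are implementation choices that realize
that topology at the default distances.

`decode_reads()` concatenates channel letters in cycle order, looks the
barcode up in the codebook, places the read at the centroid of its
detections, and records the maximum pairwise detection distance. Unmatched
barcodes are labelled `UNEXPECTED` and retained — they are the negative
class for quality calibration.

## Read quality

Per decoded base, with competitors the merged-away candidates of that cycle
whose probability exceeds 0.5:

$$Q_{sb} = \frac{I\,p}{I\,p + \max_c I_c\,p_c},$$

and $Q_{sb} = p$ with no competitor. Per read,

$$Q_s = \mu_s \sum_{b=1}^{n} Q_{sb}, \qquad
\mu_s = \mathrm{clip}\!\left(1 - \frac{\log(1+d)}{\sigma},\, 0,\, 1\right),$$

where $d$ is the maximum distance between the path's detections. Natural
logarithms are used throughout, consistent with the graph weights, and
$Q_s$ is a **sum** over bases, so it ranges over $[0, n]$ and the
conventional read filter $Q_s \ge 2$ (inclusive) retains roughly the reads
whose bases are confident and whose geometry is tight. $\sigma$ is chosen
on a grid (default 20 log-spaced values in $[0.5, 10]$) to maximize the
ROC AUC separating codebook matches from `UNEXPECTED` reads, smallest
$\sigma$ on ties. `decode_stack()` only trusts this calibration when both
classes have at least 50 reads: an AUC landscape estimated from a handful
of junk reads is noise, and because the downstream threshold is fixed at 2,
a spuriously small $\sigma^*$ silently discards most true reads. Below that
evidence level a fallback $\sigma = 3$ is used (at which a typical
one-pixel-wide path retains $\mu_s \approx 0.77$).

## Patch expression, normalization, compartments

Quality-filtered reads are aggregated over a regular grid of 128-px tiles,
each patch counting reads in a window of
$\texttt{tile} + 2\cdot\texttt{overlap} = 384$ px (half-open intervals), so
neighbouring windows share two-thirds of their area and one read
contributes to up to 9 patches. Gene columns with fewer than 500 decoded
reads (each read counted once) and then patches with fewer than 10 counted
reads are dropped (strict thresholds). `normalize_matrix()` applies the
Anscombe transform $2\sqrt{x + 3/8}$, regresses each gene on
$\log(\text{patch total} + 1)$ by OLS keeping residuals (removing
cell-density confounds; the $+1$ only matters for hypothetical empty
patches), and scales each gene to zero mean, unit variance. A state flag
rejects double normalization; zero-variance genes are zeroed with a
warning.

`embed_patches()` embeds all samples jointly with UMAP
(`n_neighbors = 15`, `min_dist = 0.1`, seeded, single-threaded for
determinism): 3 dimensions min–max normalized to $[0,1]^3$ for RGB maps, or
50 dimensions for clustering. Spectral initialization is ill-posed when the
target dimension approaches the gene-panel size, so embeddings beyond 3-D
start from random coordinates. `cluster_patches()` builds a kNN graph
(default $k = 20$, the customary neighbourhood size for expression graphs)
and runs Leiden community detection with the modularity objective at
resolution 0.5. Both defaults were set by their behaviour on planted-region
simulations: $k = 15$ leaves sparse subgraphs that modularity splits, and
resolution 1.0 fragments single coherent compartments into ~3 pieces
(adjusted Rand index ~0.47 against planted truth versus 1.0 at 0.5). Higher
resolutions remain available for finer parcellations of large sections.

Cluster profiles are raw counts summed over member patches, divided by the
member count (area) and scaled to unit total; `match_clusters()` groups
profiles across samples by average-linkage hierarchical clustering on
$1 - $ Pearson correlation, exports Newick, and cuts the tree into a
configurable number of groups (e.g. the top 20 distinct compartments).
`subset_panel()` re-derives a matrix from the raw counts of a marker set —
the packaged 18-gene panel (6 inhibitory, 6 pan-excitatory, 2 layer,
4 shared markers) supports compartment definition that leaves the remaining
genes untouched for unbiased differential expression
(`differential_expression()`: per-gene two-sided Wilcoxon rank-sum of
compartment vs rest on raw counts, Benjamini–Hochberg correction per
compartment, natural-log fold change of means; compartments under 3 patches
are skipped with a warning).

## Atlas comparison by KL divergence

`pattern_from_reads()` rescales a gene's read coordinates onto a target
voxel grid and evaluates a Gaussian kernel density whose kernel covariance
is $0.05^2$ times the data covariance of the rescaled positions — the
"covariance factor" is read as the bandwidth scaling applied to the data
covariance, the convention of standard KDE implementations. Per-axis kernel
standard deviations are floored at half a grid cell: a kernel much narrower
than the grid aliases the density (and degenerates entirely when all reads
coincide). Densities are normalized to total mass 1.
`kl_divergence()` computes $\sum_v p_v \log(p_v/q_v)$ with the reference
floored at $10^{-12}$ so sparse reference grids keep the divergence finite;
the direction is KL(decoded ‖ reference). `kl_match_table()` scores each
gene by KL(self pair) − min KL(off pairs) and sorts rows and columns
ascending, so genes whose decoded pattern is best explained by their own
reference pattern come first; top-k/bottom-k extraction is provided.
Reference grids are consumed as plain 2-D matrices — selecting a coronal
level from a 3-D atlas grid, and obtaining the atlas at all, is the
caller's responsibility.

## The synthetic-data generator

`simulate_iss()` emulates: uniformly placed rolonies with a minimum
centre separation of 4 px (rolling-circle products are ~1 µm solid balls
and cannot coincide), log-normal peak amplitudes
($e^{\log 900 \pm 0.25}$ over a background of 100), a Gaussian PSF
($\sigma = 1.5$ px), one spot per cycle in the barcode's channel plus the
anchor, a fixed-fraction (default 0.1) bleed-through copy into the next
base channel (cyclically A→C→G→T→A; the underlying mechanism is spectral
leakage into adjacent emission bands), independent per-cycle positional
jitter ($\sigma = 0.5$ px), Poisson-count spurious spots (10 per
base-channel image, at ~1/e of rolony amplitude, with positions reported in
the output), additive Gaussian noise ($\sigma = 10$), and a static nuclei
texture. Identical configurations are bit-identical. The default field is
256 px with 200 rolonies — about 0.3 spots per 100 px², a realistic
moderate density at which the percentile normalization sees enough spot
pixels per patch to estimate signal meaningfully.

`simulate_patch_expression()` emulates the *input of the compartment
stage* directly: a patch grid split into vertical bands, each expressing a
disjoint program of marker genes (Poisson mean 20 inside, 2 outside, 2 for
panel-padding background genes).

What passing tests on these simulations do **not** show about real data:
the generator has no tissue autofluorescence texture, no optical
aberrations, no z-dimension, no chromatic misregistration beyond rigid
jitter, no cross-*cycle* bleed-through, and barcodes behave identically in
every cycle (no chemistry decay); the tissue generator has sharp region
borders and spatially uniform cell density. Results on real slides depend
on registration quality and on panel design in ways the simulations only
partially probe.

## Numerical and reproducibility choices

* All randomness is seeded explicitly; seeds are recorded in result
  objects. UMAP runs single-threaded; Leiden runs under a set seed.
* Min-cost flow tie-breaks follow a fixed deterministic edge order;
  merging ties prefer the lexicographically smallest (channel, x, y).
* Degenerate inputs fail loudly: constant channels, single-class training
  data, unfitted models, all-filtered matrices, constant profiles,
  sub-2-read KDEs, mismatched grids and panels all raise errors naming the
  offender.
* Problem sizes in the tests and the acceptance script: 256-px fields with
  200 rolonies and 5 replicates for end-to-end decoding; 200 random graphs
  of ≤ 12 candidates for solver verification against brute force; 18×18
  patch grids with 3 planted regions for compartment recovery; 100 random
  64×64 images for the reconstruction oracle. These sizes give stable
  statistics while keeping a full run in the minutes range on one CPU.

## Known limitations

* 2-D only; z-stacks must be projected upstream.
* The percentile normalization assumes every (cycle, channel) image
  contains real spots; channel-starved panels degrade gracefully but
  noticeably (see `design_codebook()`).
* No error-correcting barcode matching: one wrong base loses the read to
  `UNEXPECTED` rather than rescuing it at Hamming distance 1.
* The signal probability model is intentionally simple; with hard real
  data a stronger classifier can be substituted behind the same contract.
* `calibrate_sigma()` optimizes class separation, not compatibility with
  the fixed quality threshold; with few off-target reads the fallback
  $\sigma$ is used deliberately.
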