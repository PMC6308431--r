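---
title: "Methods: blastocyst image grading and the small-image scaling algorithm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blastocyst image grading and the small-image scaling algorithm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blastograde)
```

## The problem

Bovine blastocysts are graded on the IETS quality scale (1 excellent/good,
2 fair, 3 poor) by visual inspection, which is notoriously
evaluator-dependent. An image pipeline replaces that judgment with numeric
variables extracted from a segmented brightfield capture. Two capture
regimes matter in practice: inverted-microscope images, where the embryo
fills roughly a quarter of the frame, and smartphone captures taken through
a stereomicroscope ocular, where the embryo occupies between about 0.2% and
3% of the frame and the standard segmentation fails outright. This package
implements the grading pipeline and the scaling algorithm that rescues the
small-embryo regime, plus a synthetic generator that stands in for real
captures in every test.

## Standardization

All inputs are reduced to a canonical working image: 8-bit grayscale
(BT.601 luminance weights, rounded half-up — recorded as a module
constant), 640 × 480 pixels, contrast-stretched so 1% of the pixel mass
saturates. Design choices the pipeline fixes where the procedure is
underdetermined:

* **Aspect handling.** The larger relative dimension is scaled to fit and
  the remainder is center-padded with the median border intensity. Padding
  is recorded on the object so downstream stages can ignore those margins;
  an alternative (distorting to fit) would silently change radii and break
  the Hough windows' physical meaning.
* **Saturation split.** The 1% saturated mass is split evenly, 0.5% per
  tail. The stretch quantiles are computed on the un-padded content only.
* **Interpolation.** The standardization resize is bilinear; bicubic
  interpolation is deliberately reserved for the scaling algorithm, where
  information preservation under magnification is the point.

The stretch is monotone and idempotent up to one intensity level, which the
suite checks.

## Segmentation

Edges come from the 3 × 3 Sobel pair (replicated borders); the magnitude is
min–max rescaled to [0, 255] per image so the fixed threshold of 128
means the same thing across exposures (values equal to the threshold count
as edges). The circular Hough transform then votes: every edge pixel votes
for all centers at distance *r*, and a candidate's *strength* is its vote
count divided by the ideal full-circle count for that radius — a complete
ring scores near 1 regardless of size. The search runs in two stages,
radii 100–150 then 151–200 px, keeps the best candidate of each, and picks
the stronger, ties toward the larger radius. Candidates under a strength
floor of 0.25 are rejected; that floor is what makes a blank frame, or a
60 px embryo, return "no detection" rather than noise. The coarse sweep
uses a 2 px radius step and the winner is re-scored at 1 px resolution —
at the suite's 3 px recovery tolerance the quantization is invisible, at
half the accumulator cost.

Region isolation applies the pipeline's fixed offsets: ER = detected disk
grown 5 px (zona pellucida included), RR = disk shrunk 40 px (inner cell
mass + blastocoel), TE = ER minus RR. Disks are inclusive
("distance ≤ radius"), 0-based only at the C++ boundary. A detection with
radius ≤ 40 px cannot produce an RR and raises a degenerate-region error.

Segmentation status: with synthetic ground truth, full/partial/none follow
the intersection-over-union of the detected ER disk with the true embryo
disk at 0.9 and 0.3; on real images, where no truth exists, the criterion
is the fraction of above-background pixels inside ER (background = median
intensity outside ER) against a configurable fill threshold (default 0.8).

## Features and collinearity pruning

The 36-variable schema is frozen in a single registry
(`feature_schema()`): per region (ER, RR, TE) the five Haralick GLCM
statistics — contrast, correlation, energy, homogeneity, entropy — at
distance 1, 8 quantization levels (bin width 32), averaged over the 0°,
45°, 90°, 135° offsets, plus regional mean, SD and above-background area
fraction; and 12 whole-embryo variables (radii, areas, inter-region
intensity ratios, detection strength, gradient energy, ER border contrast,
above-background centroid offset and eccentricity, ER histogram entropy).
GLCMs count only pairs with *both* pixels in-mask, symmetrically; padding
never pairs with content. Degenerate cases are pinned: correlation is 0
when a marginal is degenerate, 0·log 0 = 0 in the entropy.

Pruning removes, per iteration, the single column with the largest
VIF = 1/(1−R²) strictly above 10 (ties toward the earlier schema column),
until all survive at ≤ 10. Perfect collinearity (1−R² < 1e−12) returns an
`Inf` sentinel. The constructed 36-column datasets append 12 columns, each
the mean of a disjoint pair of originals plus small noise: the appended
column's VIF is algebraically about twice its parents' (regressing the
parent on the rest must pay twice the perturbation variance), so greedy
pruning removes exactly the appended twelve — 12 removal iterations plus
one confirming pass, 13 in all.

## Grading ensemble and architecture search

Networks are feedforward, 24 inputs → up to 3 hidden layers → 3 outputs,
trained full-batch by backpropagation on cross-entropy with one-hot
targets. The 9-gene chromosome fixes: neurons per hidden layer (1–64),
transfer function per hidden layer and for the output layer (logistic,
tanh, linear), the training function (plain gradient descent, gradient
descent with momentum 0.9, or Rprop with the standard 1.2/0.5 step
adaptation), and the active depth (genes beyond the depth are carried but
inert, exactly as the search treats them). Inputs are z-scored with
training-split statistics stored on the model; weights start from a seeded
uniform(−0.1, 0.1); early stopping watches the validation loss with
patience 25 and restores the best weights. Output scores are
softmax-normalized for reporting — monotone, so the argmax is unaffected —
and exact ties in the argmax resolve toward the worse grade, a conservative
convention for a quality score.

The split is stratified 70/15/15 per class with at least one sample per
class per split, deterministic per seed. The ensemble is three independent
networks; the reported grade is their mode, and under full three-way
disagreement the mode is undefined and the final grade falls back to the
median of the three ordinal grades (a convention this package fixes; one
could equally surface all three).

The genetic algorithm evaluates fitness as test-split accuracy by default
(validation accuracy is available to avoid test leakage in model
selection), memoized per (architecture, dataset, seed). Generations carry
the population sorted by fitness: elite slots are immutable; each remaining
slot undergoes uniform crossover of two tournament-selected parents (size
3) with probability 0.8, per-gene mutation at 0.05 (redraw from the gene's
domain), and a 0.05 migration fraction is replaced by fresh random
chromosomes. This in-place scheme keeps the population unchanged (up to
ordering) when all operator rates are zero and makes the best-fitness trace
non-decreasing whenever at least one elite slot exists. Runs are
reproducible bit-for-bit from the config seed. Published-scale searches use
populations of 100–300; the suite demonstrates convergence at population 20
over 5 generations on separable features.

## The scaling algorithm

The rescue path for smartphone-regime frames:

1. grayscale, then global histogram equalization (CDF mapping; constant
   images pass through);
2. contrast magnification (2% symmetric saturation) with light box
   smoothing, and binarization. Thresholding is computed from the
   contrast-magnified *raw* intensities rather than the equalized image: on
   a frame that is ~97% background, equalization spreads the background
   mode across nearly the whole intensity range, and any global threshold —
   Otsu included — then lands inside the background. Otsu on the raw
   intensities anchors correctly whenever the embryo carries enough mass;
   when it does not (the sub-1% regime) the foreground fraction it returns
   is implausibly large, and the binarization falls back to the 1%
   intensity tails, keeping the tail whose mask is more spatially coherent
   (larger connected component). Polarity is normalized so foreground is
   the minority class.
3. a variable-range circular Hough sweep over radius windows 8–20, 20–45,
   45–75, 75–100 px on the *boundary* pixels of the mask (interior pixels
   of a filled blob would vote all radii below the true one to full
   strength), strongest window winner above the 0.25 floor;
4. if the sweep fails, a watershed of the Euclidean distance transform
   proposes regions scored by circularity 4πA/P² (≥ 0.6) and area (≥ 50
   px); the equivalent-disk radius is √(A/π);
5. crop a box of 3 detected radii around the center, expand by the bicubic
   patch interpolant f(x, y) = Σ aᵢⱼ xⁱ yʲ fit through each 4 × 4
   neighborhood (clamped replication at edges) — exact for surfaces that
   are polynomials of degree ≤ 3 in each coordinate, which the suite
   verifies at 1e−6 — to a target radius of 150 px, the midpoint of the
   main detector's windows, and center the result on a 640 × 480 canvas
   padded with the crop's median border value. Expansion is capped at 20×
   as a guard against watershed slivers implying absurd scales.

The pipeline attempts the rescue only after the primary two-stage detection
fails, and records the provenance on the report.

## The synthetic generator

Rendered embryos are the testbed, so their realism bounds what the tests
can show. Each image contains one embryo: a bright zona-pellucida ring at
the true radius (4 px thick at radius 150, scaled proportionally), a
textured trophectoderm annulus (40 px at radius 150, scaled), a darker
blastocoel and an off-center inner-cell-mass blob, over a flat or gradient
background with Gaussian pixel noise (default SD 5, a level at which
detection remains reliable; the suite's recovery guarantees are stated for
SD ≤ 10). Grade drives degradation: grade 1 is clean and symmetric; grade 2
erases 15% of the ring in arcs, adds 2% radial wobble and drops ring
contrast; grade 3 erases 35%, wobbles 5%, drops contrast further and adds
vacuole speckles. Smartphone regimes render at 1280 × 960 and downsample by
two, mimicking capture through an ocular. Radius defaults per regime —
100–200 px (microscope), 45–75 px (Dataset-1-like smartphone), 10–20 px
(Dataset-2-like) — are calibrated against the reference occupancies (about
27%, 3% and 0.24% of the frame area respectively); since the microscope
default range is wide, the calibration band (20–35% area) is asserted on
the mean over draws rather than per draw.

What the renderer does **not** model: optical blur and chromatic effects,
debris and multiple embryos, MOET-vs-IVP appearance differences, uneven
illumination beyond a linear gradient. Passing tests therefore demonstrate
the machinery — detection geometry, feature computation, learning dynamics
— not clinical-grade performance on real captures; the grading networks are
always trained fresh on whatever data they are given, and no claim is made
that synthetic-trained weights transfer to real images.

## Numerical and statistical conventions

* Two-sided Fisher exact p-values sum the hypergeometric point
  probabilities not exceeding the observed table's — stated explicitly
  because two-sided conventions differ; the suite cross-checks against a
  full enumeration oracle.
* The chi-square test uses no continuity correction; expected counts must
  be positive; significance is read at 5%.
* Problem sizes in the suite and the acceptance script are chosen for
  desk-scale runs: 50 seeds for circle recovery, 20 for the rescue
  property, GA population 20 over 5 generations, 120 training epochs per
  fitness evaluation. Each is a deliberate scaled-down setting of the
  published-scale procedure (populations of 100–300, hundreds of epochs).

## Known limitations

* The 36-variable schema is this package's reconstruction; the historical
  variable list it stands in for was never published. The registry is
  centralized precisely so a different schema can be swapped in without
  touching segmentation or grading.
* The Hough accumulator quantizes centers to the pixel grid; sub-pixel
  refinement is out of scope.
* `classify_status` on real images uses a heuristic fill criterion; the
  IoU bands apply only when ground truth exists.
* Grade-3 embryos in the smallest smartphone regime localize least
  reliably (heavy ring erasure at radii near 10 px leaves little
  circumference to vote with) — consistent with the harder of the two
  capture regimes remaining harder after rescue.
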