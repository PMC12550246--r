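---
title: "Multi-level descriptor fusion for leaf classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-level descriptor fusion for leaf classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Fine-grained plant identification from leaf photographs is hard
precisely where it matters: morphologically similar species differ in
subtle pigmentation, venation frequency, surface micro-texture and
margin geometry rather than in gross appearance. `leaffusion`
implements a classical answer to this: describe each leaf with four
complementary handcrafted descriptors — one for color, two for texture
at different granularities, one for shape — and classify on their
concatenation, so that no single failing cue sinks the prediction.

The pipeline is, per image:

1. bilinear resize to the working resolution (default 128×128),
2. grayscale conversion (BT.601 luma) for the texture/shape descriptors,
3. descriptor extraction: C1 joint 3-D color histogram, C2 riu2 LBP
   histogram, C3 Gabor bank statistics, C4 HOG,
4. fusion by concatenation with a recorded segment map,

then, per dataset: SMOTE balancing, per-column z-scoring, and
stratified k-fold evaluation of a classifier suite, followed by an
inter-class cosine-similarity diagnostic and an optional stress pass.

The implicit assumptions are those of every handcrafted-descriptor
model: leaves are photographed against a quiet background at roughly
consistent scale; color is informative but not reliable alone (hence
the texture/shape channels); and descriptor statistics pooled over the
whole frame are acceptable (no segmentation is performed — see
Limitations).

# Descriptor parameters and their meaning

**Color (C1).** The joint histogram discretizes the RGB cube into
`8 × 8 × 8` cells (channel value `v` falls in `floor(v·b/256)`),
flattened R-major and divided by the pixel count. The *joint* form is
the default because inter-channel correlation — which greens co-occur
with which browns — is exactly what distinguishes look-alike species; a
`color_mode = "marginal"` flag produces the three concatenated
per-channel histograms (24-D) for comparison with the cheaper variant.
Equal-width bin edges over [0, 256) are assumed; nothing in the method
depends on a different edge convention.

**LBP (C2).** Each pixel's `P = 24` circular neighbors at radius
`R = 3` are sampled by bilinear interpolation and thresholded against
the center with ties counting as 1 (`S(t) = 1` iff `t ≥ 0`; an interior
tolerance of 1e−9 keeps interpolation round-off from flipping exact
ties, which is what makes a constant image land entirely in the
all-ones bin). The rotation-invariant uniform ("riu2") reduction maps
patterns with ≤ 2 circular transitions to their ones-count and the rest
to one residual bin: `P + 2 = 26` bins. This is the only mapping
consistent with a 26-bin histogram at P = 24 (plain uniform LBP would
give 555 bins), and `lbp_pattern_bins(24)` verifies the count by
enumerating all 2²⁴ patterns. Border pixels without a full neighborhood
are excluded rather than padded, so the histogram is a statistic of
honestly observed patterns only.

**Gabor (C3).** The real kernel
`exp(−(x′² + γ²y′²)/(2σ²))·cos(2πx′/λ + ψ)` is built for every
(orientation, scale) pair with λ = 1/frequency, frequency 0.6
cycles/pixel (λ ≈ 1.67 px — a mid-frequency probe at the working
resolution), ψ = 0, γ = 0.5, kernel half-width ⌈3σ⌉. Orientations
{0°, 45°, 90°, 135°} × σ ∈ {1, 2, 3} give 12 filters; each contributes
the mean and standard deviation of its reflect-padded convolution
response, 24 values in all. Intensities are rescaled to [0, 1] first so
the statistics are bit-depth stable. ψ and γ are not dictated by the
method; the common defaults are fixed here and echoed in the config
output for provenance. With ψ = 0 the kernel has exact 180° parity,
which the tests assert. The "frequency 0.6" setting is read as
cycles/pixel; it is a config knob, so the alternative reading (a
library-normalized unit) costs one argument to reproduce.

**HOG (C4).** Central-difference gradients with edge replication;
unsigned orientations on [0°, 180°) in 9 bins (the canonical
configuration); per-cell magnitude-weighted votes split linearly
between the two nearest bin centers (centers at `i·20°`, wrapping at
180°, so a pure horizontal ramp votes entirely into bin 0 — a
hand-checkable anchor case); 2×2-cell blocks at 1-cell stride;
L2-Hys normalization (L2, clip at 0.2, re-L2) with all-zero blocks left
at zero, giving block norms in {0, 1} exactly. At 128×128 with 8-px
cells this yields (16−1)²·36 = 8100 values. Images not divisible by
the cell size are cropped to the largest multiple with a warning rather
than silently resampled.

**Working resolution.** The printed sources for this family of
pipelines state three different input sizes in different places
(128/224/256). 128×128 is the default here because it is the size the
end-to-end procedure is specified at and the HOG geometry is stated
alongside it; it is exposed as `resize` everywhere, never hard-coded.

# Balancing, evaluation, similarity

**SMOTE** oversamples every minority class up to the majority count:
pick a seeded random minority row, one of its k = 5 nearest same-class
neighbors (Euclidean), and emit the convex combination with a single
δ ~ U[0, 1] per sample (δ per sample, not per coordinate: the
interpolation walks the segment to one neighbor). k is capped at
class-size − 1 with a warning; a singleton class is an error naming the
class, because no neighbor exists. Original rows are never modified,
and synthetic rows carry a provenance flag — which matters later.

**Leakage policy.** The straightforward ordering — balance and
standardize the full matrix, then split — leaks synthetic copies of
test-adjacent points into training and inflates scores. The default
`"guarded"` mode therefore fits SMOTE and the z-scoring inside each
training fold only; `"paper_order"` reproduces the balance-first
ordering so both numbers can be reported side by side.

**Metrics.** Confusion matrices use rows = actual, columns = predicted.
Precision is the diagonal over the column sum, recall over the row sum
(one printed formula in the source material contradicts its own matrix
form; the matrix form is implemented), accuracy is the trace over the
total, F1 the harmonic mean. Zero denominators yield 0 with a logged
note instead of an exception, so per-class reporting survives a class
that is never predicted. Micro-averaged recall equals accuracy
algebraically; the tests assert it on random matrices. `CVp` is the
unweighted mean of each fold metric. k = 5 folds is the default (the
fully specified procedure; a ten-fold variant is mentioned elsewhere in
the source narrative and available via the `k` argument).

**Classifier suite.** Hyperparameters mirror the reference table:
SVM (RBF, C = 10, γ = 0.1), RF (100 trees), KNN (5), LR (max_iter
1000), DT (Gini, unlimited depth, min split 2, seed 42), GB (100
stages, rate 0.1, depth 3, seed 42), AdaBoost (50 stumps, rate 1.0,
seed 42), Gaussian NB (the continuous-feature variant; the table lists
no NB parameters). The runtime environment provides no CART/forest/
boosting/SVM packages, so the tree family is built on a compact Rcpp
CART core (weighted Gini or variance splits, midpoint thresholds,
per-node feature subsampling) shared by DT (all features), RF
(bootstrap + √d mtry, probability = mean of leaf distributions), GB
(multinomial deviance, depth-3 regression trees on the residuals,
Friedman leaf updates) and AdaBoost (SAMME stumps; probabilities are
normalized stage-weight votes). The SVM solves the binary C-SVM dual
with `quadprog` (one-vs-rest, small ridge on the kernel matrix for
numerical definiteness) and converts decision values to probabilities
by per-class Platt scaling so it can join the soft vote. KNN rides on
`FNN`; LR is ridge-regularized multinomial `glmnet` with a tiny penalty
(1e−4) — an unpenalized fit is not identifiable at d ≫ n. Soft voting
averages member probability matrices (uniform weights by default) and
takes the argmax, ties to the lowest class index; the default ensemble
is {SVM, RF, GB}, the members named by the method's own summary.

A note on the SVM defaults: with γ = 0.1 on thousands of standardized
features, squared distances concentrate near 2d and the RBF kernel
collapses toward the identity, so the SVM degenerates to near-priors.
This reproduces a pathology visible in the source material's own SVM
rows; the configuration is kept faithful rather than silently repaired
(a different γ is one argument away).

**Similarity.** Class means are computed on real (non-synthetic)
training rows by default — interpolated SMOTE rows would pull means
toward segment midpoints — and on standardized features, because the
diagnostic should describe the space in which misclassification
happens. Cosine similarity is mapped by `(c + 1)/2` onto [0, 1]; "the
cosine is quantized to [−1, 1]" is read as a statement of its natural
range, not as an extra quantization step. An importance-weighted
variant is mentioned in the source narrative without a formula; it is
deliberately not implemented rather than guessed.

# The stress harness

Perturbations apply to evaluation images only; training, SMOTE and the
fitted scaler are untouched. Noise is additive zero-mean Gaussian per
pixel per channel (the stated noise model; the printed equation is
ambiguous about multiplicativity), rounded and clipped, with the sweep
σ ∈ {10, 20, 30} on the 0–255 scale as a default (no sweep is printed).
Scaling resizes to 64/128/256 and back through the working resolution,
so information loss — not array shape — is what is measured. Rotations
are restricted to the lossless 90/180/270 grid set; arbitrary angles
would smuggle in an unspecified interpolation and padding policy.
Occlusion (named in the source only as a worst-case condition at 20%)
is interpreted as one seeded axis-aligned rectangle of the requested
area filled with a background color. Because the color histogram is a
pure intensity statistic, a color-only model's accuracy under rotation
equals its clean accuracy bit-for-bit — a strong internal consistency
check the suite asserts.

# The synthetic generator: what it does and does not establish

The generator renders one leaf per image: a super-ellipse silhouette
(exponent 2.5) with optional sinusoidal margin serration, filled with a
base color plus an additive 2-D sinusoidal "vein" texture at a
controllable frequency and orientation, over a near-uniform background,
with a per-image global color shift and per-pixel noise both scaled by
`color_jitter`, and mild seeded pose variation (scale 0.85–1.0, small
center offsets). Every image draws from a stream derived from
(dataset seed, class index, image index), so regeneration is
byte-identical and insertion-order independent, and the imbalance
option removes images without perturbing the rest.

The dials map one-to-one onto the descriptor axes: hue separation onto
C1, vein frequency/orientation onto C2/C3, elongation and serration
onto C4. Two regimes are packaged: `demo_class_specs()` (distinct hues
— linearly separable on color alone, which the tests assert with
logistic regression at 100% training accuracy) and
`lookalike_class_specs()` (one color-matched pair differing only in
vein texture: color-segment cosine similarity above 0.95, fused
similarity below it — the high inter-class-similarity regime the
fusion model exists for).

What a green test on this generator does **not** establish: performance
on photographs. The generator has no specular highlights, shadows,
background clutter, perspective, camera noise statistics, or biological
intra-class variation beyond color jitter and pose; its textures are
single sinusoids, not venation networks. Green tests establish that the
descriptors measure what they claim, that the pipeline is leak-free and
deterministic, and that fusion beats single descriptors exactly where
it should by construction — not that any published accuracy on a real
archive is reproduced. Reported accuracies on real leaf archives would
require that archive.

# Numerical choices and degenerate inputs

- Grayscale and noise rounding are half-up (`floor(x + 0.5)`); base R's
  banker's rounding would make fixtures platform-lottery-dependent.
- Bilinear resize maps target index `i` to source `i·src/target` with
  edge clamping (the stated floating-coordinate convention); a
  `"corners"` alignment mode (endpoints pinned) exists because the
  hand-checkable 2×2→3×3 example is naturally stated in it. The printed
  "sum of four neighbors" formula is treated as a typo for the
  fractional-weight combination — an unweighted sum would brighten a
  constant image 4×.
- LBP threshold ties count as 1, with a 1e−9 interior tolerance against
  interpolation round-off; integral sampling offsets are snapped to the
  grid.
- Zero-variance feature columns standardize to 0, not NaN.
- CART splits use midpoint thresholds between distinct sorted values;
  impurity gains below 1e−12 do not split, so constant features are
  inert.
- The SVM dual adds 1e−8·I to the kernel matrix for positive
  definiteness; the bias averages over margin support vectors when any
  exist.
- Probability ties in every argmax resolve to the lowest class index.
- All seeds funnel through one integer-mixing stream derivation kept
  below 2³¹, and RNG state is saved/restored so library calls never
  perturb user RNG.

# Known limitations

- No background segmentation or illumination correction; descriptors
  pool over the full frame.
- The AdaBoost member uses discrete SAMME stump votes for its
  probabilities — coarser than the other members' calibrated outputs.
- The SVM defaults degenerate at high dimensionality (see above) — kept
  deliberately.
- Arbitrary-angle rotation, EXIF orientation and RAW inputs are out of
  scope; the importance-weighted similarity variant is unimplemented
  for lack of a definition.
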