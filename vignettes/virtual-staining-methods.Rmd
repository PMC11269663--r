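---
title: "Virtual H&E staining with dual contrastive learning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual H&E staining with dual contrastive learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Hematoxylin and eosin (H&E) staining is the routine preparation for
microscopic examination of tissue: hematoxylin colours nuclei blue-purple,
eosin colours cytoplasm and most proteins pink.  Chemical staining is slow,
destructive and uses hazardous reagents.  *Virtual staining* replaces the
chemistry with an image-to-image translation model: a brightfield scan of
the **unstained** section (domain $A$) is translated into an image that
looks **H&E-stained** (domain $B$).

Because tissue deforms during staining, pixel-perfect supervised pairs are
not available, so the translator must be trained in the unpaired regime.
`virtualstain` implements a three-stage pipeline around a dual contrastive
learning GAN:

1. **Preprocessing** — tissue foreground segmentation, registration of the
   unstained slide onto the stained slide, extraction of overlapping
   patches, removal of background-only patches.
2. **Training** — two generators $G_1\colon A \to B$ and
   $G_2\colon B \to A$, two patch discriminators $D_A, D_B$, and two
   2-layer projection heads $H_A, H_B$, optimised with adversarial,
   identity and patchwise contrastive (PatchNCE) losses.
3. **Inference** — tile a whole slide at 50% overlap, translate each tile
   with $G_1$, and alpha-blend with a partition-of-unity weight matrix.

Evaluation uses the Fréchet distance between Gaussian fits of image
features (FID) and the polynomial-kernel squared MMD (KID).

# The model

## Contrastive correspondence

The translated image should correspond *locally* to its input: the patch at
a given location of $G_1(a)$ should look like the patch at the same
location of $a$, not like a random patch elsewhere.  This is enforced with
noise-contrastive estimation.  Each query embedding $v$ (from the
translation) is classified against its positive $v^+$ (same location in the
source) and $N$ negatives $v^-_n$ (other locations of the same image), an
$(N{+}1)$-way problem:

$$
\ell(v, v^+, v^-) = -\log
\frac{\exp(\mathrm{sim}(v, v^+)/\tau)}
     {\exp(\mathrm{sim}(v, v^+)/\tau) + \sum_{n=1}^{N}\exp(\mathrm{sim}(v, v^-_n)/\tau)},
$$

with $\mathrm{sim}(u,v) = u^\top v / \lVert u\rVert\,\lVert v\rVert$ and
temperature $\tau$ (default 0.07, the reference-implementation default; the
loss is computed with a log-sum-exp-stable formulation and stays finite
down to $\tau = 0.01$).

Embeddings come from tapped layers $l \in L$ of the generator *encoders*:
features at $S_l$ sampled spatial locations are pushed through the domain's
two-layer perceptron head and L2-normalised.  Each domain keeps its own
encoder and head ($G_{1,\mathrm{enc}} + H_A$ for $A$,
$G_{2,\mathrm{enc}} + H_B$ for $B$), which lets the two domains learn
different representations.  The multilayer PatchNCE loss for $A \to B$
uses the stack $\{z_l\} = \{H_A(G_{1,\mathrm{enc}}(a))\}$ as
positives/negatives and $\{\hat z_l\} = \{H_B(G_{2,\mathrm{enc}}(G_1(a)))\}$
as queries, averaging $\ell$ over layers and locations; $B \to A$ is
symmetric.  The same sampled locations are used on both sides — the
`sample_and_project()` contract returns the drawn locations precisely so
the paired stack can reuse them.

## Adversarial and identity terms

Each direction has a PatchGAN discriminator that outputs a spatial map of
realness logits.  The default adversarial form is the cross-entropy (log)
loss with the non-saturating generator update; the least-squares variant
used by some reference implementations is available via
`train_config(adversarial = "lsgan")`.  We default to the log form because
it is the form the objective is usually displayed in; on the synthetic task
both train stably.

The identity loss
$\mathbb{E}\lVert G_2(a) - a\rVert_1 + \mathbb{E}\lVert G_1(b) - b\rVert_1$
keeps each generator close to the identity on images already in its output
domain, which in practice preserves colour.

The collective objective is

$$
\lambda_{GAN}\,(\mathcal{L}_{GAN,1} + \mathcal{L}_{GAN,2})
+ \lambda_{NCE}\,\mathcal{L}_{PatchNCE_A}
+ \lambda_{NCE}\,\mathcal{L}_{PatchNCE_B}
+ \lambda_{idt}\,\mathcal{L}_{identity},
$$

with default weights $\lambda_{GAN}=1$, $\lambda_{NCE}=2$,
$\lambda_{idt}=1$.

## Architectures

Generators are resnet translators: a 7×7 input convolution, stride-2
downsampling stages, residual blocks, nearest-neighbour-upsample +
convolution stages (chosen over transposed convolutions to avoid
checkerboard artifacts), and a 7×7 output convolution with tanh, all with
instance normalisation.  Discriminators are PatchGAN stacks of stride-2
4×4 convolutions with leaky ReLU.  The full-size preset (64 base channels,
2 downsamples, 9 blocks; taps at the input, first convolution, both
downsamples and the middle residual block, $S_l = 256$, $K = 256$) follows
reference practice.  The **tiny preset** used throughout the tests — 8 base
channels, 1 downsample, 2 residual blocks, $K = 32$, 64 locations, 64×64
patches — is small enough to train on one CPU in minutes while retaining
every architectural ingredient.

Everything is built on a small reverse-mode autodiff tape written for this
package (R matrices, Rcpp kernels for im2col/col2im, instance
normalisation, ReLU and upsampling; BLAS for the matrix products).  All
gradients are verified against central finite differences in the test
suite, and the tape-evaluated losses are asserted
equal to the package's plain numeric loss functions — two independent
routes to the same quantities.

## Optimisation

Adam with learning rate 2e-4 and betas (0.5, 0.999) — standard GAN
practice.  Each step first updates both discriminators on detached
translations, then jointly updates both generators and both heads.
Batches are drawn *unpaired*: the two domains are shuffled independently
every epoch, so the optimiser never exploits the fixtures' pixel
correspondences.  No data augmentation is applied, matching the
fixed-orientation convention of pathology review.  All randomness
(initialisation, batch order, location sampling) derives from the
configured seed; checkpoints store weights, Adam state and iteration
counters, and a restored run continues bit-exactly.

# The synthetic data generator

Real paired unstained/stained slide scans are scarce, so the `fixtures`
module fabricates them with known ground truth:

* **Geometry** — cytoplasm blobs are a thresholded smoothed-noise field
  (threshold set to hit the requested `cytoplasm_fraction`); elliptical
  nuclei are scattered inside tissue with a Poisson count
  (`nucleus_density` per 10^4 px²) and uniform placement.  The per-pixel
  class map (background / cytoplasm / nucleus) is returned.
* **Stain oracle** — each class has a target colour (defaults: nucleus
  (72, 61, 139), cytoplasm (244, 184, 196), near-white background),
  modulated multiplicatively by the local luminance so texture survives
  and hue is preserved, and mixed across class edges with a Gaussian
  kernel.  The mapping is decidable from local class + texture — i.e.
  learnable by a patch-level translator, the property the training tests
  rely on.
* **Unstained appearance** — the latent stained luminance is compressed
  into the 200..255 band plus Gaussian noise (sd 3), mimicking the faint
  contrast of an unstained brightfield section.
* **Misalignment** — optionally the unstained image is warped by a random
  mild homography (rotation ≤ 5°, translation ≤ 20 px, small projective
  terms); the manifest stores the *aligning* transform as ground truth for
  registration experiments.

What the generator does **not** emulate: optical physics of staining,
out-of-focus blur, scanner colour profiles, tissue deformation beyond a
homography, and the scale of real slides (gigapixels).  Passing tests
therefore demonstrate the correctness of the pipeline's machinery and the
learnability of a local colour/texture mapping — not clinical-grade
staining quality on real tissue.

# Preprocessing choices

* **Foreground segmentation.**  Tissue is darker than the illuminated
  background.  A pixel is foreground if it is more than `offset` (10 gray
  levels) below its 101×101 neighbourhood mean *or* more than `2*offset`
  below the global illumination level (90th percentile of gray).  The
  purely local criterion concentrates on edges and texture — the interior
  of a region wider than the block is close to its own local mean — so the
  raw mask is morphologically closed and hole-filled; the image is
  mirror-padded first so regions clipped by the canvas border still close.
  Opening with a small disc and removal of components under 256 px clean
  up noise.  On fixtures the recovered tissue fraction tracks the label
  map within ±0.03.
* **Registration.**  Difference-of-Gaussian keypoints over a four-scale
  pyramid with quadratic sub-pixel refinement; descriptors are 16×16
  zero-mean, unit-norm intensity patches sampled at the keypoint scale
  (orientation assignment is omitted because the misalignment envelope
  involves only mild rotation); Lowe ratio matching (0.75); RANSAC with a
  3 px tolerance followed by a normalized-DLT refit over all inliers.  The
  unstained image is always warped onto the stained frame.  Median corner
  reprojection error on fixtures is ~0.3 px.
* **Patching.**  512×512 tiles at stride 256 (50% linear overlap) on the
  shared grid of the registered pair; 0-based, row-major, half-open tiles;
  reflect padding completes edge tiles.  Patches whose foreground fraction
  is below 0.05 (configurable) are discarded.

# Stitching

At inference the slide is tiled at exactly 50% overlap, each tile is
translated independently, and tiles are blended with separable triangular
windows sampled at pixel centres: the weight ramps linearly to zero across
every side shared with a neighbour and stays 1 toward canvas borders.  At
this overlap every interior pixel is covered by exactly 4 tiles and the
triangular windows are complementary, so the weights sum to exactly 1
everywhere (partition of unity).  Consequently stitching *un-translated*
tiles reproduces the input to within one 8-bit rounding step — the
module's core correctness property — and translated tiles blend without
visible seams.  A flat-topped window cannot satisfy the partition-of-unity
property at 50% overlap, which is why the ramps span the full half-tile.
Accumulation is floating point with a single final rounding.

# Metrics

FID fits a Gaussian (mean, covariance) to the feature vectors of each
image set and computes
$\lVert\mu_a-\mu_b\rVert^2 + \mathrm{tr}(\Sigma_a+\Sigma_b-2(\Sigma_a\Sigma_b)^{1/2})$,
with a 1e-6 diagonal jitter and symmetric eigendecompositions for the
matrix square root.  KID is the unbiased squared MMD under the kernel
$(x^\top y/d + 1)^3$, averaged over seeded subsets (defaults: subset size
100, 10 subsets).

The production feature space for both metrics is the 2048-feature pool
layer of a pretrained Inception-v3 at 299×299.  Pretrained weights cannot
be bundled, so the package ships a **toy extractor** — block-average
pooling to an 8×8 grid per channel, a fixed seeded Gaussian projection and
a tanh squash — which is bit-reproducible, sensitive to colour and coarse
structure, and entirely adequate for *ordering* comparisons on fixtures.
Requesting the Inception extractor without supplying the network raises an
error that names the alternative.  Toy-extractor FID values live on a much
smaller scale than Inception FID values; only comparisons within one
extractor are meaningful (the report embeds the extractor id and refuses
cross-extractor distances).

# Desk-scale experiment sizes

The package's own experiments (tests and `scripts/acceptance.R`) run the
tiny preset on 64×64 synthetic patches: 16 training pairs, 24 held-out
evaluation pairs, 300 optimisation steps per seed, toy extractor with
d = 16.  Three hundred steps is ample for this task — pilot runs show the
FID between true stained and translated images dropping by ~90% from the
untrained baseline within 250 steps — and keeps a five-seed learnability
experiment in the ten-minute range on a single CPU.  The quantitative
contracts asserted are: FID(stained, translated) at least halves relative
to the untrained generator in at least 4 of 5 seeds, and
FID(stained, translated) < FID(stained, unstained) — the same ordering
that holds for the full-scale system (stained↔virtual far below
stained↔unstained).

# Numerical and degenerate-input notes

* Convolution padding is reflective inside generators (7×7 and residual
  convolutions) and zero inside downsampling and discriminator stages.
* Instance normalisation uses eps 1e-5; with single-image batches the
  `"batch"` normalisation option coincides with `"instance"`.
* Projection-head biases are initialised with sd-0.01 noise rather than
  zeros: a sampled feature location that is exactly zero (a dead ReLU
  position) would otherwise project to the zero vector, which cannot be
  L2-normalised.
* `nce_cross_entropy` with zero negatives is exactly 0 (the classification
  is trivially correct); with at least one negative it is strictly
  positive.
* Homographies are normalised to $h_{33}=1$ and must be invertible;
  singular or non-normalisable matrices are input errors.
* RANSAC is the only stochastic step of registration and takes an explicit
  seed; every other stage is deterministic given its inputs.
* Errors are classed conditions (`vs_config_error`, `vs_input_error`,
  `vs_io_error`, `vs_registration_error`, `vs_numeric_error`) so pipelines
  can react programmatically; registration failures name the pair.

# Known limitations

* The CPU training loop is practical for the tiny preset and desk-scale
  patches; the full-size preset is provided for completeness but is not
  sized for CPU training runs.
* The toy feature extractor is not Inception-v3; absolute FID/KID values
  are not comparable with values computed in Inception feature space.
* Registration assumes a projective (planar) misalignment; elastic tissue
  deformation is out of scope.
* The synthetic stain task is intentionally easier than real virtual
  staining; success on it validates machinery, not clinical utility.
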