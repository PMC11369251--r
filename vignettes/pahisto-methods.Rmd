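---
title: "Methods: virtual staining, segmentation and fusion classification for label-free photoacoustic histology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual staining, segmentation and fusion classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Ultraviolet photoacoustic microscopy images unstained tissue sections
label-free: DNA/RNA absorb UV strongly, so cell nuclei appear bright on a
dark background. Pathologists, however, read hematoxylin-and-eosin (H&E)
slides. `pahisto` implements a three-step analysis chain for such
photoacoustic histology (PAH) images of liver tissue:

1. **Virtual staining** — an unpaired image-to-image translation network
   (E-CUT) renders H&E-style RGB tiles (VHE) from grayscale PAH tiles.
2. **Segmentation** — a U-Net extracts nucleus masks, from which three
   morphometric features per tile are computed: mean nucleus area, nucleus
   count, and mean intercellular distance.
3. **Classification** — a stepwise feature-fusion head (StepFF) combines
   deep feature vectors (DFVs) from the PAH image, the VHE image and the
   segmentation features into a binary cancer call per tile, stitched into
   a whole-slide cancer-probability map.

## Virtual staining (E-CUT)

The translator is a single generator/discriminator pair trained on
*unpaired* source (inverted PAH, channel-stacked to RGB shape) and target
(H&E-style) tiles. The generator is a ResNet-style encoder-decoder: two
stride-2 downsampling stages, nine padding-preserving residual blocks, two
nearest-upsample + convolution stages, and a tanh output head. The
discriminator is a 70x70-patch classifier applied fully convolutionally;
its scalar output is the mean over patch scores.

The training objective is an equal combination of three terms,

$$\ell = \ell_{adv} + \tfrac{1}{2}\bigl(\ell_{NCE}(X) + \ell_{NCE}(Y)\bigr) + \ell_{sal},$$

* $\ell_{adv}$ — least-squares GAN loss (the adversarial form of the
  cited PatchGAN lineage): the discriminator drives real patch scores to 1
  and fake to 0; the generator drives fake scores to 1.
* $\ell_{NCE}$ — PatchNCE: feature maps are taken from five encoder
  depths (the input itself, the stem, both downsampling stages, and the
  middle residual block); at each depth a set of random spatial locations
  is projected by a two-layer head and L2-normalised, and an InfoNCE
  cross-entropy matches each output-image location to the same location of
  the input image against all other locations as negatives. The $Y$ term
  repeats this on the identity pass $G(y)$ and discourages gratuitous
  changes. Defaults follow the CUT lineage: temperature 0.07, 256
  locations per depth, 256-dim projections.
* $\ell_{sal}$ — the L1 distance between the soft-threshold saliency
  masks of the input and of the generated output,
  $m = 1 - \mathrm{sigmoid}((v - \theta)\cdot 100)$ computed on the 0-255
  intensity scale, with $\theta = 90$ for the source domain and
  $\theta = 170$ for the target domain after unweighted RGB-to-gray
  averaging. With slope 100 the mask is a differentiable but effectively
  hard foreground indicator (exactly 0.5 at the threshold); it keeps the
  nuclear morphology of the input aligned with the output and doubles as
  an explainability visualisation.

Training uses Adam ($\beta_1 = 0.5$, $\beta_2 = 0.999$), batch size 1,
horizontal flips applied independently per domain (pairing is undefined in
unpaired training), and a learning rate of 2e-4 held constant for the
first half of the epochs then decayed linearly to exactly zero at the
final epoch (400 epochs at full scale). All loss weights default to 1 and
are configurable; setting the saliency weight to 0 recovers the plain CUT
objective term by term, which the test suite asserts as an ablation
identity.

For attribution, integrated gradients approximate the path integral of
the discriminator's mean patch score from a zero (black) baseline to the
input in 50 steps; the completeness identity
$\sum_i IG_i \approx F(x) - F(b)$ is checked in the tests. Per-epoch
saliency-mask and attribution snapshots can be written to disk
(`snapshot_dir`); scalar saliency statistics are always recorded in the
history. Snapshots are per epoch rather than per optimisation step —
per-step dumps of a 400-epoch run would be prohibitively large, and the
epoch cadence preserves the diagnostic intent.

## Segmentation and morphometry

The U-Net has four downscaling and four upscaling levels with skip
connections, instance normalisation, and a 1-logit output. The loss is
binary cross-entropy plus Dice, $\mathrm{BCE} + (1 - \mathrm{Dice})$, with
Dice smoothing $\varepsilon = 1$. Training uses Adam ($\beta_1 = 0.9$),
learning rate 1e-4, batch 64, up to 300 epochs with early stopping on
validation loss, and horizontal/vertical flip augmentation. At test time,
probabilities are averaged over the four flip orientations (TTA), making
predictions exactly invariant to input flips, then thresholded at 0.5.

Morphometry treats 8-connected components of the binary mask with at
least `min_area = 10` px as nuclei (the connectivity matches the default
behaviour of the contour tools the procedure is modelled on; the area
floor suppresses speckle and is a package choice, as no published value
exists). Nucleus centres are centres of minimum enclosing circles (Welzl's
algorithm), not centroids, for fidelity to the named operator. "Mean
intercellular distance" is ambiguous in the source procedure; the package
defaults to the mean nearest-neighbour distance between centres — which
matches the density intuition (denser tissue, smaller distance) — with the
all-pairs mean available behind `distance = "allpairs"`. Outlier fencing
retains values within $[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]$
with linear-interpolation quartiles; feature tables report per-class
summaries both with and without fencing, since plots may average either
way.

## Fusion classification (StepFF)

Each image modality is embedded by a ResNet-18-style backbone (stem plus
four stages of two basic blocks, widths doubling per stage, global average
pooling). At the canonical width 64 the embedding is 512-dim; a fully
connected layer maps it to a 16-dim DFV. The six segmentation features
(area, count, distance from PAH and from VHE) are z-normalised with
mean/sd fitted on the training fold only — never on held-out data, which
the tests verify by recomputation — and mapped by a fully connected layer
to a third 16-dim DFV. Missing distances (tiles with fewer than two
nuclei) map to the training mean, i.e. 0 after normalisation. The DFVs
are concatenated in the fixed order (PAH, VHE, segmentation; 48-dim for
the full model) and a final fully connected layer with softmax yields the
two class probabilities; the cancerous-class probability is reported.
Ablations (PAH-only, VHE-only, PAH+VHE, ...) use the same head over the
present DFVs. The branches and head are trained jointly end to end (the
simplest consistent reading; per-branch freezing is a config flag away in
spirit but not needed by any result here).

Training uses focal loss ($\gamma = 2$, $\alpha = 0.5$; canonical
focusing parameter, neutral class weight for balanced data), Adam at
lr 1e-4, batch 32, up to 1000 epochs with early stopping, h/v flips, and
stratified five-fold cross-validation with the normaliser refit per fold.
Items can carry group ids so that tiles sharing pixels through 50%
overlap are co-assigned to one fold, preventing pixel-level leakage.
Cross-validation runs inside the training portion of any train/test
split; the held-out fold doubles as the early-stopping monitor. Reported
metrics are accuracy, F1, precision and recall with cancerous as the
positive class; degenerate ratios (no predicted positives) are reported
as 0 with a warning.

The whole-slide probability map paints each tile with the linear
interpolation between blue (RGB 0/0/255 at probability 0) and purple
(128/0/128 at probability 1) — the named endpoint colours, fixed
numerically here since no published values exist — and merges tiles with
the overlap-averaging stitcher.

## Tiling and pre/post-processing

Slides are cropped into `tile_size` x `tile_size` windows (512 default) at
50% overlap using 0-based, row-major, half-open windows. Ragged edges are
padded with a constant (255, the white background of the inverted-PAH /
H&E domain) up to the next stride multiple; the padding extent is recorded
and removed on stitching. Stitching sums tile values per pixel in float64,
divides by the cover count, and rounds half-away-from-zero to the 8-bit
grid, making the crop-stitch round trip exact on integer images; the
stitched result is invariant to tile order. Intensity inversion
($v \mapsto 255 - v$), 2x area-average downsampling (magnification
matching), 1-to-3-channel stacking and a tissue-coverage measure (fraction
of pixels deviating from background by more than a tolerance; tiles under
20% coverage are excluded from evaluation sets) complete the plumbing.
The raw-scan clean-up of the source pipeline (contrast adjustment,
denoising, background erasing) has no published parameters and synthetic
data does not need it; it is deliberately out of scope here.

## Generation metrics and rater agreement

FID is the Frechet distance between Gaussian fits of two embedding sets,
$\lVert\mu_a-\mu_b\rVert^2 + \mathrm{tr}(\Sigma_a + \Sigma_b -
2(\Sigma_a\Sigma_b)^{1/2})$, computed with unbiased covariances and a
symmetric eigendecomposition square root with negative eigenvalues
clipped to zero (stable at small n). KID is the unbiased MMD² estimator
with kernel $(x\cdot y/d + 1)^3$, optionally block-averaged. The feature
extractor is injected: the bundled lightweight extractor is a fixed-seed
random convolutional projection with mean/sd pooling — deterministic,
download-free, and sufficient for relative comparisons on synthetic data.
Scores comparable to published Inception-based numbers require the
standard pretrained Inception extractor, which is not shipped.

Inter-rater agreement uses Cohen's kappa for two raters
($\kappa = (p_o - p_e)/(1 - p_e)$, $-1$ complete disagreement, $1$
complete agreement; defined as 1 when both raters are constant and
identical) and Fleiss' kappa for three or more, with pairwise Cohen's
also available — the multi-rater variant is unnamed in the source
procedure, so both are provided.

## The synthetic data generator

The clinical human-liver dataset behind this methodology is available
only on request, so the package ships a seeded scene generator as its
test substrate. A scene is a set of nucleus disks on a canvas: count is
Poisson with mean `density * area / 1e4`, centres are placed by rejection
sampling on the pixel lattice with minimum separation
`0.8 * (r_i + r_j)` (mild overlap allowed, so dense cancerous fields
exercise contour merging), radii are truncated normal. Defaults encode
the class contrast of hepatocellular carcinoma at tile scale: densities 6
vs 30 nuclei per 10^4 px^2 and mean radii 4.5 vs 5.5 px for noncancerous
vs cancerous tissue — nuclear crowding and enlargement — so ground-truth
count is higher and nearest-neighbour distance lower for cancerous
scenes. Intensities (PAH background 20, nuclei 200; H&E palette purple
nuclei 120/60/160, pink cytoplasm 230/180/200, near-white background
250/250/250; Gaussian noise sd 8) saturate the saliency sigmoid exactly
as real 8-bit data would. All units are pixels; the source material
publishes no physical pixel calibration for these features, so none is
invented.

One scene renders consistently into a PAH tile, an H&E-style tile and a
binary mask, giving *paired* data the real (unpaired) study never had —
the pairing is used only by tests and oracles, never by unpaired
training. What the generator does **not** emulate: stain vectors and
chromatic variability, stromal texture, imaging physics (resolution
anisotropy, speckle, depth effects), nuclear pleomorphism beyond a radius
distribution, and tissue-level architecture. Tests passing on this
substrate therefore demonstrate that the algorithms are implemented
correctly and can learn the encoded contrasts — not clinical-grade
performance on real tissue.

## Numerical choices

* Networks run on a small tape-based reverse-mode autodiff engine over R
  arrays with C++ (Armadillo) im2col convolution kernels; instance
  normalisation throughout (batch statistics are meaningless at batch
  size 1); zero padding inside convolutions.
* Network tensors live on [-1, 1]; saliency is computed after rescaling
  to 0-255, where the printed thresholds and the x100 slope are
  meaningful. The saliency loss includes every pixel (no border
  exclusion).
* Checkpoints are self-describing (architecture hyperparameters + format
  version travel with the weights); a save/load round trip yields
  bitwise-identical inference.
* All randomness flows from R's RNG under explicit seeds; a master seed
  fans out to per-stage seeds through a fixed integer derivation, so
  identical configurations reproduce loss histories bitwise.
* Quartiles use R's default linear interpolation (type 7); Dice uses
  smoothing 1; Adam uses eps 1e-8; the integrated-gradients path integral
  uses the midpoint rule, which keeps the completeness residual well
  under control at 50 steps.

## Desk-scale profile

The shipped defaults are the full-scale recipe (512-px tiles, 400/300/
1000 epochs, widths 64). The test suite and the acceptance script use the
reduced profile the configs expose for CPU work: 64-px tiles, generator/
discriminator width 8, U-Net width 8, classifier backbone width 4 on 2x
downsampled (32-px) inputs, 16-64 patches per NCE depth, and single-digit
epoch counts chosen so each property is demonstrated in minutes on one
core. Tile size and channel width are architectural free parameters of
fully convolutional networks; the profile changes scale, not mechanism.

## Known limitations

* The translator at desk scale learns palette and coarse morphology, not
  publication-quality staining; FID/KID values from the lightweight
  extractor are comparable only within an experiment.
* Dense overlapping nuclei merge into single components (no watershed
  splitting), biasing count down and area up in crowded fields — the
  same direction of bias the source methodology reports for cancerous
  tissue.
* Cohen's/Fleiss' kappa assume categorical ratings with no missing
  values.
* The pure-R autodiff engine is single-threaded and optimised for
  clarity; full-scale (512 px, 400-epoch) training is possible but slow —
  the architecture is faithful, the wall-clock is not the point.
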