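---
title: "Stain-free live/dead classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stain-free live/dead classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Adherent cancer cells imaged in bright-field carry visible morphological
signatures of viability: live cells present a mostly uniform grey body with
small, crisp, dark nuclei, while dying cells lose that harmonic texture and
appear as blurred dark halos with contracted cytoplasm. Fluorescent
viability stains (propidium iodide, PI) make the distinction trivial but
are costly, phototoxic, and perturb the culture. This package implements a
weakly supervised pipeline that uses paired fluorescence only *once*, at
training time, to label bright-field patches — the deployed classifier sees
bright-field alone.

The pipeline has five stages, each exposed as ordinary functions over
tibbles so they compose with the pipe:

1. **Patch extraction** (`crop_patches()`): raw captures (1344 x 1024 px,
   16-bit) are cut into 224 x 224 patch pairs on an overlapping grid.
   A single patch-level label is far more reliable than an image-level one
   because neighbouring cells tend to share state.
2. **Empty-patch curation** (`extract_features()`, `fit_empty_detector()`,
   `filter_patches()`): patches without properly captured cells are
   detected from frozen deep features with an SVM and discarded.
3. **Weak labeling** (`fit_mixture()`, `derive_thresholds()`,
   `label_dataset()`): per-patch mean PI fluorescence is modelled as a
   two-component Gaussian mixture; patches below
   $\bar{x}_{live} + s_{live}$ are labelled live, above
   $\bar{x}_{dead} - s_{dead}$ dead, and the open band in between is
   discarded as ambiguous.
4. **Grouped splitting and training** (`grouped_split()`,
   `train_classifier()`): a CNN is fine-tuned on bright-field patches with
   a class-balancing weighted sampler and dihedral augmentation; all
   patches of a raw image share a partition so no capture leaks across
   train/validation/test.
5. **Evaluation and inspection** (`evaluate_classifier()`,
   `embed_features()`, `project_2d()`, `grad_cam()`): balanced accuracy
   with a bootstrap CI, ROC/AUC, the fluorescence-score correlation,
   t-SNE maps of penultimate features and Grad-CAM heatmaps.

## The weak-labeling model

Let $m_i$ be the mean raw fluorescence intensity of patch $i$. We model

$$m \sim w\,\mathcal{N}(\mu_{live}, \sigma_{live}^2) +
        (1-w)\,\mathcal{N}(\mu_{dead}, \sigma_{dead}^2),$$

fitted by EM on the *reference (untreated) condition only*, which holds the
most balanced class mix. Components are identified by sorted mean: the low
component is live (PI only enters membrane-compromised cells). The label
rule is

* live: $m < \mu_{live} + \sigma_{live}$,
* dead: $m > \mu_{dead} - \sigma_{dead}$,
* discarded otherwise — values exactly equal to a cut-off fall in the
  discard band (the band is printed as an open interval; treating
  boundaries as ambiguous is the conservative reading).

The same thresholds are applied to every condition without refitting, so
label semantics are constant across treatments. For the reference
parameter set ($\mu_{live} = 224.51$, $\sigma_{live} = 34.46$,
$\mu_{dead} = 550.44$, $\sigma_{dead} = 153.55$) the cut-offs are 258.97
and 396.89.

Two scale conventions matter:

* **Labeling uses raw 16-bit intensities.** The component means above
  exceed 255, so thresholding must happen before (or beside) the 8-bit
  display conversion. `crop_patches()` therefore keeps the raw
  fluorescence crop alongside the 8-bit bright-field view.
* **The classifier consumes 8-bit bright-field**, produced by
  `convert_16bit_to_8bit()`: a linear full-range rescale by $1/257$
  (so 65535 maps to 255), rounding half away from zero.

### EM details

`fit_mixture()` runs EM in log-space with 10 restarts (first from the
k-means solution, the rest from jittered variants), relative log-likelihood
tolerance $10^{-6}$, at most 500 iterations, and a variance floor of
$10^{-6}\,\mathrm{sd}(x)$ to survive degenerate clusters. The best restart
by log-likelihood is returned with its seed and all restart likelihoods
recorded; non-convergence is an error, not a silent result. The restart
count and tolerance are package choices — fitting 1-D mixtures of two
well-separated components is benign, and the tests verify both recovery of
simulated parameters (bias under 2% across 20 seeds) and agreement with an
independent mixture implementation (mclust).

## Empty-patch curation

The curation stage follows a 226 + 226 design: a small manually labelled
set of empty/unsuitable patches and properly captured ones, embedded with a
*frozen* convolutional backbone and separated by an SVM. Two open choices
were resolved as follows:

* **Two-class RBF SVM by default.** Although the stage is often described
  as outlier detection, the curation design labels *both* classes, which is
  exactly supervised two-class training; a one-class mode
  (`mode = "one_class"`, $\nu$-SVM on non-empty features only) is kept as
  an option. Kernel and cost are the e1071 defaults with
  $\gamma = 1/d$; features are standardised once and the scaling stored in
  the detector.
* **Global average pooling** over the last convolutional map produces the
  feature vector (512-dimensional for an 18-layer-residual-style
  extractor); the pooling operator is not dictated by the design, and GAP
  is the convention for feature reuse.

Because genuinely pretrained backbones cannot be bundled, the package
ships `random_backbone()`: a fixed-seed random-weight convolutional
extractor with the same 224 x 224 $\to$ pooled-vector contract. Random
convolutional features are a well-studied stand-in for this kind of
texture/presence discrimination; a pretrained network can be plugged in
through `custom_backbone()` without touching any other stage.

## Classifier and training recipe

The reference recipe is kept verbatim as defaults in `train_config()`:
cross-entropy loss, Adam with $\beta = (0.5, 0.999)$, learning rate
$10^{-5}$, weight decay $10^{-5}$, batch size 4, 30 epochs, a weighted
random sampler with replacement whose class weights are inverse sample
counts, and augmentation by random 90-degree rotations and flips (the
eight-element dihedral group, which leaves the pixel multiset and the
label invariant). Model selection retains the weights with the best
validation balanced accuracy — the selection criterion on the validation
set is a package choice.

The engine behind `train_classifier()` is a small, fully tested
convolutional network implementation (im2col convolutions, average
pooling, global average pooling, dense head) with an explicit backward
pass. The backward pass is what enables Grad-CAM and makes the gradient
flow verifiable: the test suite checks every layer's analytic gradients
against central finite differences.

The built-in `tiny_test` backbone (an average-pool stem followed by three
3 x 3 conv blocks of 8/16/32 channels, GAP, and a 2-way head; about 6,000
parameters) is the desk-scale workhorse. Two deliberate deviations from
the full-size recipe apply to it:

* **Input centring**: patches enter the network as $x/255 - 0.5$. With
  uncentred inputs the head learns an order of magnitude more slowly (the
  score ranking becomes perfect long before the logits separate).
* **Learning rate $10^{-3}$** in the examples and tests: the $10^{-5}$
  default is tuned for *fine-tuning pretrained* weights; training the tiny
  backbone from scratch at that rate would need far more epochs than a
  desk-scale run warrants.

The full-size backbone names (`residual18`, `squeeze`, `inception_v3`) are
accepted in the configuration but require externally supplied weights;
requesting them without weights fails with guidance rather than silently
training a random large network.

## Evaluation

* **Balanced accuracy** — the mean of per-class recalls — is the headline
  metric because the treated condition is severely imbalanced (about 1:10
  live:dead).
* Its 95% CI is a **percentile bootstrap** over resampled test indices
  (2,000 resamples, seeded; single-class resamples are redrawn with a
  cap). The CI construction is a package choice; the tests verify
  coverage on simulated test sets.
* **AUC** is computed from mean ranks, equal to all-pairs concordance with
  ties counting one half; the test suite pins this to a brute-force
  pairwise oracle at $10^{-12}$.
* The **fluorescence-score correlation** is Pearson's $r$ (with the
  two-sided test from `cor.test`) between each test patch's mean raw
  fluorescence and its classification score, defined as $P(\text{live})$.
  With that orientation an effective classifier yields $r < 0$: high-PI
  patches get low live-scores. Correlation is computed on the test
  partition only.

## Interpretability

`embed_features()` reads the globally pooled activations of the last
convolutional stage — the vector feeding the classification head — as the
patch signature. `project_2d()` embeds those signatures with exact t-SNE
(theta 0, perplexity 30 by default, fixed seed); none of the t-SNE
hyperparameters are dictated by the design, so defaults follow common
practice and the requirement `n > 3 * perplexity` is enforced.
`plot_projection()` marks patches whose predicted and true labels disagree
as white dots, which visualises the boundary confusion between the live
and dead clusters.

`grad_cam()` follows the standard formulation: channel weights are the
spatially averaged gradients of the target-class logit with respect to the
last convolutional layer's activations; the map is the rectified weighted
sum, min-max normalised per map to $[0, 1]$ (an identically zero map —
e.g. when the target logit is constant in the input — stays zero, and a
constant non-zero map becomes 1), then bilinearly upsampled to the input
size. Per-map min-max scaling is a display choice the original
formulation leaves open.

## The synthetic data generator

`generate_raw_pair()` emulates exactly the statistical structure the
analysis assumes, nothing more:

* Cells are laid out on a fixed 224-px grid of regions; each region is
  empty (probability `frac_empty_regions`), otherwise dead with
  probability `frac_dead_cells`. Cells within a region share state,
  mirroring the spatial coherence that makes patch-level labels sensible.
* Bright-field morphology carries the class signal: live cells are crisp,
  mildly darker ellipses with a small dark nucleus; dead cells are soft
  dark halos (rendered analytically as radial profiles — procedural
  rendering, not photorealism, because only the statistical contract
  matters for testing).
* The *patch-mean* fluorescence of each region is drawn from the matching
  component of the configured mixture, and the rendered blob field is
  mean-centred so the realised patch mean equals the draw up to pixel
  noise and 16-bit rounding. Dead-region draws are truncated above the
  dead cut-off and live-region draws below the live cut-off, so
  ground-truth state and the threshold rule agree by construction — the
  ambiguous band is precisely what the pipeline discards, so the
  generator does not place truth there.
* Default mixture parameters are the reference-condition estimates
  (224.51/34.46, 550.44/153.55); the mixture weight defaults to 0.5 for
  untreated-like data and 0.08 live for treated-like data, mirroring the
  roughly 1:10 imbalance of the treated condition. Per-condition weights
  and the spatial autocorrelation of fluorescence are not reported
  quantities; these defaults are stand-ins chosen once.
* Determinism: the image seed is derived from `(rng_seed, image_index)`,
  so identical configurations reproduce identical bytes.

What the generator deliberately does **not** emulate: optical vignetting,
focus drift, debris, condition-dependent morphology drift over days in
culture, fluorescence bleed between neighbouring regions, and cell
overlap across region borders. Passing tests on synthetic data therefore
demonstrate that the pipeline's machinery is correct under its stated
assumptions — not that the trained tiny model would transfer to real
captures.

## Problem sizes

The test suite and worked examples run a deliberately small study: 20 raw
images of 672 x 448 px (six grid regions each, so ~120 patches), stride
224, a 15-epoch training run of the tiny backbone, and 5 x 20,000-draw
mixture refits. These sizes were chosen so the whole pipeline exercises
every stage in a few minutes on a single CPU while leaving comfortable
statistical margins (the separable synthetic task is learned to
validation balanced accuracy 1.0 well before epoch 15). The stride
default of 112 px (50% overlap) is used for real-scale cropping; the
overlap fraction is not a reported quantity, and 112 is the natural
divisor of 224 consistent with overlapping contiguous patches.

## Known limitations

* The tiny backbone is a testing instrument, not a competitive
  classifier; real-data performance claims require a pretrained full-size
  backbone and the released dataset.
* Weak labels inherit the threshold rule's blind spots: a patch mixing
  live and dead cells gets a single label from its mean fluorescence.
* The discard band removes ambiguous patches from training *and*
  evaluation; metrics are conditional on the unambiguous population.
* Per-cell segmentation and labeling are out of scope (irregular contours
  of adherent monolayers defeat it); the patch is the unit of analysis.
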