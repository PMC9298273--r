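---
title: "Channel-ablation deep learning screens: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Channel-ablation deep learning screens: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the pipeline answers

High-content imaging of iPSC-derived motor-neuron cultures stains each well
with three fluorescent markers: DAPI (nuclei), beta-III-tubulin (BIII; the
neurite network) and one ALS-relevant RNA-binding protein (RBP) such as
TDP-43 or FUS. Whether a disease mutation or an extrinsic stress changes the
*nuclear* compartment, the *neuritome*, or the *localization of an RBP* can
be read off — without segmentation — from how well a convolutional
classifier separates two conditions when it is shown only a subset of the
channels. `neuroscreen` implements that channel-ablation logic end to end:

1. compose every legal marker subset into an RGB image (13 combinations
   when five RBPs are available: three single channels, DAPI:BIII, and
   DAPI:BIII:RBP per marker);
2. train one binary classifier per (condition test, combination) cell —
   4 tests x 13 combinations = 52 classifiers at full scale;
3. compare cross-validated AUC distributions between combinations with
   one-sided Mann-Whitney tests: the combination whose removal hurts tells
   you which compartment carries the phenotype;
4. explain individual predictions with integrated gradients;
5. quantify condition effects on per-culture predictions with
   random-intercept linear mixed models, and cluster the resulting
   effect-size profiles to ask which stress condition best mimics disease.

Because the original 1 TB image corpus is not needed to test any of this
logic, the package ships a seeded synthetic-microscopy generator that
produces images with the same hierarchical structure (experiments, cell
lines, wells, 10-12 fields per well, 3-5 z-planes) and known ground truth.

## Preprocessing model

The image path is fixed: per-channel maximum-intensity projection over z;
16-to-8-bit conversion by `floor(x/256)` (content-independent, so
conversion cannot leak condition information); RGB composition with BIII in
red, the RBP in green, DAPI in blue and pitch-black placeholders for absent
channels; per-channel autocontrast that trims 0.1% of pixels from each
histogram tail and linearly remaps the remaining range to 0-255 (constant
channels are left untouched, so placeholders stay black); division of the
1080 x 1080 field into 16 non-overlapping 270-px tiles; bilinear resize to
224 px; and standardization with the natural-image channel statistics
(mean 0.485/0.456/0.406, sd 0.229/0.224/0.225) expected by pretrained
backbones. A composed `preprocess_field()` equals the chained single
operations exactly (this is tested). Training images are augmented sixfold
(original, 90-degree rotation, both mirrors, rotated mirrors); evaluation
images never are.

## Classifier and training recipe

The default backbone is a deliberately small scratch CNN: four 3x3
stride-2 convolution/ReLU blocks (8, 16, 32, 64 filters), global average
pooling and a 2-way linear head — about 10^5 parameters, trained with
minibatch SGD (momentum 0.9) under cross-entropy. The configuration
defaults (`classifier_config()`) keep the published constants — learning
rate 0.001, batch 32, 10 epochs — which are appropriate for *fine-tuning* a
pretrained network. A scratch-initialized network of this size does not
move at that rate within 10 epochs, so the package's own recovery
experiments train at learning rate 0.01 for 6-16 epochs; both settings are
recorded in every result's metadata. `pretrained_mobilenet_v2` is accepted
as a backbone name but requires externally supplied weights; no weights are
bundled, and the framework (not the backbone) is what the package tests.

Cross-validation splits at the *field-image* level by default: all 16 crops
of one field travel together between train and test folds, because sibling
crops share local content and crop-level shuffling would leak. A
`split_level = "crop"` mode reproduces the image-level shuffling described
in classical pipelines. "Five subsets" is implemented as five repeats of
stratified 10-fold cross-validation under different shuffle seeds, which is
the most conservative reading of an underspecified design; each (test,
combination) cell therefore yields 50 AUC values.

Probabilities are aggregated bottom-up by arithmetic means: crop to field
image, image to culture (one well of one line under one condition). The
culture is the statistical unit of the mixed models.

## Statistics

AUC distributions are compared with a one-sided Mann-Whitney test: exact by
complete enumeration of rank assignments when the combined sample is at
most 12, otherwise a normal approximation with midrank tie correction and a
0.5 continuity correction (the continuity correction keeps the
approximation within 0.01 of the exact tail at n = 6 + 6).

Condition effects on per-culture predictions are estimated with
`prediction ~ condition + (1 | cell_line) + (1 | experiment)`, fitted by
maximum likelihood (not REML: every reported p-value is a likelihood-ratio
test between nested fixed-effect structures, and REML likelihoods are not
comparable across fixed effects). The LRT uses one degree of freedom with
no boundary correction, since the tested term is a fixed effect. Random
groupings with a single observed level are dropped with a warning; if none
remain the model falls back to ordinary least squares, again with a
warning. Effect sizes stay on the raw probability scale of the classifier.
Profiles of effect sizes (conditions x classifiers) are clustered with
Ward's minimum-variance method on Euclidean distances.

## Integrated gradients

Attribution uses the straight-line path integral approximated by a
right-endpoint Riemann sum: `values = (x - x') * mean_m dF/dx` at
`x' + (m/steps)(x - x')`, m = 1..steps, with an all-zero baseline (the
pipeline's pitch-black placeholder convention) and the *pre-softmax* score
of the predicted class as the target (post-softmax probabilities saturate
and produce vanishing gradients). For a linear scorer the Riemann sum is
exact at any step count; for trained CNNs the completeness residual
`|sum(values) - (F(x) - F(x'))|` falls below 2% of the score difference by
200 steps. The displayed magnitude is the per-pixel L1 norm over colour
slots, max-normalized to [0, 1] per image (an all-zero map is returned if
every attribution is zero), rendered as a white-to-blue ramp over the
original image.

## The synthetic generator

`render_field()` emulates one field of view at 16-bit depth:

* **Nuclei** — ellipses (eccentricity up to 0.3, radius ~ N(r, 10% r))
  whose boundary radius is modulated by the first six Fourier modes with
  fixed amplitude and random phases, so that the radial standard deviation
  equals `nuclear_irregularity` x radius. The perturbation is normalized to
  preserve expected area: the nuclear phenotype is an *outline* phenotype,
  not a size phenotype, which keeps the attribution readout interpretable.
* **Neurites** — branching random walks (step 2 px, bounded heading noise,
  branch probability 0.1 per step) rooted at nuclei, rendered as Gaussian
  tubes of sigma `neurite_width_px`; consecutive steps are grouped into
  chunks that are deleted independently with probability
  `neurite_fragmentation`.
* **RBP channel** — flat unit signal inside nuclei plus `1/rbp_nc_ratio`
  inside the cytoplasm (somata and neurite tubes minus nuclei), so the
  measured nuclear-to-cytoplasmic mean-intensity ratio equals the parameter
  by construction.
* **z-stacks** — plane k is the in-focus render blurred with sigma
  `2 * |k - focus|`; Poisson shot noise and Gaussian read noise
  (`noise_sd`, in counts) are added unless `noise_sd = 0`, which requests a
  noise-free geometric render for ground-truth checks. Signals are scaled
  so bright structures sit near 20,000 counts, leaving headroom and making
  autocontrast non-trivial.

Condition effects are additive shifts on the phenotype parameters declared
in one table (`condition_effects()`): the mutant condition roughens nuclear
outlines (+0.30) and fragments neurites (+0.30); heat stress moves the same
two parameters in the same direction at 80% magnitude; oxidative stress
relocalizes the RBP towards the cytoplasm (ratio -1.0); osmotic stress
shrinks nuclei (-6 px) and relocalizes the RBP (-1.5). This design encodes,
as a generator ground truth, the qualitative claim under test: heat stress
shares the disease phenotype direction while the other stresses are
orthogonal. Stress shifts decay exponentially with recovery time (2 h time
constant); the genotype does not recover. Cell-line and experiment random
intercepts perturb every parameter with small Gaussian offsets drawn from
sub-seeds of the identifiers, so the same line always carries the same
idiosyncrasy — exactly the nuisance structure the mixed models are meant to
absorb.

All generator outputs are pure functions of (spec, seed): a private RNG
stream is seeded per field and restored afterwards.

## Desk-scale study conditions

The recovery experiments and the acceptance script run at sizes chosen for
a single CPU: 256-px fields, 128-px tiles resized to 64 px (96 px for the
attribution-localization check, where outline detail matters), 16 wells
per class with 2 fields each, 10-fold cross-validation with one repeat,
and 6-16 training epochs. The variance-component and calibration checks
use the simulator directly (e.g. 7 lines x 3 experiments x 10 cultures for
effect recovery; 200 replicates for type-I error). These scales are stated
here as the package's own experimental design; the full-scale defaults
(1080-px fields, 224-px inputs, 5 x 10-fold CV) remain the configuration
defaults.

## What passing tests do and do not show

The generator produces flat-shaded, mask-derived structures with simple
noise; it has no point-spread function, chromatic aberration, illumination
gradients, cell motility, staining variability or segmentation errors.
Passing recovery tests therefore demonstrate that the *pipeline logic* is
correct — that a phenotype placed in one compartment is attributed to the
right marker, that transfer ranks conditions by shared phenotype direction,
that the mixed models recover known effects at the right type-I error —
not that any particular biological claim holds, and not that the published
effect sizes would be reproduced on the original corpus. Numerical
headline values from the original study (AUCs of 0.65-0.90, effects of
0.13 and 0.4, a prediction correlation of 0.67) depend on that 1 TB
dataset and a fine-tuned MobileNetV2 and are out of scope here.

Known limitations worth keeping in mind:

* The scratch CNN's integrated-gradients maps are noisier than those of a
  large pretrained backbone; attribution near nuclear outlines is a robust
  *enrichment* (every examined high-prediction crop exceeds the uniform
  expectation) rather than a dramatic concentration.
* Training convergence of a small scratch network varies with
  initialisation; the attribution experiment trains longer (16 epochs) for
  that reason, and grid AUCs at very small fold sizes are coarse
  (a 4 v 4 image fold quantizes AUC to 1/16).
* `aggregate` / mixed-model code assumes the culture key is unique across
  experiments; manifests built by the package guarantee this.

## Numerical conventions

Degenerate inputs are handled explicitly: empty z-stacks, non-square
augmentation inputs, indivisible tilings, constant channels in
autocontrast, single-class training sets, empty score vectors, zero
variance in correlations and missing values in clustering all raise
informative errors (or, for constant channels, take the documented
identity path). Ties in ranks use midranks everywhere. The likelihood-ratio
statistic is clipped at zero and an optimisation failure is raised if the
reduced model beats the full model beyond numerical tolerance. Ward
clustering uses `ward.D2` (squared-distance update on Euclidean input),
and dendrogram tie-breaking follows the deterministic row order of the
input profile matrix.
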