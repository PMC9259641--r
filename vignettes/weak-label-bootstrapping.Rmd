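---
title: "Weak-label bootstrapping for vesicle segmentation: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weak-label bootstrapping for vesicle segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

High-throughput screening (HTS) microscopy of autophagy reporters produces
thousands of two-channel images per experiment. With a dual-fluorophore pH
biosensor (a DsRed-like reporter plus a pH-sensitive pHluorin-like reporter),
the stage of an autophagy vesicle is encoded in colour: **phagophores** are
neutral-pH and fluoresce in both channels, while **autolysosomes** are acidic,
quenching the green reporter so that only the red channel remains; they are
also larger on average. Semantic segmentation of these events is the
bottleneck of quantitative analysis.

Pixel-accurate expert labels are too expensive to produce at HTS scale. The
workflow implemented here bootstraps a convolutional network from *weak*
labels instead:

* **CIP** — a conventional-image-processing labeler (filters + thresholds +
  morphology) segments events automatically but with systematic errors;
* **CDL** — a U-net trained on the CIP output (or on controlled corruptions
  of ground truth), expected to *generalise beyond* the label noise;
* **MDL** — a U-net trained on a small curated label set, the classic
  alternative.

Because real HTS data with pixel-perfect truth does not exist, the package
ships a calibrated synthetic image simulator so every claim can be tested
against known ground truth.

## The simulator

Each field draws per-class event counts from Poisson distributions, places
disk-shaped vesicles uniformly at random, assigns each class its channel
intensity profile, and then applies a Gaussian point-spread function, smooth
background clutter, Poisson shot noise and Gaussian read noise. The clean
mask records, at every covered pixel, the class of the nearest covering
vesicle (later-drawn wins ties), which resolves overlaps deterministically;
tight bounding boxes of the 8-connected mask components accompany every
field.

Default calibration (256 x 256 px):

| parameter | value | rationale |
|---|---|---|
| phagophore count / radius | Poisson(29), N(4, 1) px | pixel share ~= 0.023 |
| autolysosome count / radius | Poisson(13.5), N(6, 1.5) px | pixel share ~= 0.024; the later-stage vesicles are larger |
| channel profiles (red, green) | (0.70, 0.80) / (0.80, 0.10) | both-bright vs green-quenched colour logic |
| brightness multiplier | N(1, 0.35), truncated at 0.2 | expression variability; dim events are what threshold pipelines miss |
| PSF sigma | 1.2 px | spinning-disk-like blur |
| noise | shot scale 300, read sd 0.015 | moderate photon + camera noise |

The count means were calibrated once so that the pooled class pixel
frequencies approximate the 0.95 / 0.023 / 0.024
background/phagophore/autolysosome imbalance of real screens; across seeds
the pooled frequencies of a 50-image dataset vary by roughly +-5% relative.
A `simulation_config_scaled()` helper transfers the calibrated *density* to
other geometries (e.g. the native 680 x 512 frame, or 128 x 128 desk
experiments).

What the simulator deliberately does **not** model: optics-accurate PSFs,
flat-field artefacts, cell bodies and textured organelles, vesicle shape
irregularity, and the two rare intermediate autophagy stages. Passing tests
on synthetic data therefore demonstrate the *mechanics* of the workflow —
they do not certify performance on any particular real microscope.

## The weak labeler

`segment_events()` chains the classic spot-detection vocabulary: a
difference-of-Gaussians band-pass (sigmas 1.5 / 6 px), a white top-hat
(disc radius 9), Otsu or fixed thresholding, small-object removal
(minimum 5 px), an optional watershed split on the distance transform, and
per-component classification by the green/red mean-intensity ratio with
cutoff `ratio_tau = 0.5` — the midpoint between the two simulated colour
regimes. Detection runs on the pixelwise maximum of the two channels so that
red-only autolysosomes are found. The original MATLAB pipeline this emulates
also contained deconvolution, Butterworth and flat-field steps; those correct
optics that the simulator does not produce, so they are deliberately omitted.

On simulated fields this labeler exhibits exactly the three canonical error
types — missed (dim) events, misclassified events, incomplete outlines —
which the controlled corruption model (`corrupt_mask()`) can also inject at
chosen rates: per 8-connected event, mutually exclusively, delete with
`p_miss`, class-flip with `p_swap`, else peel `erosion_fraction` of its
pixels from the boundary inward (never below one pixel). Mutual exclusivity
keeps the error types attributable in tests.

## The network and its training

The U-net is the standard symmetric encoder-decoder: 3 max-pooling stages
and 3 skip connections, two 3 x 3 convolution + ReLU layers per block,
nearest-neighbour upsampling, a 1 x 1 scoring convolution and a softmax.
Channel widths start at `base_filters` and double per stage; widths are not
part of the published architecture, so they are configurable (desk default
8 — trainable in minutes on one CPU core; 16 at full scale).

The loss is the generalized dice loss with squared-inverse class-volume
weights,

$$ L = 1 - 2\,\frac{\sum_l w_l \sum_n r_{ln} p_{ln}}
                   {\sum_l w_l \sum_n (r_{ln}+p_{ln}) + \epsilon},
\qquad w_l = \frac{1}{(\sum_n r_{ln} + \epsilon)^2}, $$

with $\epsilon = 10^{-7}$. One numerical choice matters: inside the
*training* criterion, classes absent from an image's reference mask get
$w_l = 0$. With the tiny $\epsilon$ the absent-class weight would otherwise
be $\sim 10^{14}$ and dominate every present class, stalling optimisation —
at desk scale many small images lack one event class entirely. The exported
`generalized_dice_loss()` keeps the plain formula (its identities — 0 at a
perfect prediction, 1 at a fully wrong one — are tested as stated).

The optimiser is stochastic gradient descent with momentum 0.9, L2
regularisation 0.001, mini-batch 4, and a stepped schedule dropping the rate
by 0.8 every 3 epochs; augmentation applies one of the eight axis-aligned
square symmetries (random reflection and 90-degree rotation) identically to
image and mask, so masks need no interpolation. Splits are 0.85/0.10/0.05
(weak-label mode) or 0.80/0.10/0.10 (curated mode), floor-sized with the
remainder assigned to training. All randomness (weight init, shuffling,
augmentation draws) derives from the single training seed, so runs are
bit-reproducible.

**Learning-rate scaling at desk scale.** The reference schedule (initial
rate 0.002 weak-label / 0.001 curated) belongs to a full-scale run of
roughly 13k parameter updates (4000 x 0.85 / 4 x 15). Desk experiments run a
few hundred updates, and with a bounded loss like generalized dice the SGD
step size must compensate: `train_config()` keeps the reference defaults,
while desk runs (`experiment_config()`, the shipped experiments) use
0.01 weak-label / 0.005 curated — five times the reference rates, keeping
the 2:1 mode ratio and the stepped 0.8-every-3-epochs schedule.

Pure generalized dice shows a characteristic profile in short runs: a
plateau while features form, then a rapid drop — and on some seeds that
cliff destabilises SGD badly enough that one or both event classes saturate
to zero probability and never recover (see below). Desk runs therefore
compound the criterion with a small cross-entropy term
(`ce_weight = 0.3`, i.e. loss = GDL + 0.3 CE): the cross-entropy gradient
`(p - r)` does not vanish at saturation, which both removes the plateau
(features start forming from the first updates) and makes a collapsed class
recoverable, while the dice term continues to carry the class balancing.
Compounding dice with cross-entropy is the standard recipe in modern
segmentation frameworks for exactly this reason. `ce_weight = 0` recovers
the pure reference criterion.

The saturation pathology in detail: the softmax gradient of a dice-type
loss vanishes once a class's predicted probability saturates near zero, so
a rare class pushed down hard early in training dies irreversibly — and the
inverse-square-volume weights deprioritise the *larger* of two rare classes
(their weights differ by the squared volume ratio). Collapse is most easily
provoked in degenerate regimes: a single image repeated, or fields so small
that a class averages under one event per image. Three further consequences
in the package: the overfit sanity test trains on one single-class field
per event class; desk experiments keep fields at 128 x 128 or larger so
every class appears in nearly every image; and an optional global L2-norm
gradient-clipping threshold (`grad_clip`, off by default) is available.
Initialising the final-layer bias to log class priors, a standard trick for
cross-entropy under imbalance, is deliberately *not* used: it starts the
rare classes close to saturation and measurably worsens dice-loss
training.

## Evaluation

Three independent strategies, as in the workflow being modelled:

1. **Pixel metrics.** Per-class one-vs-rest TP/FP/FN/TN from the pooled
   confusion matrix (rows = predicted, columns = actual), with precision,
   recall, specificity, IoU, boundary-F1, and three aggregations: *Global*
   (correct pixels over all pixels), *Mean* (unweighted over classes;
   undefined 0/0 classes are excluded rather than zero-filled), *Weighted*
   (IoU weighted by true class pixel share). Per-class *accuracy* is
   TP/(TP+FN); the printed-formula variant TP/(TP+TN) is additionally
   exposed as `accuracy_as_printed` because that formula is neither standard
   accuracy nor consistent with per-class usage — we treat it as a
   typographical slip and keep both visible. "Mean over all classes in all
   images" is read as pool-pixels-then-average; a `per_image` option
   averages per-image scores instead.
2. **Bounding-box surrogate detection.** Boxes are extracted per 8-connected
   component, matched one-to-one greedily by descending IoU with a 0.1
   admission threshold (removing random overlap), and summarised as
   false-positive/false-negative ratios (each normalised by the detecting
   source's own box count), matched counts in the lower [0.1, 0.5) and
   higher [0.5, 1] overlap bins — an IoU of exactly 0.49 falls in the lower
   bin, 0.50 in the higher — and the detection-overlap percentage. Greedy
   one-to-one matching prevents double counting; on instances with up to
   four boxes per side it almost always coincides with the optimal
   assignment, and tests verify it against exhaustive enumeration.
3. **Rating analysis.** Expert quality scores (1-10) for two methods are
   compared with the two-sample Kolmogorov-Smirnov test (asymptotic
   p-values), overall and per expert.

The boundary-F1 tolerance defaults to 0.75% of the image diagonal, a common
boundary-matching convention; boundaries are 4-connected region edges with
out-of-image counting as outside.

## Desk experiments and problem sizes

`run_cdl()` wires simulate -> weak labels -> split -> train -> predict ->
evaluate; weak labels come either from the CIP labeler (realistic route) or
from `corrupt_mask()` applied to ground truth (dialled-noise route), so the
generalisation claim can be tested both ways. `run_mdl()` trains on a small
curated subset (clean ground truth stands in for expert-corrected masks; a
`corrected/` directory of mask PNGs, merged by filename, replaces the
interactive correction GUI of the original workflow). `compare_methods()`
lays the reports side by side with relative improvements over the reference
method.

Problem sizes used by the shipped tests and the acceptance script were
chosen so a complete run stays in the minutes range on one CPU core:
simulator calibration at 50 x 256 x 256; the generalisation experiment at
240 images of 128 x 128 (200 train / 40 test, 10 epochs, corruption rates
0.3 / 0.15 / 0.3); the three-method comparison on the same 128 x 128
dataset (network training on 120 weakly-labelled or 30 curated fields,
against the same 40-field test set). The master seed
of an experiment derives all stage seeds by fixed offsets, so non-training
stages are bit-reproducible and training is reproducible given the same
build.

## Known limitations

* The weak labeler is a re-engineering from the published operator
  vocabulary, not a port of the original MATLAB pipeline; its numeric
  thresholds are its own.
* Whether the original component classifier used absolute intensities or
  channel ratios is not documented; the green/red ratio rule is a
  reconstruction consistent with the biosensor colour logic.
* No early stopping: the published training-evaluation criterion is not
  formalised, so the trainer runs the configured epochs and logs both
  losses.
* Rotation augmentation is restricted to multiples of 90 degrees (the
  published description says only "rotation"); arbitrary angles would
  require mask interpolation.
* Training uses one CPU thread plus whatever parallelism the linked BLAS
  provides; there is no GPU path.
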