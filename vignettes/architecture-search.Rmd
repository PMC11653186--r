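---
title: "Evolving compact CNN architectures: model, parameters and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving compact CNN architectures: model, parameters and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(evocnn)
```

## The search problem

`evocnn` optimizes the architecture of a small convolutional classifier
for two-class grayscale images. The decision variables are the number of
convolutional layers and, per layer, the filter count and the square
kernel size; for the transfer-learning variant, the widths of the dense
layers appended to a frozen feature extractor. These are encoded as
chromosomes:

- `conv_genome`: an ordered list of `(filter_count, filter_size)`
  integer pairs, length 1..`max_layers`. The flat encoding interleaves
  the pairs (`c(f1, k1, f2, k2, ...)`) so that the length-altering
  crossover operates on whole layers.
- `dense_genome`: a vector of dense-layer widths, each within
  `[min_neurons, max_neurons]`.

All gene domains are integers with inclusive bounds and minimum 1 (the
source material states only maxima; a zero-filter layer is meaningless).

## The evolutionary loop

Each generation `evolve()`:

1. evaluates every not-yet-scored genome with the fitness function;
2. records best/mean fitness and the best genome;
3. keeps the `elitism_k` best individuals unchanged (ties broken by
   fitness, then earlier birth generation, then lexicographically
   smaller encoding, making selection a deterministic total order);
4. refills the population with children: two parents are drawn
   uniformly from the elite pool; equal-length parents undergo *uniform
   crossover* (gene i from parent 1 with probability `p_c`, else parent
   2), unequal-length parents the *length-altering crossover* (child
   length uniform on the parents' length interval, each layer copied
   from a uniformly chosen parent that has that layer); every child is
   then mutated.

Uniform parent selection over the elite pool, rather than
fitness-proportional selection, is the simplest mechanism consistent
with "parents with high fitness": the elite pool already applies the
selection pressure, and it avoids a second scaling choice.

The two crossover sub-operators are composed exclusively, not
sequentially: the length-altering operator already mixes layer sources
uniformly (it is gene-mixing at probability 1/2 on the overlap), so
running uniform crossover after it would be redundant.

Mutation adds to each gene, independently with probability
`mutation_rate`, an integer drawn uniformly from
`{-d, ..., -1, 1, ..., d}` and clamps to bounds, with
`d = ceiling(10% of the gene's range)` by default ("auto"). The default
`mutation_rate = 0.25` gives roughly one perturbed gene per child on the
short 4-12-gene chromosomes this search uses — the classic
one-mutation-per-chromosome (1/L) heuristic. Lower rates (e.g. 0.1)
leave well under one expected perturbation per child and measurably
stall the search on enumerable landscapes one step short of the optimum;
the recovery property in the test suite is robust across rates 0.2-0.3,
so the default is not a knife-edge setting. An optional structural
mutation (insert/delete a random layer with the same rate) is off by
default because the length-altering crossover already explores depth.

**Stopping.** The run halts at `max_generations`, or once the best-ever
fitness has not improved by more than 1e-9 for `patience` consecutive
generations. On a constant landscape this yields exactly
`patience + 1` evaluated generations. With `elitism_k >= 1` the
best-fitness trace is non-decreasing by construction, and the test suite
asserts it on every run.

## Fitness

Two fitness variants are provided; both are computed on the *validation*
split during evolution so the test split stays untouched until the final
best genome is retrained and scored once (`run_optimize()` asserts
this separation):

- `accuracy_pct` (default): `100 * correct / total`;
- `confusion`: `TP / (TP + FP + FN)`, which ignores true negatives and
  so emphasizes detection quality for the positive (pneumonia-like)
  class.

A third kind, `surrogate`, bypasses training entirely with a
user-supplied deterministic function; `surrogate_fitness_l1()` (negative
L1 distance to a hidden target genome, with a full-gene-range penalty
per missing/extra layer) gives a landscape whose unique optimum is known
by construction and cheap to verify by exhaustive enumeration — this is
how the search mechanics are tested without any model training.

Losses follow the standard definitions with natural logarithms and
probability clipping at `1e-7`; for two classes the categorical
cross-entropy on one-hot targets coincides with the binary
cross-entropy (property-tested at tolerance 1e-9). The error rate is
the mean absolute difference of label vectors, which equals the
misclassification fraction for hard binary labels, so accuracy/100 and
error rate always sum to one. `arch_cost()` exposes the weighted
size/error trade-off `αL + βF + γE` for reporting.

## From chromosome to network

`build_cnn_spec()` compiles a chromosome into a fixed scaffold: per
layer a same-padded stride-1 Conv2D (rectifier) followed by batch
normalization, a 2×2/stride-2 max pool after every second conv block,
then flatten and one sigmoid output unit. A 6-layer chromosome therefore
yields 6 conv + 6 batch-norm + 3 max-pool layers; in general `L` layers
yield `floor(L/2)` pools. Pool positions are this ratio generalized —
the source scaffold fixes only the 6/3 count — and inputs smaller than
`2^pools` pixels per side are rejected with a shape error. Activations
and the pooling schedule are scaffold metadata, not genes.

`build_head_spec()` compiles a dense chromosome into
flatten → dropout (0.5 by default; the rate is conventional, the source
names dropout without a rate) → dense stack → sigmoid output, marked as
attached to a frozen feature extractor. `standin_backbone()` provides a
fixed seeded two-block convolutional extractor so head search needs no
pretrained weights; substituting a genuinely pretrained backbone is a
configuration choice, not a code change.

`count_params()` uses the standard formulas
(`F·(k²·C_in) + F` per conv, `2C` per batch norm, `in·out + out` per
dense) and is tested against independent per-layer hand computation.

## The training backend

No trainable-CNN package is part of this package's dependency set, so
training runs on a small built-in CPU backend: im2col convolutions
evaluated as BLAS matrix products (the block copies are C++), batch
normalization, max pooling, dropout, dense layers, and Adam
(lr 1e-3, β₁ 0.9, β₂ 0.999) minimizing binary cross-entropy. Every
gradient path is validated against central finite differences at
relative tolerance 1e-6 (the check jitters parameters away from the
ReLU kink, where subgradient and finite differences legitimately
disagree).

Numerical choices worth knowing:

- Batch-norm running statistics are bias-corrected (exact average over
  the first updates, exponential with momentum 0.9 thereafter). At desk
  scale a model may see only a few dozen batches, where a
  conventionally initialized exponential average is still dominated by
  its (0, 1) start and inference-mode accuracy collapses.
- Same padding puts the extra pixel of even kernels bottom/right; max
  pooling floors odd spatial dims.
- A non-finite loss or a shape mismatch raises a structured training
  failure which `genome_fitness()` maps to fitness 0, so broken
  configurations are discarded by selection rather than aborting a run.
- Search evaluations use a small budget (5 epochs by default) and the
  final best genome is retrained at a larger one (`final_epochs`,
  default 3× the search budget) — brief training is a noisy but usable
  ranking signal, and only the winner merits the full budget.

## Data pipeline

`load_dataset()` reads the `root/{train,test,val}/{NORMAL,PNEUMONIA}`
PNG/JPEG layout, converts to single-channel, resizes bilinearly
(default target 64×64; 32×32 is used throughout the desk-scale runs)
and scales to [0, 1]. `stratified_split()` allocates each class by
seeded shuffle and largest-remainder rounding, so the canonical
5856-image corpus proportions reproduce exactly (4192/624/1040) and any
class is balanced across splits within one image.

`augment()` returns the originals plus `multiplier` transformed copies:
rotation uniform in ±20°, center-anchored zoom with scale in
[0.9, 1.1], integer shifts up to ±10% of each dimension, horizontal
flip with probability 0.5 — the standard radiograph recipe. Out-of-frame
pixels are filled with the image's mean border intensity (less
artificial than black for bright-background radiographs). Transforms
whose sampled parameter is the exact identity are skipped, so zeroed
ranges reproduce inputs bit for bit — which is also what makes the
augmentation tests exact. Gaussian blur is deliberately not part of the
set. Only the training split is ever augmented by the pipeline drivers;
`run_optimize()` asserts that val/test sizes are untouched.

## The synthetic generator

`generate_images()` emulates exactly one statistical property of the
clinical task: the positive class carries localized bright structure
(opacities/consolidations) on an otherwise identical image
distribution. Class 0 = smooth low-frequency background (coarse uniform
grid, bilinearly upsampled, intensities in [0.25, 0.45]) + Gaussian
noise (sd 0.05); class 1 adds 1-3 soft elliptical Gaussian blobs
(radius 10-22% of image width, random orientation and 0.6-1.4 aspect)
with peak intensity lift 0.5 by default. Classes are exactly balanced
and generation is byte-reproducible under the seed.

The background variability and blob radii were calibrated once so that
at the default lift and noise the global intensity statistic separates
the classes — a pixel-mean threshold rule, fitted by exhaustive sweep on
the training split (`oracle_threshold_classifier()`), reaches ≥95% test
accuracy on 200+200 images at 32×32, mirroring real radiographs where
consolidation contrast exceeds exposure variation. With a wider
background range the background-mean variance masks the smallest blobs
and the oracle drops to ~93%. Zero lift makes the classes
distributionally identical (a chance-level control), and oracle accuracy
is monotone in the lift (property-tested over a lift grid and three
seeds).

What passing tests on this generator shows — and does not show: the
search loop, operators, stopping rule, data plumbing and training
backend are correct and effective on a task whose difficulty is
independently certified; it does not show clinical-grade performance on
real radiographs, which vary in resolution, anatomy, positioning and
label noise far beyond this model.

## Problem sizes used by the tests and the acceptance script

Sizes were chosen so the whole loop runs comfortably on a single CPU:
operator calibration uses 10,000-trial frequency checks against 3σ
binomial bounds; optimum recovery uses a 342-point enumerable space
(2 layers × 6 filters × 3 kernels), population 20, patience 5, 20
seeded runs; the end-to-end run uses 200 images/class at 32×32, a
population of 6 for at most 4 generations with a 5-epoch search budget,
3 layers and ≤32 filters, and a 10-epoch final retrain; the zero-lift
control uses 400 images/class so its chance-level band is measured on
~86 test images. The oracle certificate accompanies every end-to-end
run.

## Known limitations

- Parent selection, pool placement and the refill policy are the
  simplest mechanisms consistent with the source material; other
  choices (fitness-proportional selection, evolved pooling) may search
  differently.
- The backend is deliberately minimal: no GPU, no optimizer schedules,
  no regularization beyond batch norm and head dropout; large
  chromosomes (256 filters, 64×64 inputs) train slowly in it.
- The stand-in backbone is a random (untrained) extractor; head-search
  results transfer to pretrained backbones only in mechanism, not in
  accuracy.
- The error-rate scale in the source material is inconsistent across
  its tables; this package always reports the fraction in [0, 1].
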