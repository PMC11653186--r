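# evocnn

Genetic-algorithm architecture search for compact convolutional image
classifiers, built around two-class grayscale medical-imaging tasks such
as normal-vs-pneumonia chest radiographs.

Hand-tuning a CNN's depth, filter counts and kernel sizes is slow and
expert-bound. `evocnn` treats those choices as a **variable-length
chromosome** — an ordered list of `(filter_count, filter_size)` pairs, one
per convolutional layer — and evolves a population of candidate
architectures: candidates are trained briefly, scored on a held-out
validation split, and the best survive into the next generation through
elitist selection, two crossover sub-operators (a *uniform* gene-mixing
operator for equal-length parents and a *length-altering* operator that
changes the number of layers), and bounded additive mutation. The run
stops when the best fitness plateaus. A second chromosome type searches
the widths of dense layers appended to a frozen convolutional feature
extractor (transfer-learning head search).

The scoring formulas are the standard ones of the field:

- confusion fitness `F = TP / (TP + FP + FN)`
- percentage accuracy `Fitness = 100 · correct / total` (the default
  search fitness, computed on the validation split)
- binary cross-entropy `-(1/N) Σ [y log p + (1−y) log(1−p)]` and its
  categorical counterpart `-(1/N) Σ_i Σ_j t_ij log g_ij`
- error rate = mean |y − ŷ| (the misclassification fraction for hard
  binary labels)
- architecture cost `Cost(L, F) = αL + βF + γE` over layer count, total
  filters and error rate.

Each chromosome is compiled into a fixed scaffold: per layer a
same-padded Conv2D + batch normalization, a 2×2 max pool after every
second conv block, then flatten and a single sigmoid output unit — so a
6-layer chromosome yields 6 conv, 6 batch-norm and 3 max-pool layers.
Training runs on a small built-in CPU backend (BLAS-backed im2col
convolutions with full backprop and Adam, validated against
finite-difference gradients), which keeps the whole loop self-contained
at desk scale.

Because the search loop must be testable without external data, the
package ships a synthetic radiograph-like generator: both classes share a
smooth low-frequency background plus Gaussian noise, and the positive
class carries soft elliptical bright "opacity" blobs with a tunable
intensity lift — zero lift gives a provably chance-level task, and a
pixel-mean threshold oracle certifies separability independently of any
network.

## Worked example

```r
library(evocnn)

# 1. simulate a separable two-class dataset (PNG tree on disk)
cfg <- tempfile(fileext = ".yaml")
writeLines(c(
  "synth:",
  "  n_per_class: 200",
  "  image_size: [32, 32]",
  "  intensity_lift: 0.5",
  "ga:",
  "  population_size: 6",
  "  max_generations: 4",
  "  max_layers: 3",
  "  max_filters: 32",
  "  max_filter_size: 5",
  "  elitism_k: 2",
  "  patience: 2",
  "budget:",
  "  epochs: 5",
  "image:",
  "  target_size: [32, 32]"), cfg)
run_simulate(cfg, "data", seed = 1)

# 2. certify separability independently of any network
data <- load_dataset("data", c(32, 32))
oracle_threshold_classifier(data$train, data$test)$test_accuracy
#> [1] 1

# 3. evolve an architecture and score the best genome on the test split
res <- run_optimize(cfg, "data", "run", seed = 1, final_epochs = 10)
res$best$genome
#> <conv_genome: 1 layer>
#>   filters: 4
#>   kernels: 1
res$best$fitness        # validation accuracy (%) during search
#> [1] 100
res$final_eval
#> <eval_result> train 1.0000 | val 1.0000 | test 1.0000 | loss 0.0229 | error 0.0000
run_report("run/history.csv")
#> generation  best_fitness   mean_fitness   best_genome
#> 0           100.0000       99.7685        {"kind":"conv","layers":[[4,1]]}
#> 1           100.0000       99.7685        {"kind":"conv","layers":[[4,1]]}
#> 2           100.0000       100.0000       {"kind":"conv","layers":[[4,1]]}
```

(On this easy synthetic task even a one-layer architecture is perfect,
so the search plateaus and stops after three generations; harder tasks
drive it toward deeper genomes.)

The same functions back the command-line tool in `inst/cli/evocnn`
(`simulate`, `optimize`, `evaluate`, `report` subcommands, global
`--seed`, exit codes 0/2/3).

The fitness printed per generation is the percentage of correct
validation predictions of the generation's best architecture; with
elitism it never decreases. `final_eval` is the best genome retrained at
the full budget and scored once on the held-out test split.

## Scope

The package searches architectures at desk scale on synthetic or
directory-structured image data
(`root/{train,test,val}/{NORMAL,PNEUMONIA}/*.png`). It does not ship
pretrained backbone weights (a fixed stand-in extractor is provided for
head search), GPU training, or multi-objective selection. See the
vignette in `vignettes/` for the model, parameter and calibration
details.
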