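---
title: "Learned phenotypic distances for behavioral screens: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learned phenotypic distances for behavioral screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model it
implements, what the synthetic-data generator does and does not emulate,
the numerical choices baked into defaults, and the known limitations. It
states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## 1. The problem and the model

A plate-based behavioral screen reduces each well to a motion-index (MI)
trace: per frame, the number of pixels whose grayscale intensity changed by
at least 10 units since the previous frame (`motion_index()`, threshold
exposed but defaulting to the conventional 10). Replicates of an active
compound produce similar traces; the task is a *verification* problem —
decide whether two traces come from the same treatment — under replicate
noise, response-strength variation and slight temporal misalignment.

Equal-weight metrics falter here because they value every frame alike: a
compound that sedates fish except for one motion spike looks, to Pearson
correlation, almost identical to a lethal control. The package's core is a
twin (Siamese) network: one encoder, applied to both members of a pair,
maps each preprocessed trace to a low-dimensional embedding, and a
contrastive loss

$$
L = \tfrac12 d^2 \;\; \text{(matched)}, \qquad
L = \tfrac12 \max(0,\, m - d)^2 \;\; \text{(mismatched)}, \qquad
d = \lVert y_1 - y_2 \rVert_2
$$

with margin $m = 0.5$ shapes the embedding so that the Euclidean distance
between embeddings is a phenotypic distance. Because the two branches share
every parameter, the distance is symmetric by construction and
$d(x, x) = 0$ exactly.

Two encoders are provided. `twin_nn` is the plain MLP: at full scale a
101,250-frame trace is subsampled at stride 5 to a 20,250-point input and
passed through layers of width 4000, 500, 250 and 100 to a 10-dimensional
embedding, with batch normalization and ReLU after every linear map except
the last. `twin_dn` keeps the same interface but uses DenseNet-style
connectivity adapted to fully connected layers: within a block, every layer
consumes the concatenation of the block input and all previous layer
outputs and emits a fixed number of new features (growth 12, 4 layers per
block, 3 blocks by default), with linear transitions halving the width
between blocks. The defining property retained from the convolutional
original is dense feature reuse — each layer sees all earlier
representations — which is what makes the architecture more expressive per
parameter; convolution itself adds a locality prior that a fixed-length,
globally min-max-normalized trace does not require, so the package's
variant is fully connected. Both architectures are configurable
(`twin_config()`), and `twin_layer_shapes()` reports the implied layer
sizes without allocating parameters (the full-scale first weight matrix
alone holds 81 million).

Training (`train_twin()`) follows the standard recipe: per epoch the
training pairs are shuffled and each pair's member order randomly swapped
(a symmetry-preserving augmentation for a weight-shared encoder), traces
are stride-subsampled and min-max normalized with bounds frozen in the
configuration (dataset-wide 0–6750 MI units by convention), and Adam
(learning rate 5e-4, weight decay 1e-6) steps after every batch (32 pairs
for `twin_nn`, 8 for `twin_dn`). Validation pairs — the held-out-drug
split — are scored every epoch with frozen running batch-norm statistics;
training stops at `max_epochs` or after `patience` epochs without
validation-loss improvement, returning the best-validation-epoch weights.
The adversarial stress tests instead request final-epoch weights
(`selection = "final"`), because their validation labels must not influence
the returned model. Every stochastic step derives from one integer seed,
so runs are bit-reproducible.

The whole engine — forward pass, batch-norm backward, Adam — is written in
plain R matrix algebra. At desk scale (1,000-point inputs, hundreds of
pairs) an epoch takes well under a second; the design favors exact
reproducibility and inspectability over throughput.

## 2. Pair construction

Pairs are built drug-wise (`split_by_drug()`, 80/20): no replicate of any
drug appears on both sides of the split, which forces the model to learn
features that transfer across compounds. Candidate positives are all
same-drug replicate pairs whose members are both labeled active by the
activity filter; labeling replicates of an ineffective compound "matched"
would teach the model nothing but vehicle noise. Negatives are sampled
cross-drug and subsampled to match the positives exactly. On top, 25% of
final positives are control–control and toxin–toxin pairs (evenly) and 25%
of final negatives control–drug, control–toxin and toxin–drug (evenly up
to rounding): a deployed metric constantly meets such pairs, and a model
never shown them ranks vehicle wells among a drug's nearest neighbors. The
quota arithmetic treats the drug-drug pairs as 75% of the final total
(total = drug-drug/0.75); when a bucket lacks candidates (e.g. a screen
without lethal controls) the shortfall reallocates proportionally with a
warning, keeping the positive/negative balance exact.

The activity filter is a random forest on raw MI vectors (`binary`:
treatment vs vehicle; `ternary`: active/inactive/lethal with eugenol wells
seeding the lethal class), trained on classes balanced by seeded
undersampling with an 80/20 well split for reported accuracy. Wells that
served as training examples are labeled by their out-of-bag votes rather
than by re-running them through the forest — re-prediction of training
rows returns their (noisy, role-derived) training labels and would wave
every inactive drug through the gate. The per-drug "phenotype strength"
score is the forest's active-class probability averaged over replicates.
The forest consumes raw, unnormalized traces; 500 trees by default, and
the pipeline's results are insensitive to 100 vs 500.

## 3. The synthetic screen generator

`generate_screen()` emulates the statistical structure the method assumes,
not any particular instrument:

* **Layout.** 96-well plates (8 x 12), one plate per replicate; per plate
  10 vehicle wells (8 DMSO + 2 H2O, treated identically throughout, as
  vehicle kinds are behaviorally indistinguishable) and 2 lethal
  (eugenol-like) controls. `fixed` mode pins every drug to one (row, col)
  across plates — the supplier-preset layout in which all replicates of a
  compound share a position; `randomized` mode draws an independent seeded
  permutation per plate. Unused treatment slots revert to vehicle.
* **Templates.** A stimulus schedule (alternating dark and
  blue/purple-light, acoustic and tap epochs laid out proportionally over
  the trace) drives class response templates: per epoch an onset burst
  decaying toward a sustained plateau, with class-specific gain, latency,
  decay and plateau. Active classes are distinctly hypo- or
  hyper-responsive per epoch (gain $1 \pm \text{sep} \cdot U(0.35, 0.8)$);
  vehicle-likeness is modeled *explicitly* by the inactive drug fraction
  (default 25%) rather than by classes that happen to sit on the vehicle
  response. `class_separation` scales the spread — the separability dial.
* **Replicate noise.** Per well: a time shift (±1.2% of the trace), a
  global amplitude factor (lognormal, sd 0.2; fish count and vigor vary by
  well), per-epoch response-gain jitter (lognormal, sd 0.3; response
  strength varies per assay), smooth low-frequency noise (white noise
  filtered with a wide Hanning window, sd 40 MI) and per-frame
  high-frequency sensor noise (sd 15 MI). Traces are clipped to
  [0, 6750]. Lethal wells show near-zero motion. These defaults were set
  once, during design, so that correlation-distance pair AUROC lands in
  the 0.7–0.8 band — the difficulty regime in which conventional metrics
  are reported to operate on real screens — and were not revisited.
* **Positional artifact.** `plant_positional_artifact()` adds a
  deterministic sinusoid at 0.425 cycles/frame whose amplitude and phase
  are smooth functions of (row, col) — a model of position-dependent
  instrumentation effects (distance to light and sound sources) imprinted
  in the high-frequency band. Two wells at the same position always carry
  the identical component. Hanning(11) smoothing removes essentially all
  of its power; under stride-5 subsampling it aliases to a slow 0.125
  cycles-per-sample oscillation, mimicking how undersampling folds
  instrument vibration into the model's input band. The real artifact's
  spectral shape is uncharacterized; this planted form is a modeling
  choice, and nothing downstream depends on its exact shape — only on its
  being position-keyed and high-frequency.
* **Ground truth.** Drug-to-class map, activity flags, binary target
  profiles (each class owns 3 characteristic targets; drugs inherit them
  plus occasional extras) and the artifact descriptor, for use as oracles
  in tests and enrichment analyses. `synthetic_fingerprints()` adds
  family-structured fingerprints (shared on-bits within a structural
  family, disjoint across families), optionally splitting one phenotype
  class across two families to create ground-truth scaffold-hopping pairs.

What the generator does **not** emulate: per-fish agent behavior, dose
response (screens are single-dose), habituation across epochs, plate-edge
evaporation effects, or any real sensor's noise spectrum. Passing tests on
this simulator therefore demonstrate that the pipeline recovers planted
structure of the assumed form — treatment-keyed, stimulus-locked,
replicate-noised — not that it will match any particular instrument's
artifact profile.

## 4. Evaluation and stress tests

`roc_auc()` implements the Mann–Whitney form (ties count one half);
`prc_auc()` uses the standard step interpolation. `knn_classify()`
reproduces the reference-drug quality-control task: per drug, 8 training
and 2 validation replicates, majority vote among the k = 15 nearest
training wells (neighbors necessarily pool across drugs since 15 > 8; ties
break by summed distance, then lexicographically).
`replicate_identification()` counts same-drug wells in each well's top-50
neighbors and aggregates per drug by the maximum over its wells (the
per-well mean is available via `aggregate = "mean"`; the maximum matches
the reading "how many replicates *can* be found from this drug").
`behaviorome_map()` lays compounds out in 2-D from a precomputed distance
matrix through a pluggable engine; the default is classical
multidimensional scaling, which is deterministic and dependency-free, and
any neighbor-embedding function of the same signature (e.g. a UMAP-family
method) can be dropped in, with `n_neighbors`/`min_dist` forwarded.

The stress battery probes shortcut learning:

* `smoothing_ablation()` compares held-out AUROC of a model trained on raw
  traces with one trained on Hanning(11)-smoothed traces (smoothing
  applied before subsampling and normalization). Training-on-smoothed is
  the primary mode because it asks the right question — *is the
  achievable performance carried by the high-frequency band?* — whereas
  feeding smoothed inputs to a raw-trained model confounds reliance with
  distribution shift. The evaluate-only mode is kept for probing a
  specific trained model.
* `label_shuffle_test()` is classic y-scrambling: labels permuted within
  each split, model retrained, held-out AUROC scored against the scrambled
  labels; anything above chance indicates leakage in the machinery.
* `random_input_test()` replaces traces by uniform noise over the observed
  MI range, keeping labels. Held-out scoring uses only pairs that share no
  well with any training pair, because control wells straddle the
  drug-wise split and a memorized noise trace would otherwise leak its
  trained-in embedding position into the held-out score.
* `well_distance_test()` asks whether plate geometry alone is learnable
  from traces: wells are partitioned 80/20, balanced pair sets are labeled
  by within-plate (row, col) Euclidean distance against a cutoff
  (conventionally 2 and 5.2 well-pitch units; plate identity is ignored,
  since within-plate geometry is where position effects live), and a twin
  model is trained on these geometric labels. Artifact-free data yields
  chance AUROC; a planted positional artifact makes geometry learnable.

## 5. Phenosearch and scaffold hopping

`phenosearch_rank()` ranks a library against each query trace by ascending
distance (top 500 by default). `moa_enrichment()` calls a ranked compound
a hit when its binary target profile shares at least one target with the
query's (the threshold is configurable; one shared target is the loosest
defensible reading of "profiles match") and compares cumulative hits
against the analytic random baseline $m \cdot H / L$, with a bootstrap
band over queries. `control_contamination()` counts vehicle wells in the
ranked lists — a metric that cannot tell weak phenotypes from vehicle lets
controls flood the top. `quadrant_analysis()` annotates all compound pairs
with structure distance (Tanimoto on fingerprints), phenotypic distance
and target-profile similarity; scaffold-hop candidates are pairs with
phenotypic distance < 0.3, structure distance > 0.5 and target similarity
> 0.2, ranked by target similarity (quadrant axes default to 0.3/0.4).
Fingerprints can be supplied from any source as 0/1 matrices; the
simulator provides family-structured synthetic ones, so no cheminformatics
dependency is required.

## 6. Numerical choices and degenerate inputs

* Correlation distance of a zero-variance trace is defined as 1 (with a
  warning): an uninformative flat trace is neither similar nor
  anti-similar to anything.
* `smooth_hanning()` uses reflection padding, preserving length and
  interior means; windows must be odd and no longer than the trace.
* FastDTW uses radius 1 by default (the common convention for the cited
  approximation), absolute-difference local cost and the classic
  diagonal/up/left step pattern; `exact = TRUE` runs the full dynamic
  program, and the banded cost never falls below it.
* Contrastive gradients at exactly zero embedding distance use the zero
  subgradient.
* Batch normalization uses eps 1e-5 and momentum 0.1; running variance is
  unbiased. The gradient of the whole network checks against central
  finite differences in the test suite.
* Pair-order swapping, batch order, splits, undersampling, forest fits and
  initialization all derive child seeds from one master seed via a string
  hash, so sub-draws are decoupled but reproducible; all seeds stay below
  2^31.
* Traces shorter or longer than a model's expected input raise shape
  errors rather than being silently resampled.

## 7. Problem sizes used by the tests and acceptance script

Desk-scale runs use 5,000-frame traces (stride-5 model input of 1,000
points) and a reduced `twin_nn` (widths 200, 100, 50, 20). The reference
screen is 24 pseudo-drugs x 8 replicates in 8 classes at default
separability; the shortcut-learning contrast uses 36 drugs at separability
0.4 with a planted artifact of amplitude 300 — the lower separability
leaves headroom between the biological ceiling and the artifact-inflated
score, which is precisely the regime in which preset layouts mislead — and
the null-control battery uses 40 drugs (≥ 2,000 pairs). The scaffold-hop
analysis uses 30 always-active drugs in 6 classes so that classes hold
enough compounds to split across two structural families. The full-scale
architecture (20,250-point input) is supported and its shapes are tested,
but training it is a cluster-scale exercise by design.

## 8. Known limitations

* The learned distance is a pseudometric: distinct wells can embed
  identically, and the triangle inequality is inherited from the embedding
  space, not from trace space.
* Same-class different-drug pairs are labeled negative during training (a
  deliberate, paper-faithful simplification), so the model is pushed to
  separate compounds that a pharmacologist might call equivalent; at the
  compound level this can loosen class clusters even as replicate clusters
  tighten. Target-profile-based relabeling is out of scope.
* The activity filter's reference labels are noisy by construction
  (role-derived), so its reported accuracy under-states its usefulness as
  a gate; the pair builder only consumes its labels, never its accuracy.
* The simulator's artifact is one plausible positional channel; real
  screens may carry several with different spectra, and a smoothing window
  tuned to one band may miss another.
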