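---
title: "Structure-aware transcription factor prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-aware transcription factor prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Transcription factors (TFs) are DNA-binding proteins that regulate gene
expression. Sequence-based deep learning classifiers predict TFs from a
one-hot encoding of the amino-acid sequence alone. Because proteins act in
their folded form, per-residue secondary structure carries discriminative
signal that a pure sequence encoding cannot express: the same amino-acid
stretch in an alpha helix and in a coil is one and the same input to a
sequence model but two different inputs to a structure-aware model.

`structf` implements a structure-aware TF classifier together with the full
study pipeline around it: structure parsing and quality filtering, GO-based
labeling, redundancy-aware dataset curation, cross-validated training and
evaluation, and attribution analysis.

## Input encoding

Each protein of length $\ell \le 1000$ is encoded as a zero-padded
$1000 \times 63$ binary matrix. The 63 columns are the lexicographic pairs
$(r, g)$ of the 21-letter residue alphabet (20 standard amino acids plus
the wildcard `X`, sorted alphabetically, so `X` sits between `W` and `Y`)
and three secondary-structure groups (SSGs) in the fixed order alpha-helix
< beta-sheet < coil-turn. The SSGs collapse the eight classic DSSP
categories: `H`, `G`, `I` to alpha; `B`, `E` to beta; `T`, `S` and the
undetermined blank to coil. Codes outside the classic eight (such as the
polyproline `P` emitted by newer DSSP releases) are treated like the
undetermined blank. Row $i$ carries a single 1 at the column of position
$i$'s pair; rows past $\ell$ are zero. A 21-column sequence-only encoding
of identical layout drives the comparator model, and
`marginalize()` maps the 63-column encoding onto it exactly (summing each
residue's three SSG columns), which the tests exploit as an invariant.

Two choices here are package decisions rather than published facts: padding
rows are all-zero (a pad symbol would give the classifier a spurious
length feature), and the wildcard's alphabet slot is defined once in
`residue_alphabet()` so a single constant controls the column order.
Column indices are 1-based, as is idiomatic in R.

## Dataset curation

Proteins enter the study when they have at most 1000 residues and contain
only the 20 standard amino acids (`is_eligible()`), and a predicted
structure is called reliable when at least 90% of its residues have a
model confidence (pLDDT, read from the PDB B-factor column of the CA atom)
of at least 70, both comparisons inclusive (`is_reliable()`).

TF labels follow a two-clause GO rule: a protein is a TF iff it carries a
TF GO term, or a transcription-regulation GO term together with a
DNA-binding GO term. The three term sets are configuration
(`go_rule_config()`); matching is exact string matching without
ontology-graph propagation, which reproduces a fixed-term-list criterion
without an ontology dependency.

Sequence redundancy is removed on top of an externally computed clustering
(the `easy-cluster` output of MMSeqs2 at 30% identity and 80% coverage;
the package consumes the membership TSV and does not re-implement the
clustering). One protein survives per cluster: the tool's representative
if the cluster has no TF or the representative is itself a TF, otherwise a
uniformly drawn TF member — keeping as much TF data as possible.

Class imbalance is handled by ratio sampling: all TFs are kept and exactly
$s \in \{3, 5, 10\}$ times as many non-TFs are drawn without replacement,
giving the dataset family $D(x, z, s)$ with $x$ the structure-reliability
choice and $z$ the redundancy choice. With the 635 TFs of the reliable
non-redundant protein set this yields datasets of 2540, 3810 and 6985
proteins. Each dataset receives a stratified 5-fold plan; a split
combination holds one fold out as the independent test set (20%) and
divides the rest, stratified, 9:1 into training (72%) and validation (8%).
The train/validation subdivision is stratified for consistency with the
fold construction; leftover proteins after integer division are spread one
each over seeded-randomly chosen folds, keeping per-class fold sizes
within one protein. Samples for different ratios are drawn independently,
each from a seed derived from the master seed, so every dataset is
individually reproducible.

## Model

The classifier is a convolutional network over the padded input matrix:

* three parallel subnetworks, each three blocks of valid convolution
  (stride 1, no padding) + batch normalization + ReLU + dropout (rate
  0.1). The time-kernel stacks are (4, 4, 16), (12, 8, 4) and (16, 4, 4);
  the first kernel of each subnetwork spans all input columns, so the
  column dimension collapses to 1 after the first layer. All three stacks
  shrink the temporal axis by the same 21 rows — 979 rows at input length
  1000 — so their feature maps align and concatenate on the channel axis;
* one further convolution + batch norm + ReLU over the concatenated map,
  then a global max-pool over the temporal axis, giving a fixed-size
  vector for any input length;
* a hidden fully connected layer with batch norm and ReLU, and a final
  fully connected layer with batch norm feeding a sigmoid, so the output
  is a TF probability in (0, 1).

Weights are Xavier-uniform initialized from a seed; biases start at zero.
The sequence comparator reuses the identical topology with first-layer
kernels spanning 21 columns, so any performance difference is attributable
to the encoding alone.

Channel width (default 128), hidden width (default 512), and the
post-concatenation kernel (default 4) and channel count (default =
channels) are exposed in `model_config()` as package defaults, not
published constants: the published description fixes the subnetwork
kernels, strides, dropout and initialization but not these widths, so they
follow the conventions of the sequence-based predecessor architecture and
remain configurable.

The engine itself is a compact CNN implementation (R with
RcppArmadillo/BLAS kernels): batched valid convolutions in a shift-GEMM
formulation, batch normalization with running statistics, inverted
dropout, Adam, and backpropagation that also yields input gradients for
attribution. Training and initialization draw exclusively from R's seeded
RNG, which makes builds, histories and attributions bit-reproducible; its
gradients are verified against finite differences in the test suite.

## Training protocol

Binary cross-entropy is minimized with Adam at a constant learning rate of
0.001, batch size 128, for 50 epochs — no early stopping and no schedule.
Loss and optimizer are package choices (the published protocol names the
hyperparameter values but not the loss/optimizer pair; these are the ones
conventional for the predecessor architecture). After every epoch the
validation loss is computed in eval mode; by default the returned model is
the checkpoint with the lowest validation loss (`selection = "best_val"`),
with `"final"` available since the published protocol does not state which
was kept. The full experiment grid enumerates methods x datasets x splits
(3 x 12 x 5 = 180 at full scale) with per-cell seeds derived from one
master seed.

## Evaluation

AU-ROC is computed in rank form (identical to trapezoidal integration with
tie-averaging) and AU-PRC as step-wise average precision, which avoids the
optimistic bias of linear PR interpolation; the published text does not
name its PR estimator, so the unbiased one was chosen. The confusion
matrix uses the published decision rule — TF iff score strictly greater
than 0.5 — and MCC is reported as `NaN` whenever a marginal is zero (for
example a model predicting everything negative); aggregate tables
propagate it as missing rather than as zero. Method comparisons use the
paired two-sided Wilcoxon signed-rank test over dataset x fold cells,
exact for 25 or fewer untied non-zero differences (two-sided chosen as the
conservative reading; zero differences dropped).

## Attribution

Integrated gradients attribute the eval-mode sigmoid output along the
straight-line path from a baseline to the input, with a Riemann-midpoint
rule (default 64 steps; completeness residuals are exposed on the result
and are below 1e-2 at 256 steps in the tests). The baseline is the
all-zero matrix — the natural "no residue" input under zero padding; the
published analysis does not state its baseline, so it is configurable.
Row sums give one signed score per sequence position; positions inside the
union of a TF's annotated DNA-binding-domain (DBD) intervals (overlaps
counted once) sum to the DBD-related score and the rest to the
non-DBD-related score, which together equal the total by construction.
Signed scores (not magnitudes) are summed. DBD intervals are 1-based
inclusive, following UniProt feature conventions, and are never used in
training.

## The synthetic cohort: what it does and does not show

`generate_cohort()` builds a fully self-contained desk-scale cohort:
150 TFs and 450 non-TFs (class ratio 3) of 80-300 residues, uniform
background residue composition, and background secondary structure drawn
as alternating segments with geometric run lengths (mean 6 residues) —
mimicking realistic secondary-structure run statistics without any
sequence-structure coupling. Every TF carries a fixed 12-residue
amino-acid motif rendered as an alpha helix at a uniformly random offset,
recorded as its DBD interval; half of the non-TFs carry the *same*
amino-acid motif in coil conformation; the remaining non-TFs contain no
motif. pLDDT profiles place at most 2% (reliable mode) or exactly 20%
(unreliable mode) of residues below the confidence threshold, so the
reliability filter passes or rejects them by construction, and no score
ever equals the threshold exactly, keeping boundary behaviour out of
stochastic fixtures. Fixture directories (FASTA, per-protein classic DSSP
and AlphaFold-style PDB files, annotation, cluster and sidecar tables) are
byte-reproducible from the seed.

The signal placement is the point: the amino-acid motif is identical in
both classes, so a sequence-only model faces an irreducible ambiguity on
confounded non-TFs (its best attainable test AU-ROC on this design is
0.75), while the joint encoding can separate the classes completely. The
end-to-end check trains both encodings on the same proteins, the same
split and the same seed, and requires the structure model to exceed 0.9
test AU-ROC while beating the sequence model by at least 0.05, for the
majority of three seeds. For these desk-scale runs the models use 8
channels, 32 hidden units and padding length 300 (the cohort's maximum
protein length) — widths chosen as the smallest that train stably here,
since the full-scale defaults would be needlessly large for a
600-protein cohort.

Passing these tests shows that the pipeline is internally consistent and
that the architecture can exploit joint sequence-structure signal that a
sequence encoding cannot express. It does not show real-data performance:
the cohort has no TF family structure, no homology, no realistic
amino-acid composition, and a single planted motif instead of diverse
DBDs. Published full-scale results (hundreds of thousands of proteins
from real structure databases) are outside what this package's fixtures
can reproduce.

## Numerical and degenerate-input choices

* Batch-norm epsilon 1e-5, running-statistics momentum 0.1 (unbiased
  variance in the running estimate).
* BCE probabilities are clamped to [1e-12, 1 - 1e-12] before logs.
* Max-pool ties break to the earliest position, keeping eval-mode
  forwards and attributions deterministic.
* Empty proteins encode to all-zero matrices; an all-zero input is a
  valid model input (it scores as a padded empty protein).
* A single-class training set warns and proceeds; empty splits and
  overlapping train/validation sets are errors.
* Unknown residues are substituted by `X` with a warning inside the
  encoder, although eligibility filtering removes such proteins upstream.
* Score exactly 0.5 is a non-TF call, matching the strict-greater rule.

## Known limitations

* Only the classic fixed-column DSSP text dialect is parsed, not the
  mmCIF dialect; an optional `mkdssp` shell-out exists but is never
  required.
* Multi-chain PDB files use the first chain (with a warning) and the
  first alternate location; structure prediction itself is out of scope.
* No GO-DAG reasoning: descendant terms of a configured term do not
  match.
* The recurrent/attention comparator family is out of scope; the
  sequence comparator here isolates the encoding, not the architecture.
* MCC aggregation over folds propagates `NaN`; downstream consumers that
  need a number must handle missingness explicitly.
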