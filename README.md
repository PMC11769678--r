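# structf — structure-aware transcription factor prediction

`structf` predicts whether a protein is a transcription factor (TF) from
its amino-acid sequence **jointly with its per-residue secondary
structure**. Sequence-based deep learning TF predictors encode a protein
as a one-hot matrix over the 21-letter residue alphabet; `structf`
instead encodes the pair *(residue, secondary-structure group)* at every
position, so the same amino-acid stretch in an alpha helix and in a coil
becomes two different inputs. Around that encoding the package implements
a complete, reproducible study pipeline for anyone benchmarking TF
predictors or adapting them to new proteomes.

## What is inside

**Encoding.** Per-residue DSSP categories are collapsed into three
secondary-structure groups (SSGs) — `H,G,I` → alpha-helix, `B,E` →
beta-sheet, `T,S,blank` → coil-turn — and each protein of length
ℓ ≤ 1000 becomes a zero-padded 1000 × 63 binary matrix over the
lexicographic (residue, SSG) pairs, `M[i, j] = 1` iff position *i* is
pair *j*. A 21-column sequence-only encoding drives the comparator model;
`marginalize()` maps one onto the other exactly.

**Model.** A CNN with three parallel subnetworks (kernel stacks
[4,c]/[4,1]/[16,1], [12,c]/[8,1]/[4,1], [16,c]/[4,1]/[4,1], each
convolution followed by batch norm, ReLU and dropout 0.1), whose
temporally aligned feature maps (979 rows at input length 1000) are
concatenated and passed through one more convolution, a global max-pool
and two fully connected layers into a sigmoid TF score. Xavier-uniform
initialization, Adam at learning rate 0.001, batch size 128, 50 epochs,
best-validation-loss checkpointing; everything is bit-reproducible from a
seed. The engine is a compact native implementation (R + RcppArmadillo
kernels) with gradients verified against finite differences.

**Pipeline.** AlphaFold-style PDB parsing (pLDDT from the B-factor
column) and classic DSSP parsing; eligibility (≤ 1000 standard residues)
and structure-reliability (≥ 90% of residues at pLDDT ≥ 70) filters;
two-clause GO labeling (TF term, or regulation term + DNA-binding term);
cluster-based redundancy removal that prefers TF members; ratio sampling
into the D(x,z,s) dataset family; stratified 5-fold plans with 72/8/20
train/validation/test splits; AU-ROC, average-precision AU-PRC, MCC (with
explicit `NaN` when undefined) and paired Wilcoxon comparisons;
integrated-gradients attribution with DNA-binding-domain (DBD) score
aggregation; and a synthetic-cohort generator that plants a
structure-dependent motif so the whole pipeline trains and validates with
no external data.

## Worked example

Simulate a cohort in which every TF carries a 12-residue motif in helical
conformation while half of the non-TFs carry the *same* motif as coil —
so only a structure-aware encoding can fully separate the classes — then
train, evaluate and interpret:

```r
library(structf)

## 1. Simulate a cohort with a structure-dependent motif
gen <- generate_cohort(
  synthetic_cohort(n_tf = 150, n_nontf = 450, min_length = 80,
                   max_length = 300, seed = 7),
  motif_spec())

## 2. Encode, build the D(rl,nr,3)-style manifest and one split
enc <- encode_records(gen$records, "structure", pad_length = 300)
man <- sample_ratio(enc$ids[enc$labels], enc$ids[!enc$labels], s = 3,
                    seed = 7, name = dataset_name("rl", "nr", 3))
man <- stratified_folds(man, k = 5, seed = 7)
sp  <- make_split(man, test_fold = 0, seed = 7)
slot <- setNames(seq_along(enc$ids), enc$ids)

## 3. Train the structure-aware CNN (desk-scale widths)
cfg <- model_config(input_cols = 63, pad_length = 300, channels = 8,
                    fc_hidden = 32, seed = 7)
model <- train_model(build_model(cfg), enc$X, as.numeric(enc$labels),
                     unname(slot[sp$train_ids]), unname(slot[sp$val_ids]),
                     train_config(epochs = 50, seed = 7))

## 4. Evaluate on the held-out test fold
te <- unname(slot[sp$test_ids])
scores <- predict_scores(model, enc$X[, , te])
res <- evaluate_scores(as.numeric(enc$labels)[te], scores)
cat(sprintf("test fold 0: AU-ROC %.3f  AU-PRC %.3f  MCC %.3f\n",
            res$au_roc, res$au_prc, res$mcc))

## 5. Where does the model look? Integrated gradients on one test TF
tf_id <- intersect(sp$test_ids, enc$ids[enc$labels])[1]
rec <- gen$records[[which(enc$ids == tf_id)]]
x <- encode_structure(rec$sequence, rec$ssg, pad_length = 300)
prof <- attribution_profile(model, x, dbd_intervals = rec$dbd_intervals,
                            steps = 64, protein_id = tf_id)
cat(sprintf("%s: prediction %.3f, DBD score %.3f, non-DBD score %.3f\n",
            tf_id, prof$prediction, prof$dbd_score, prof$non_dbd_score))
```

Output (about two minutes on one CPU):

```
test fold 0: AU-ROC 1.000  AU-PRC 1.000  MCC 1.000
TF0003: prediction 0.883, DBD score 0.692, non-DBD score -0.048
```

The structure model separates the held-out fold perfectly, and the signed
attribution mass concentrates on the protein's annotated DBD interval —
the motif it was never told about — while the rest of the sequence
contributes almost nothing. Training the 21-column sequence comparator on
the same split and seed leaves a large AU-ROC gap (its best attainable
AU-ROC on this design is 0.75, since half of the motif-bearing proteins
it sees are non-TFs).

A thin command-line front end over the same functions lives at
`inst/cli/structf.R` (`simulate`, `filter`, `build-dataset`, `train`,
`predict`, `evaluate` subcommands).

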