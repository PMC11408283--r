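---
title: "Methods: curation, featurization, modeling and applicability in cpipred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curation, featurization, modeling and applicability in cpipred}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Compound-protein interaction (CPI) prediction asks, for a small molecule and
a protein, whether the molecule binds or modulates the protein. Public
bioactivity databases hold many potency measurements (IC50, Ki, EC50) and
binary annotations for overlapping sets of compound-protein pairs, but the
raw records are noisy in characteristic ways: the same pair is measured by
several sources with different values, near-duplicate ligands of a protein
inflate benchmark performance ("hidden ligand bias"), and inactive records
are vastly over-represented for some proteins while absent for others. A
model trained naively on such data learns compound-only cues rather than
interaction cues, and nothing in its output says for which new proteins its
predictions can be trusted.

`cpipred` implements a complete desk-scale pipeline that addresses these
issues: rule-based curation into an unbiased benchmark, a correlation-space
screen that confirms candidate negatives, fixed-length featurization of
compounds and proteins, a fully connected neural classifier with a grid
search, threshold-free evaluation, and an applicability-domain analysis that
scores each new protein by its embedding distance to the training set.

# Curation rules

Raw records (`compound_id`, `protein_id`, assay type, value, unit, binary
label, source) pass through the following rules, in order. All potencies are
in micromolar after ingest; nM and mM are converted, unknown units reject
the record with a warning.

1. **Molecular weight window.** Compounds outside 100-1000 Da (inclusive at
   both ends) are removed; the focus is small molecules. The bounds are
   inclusive because the removal criterion is strict inequality on either
   side.
2. **Label resolution.** A pair is *positive* if any record supports
   activity: a potency at or below 10 uM (the conventional high-throughput
   hit cutoff; the boundary is inclusive), a binary "active" annotation, or
   membership in a configured known-interaction catalogue source. A pair is
   *negative* only if every interpretable record is negative. The
   representative potency is the minimum across records - the most potent,
   biologically most relevant measurement. Pairs with both kinds of evidence
   are resolved positive and counted as conflicts in the curation report.
3. **Ligand deduplication.** Within one protein, compounds with Tanimoto
   similarity above 0.8 (on 2048-bit circular fingerprints) form redundancy
   groups; only the member with the largest interaction count survives.
   Grouping is greedy leader clustering: compounds are visited by
   descending interaction count (ties broken lexicographically by id); a
   compound joins the first similar retained leader, otherwise it becomes
   one. This is deterministic and order-stable, and it directly realizes
   "the compound with the most interactions survives". Deduplication is
   applied to positives and negatives separately so that a heavily measured
   positive cannot suppress a legitimate negative of the same scaffold.
   The *interaction count* of a compound is the number of resolved pairs it
   participates in anywhere in the working dataset, of either label.
4. **Negative capping.** Inactive records concentrate on a few heavily
   screened proteins, so negatives are capped at 1000 per protein: ranked by
   interaction count, accepted only if their similarity to every previously
   accepted survivor is strictly below 0.8.

The train/test split is uniform at random with an 80% train fraction,
rounding half-up on the train side, deterministic under the configuration
seed.

# The correlation-space negative screen

Unmeasured or weakly measured pairs used as negatives are the main source of
false negatives in CPI training sets. The screen projects compounds and
proteins into a shared canonical-correlation space fitted on the *known
positive* pairs: descriptor vectors on both sides are standardized,
covariance blocks are ridge-regularized (1e-6) for stability on collinear
descriptors, and the paired projections maximize per-component correlation
(components default to `min(5, rank)`). For each compound with at least two
known targets, those targets form its *target space*; the distance threshold
is the upper limit of the 95% confidence interval of the mean pairwise
Euclidean distance among the targets, `mean + t(0.975, m - 1) * sd /
sqrt(m)` over the `m` target pairs. With a single pair the threshold
degenerates to that distance itself. A candidate negative is *confirmed*
when the candidate protein's minimum distance to the compound's targets
exceeds the threshold; compounds without a usable target space pass through
unscreened rather than being silently dropped.

Three choices here were genuinely open:

- **Distance to the target space** could mean distance to the centroid or to
  the nearest target; we use the minimum over targets, the conservative
  choice against discarding true binders (a protein close to *any* known
  target is not confirmed negative). The alternative is one argument away in
  `confirm_negative()`.
- **The confidence interval** is computed as a t-based CI of the mean over
  the set of pairwise distances; other readings (quantiles of the distance
  distribution) would systematically widen or narrow the threshold.
- **Ordering**: capping precedes screening, matching the order in which the
  rules are stated for dataset construction.
- **Descriptors**: the built-in sets (folded fingerprint counts plus
  molecular weight for compounds; amino-acid composition, a fixed dipeptide
  subset and length for proteins) are deliberately simple, reproducible and
  license-free. Externally computed descriptor tables with the same shape
  plug in directly, so richer commercial descriptor sets can be used where
  available.

Distances are measured in the protein-side canonical coordinates: targets
and the candidate protein are both projected with the protein weights, so
they live in the same coordinate system.

# Featurization

**Compounds.** 2048-bit circular (Morgan-type) fingerprints of radius 2,
computed by RDKit from SMILES, or supplied directly as bit patterns.
Principal component analysis on the centered training-set bit matrix retains
the top 200 components. The PCA is fitted on training compounds only; test
and external compounds are transformed with the frozen rotation, avoiding
information leakage through the feature model.

**Proteins.** A sequence is read as a document of non-overlapping 3-mer
words, one reading frame starting at the first residue, trailing one or two
residues dropped. A continuous bag-of-words (CBOW) model with negative
sampling learns 100-dimensional word vectors (window 5, 5 negative samples
drawn from the 3/4-power unigram distribution, learning rate 0.05 with
linear decay); the protein representation is the arithmetic mean of its
word vectors. The word model is trained on training-split proteins only;
out-of-vocabulary words at inference are skipped from the mean, and a
protein with no in-vocabulary word is an error (outside the feature space)
rather than a silent zero vector. Training defaults to one worker with a
fixed seed so results are bit-reproducible; the `workers` field is accepted
for interface compatibility.

A labeled pair is the 300-dimensional concatenation: 200 compound
components followed by 100 protein components.

# The classifier

A fully connected network with two hidden layers maps the 300-dimensional
pair vector to an interaction probability. Each hidden block applies, in
order: affine transform, batch normalization, ReLU, dropout (the
conventional arrangement; the components themselves fix the block, not the
order). The head is affine plus a sigmoid, so outputs are strictly inside
(0, 1). Training minimizes binary cross-entropy (predictions clipped at
1e-7 to avoid log(0)) with the Adam optimizer on minibatches (default 256;
batch size is a free parameter). Inputs are standardized with training
statistics; batch normalization uses batch statistics during training and
running averages at inference; dropout is inverted so inference needs no
rescaling. Training aborts with a diagnostic on a non-finite loss. The
probability cutoff is 0.5, inclusive on the positive side.

The hyperparameter search spans first hidden layer {256, 512, 1024, 2048},
second hidden layer {128, 256, 512, 1024}, dropout {0, 0.2, 0.5}, learning
rate {0.01, 0.001, 0.0001} and epochs {100, 200, 500} - 432 combinations.
Selection uses k-fold cross-validation (default 5) on the training split
with accuracy as the criterion and enumeration order as the tie-break;
held-out metrics are reported on the untouched test split. Two hidden
layers exactly are implied by the two hidden-size ranges and the output
layer's reference to the second hidden activation.

# Metrics

Accuracy, sensitivity (= TPR = recall), specificity, false positive rate
and precision follow their standard confusion-table definitions; a metric
with a zero denominator is reported as `NA`, never as a silent zero. AUROC
is computed by ranks (the Mann-Whitney statistic), giving ties half credit.
AUPR uses the step-wise precision-recall curve over descending score
thresholds with no linear interpolation - the conservative standard.

# Applicability domain

Word embeddings place similar proteins near each other, so the Euclidean
distance between a new protein's embedding and its nearest training protein
predicts how reliable the model's output is. The package supports three
protein-protein similarity measures - Euclidean distance, cosine
similarity, and global-alignment sequence identity (match +1, mismatch 0,
gap -1; identity = identical positions / alignment length) - and validates
them against the similarity-ensemble principle: proteins sharing active
compounds should score as similar. `similarity_vs_shared_report()` bins all
protein pairs by a metric and summarizes shared-active-compound counts per
bin; `binned_performance()` reports accuracy and AUROC per distance bin
(half-open bins, last bin closed). The critical value 0.4 - inclusive, so a
protein exactly at the threshold is inside the domain - marks the default
boundary between reliable and unreliable predictions; bin edges are
configuration, not constants, since useful boundaries depend on the
embedding geometry of the dataset at hand. For synthetic data the analysis
scales the threshold by the training set's embedding scale (the median
pairwise distance among training embeddings) because the absolute scale of
CBOW coordinates varies with corpus size and training length.

# The synthetic benchmark

Real bioactivity corpora cannot ship with a package, so the generator
plants a recoverable latent interaction signal in data with the same
artifact structure the pipeline exists to handle. Every compound carries a
latent vector `u` (standard normal, 4 dimensions by default) expressed in
its fingerprint: half the bits load on one latent dimension each with
logistic weight +/-2 around a base on-rate of 8%, so PCA on the bit matrix
recovers the latent coordinates. Every protein carries a latent `v`
expressed in its sequence: a fixed vocabulary ties six 3-mer words to each
(dimension, polarity) pair, word sampling weight is `exp(sign * v_dim)`
against a 60-word background, and sequence lengths are uniform in 240-600
residues - so 3-mer frequencies, and therefore averaged word embeddings,
encode `v`. A pair interacts with probability `logistic(u . v / 0.3)`;
interacting pairs draw potencies log-normally around 1 uM and
non-interacting around 100 uM (sd 1 log unit), which separates cleanly at
the 10 uM rule while keeping realistic overlap tails.

The artifact dials, all rates in [0, 1]:

- `near_duplicate_rate` (default 0.05): fraction of compounds given a
  structural twin (5% of on-bits swapped, guaranteeing Tanimoto > 0.8) to
  exercise deduplication.
- `multi_source_rate` (default 0.2): fraction of observed pairs duplicated
  in a second source with jittered values; 15% of records are binary
  annotations, exercising the any-active and minimum-value rules.
- `label_noise_rate` (default 0.02): per-record probability that the
  sampled potency contradicts the ground truth, planting conflicts.
- `observed_fraction` (default 0.3): fraction of pairs with any record at
  all, reflecting the sparsity of real assay coverage.

Defaults were chosen once to resemble a mid-size kinase-panel-like corpus
and to keep the planted signal recoverable by the pipeline's own feature
models; the default benchmark is 2000 compounds by 50 proteins.

External proteins for the applicability analysis come in two families
sharing the benchmark's latent model: *near* proteins perturb training
latents (sd 0.05) with the training corpus's sequence statistics; *far*
proteins draw fresh latents but encode them weakly (signal strength 0.15)
and over-represent a random dozen background words eight-fold - a protein
family whose sequence statistics the training corpus has never seen. Their
embeddings land far from the training cloud and carry little usable signal,
which is what produces the characteristic accuracy drop beyond the critical
distance. An earlier design that inflated far-family latents instead was
discarded: extreme latents make labels *more* deterministic and the far
group paradoxically easier.

What the generator does **not** emulate: real chemical space (bit patterns
are not valid molecules unless the SMILES mode of the fingerprint path is
used), real protein families or phylogenetic correlation, assay-type
systematic biases, and activity cliffs. Passing tests on this benchmark
therefore demonstrates that the pipeline's machinery is correct and that it
recovers a planted signal under realistic artifact rates - not that the
model reaches any particular accuracy on real corpora.

# Desk-scale problem sizes and numerical choices

The package's own experiments run on one CPU in minutes: the default
benchmark (2000 x 50, about 38k records, about 31k curated pairs) trains
the 300-256-128-1 network with dropout 0.2, learning rate 1e-3, batch 512
for 30 epochs; the CBOW model uses 10 epochs over the roughly 50-protein
corpus. These sizes were chosen as the smallest at which every stage's
statistical behavior (ligand bias, capping, signal recovery, domain
degradation) is clearly expressed. The full 432-model grid search is
enumerated and unit-tested on singleton grids; running it end-to-end on the
default benchmark is possible but takes hours, which is why model selection
is exposed as a function rather than wired into the default experiment.

Numerical details worth knowing: batch-normalization epsilon is 1e-5 with
momentum 0.9 on running statistics; He-uniform weight initialization;
nearest-neighbor distances use the squared-norm expansion with negative
residues clamped at 1e-12 before the square root; Tanimoto at scale runs
through sparse pattern-matrix cross-products, with the scalar set
definition kept as the reference implementation; the minimum batch size for
a batch-normalized step is 2 (smaller trailing batches are skipped);
degenerate PCA/CCA requests beyond rank truncate with a warning rather than
erroring.

# Known limitations

- The CBOW implementation is single-threaded R; adequate for corpora of
  tens to hundreds of proteins, not for proteome-scale vocabularies.
- The curation rules assume identifiers are already harmonized across
  sources; no CID/UniProt mapping is attempted.
- The negative screen's built-in descriptors are intentionally minimal;
  with them, the screen separates planted geometry well but should not be
  expected to match screens built on rich commercial descriptor sets.
- Whether DrugBank-style catalogue positives lacking potency carry a
  representative value was left open; they carry `NA`.
- The applicability threshold of 0.4 is meaningful on the embedding scale
  of a large training corpus; for small synthetic corpora the scaled
  variant must be used, and the package makes that scaling explicit.
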