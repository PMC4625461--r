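---
title: "Set-level classification with regulatory gene sets: models and methods"
author: "regulonSets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Set-level classification with regulatory gene sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulonSets)
```

# The problem

Phenotype classification from bacterial expression data faces an extreme
samples-versus-features imbalance: a typical binary dataset has 6--10
arrays and thousands of genes. Set-level classification replaces the
gene features by aggregated features over predefined gene sets, hoping
that the dimensionality reduction curbs overfitting. That hope only
materialises if the sets collect genes whose expression is actually
correlated, so that averaging inside a set discards noise rather than
signal. Functional annotations (GO terms, metabolic pathways) group
genes by what their proteins do, not by how their transcription is
controlled, and are therefore weakly correlated at the mRNA level.

This package builds gene-set families directly from the machinery of
prokaryotic transcription:

* **OPR** -- one set per operon (genes co-transcribed as one mRNA).
* **TU** -- one set per distinct transcription unit (the genes driven by
  one promoter); TUs overlap and nest because operons can carry internal
  promoters.
* **COPR** -- maximal "chunks" of an operon with no TU start or end
  strictly inside: the genes that are co-transcribed under *every*
  promoter configuration. A cut is placed at every inter-gene boundary
  where some TU of the operon starts or ends; chunks are the runs
  between cuts, and they partition the operon. An operon without an
  annotated TU is treated as carrying one implicit whole-operon TU,
  which makes COPR well defined on incomplete annotations and reduces
  it to OPR there.
* **TF** -- for each transcription factor and each regulatory role
  (activation, repression, dual, unknown), the targets it regulates with
  that role; at most four sets per TF.
* **REG** -- equivalence classes of regulated genes sharing exactly the
  same set of regulators, roles ignored. The aggregated expression of a
  regulon is a proxy for the *activity* of its regulators -- information
  that the expression of the TF gene itself does not carry.
* **SREG** -- the refinement of REG in which every shared regulator must
  also act with the same role on all members.

All families are *maximal* (every gene satisfying a set's defining
condition belongs to the set), and each family has a size-preserving
**randomized control**: a uniformly random bijection on the union of
member genes relabels every membership, keeping the set count, the size
multiset and the entire overlap structure while destroying biological
coherence. We chose the bijection reading (rather than reshuffling the
flattened membership list) because it is the only one that keeps
overlapping families well formed -- no set can acquire a duplicate
member -- while preserving size proportions exactly.

# Evaluation protocol

`buildPool()` turns multi-phenotype series into one binary dataset per
unordered class pair. `selectTesting()` extracts a greedy-maximal
collection of pairwise class-disjoint testing datasets;
`selectSelection()` draws an auxiliary selection collection disjoint
from them. Accuracy is estimated by leave-one-out cross-validation
(`loocvAccuracy()`): for each held-out sample the classifier is trained
on the rest, with feature standardization fitted on the training fold
only. Methods are ranked across datasets by Friedman rank sums
(`friedmanRanks()`; best method gets the highest rank, ties get
mid-ranks) and compared pairwise by win/tie/loss counts with a
one-sided paired Wilcoxon signed-rank test (`compareMethods()`).

Numerical choices in the statistics:

* LOOCV accuracies are multiples of 1/n, so a *tie* is exact equality.
* Zero differences are dropped from the Wilcoxon statistic (Pratt
  handling is available via `zeros = "pratt"`).
* For up to 25 non-zero pairs the exact null distribution is computed
  by subset-sum convolution over the (possibly tied, mid-) ranks --
  `stats::wilcox.test` refuses exact p-values under ties, which the
  accuracy grid makes routine. Beyond that a normal approximation with
  tie correction and continuity correction is used. No multiple-testing
  correction is applied; raw p-values are reported.
* A comparison in which every dataset is tied is flagged `"same"` with
  p = 1.

## The classifier

No particular SVM configuration is canonical for this protocol, so the
choice is a package design decision, fully exposed through
`svmConfig()`. The
default is a soft-margin **linear** SVM (e1071), cost 1, features
standardized on the training fold. We initially used an RBF kernel with
gamma = 1/#features, but with ~2000 standardized features and 7
training samples pairwise distances concentrate, the kernel matrix
becomes near-diagonal, and the SVM degenerates into majority voting --
every representation then scores 0 under leave-one-out (the held-out
sample's class is always the training minority). The linear kernel is
the standard choice for n << p expression data and behaves sensibly
across the whole effect-size range. A degenerate single-class training
fold predicts its majority class. Note the flip side of the same
phenomenon: on signal-free data LOOCV accuracy is systematically
*below* 1/2 (majority-vote pessimism), not at it.

## Aggregation

The protocol aggregates by the arithmetic mean over the measured
members of each set (sets are intersected with the measured genes;
empty sets are dropped with a warning). `median` and `pc1` variants are
provided. For `pc1` the samples are projected on the first principal
component of the gene-centered within-set submatrix; the sign is fixed
so the loading sum is non-negative, and the set's grand mean is added
back so that a singleton set reproduces its gene's expression row
exactly. The per-fold-versus-global question for PCA aggregation is
left to the caller's fold discipline. The set-signature aggregation
method of the wider literature is deliberately not implemented; the
enum slot is reserved. The gene-level baseline uses the union of the
family's sets (for COPR this is every annotated gene), so both
approaches see the same information. `clustFamily()` provides the
data-driven clustering baseline: average-linkage hierarchical
clustering with distance 1 - Pearson correlation (the most common
expression-clustering default; zero-variance genes are treated as
uncorrelated), cut to exactly k clusters on training samples only.

## Correlation study

`sampleWithinFamily()` iterates: draw a set with probability
proportional to C(size, 2) (measured members only, singletons omitted),
then a uniform pair of distinct genes inside it, then their Pearson
correlation across all samples (Spearman behind a flag). Pairs with a
zero-variance gene have no defined correlation; they are rejected and
redrawn, and the rejection count is attached to the result.
`sampleRandomPairs()` is the unconstrained baseline and
`correlationSummary()` bins the coefficients over [-1, 1].

# The synthetic generator

`simulateAnnotation()`/`simulateExpression()` produce the study
conditions every test runs under. The genome: operons with sizes from a
truncated geometric law on [1, 16] with mean 1.7 -- matching the E. coli
operon map, where some 60% of operons are single-gene, the mean operon
has 1.7 genes, and always-co-transcribed chunks average 1.4 genes -- and
an internal promoter at each inter-gene boundary with probability 0.25
(reproducing the observed ratio of chunks to operons). Internal
promoters spawn *suffix* TUs (starting at the boundary, running to the
operon end), the dominant prokaryotic arrangement; arbitrary sub-TUs
appear in the test fixtures instead.

The network: 40 TFs (themselves genes), each targeting 3--26
transcription units, so that all genes of a targeted TU inherit the
interaction. We target TUs rather than individual genes deliberately:
promoter-bound TFs act on whole transcription units, and only under
this mechanism do regulons of more than one gene arise with realistic
frequency (independent per-gene draws make regulator keys almost surely
unique, leaving REG a family of singletons; that literal mode remains
available via `targetUnits = "gene"`). Each TF has one characteristic
role drawn from (activation .45, repression .40, dual .05, unknown
.10), with a per-target deviation probability of 0.13 -- calibrated so
that the ratio of strict regulons to regulons matches the real
network's 1.18, i.e. role conflicts split regulons about as rarely as
they do in RegulonDB. About 37% of genes end up regulated, as in the
real annotation.

The expression model: per sample, each TF has a latent activity ~
N(0, 1); in the second phenotype class the activities of 5 affected TFs
are shifted by `classEffectSize` (default 4) standard deviations. A
gene's expression sums its regulators' activities signed by role (dual
resolves to a per-(TF, gene) sign drawn once), a chunk-shared noise
term (sd `sigmaChunk` = 1) and an independent per-gene term (sd
`sigmaGene` = 0.7). The noise split gives unregulated chunk mates a
correlation of about 0.67, in line with reported within-operon
correlations; the effect size was calibrated -- before any comparative
ordering was examined -- so that gene-level LOOCV accuracy lands in the
0.75--0.85 band where the real protocol operates. Samples default to
4+4, the small-n regime in which overfitting pressure is visible. All
randomness flows from one seed; a config object fully determines the
output, and the generator returns the ground-truth chunk partition,
regulator keys and affected-TF list for oracle tests.

`runComparisonStudy()` packages the end-to-end experiment: per
replicate it simulates a study, builds COPR and REG, and scores five
representations (COPR, REG, gene-level union, and the two randomized
controls) by LOOCV, alongside mean within-set correlations for COPR,
REG and random pairs. The test suite runs 50 replicates at the default
configuration (about two minutes); unit and property tests use scaled
genomes of 25--150 operons, 200 small random annotations for the
brute-force oracle comparisons, 1000 seeds for the randomization
audit, and 5000 draws for the sampling-weight and null-correlation
checks.

# What the generator shows -- and what it cannot

On generator output the qualitative correlation finding reproduces
robustly: mean pairwise correlation orders COPR > REG > random pairs in
every replicate, mirroring the skew ordering reported on real data. On
the classification side, REG set-level features beat both the
gene-level union and their randomized control, and by a wide margin --
regulon averages are direct estimates of the latent TF activities that
carry all class information in this model.

The COPR comparison exposes a real limitation of the noise model, which
we document rather than hide. Under exchangeable Gaussian noise, a
bijective relabelling of genes redistributes but cannot destroy total
linear separability (the summed squared standardized mean differences
of true and randomized COPR features are numerically identical), while
averaging *independent* genes reduces noise variance by 1/size and
averaging a true chunk cannot remove its chunk-shared noise term. With
shared noise at least as strong as per-gene noise, randomized COPR
controls therefore match or slightly exceed true COPR accuracy, and
COPR sits in a statistical tie with the gene-level baseline. The
advantage of genuine co-transcription sets observed on real microarray
collections must ride on properties this generator deliberately omits:
gene-specific heavy-tailed measurement noise, platform and batch
effects, and non-Gaussian response heterogeneity. Passing tests on
generator output therefore demonstrate correctness of the machinery and
the correlation structure, not a universal accuracy advantage of
chunk-level aggregation.

Other known limitations: no probe-level artifacts or normalization
pipeline is modelled (the loaders assume expression matrices are
already normalized and platform-homogeneous); operon gene order is
taken as transcription order with strand resolved upstream; gene
identifiers are opaque case-sensitive strings with no name/locus-tag
mapping; GO/KEGG-style baselines are consumed as GMT files only.

# Degenerate inputs and tie-breaks

* Duplicate (TF, target) interaction rows merge order-independently:
  identical roles deduplicate, activation plus repression gives dual,
  dual absorbs any known role, unknown yields to any known role. How
  the original curated network resolved per-evidence conflicts is not
  documented anywhere; this merge rule is our choice.
* Two transcription units with identical member sets collapse to one TU
  set (the feature unit is the set, not the promoter); the
  lexicographically smallest TU id survives, so GMT output is
  reproducible.
* REG/SREG exclude unregulated genes instead of pooling them into a
  "no regulator" class; the real families cover 1685 of 4524 genes,
  which implies exclusion.
* Singleton sets are kept in families and dropped only where an
  analysis requires pairs (correlation sampling).
* Set names are deterministic: operon id, operon id + chunk index,
  TF id + role code, sorted regulator key.
* `familyStats()` on an empty family reports zero counts and NA size
  statistics rather than failing.

# Reproducing the numbers

`scripts/acceptance.R --seed <int> --out <path>` recomputes the worked
regulon example and the full 50-replicate comparison study from scratch
against the installed package and writes every quantity as JSON;
`tests/testthat/test-acceptance.R` asserts the same properties inside
the test suite.
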