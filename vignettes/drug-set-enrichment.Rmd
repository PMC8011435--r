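---
title: "Drug set enrichment, consensus meta-analysis and attribute prediction with drugsets"
author: "drugsets authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug set enrichment, consensus meta-analysis and attribute prediction with drugsets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugsets)
```

# The statistical model

## Overlap testing

A drug set library is a collection of term → drug-set associations over a
member universe. Given an input drug list $I$ and a library set $S$ inside
a universe $U$, the package forms the 2×2 table

|              | in $S$ | not in $S$ |
|--------------|--------|------------|
| in $I$       | $a$    | $b$        |
| not in $I$   | $c$    | $d$        |

and reports the one-sided Fisher's exact p-value
$P(X \ge a)$ with $X \sim \mathrm{Hypergeom}(N{=}a{+}b{+}c{+}d,\;
K{=}a{+}c,\; n{=}a{+}b)$: the probability of observing at least the
attained overlap between two independent sets. The one-sided (enrichment)
alternative is the default because that is the convention of set-
enrichment tools generally — an input depleted of a set's members is not
an interesting "hit"; a two-sided option exists (`alternative =
"two.sided"`, delegated to `stats::fisher.test`). The implementation
evaluates the tail with `stats::phyper`; the test suite verifies it
exhaustively against brute-force $\sum_k \binom{K}{k}\binom{N-K}{n-k} /
\binom{N}{n}$ sums for every valid table with $N \le 30$ (agreement to
$10^{-12}$), so the fast path and the definition cannot drift apart.

Assumptions worth keeping in mind: the test treats the universe as the
sampling frame, so the choice of universe *is* the null hypothesis. The
default universe is the union of the library's own members — a
self-contained choice that makes any analysis reproducible from the
library file alone. When the input was resolved against a master metadata
table, passing that table's entity list as an explicit universe is the
more conservative background; input members outside the universe are
dropped (and counted in the report) rather than silently inflating $b$.

## Multiple testing

P-values are adjusted per library query with Benjamini–Hochberg:
$q_{(i)} = \min_{j \ge i} \min(1, p_{(j)} m / j)$. The step-up
minimisation makes $q$ monotone in $p$ and $q \ge p$ always; with one
test, $q = p$. The significance convention for *library construction*
(see below) is $q \le 0.01$: where a threshold is described ambiguously
as a "q-value at P < 0.01", this package thresholds the BH-adjusted
value, the stricter and more defensible reading; the cutoff is a
parameter (`qThreshold`), so the other reading costs one argument.

## Ranking and determinism

Report rows sort by ascending p, ties broken by larger overlap, then term
lexicographically; permuting the library's set order changes nothing.
Odds ratios use the Haldane–Anscombe +0.5 correction on every cell when
any cell is zero, keeping them finite. Before any $-\log_{10}$ transform
(consensus scoring), p-values are floored at $10^{-300}$ to stay inside
double range.

# Library construction

## Structure-derived libraries

Molecules that set the same fingerprint bit share the substructure that
bit encodes, so each bit position defines a candidate drug set. Two
dictionaries are built in:

* **MACCS keys** — the 166-position structural key dictionary, computed
  through OpenBabel's MACCS SMARTS patterns (ChemmineOB). OpenBabel
  returns a 256-bit vector indexed by key number; exactly positions
  1–166 are kept, so the exposed matrix has no dummy slot.
* **Circular (Morgan-type) fingerprints** — extended-connectivity
  environments of radius $r$ (OpenBabel's ECFP$2r$), hashed to 4096 bits
  and folded to `nBits` by OR-ing bit $j$ into $j \bmod n$. Defaults are
  radius 4 and 2048 bits, the common choice for this family. Folding by
  modular OR is the standard treatment for hashed fingerprints; it can
  only merge, never lose, set bits.

Any precomputed binary matrix (for example an 881-bit PubChem
fingerprint matrix produced elsewhere) enters the same pipeline through
`customFingerprints()` — the key semantics of external dictionaries are
deliberately not re-implemented here.

Unparseable SMILES are collected in the `failures` slot of the result
rather than aborting the batch, and the library universe is the set of
successfully fingerprinted molecules.

## The minimum-set-size rule

Every constructed library passes through `filterMinSize(k = 5)`: a
contingency-table test on a set with fewer than five members is
essentially uninformative, so such sets are dropped *after* candidate
construction, leaving the universe untouched. The rule is idempotent and
monotone in `k`, which the tests assert.

## Signature-derived libraries

Given per-drug up/downregulated gene sets and a term → gene-set
collection (e.g. GO biological processes), each drug's chosen-direction
genes are enriched against every term over a gene universe; BH correction
is applied **per drug query** — the natural unit, since each drug's query
is an independent multiple-testing family — and pairs with
$q \le$ `qThreshold` (default 0.01) are inverted into term → drug sets.
Up and down directions are separate calls producing separate libraries.
Gene symbols are uppercased on both sides before matching; a drug whose
direction set is empty is skipped with a warning, and genes appearing in
both directions for one drug are contradictory and removed from both at
construction (with a warning).

# Consensus meta-analysis

Screens probing the same biology often return hit lists with very low
pairwise overlap. Pooling their *enrichment results* rather than their
hits recovers the shared signal: for each term, the consensus score is
$\sum_s -\log_{10} p_{t,s}$ over screens $s$, with raw p (not q) feeding
the sum — adjusted values would re-penalise each screen by its own
library size — and a missing term contributing 0, equivalent to $p = 1$
(absence of evidence adds nothing). The log base is fixed at 10. Ties in
the cumulative score break by the number of screens with $p < 0.05$,
then term. Whether to sum over all terms or only per-screen-significant
terms is genuinely open; the all-terms sum is the default because it
needs no extra threshold, and a `significanceMask` argument provides the
masked variant. `overlapMatrix()` reports set sizes, pairwise
intersections, Jaccard similarities and exclusive intersection regions
(the quantities an UpSet plot draws) so the "low overlap" premise can be
checked on real inputs.

# The prediction pipeline

`assembleFeatures()` inner-joins named feature blocks on complete
InChIKeys — an exact-key join, because name-level matching across
feature sources is precisely the ambiguity the entity model exists to
avoid — and records the keys each block lost. A drug set library can be
supplied as a block via its binary drug × term incidence matrix.

Binary fingerprint blocks may be TF-IDF weighted: with $N$ rows and
column document frequency $df_j$,
$\mathrm{idf}_j = \ln\!\big((1+N)/(1+df_j)\big) + 1$, entries are
$b_{ij}\,\mathrm{idf}_j$, and each row is scaled to unit Euclidean norm
(all-zero rows stay zero). The smoothed-idf + row-L2 variant is frozen
and documented because "TF-IDF" alone underdetermines the transform; a
ubiquitous bit receives the floor weight 1 before row scaling, which is
the entire point — common scaffolds should not dominate distances.

Class imbalance is handled by inverse-frequency weights
$w_c = N/(2 n_c)$, the "balanced" convention (positive:negative weight
ratio equals the negative:positive count ratio). Four algorithms are
supported behind one interface: ridge-penalised logistic regression
(glmnet), a linear SVM (e1071), and random forest / extra trees
(ranger; extra trees uses `splitrule = "extratrees"` with one random
split per candidate feature, drawn without bootstrap). Hyperparameter
keys are validated per algorithm; the default extra-trees grid includes
the configuration `n_estimators = 1250, max_features = "log2",
criterion = "entropy"`. One caveat is documented rather than hidden:
ranger implements Gini impurity (and random splits), not an entropy
criterion, so `criterion` is validated and recorded in results and
manifests but does not change the split-quality measure; in practice the
two criteria rarely reorder tree-ensemble predictions.

Model selection in `gridSearch()` uses mean AUPRC as the primary
criterion — under heavy imbalance AUPRC separates classifiers that AUROC
cannot — with AUROC and then specification order as deterministic
tie-breaks. Training time is excluded from the contract as
hardware-dependent. Grid-search folds are a separate seeded split from
the final evaluation folds (recorded in the run manifest), avoiding the
subtle optimism of reusing selection folds for reporting.

`crossValPredict()` runs `nRepeats` (default 3) independent stratified
`nFolds`-fold (default 10) splits; every drug is predicted exactly once
out-of-fold per repeat, and the reported probability is the mean over
repeats — the quantity by which compounds are ranked, including
unlabeled compounds that the model scores highly ("known = FALSE" rows
at the top of the table are the nominations). Stratification requires at
least `nFolds` members of each class and fails loudly otherwise. Two
numerical conventions: linear-SVM "probabilities" are a logistic
transform of the decision values (monotone in the margin, hence
identical rankings and AUROC/AUPRC, and deterministic — Platt scaling's
internal randomness would break seeded reproducibility); AUROC is the
midrank U-statistic, so degenerate constant scores give exactly 0.5, and
AUPRC is average precision over the deterministic ranking.

# What the synthetic generators emulate — and what they do not

Every generator is a pure function of its seed (bitwise-identical
reruns), and each plants known ground truth:

* `synthLibrary()` — uniform random sets (default: 100 terms, sizes
  5–50, universe 500), the null background for enrichment.
* `synthEnrichedInput()` — an input with
  $\lceil f \cdot n \rceil$ members from a chosen term's set, the rest
  uniform from outside that set, so the planted overlap is exact.
* `synthScreens()` — 12 screens of 30 hits sharing planted mechanism
  terms. The default planted fraction is 0.5: with two planted terms of
  size 30–50, expected pairwise Jaccard between hit lists is ≈ 0.06,
  reproducing the "low hit overlap, shared mechanism" structure of
  multi-screen campaigns; a construction check resamples any screen
  whose Jaccard to an earlier one reaches 0.2 and errors if a 100-draw
  budget is exhausted.
* `synthMlDataset()` — an expression block (Normal noise with a mean
  shift on informative columns for positives) plus a binary fingerprint
  block (Bernoulli with elevated informative-bit rates for positives) at
  prevalence 0.011, matching the ~1% positive rate of a realistic
  side-effect label. The desk-scale default shape is 2000 compounds ×
  (200 expression + 256 fingerprint) columns — chosen so the full suite
  of property checks (including 100-seed recovery loops and four
  cross-validated classifiers) runs in a few minutes on one CPU; the
  full-scale 978/2048 shape is reachable through the same arguments.
* `synthSignatures()` — planted (drug, term) pairs receive 80% of the
  term's genes plus noise; null drugs are uniform draws.

These generators reproduce *shapes and effect structures*, not biology:
expression columns are independent Gaussians (no L1000-like gene–gene
covariance), fingerprint bits are independent Bernoullis (no chemical
scaffold correlation), and planted signals are homogeneous across
positives. Consequently, passing tests demonstrate that the machinery is
correct and calibrated under its stated model — not that any particular
real screen or side-effect label will be predicted well. On real data,
correlated features make ranking easier in some directions and harder in
others, and calibration of the null depends on how the universe was
chosen.

# Numerical and interface choices

* DMT/GMT dialect: UTF-8, tab-delimited `term, description,
  members...`; duplicate members within a line are deduplicated with a
  warning, duplicate terms across lines are an error, and a
  `noDescription` read mode tolerates 2-field lines. Write-then-read is
  the identity on (term, description, member set), property-tested on
  randomized 1000-set libraries.
* Metadata TSV dialect: required `name` column; `inchikey`, `smiles`,
  `synonyms` (`|`-delimited) recognized; all other columns are
  cross-reference namespaces; empty string means absent. Rows sharing a
  complete InChIKey collapse into one record (one entity per full key is
  law — stereoisomers differing only in the stereo block are never
  merged, and name collisions across them resolve as explicit
  ambiguities unless `firstMatch` requests the deterministic
  lexicographic pick).
* Token-kind detection precedence: InChIKey regex, DrugBank `DB#####`,
  Broad `BRD-` prefix, parseable SMILES, then name. SMILES matching
  canonicalizes both sides through OpenBabel; raw-string equality across
  SMILES dialects is meaningless.
* Seeds: all stochastic paths go through `withr::with_seed` or an
  explicit ranger seed; a run manifest (subcommand, parameters, seed,
  input digests, package version, timestamp) accompanies every CLI run.

# Known limitations

* OpenBabel's MACCS SMARTS definitions differ in a handful of keys from
  other toolkits' implementations; bit-level agreement across toolkits
  is not guaranteed (and is not required by anything downstream — sets
  are defined relative to one dictionary applied uniformly).
* The circular fingerprint is OpenBabel's ECFP family folded from 4096
  bits; radius is capped at 5 (ECFP10) by the available types.
* The two-sided test path calls `fisher.test` per set and is
  correspondingly slower; the one-sided path is fully vectorized.
* Extra trees' `criterion = "entropy"` is recorded, not enacted (see
  above).
* No connectors to live databases are included; all inputs are files in
  the documented formats.
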