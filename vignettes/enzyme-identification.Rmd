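---
title: "Sequence-based human enzyme identification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-based human enzyme identification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(enzid)
library(dplyr)
```

# The problem

Enzymes are proteins that catalyze specific biochemical reactions. Telling
enzymes from non-enzymes directly from the primary amino-acid sequence is a
binary classification task: given a protein over the 20-letter standard
alphabet, predict whether it is an enzyme. enzid implements a
frequency-based pipeline for this task — descriptor encoding, univariate
feature selection, and an RBF-kernel support vector machine — together
with the evaluation machinery (cross-validation, confusion-matrix metrics,
ROC/AUC) and a seeded synthetic-data generator so that every stage can be
exercised and verified without external downloads.

# Feature encodings

**AAC** (amino acid composition) maps a sequence of length $L$ to the
20-vector $f_i = N(i)/L$, where $N(i)$ counts residue $i$. Components sum
to 1. Residues are indexed alphabetically by one-letter code
(A, C, D, ..., Y); this fixes the otherwise implicit index-to-residue
mapping.

**CKSAAP** (composition of $k$-spaced amino acid pairs) counts ordered
residue pairs with exactly $k$ residues strictly between them: a pair
spans positions $(p, p+k+1)$, so a sequence of length $L$ contains
$L-k-1$ such pairs. The 400 components are
$f_{i,j} = N(i,j)/(L-k)$ under the package's default **paper convention**
— the formula as conventionally printed for this descriptor. Note the
subtlety: because there are only $L-k-1$ pairs, components under this
convention sum to $(L-k-1)/(L-k)$, slightly below 1. The
**pair-count convention** ($N(i,j)/(L-k-1)$), available via
`convention = "pair-count"`, is self-normalizing. Both are first-class;
the default favors fidelity to the printed formula, and which convention
a given upstream toolkit used in practice cannot generally be determined
from published numbers alone, so neither is asserted as canonical.
Dipeptide composition (DPC) is exactly the $k=0$ case.

Pairs are ordered row-major over the alphabet (AA, AC, ..., AY, CA, ...,
YY), and a gap-$k$ descriptor is displayed with $k$ stars, e.g. `A***L`.
Sequences shorter than $k+2$ residues contain no $k$-spaced pair; they
are accepted at load time but fail at encode time with a named error,
since no defensible frequency exists for them.

```{r encoding-example}
d <- tibble::tibble(id = "toy", residues = "ACACA")
encode_cksaap(d, k = 1) |> select(`A*A`, `C*C`)
```

# Input validation

Sequences are restricted to the 20 standard residues. Ambiguous codes
(B, J, O, U, X, Z), stop characters (`*`) and embedded whitespace are
reported as offenses with 1-based positions rather than silently
stripped; lowercase input is uppercased before validation since FASTA
dialects vary in case. `load_labeled_dataset()` either drops invalid
records (logging the count) or fails, per `on_invalid`. Duplicate FASTA
ids are allowed but logged — rows are keyed by position throughout.

# Feature selection

Each feature is scored by the two-group ANOVA F statistic
$F = s^2_{\mathrm{MSB}} / s^2_{\mathrm{MSW}}$, the ratio of
between-group to within-group mean squares. For two groups this equals
the square of the pooled-variance two-sample $t$ statistic, which the
test suite uses as an independent oracle. Degenerate columns get
sentinels: zero within-group variance with a real between-group
difference gives $F = \infty$ (a perfect separator, ranked first), and a
constant column gives $F = 0$ (ranked last). Ties are broken by
descriptor name so rankings are fully deterministic.

Incremental forward selection then proceeds in three steps: rank all 400
CKSAAP($k$) pairs by $F$; for each $m = 1 \ldots m_{\max}$ form the
subset "full AAC block + top-$m$ pairs"; score each subset by $k$-fold
cross-validated SVM accuracy and keep the best $m$ (ties favor the
smaller subset). The AAC block is always fully included — the procedure
adds pairs *into* the AAC base rather than selecting over the union,
which is how the accuracy-vs-$m$ curve is defined here.

Two protocol details are deliberately exposed as options:

* **Ranking scope.** By default the ranking is computed once on the full
  training matrix, mirroring the published protocol. This leaks
  selection information into the cross-validation folds, so a
  `fold_safe = TRUE` mode re-ranks within each training fold; its curve
  is an honest estimate of generalization but does not correspond to the
  published procedure. The default is the faithful one, documented as
  such.
* **Tuning scope.** Whether the published accuracy-vs-$m$ curve re-tuned
  $(c, \gamma)$ per subset size is not stated; both modes exist
  (`tune_per_m`, default `TRUE` = re-tune, the conservative reading).

# Classifier and tuning

The classifier is an RBF-kernel SVM (libsvm via e1071). Feature values
are raw frequencies in $[0,1]$ and are not rescaled by default (a
standardization flag exists). Hyperparameters are tuned by grid search
over $c = 2^a$, $\gamma = 2^b$ with pooled $k$-fold cross-validated
accuracy as the objective and ties resolved toward smaller $a$, then
smaller $b$. The fine grid steps both exponents by 0.2 — the granularity
implied by published winning exponents such as $a = 0.2$
($c = 2^{0.2} = 1.1487$) and $b = 7.2$ ($\gamma = 2^{7.2} = 147.0334$) —
over $a \in [-5, 15]$, $b \in [-15, 8]$, chosen so the published optimum
is interior; the search ranges themselves are an implementation choice,
as no published ranges exist. The coarse grid (step 2) covers the same
rectangle for quick searches. Cross-validation folds are stratified by
class by default (class imbalance in the real task is roughly 1:2);
plain random folds are available. "Jackknife" validation is the
$k$-fold family; leave-one-out is the `n_folds = n` limiting case. All
fold assignments derive from an explicit seed, and identical seeds give
bit-identical partitions, grids and argmax choices. Class-imbalance
weighting is not applied by default.

# Evaluation

From the pooled confusion matrix (TP/TN/FP/FN, positive = enzyme):

$$\mathrm{ACC} = \frac{TP+TN}{TP+TN+FP+FN} \times 100\%$$

The two class-conditional rates follow the naming used in the
human-enzyme identification literature this package follows, where
**SP** $= TP/(TP+FN)$ is the rate on positives and **SE** $= TN/(TN+FP)$
the rate on negatives — the reverse of common usage. enzid emits both
names: `sp_paper`/`se_paper` as defined above, and the standard aliases
`sensitivity` ($=$ `sp_paper`) and `specificity` ($=$ `se_paper`), so
published tables can be reproduced without silently misreading either
convention. Whether any given published table used the printed or the
standard definitions is generally unresolvable; emitting both sidesteps
the ambiguity. A rate whose denominator is zero is reported as `NA` with
a warning, never coerced to 0 or 1.

ROC curves sweep the decision threshold over the unique out-of-fold
scores in descending order; tied scores enter as one threshold,
advancing the curve diagonally in a single step (the standard
treatment). AUC is the trapezoidal area, equal to the probability that a
random positive outscores a random negative with ties counted one half —
the rank-statistic identity the tests verify.

# The synthetic-data generator

`simulate_enzyme_dataset()` emulates the *shape* of a curated
enzyme/non-enzyme collection: two classes of variable-length sequences
(default 100–400 residues, roughly the span of real protein lengths)
with residues drawn i.i.d. from a background distribution (default
uniform 0.05). Class signal is planted only in positives: for each
enriched pair $(i, j, k)$ and each eligible start position, with the
configured rate the pair overwrites positions $p$ and $p+k+1$.
Overwriting rather than inserting keeps lengths fixed and the marginal
residue composition nearly intact, so the planted signal is specifically
the $k$-spaced pair signal the selection stage must find. The defaults —
100 positives, 100 negatives, pairs (A,A) and (L,L) at gap 3 with rate
0.15 — plant the two homopairs that carry large between-class variance
in the real task, at a rate strong enough that the full pipeline should
separate the classes almost perfectly. One random stream per dataset,
fully determined by the seed, which is recorded in the output manifest.

What the generator does **not** emulate: homology and redundancy
structure (real datasets are filtered at 30% identity upstream, by
external tools that are out of scope here), realistic residue
composition, domain architecture, or correlated motifs. Passing tests on
synthetic data therefore demonstrate that the machinery is correct and
can recover planted pair signal — not that any particular accuracy will
be attained on real UniProt-derived data, where reported accuracies for
this method are in the mid-70% range rather than near 100%.

# Numerical and design choices

* Frequencies are computed in double precision; file output rounds to a
  configurable 6 decimals (10 in tests that check round-trips).
* The ANOVA F uses the exact MSB/MSW decomposition rather than a
  regression fit, so the $\infty$ and $0$ sentinels are explicit.
* Fold assignment shuffles indices through a private RNG stream that
  never disturbs the session's `.Random.seed`.
* The decision-score sign is normalized so positive scores always mean
  "enzyme", regardless of class order seen by libsvm.
* Problem sizes used by the test suite and the acceptance script — 1000
  random sequences for encoder oracle checks, 20 replicates for
  recovery, the 200-sequence default dataset with `max_m = 10` and the
  coarse grid for the end-to-end run — were chosen as the smallest sizes
  at which the checked properties are statistically unambiguous.

# Known limitations

* Redundancy reduction (CD-HIT-style clustering) and UniProt
  evidence-level filtering are upstream concerns, not reimplemented.
* Only the RBF kernel is tuned; alternative descriptor families (CTD,
  CTriad, DDE, TPC, PseAAC, Geary autocorrelation) and alternative
  selectors (mRMR, PCA) are out of scope.
* No probability calibration; decision scores are margins, not
  probabilities.
* The default selection protocol reproduces a known information leak
  (full-matrix ranking); use `fold_safe = TRUE` when an unbiased
  generalization estimate matters more than protocol fidelity.

```{r session}
sessionInfo()
```
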