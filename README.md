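# enzid

Sequence-based identification of human enzymes. Given protein sequences
over the 20-letter standard amino-acid alphabet, enzid encodes them as
residue-frequency descriptors, selects the most class-discriminative
features, and classifies enzyme vs non-enzyme with an RBF-kernel support
vector machine. It is aimed at computational biologists who want a
reproducible, fully scriptable implementation of this pipeline — plus
the evaluation machinery and a seeded synthetic-data generator so every
stage can be tested without external downloads.

## The method

**Encodings.** AAC (amino acid composition) is the 20-vector
*f*<sub>i</sub> = *N*(i)/*L* of residue frequencies. CKSAAP (composition
of *k*-spaced amino acid pairs) counts ordered residue pairs separated
by exactly *k* intervening residues — a pair spans positions
(*p*, *p*+*k*+1) — giving 400 components
*f*<sub>i,j</sub> = *N*(i,j)/(*L*−*k*) per gap value (the printed-formula
convention; a self-normalizing *L*−*k*−1 denominator is available).
Dipeptide composition is the *k* = 0 case.

**Selection.** Each pair is scored by the two-group ANOVA F statistic
F = MSB/MSW (equal to the squared pooled-variance two-sample *t* for two
groups), ranked, and added one at a time to the full AAC block; each
subset is scored by *k*-fold cross-validated SVM accuracy and the best
subset size wins.

**Classifier.** RBF-kernel SVM (libsvm via e1071), tuned by grid search
over c = 2^a, γ = 2^b with 6-fold cross-validation. Metrics follow the
field's convention — ACC plus SP = TP/(TP+FN) and SE = TN/(TN+FP), which
reverse the standard sensitivity/specificity names; enzid emits both
namings. ROC curves and trapezoidal AUC come from the pooled
out-of-fold decision scores.

The reference 40-feature configuration for the human-enzyme task
(20 AAC components + 20 informative 3-spaced pairs) ships as
`informative_pairs_k3()`.

## Worked example

```r
library(enzid)

# a seeded two-class dataset with (A,A) and (L,L) pairs enriched at gap 3
d <- simulate_enzyme_dataset(n_pos = 50, n_neg = 50, seed = 42)

fit <- run_pipeline(d, k = 3, max_m = 5, n_folds = 6, seed = 42,
                    grid = list(log2c = c(-2, 2, 6), log2gamma = c(-6, -2, 2)))
fit
#> Enzyme-identification fit
#>   features: 20 AAC + 1 CKSAAP(k=3) pairs
#>   tuned: c = 0.2500, gamma = 0.0156
#>   6-fold CV: ACC = 100.00%, SP(paper) = 1.0000, SE(paper) = 1.0000, AUC = 1.0000

head(fit$selection$ranking, 2)
#> # A tibble: 2 x 5
#>   descriptor   msb      msw     F  rank
#> 1 L***L      0.750 0.000461 1626.     1
#> 2 A***A      0.353 0.000635  555.     2

predict(fit, simulate_enzyme_dataset(n_pos = 2, n_neg = 2, seed = 77))
#> # A tibble: 4 x 4
#>   id      label      score note
#> 1 enz_001 positive  0.0158 <NA>
#> 2 enz_002 positive  0.0245 <NA>
#> 3 non_001 negative -0.0324 <NA>
#> 4 non_002 negative -0.0314 <NA>
```

The selection stage found the two planted pairs at the top of the
F-score ranking (`L***L`, `A***A`); one pair over the AAC base already
separates the classes perfectly at this planted effect size, so the
curve's best subset is m = 1 and pooled cross-validated accuracy is
100%. Decision scores are signed so positive means enzyme. On real
UniProt-derived data the same pipeline reports accuracies in the
mid-70% range — the synthetic signal is deliberately strong.

`tidy()`/`glance()` give tibble views of every result object, and
`autoplot()` draws the ROC curve, selection curve and grid-search
surface.

## Command line

A thin Rscript CLI wraps the same functions (installed at
`exec/enzid`):

```sh
enzid simulate --out data/ --seed 1
enzid pipeline --fasta data/sequences.fasta --labels data/labels.tsv --out run/
enzid predict --model run/model.rds --fasta new.fasta --out preds.tsv
```

Subcommands `encode`, `rank`, `select`, `tune` and `cv` expose the
individual stages. Exit codes: 0 success, 1 usage error, 2 data error.

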