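---
title: "aquapred: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{aquapred: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquapred)
```

## The problem

Aquaporins are a conserved family of channel membrane proteins that
transport water and small solutes; their expression correlates with the
histological grade of several tumour types, which makes fast sequence-based
family assignment useful well beyond annotation pipelines. The biological
signal that separates aquaporins from other proteins is architectural:
six α-helical transmembrane segments, each a hydrophobic stretch of roughly
20 residues. `aquapred` turns that physics into a classifier: a global
sequence descriptor dominated by physicochemical group statistics, a
univariate feature-ranking step, and a cross-validated ensemble classifier.

## The descriptor

`encode_188()` maps a validated sequence of length $L$ to 188 numbers:

* **AAC (1–20).** Residue frequencies $f_a = n_a / L$ in fixed
  alphabetical one-letter order. They sum to 1.
* **CTD (21–188).** For each of 8 properties the 20 residues are split
  into 3 groups, and per property:
  * *Composition* (3): group residue fractions, summing to 1.
  * *Transition* (3): for each unordered group pair, the count of
    adjacent positions with one residue in each group, divided by $L-1$.
    Pair order is (g1,g2), (g2,g3), (g1,g3).
  * *Distribution* (15): per group, the normalized position $p_m/L$ of the
    $m$-th group residue for $m = 1$, $\lceil 0.25\,n_k\rceil$,
    $\lceil 0.5\,n_k\rceil$, $\lceil 0.75\,n_k\rceil$, $n_k$ (floored at
    1). An empty group contributes five zeros.

All 188 features live on a common $[0,1]$ scale — distribution values are
fractions, not percentages — which keeps ANOVA variances and classifier
inputs comparable without further normalisation.

The eight group tables are the widely used CTD partitions originating with
Dubchak and co-workers and propagated by SVM-Prot/PROFEAT-style descriptor
toolkits; they ship as code (`default_partitions()`) and can be overridden
from a plain-text table (`read_partitions()`). Two ordering conventions are
fixed deliberately: the hydrophobicity property comes first with its
hydrophobic group leading, and transition pairs are ordered (1,2), (2,3),
(1,3). This is the unique layout under which the hydrophobic composition
lands at global index 21 and the neutral↔hydrophobic transition at index
26 — the two features reported as the strongest aquaporin discriminators —
and the remaining blocks simply follow the same pattern. Because the
original property tables are not published alongside the method, numeric
identity with any particular historical implementation is not guaranteed;
structural identity (layout, ranges, block sums) is, and is tested.

## Input validation

Records must use the 20 canonical residues; sequences carrying B, J, O, U,
X, Z or gaps are rejected whole, with the offending characters reported,
rather than silently stripped — stripping would shift every
position-dependent distribution feature. The minimum accepted length is 2,
the shortest sequence for which transitions are defined. Exact duplicate
sequences are removed (first occurrence kept); similarity-based redundancy
reduction (CD-HIT at 90% identity) is an upstream, external step and its
absence from a dataset will inflate cross-validation estimates through
homology leakage.

## Feature selection

`anova_f()` scores each feature with the two-class ANOVA F-statistic
$F = \mathrm{MSB}/\mathrm{MSW}$, which for two classes equals the squared
pooled-variance t statistic (a property the test suite checks numerically).
Degenerate features are given deterministic scores: zero within-class
variance with a real class difference ⇒ $+\infty$ (a perfectly separating
feature belongs at the top), constant features ⇒ 0. Ties break by ascending
feature index, so the ranking is a fixed permutation.

`ifs_search()` evaluates growing rank prefixes $d$ under stratified k-fold
CV and returns the smallest $d$ attaining the maximal objective (accuracy
by default, MCC optionally). Whenever the full width is in the grid, the
recorded optimum is by construction at least the full-width score. The
default grid is every prefix size; coarser grids trade resolution for time.

`pca_project()` provides the 2-D visual check that a selected subset
separates the classes; component signs are fixed (largest-magnitude
loading positive) so plots reproduce exactly.

## Classifiers and evaluation

Six families sit behind one `train()`/`predict()` interface:
random forest (500 trees, default), naive Bayes, RBF-kernel SVM with
probability outputs, gradient boosting (xgboost, 100 rounds, single
thread), logistic regression and a decision tree. Hyperparameters are
deliberately the backends' standard defaults, overridable per spec; the
positive-call threshold is 0.5 on the positive-class score. Seeds are part
of the classifier spec, so every reported number is a deterministic
function of (data, spec, CV seed). Trained models embed their feature-name
contract and refuse matrices whose columns differ in name or order —
a silent column permutation is the classic way to corrupt a deployed
sequence classifier.

Metrics follow the standard confusion-matrix formulas, with Sn/Sp/Acc in
percent and MCC on $[-1,1]$; a zero MCC denominator yields 0. AUROC is the
Mann–Whitney statistic (ties counted ½), identical to the trapezoidal area
under `roc_curve()`. `stratified_kfold()` reports per-fold metrics, their
unweighted mean (the default summary; fold sizes differ by at most one
sample so weighting is second-order), and metrics pooled over concatenated
out-of-fold predictions. The pooled AUROC is the right null-hypothesis
instrument: per-fold AUROC on ~15 + 15 held-out samples has a standard
error near 0.1, far too wide to verify that an uninformative pipeline sits
at 0.5, while the pooled ranking over all 300 out-of-fold scores does so
stably.

Class-imbalance experiments (`assemble()`, ratios 1:1 … 1:r … all) keep
every positive and subsample negatives uniformly without replacement; no
reweighting is applied by default, so the degradation of Sn and MCC with
growing imbalance is visible rather than masked.

## The synthetic benchmark

`gen_benchmark()` emulates the curated positive/negative sets the method
was designed for. Positives alternate polar loops (mean 25 residues) with
6 hydrophobic-enriched segments (mean 20 residues); segment and loop
lengths are Poisson-perturbed to avoid identical-length artifacts, giving
totals around 295 residues. Inside segments the background residue
probabilities of the hydrophobic group (C, L, V, I, M, F, W) are multiplied
by the enrichment factor (default 6) and renormalised. Negatives are i.i.d.
background sequences.

Two generator choices matter for interpretation:

* **The signal is routed through hydrophobicity on purpose.** The only
  difference between the classes is hydrophobic-group frequency inside
  segments, so recovering a hydrophobicity-block feature at rank 1 is a
  meaningful end-to-end check of encoder + ranking, not a tautology.
* **Negative lengths follow the positive architecture law by default.**
  Distribution features are normalized positions and are therefore
  length-distribution-sensitive; if negatives were drawn with a different
  length law (say uniform 150–500), a classifier could reach high AUROC on
  length alone even with enrichment 1, defeating the null check. Matching
  the length law makes enrichment 1 a true exchangeable null
  (pipeline AUROC ≈ 0.5) and isolates the compositional signal. A uniform
  length range remains available (`neg_len_range`) for experiments where a
  length confound is wanted.

What passing the synthetic tests does **not** show: real aquaporins carry
conserved motifs, homology structure and non-uniform background
composition that the generator deliberately omits. Synthetic accuracy
(~99–100% at default settings) says the pipeline is correct and sensitive
to the intended physics, not that any particular accuracy will be achieved
on curated UniProt/Pfam data — published results on such data were
obtained on a dataset that is not deposited and are not re-derivable here.

## Numerical and scale choices

Problem sizes used by the tests and the acceptance script — 150 + 150
benchmark sequences, 10-fold CV, a 4-point IFS grid, 200-sequence oracle
sweeps — were chosen as the smallest sizes at which every property under
test is statistically unambiguous; all complete in well under a minute
each on a single CPU. Tolerances: encoder agreement with the brute-force
oracle at 1e−12 (pure counting arithmetic), F vs squared-t at 1e−10
(one subtraction of near-equal sums), null AUROC within ±0.03 at n = 2,000
(three binomial sigmas). Seeds are fixed in tests and derived from
`--seed` in the acceptance script.

## Known limitations

* No similarity clustering: CV splits are not identity-aware, so datasets
  with close homologs in both folds will look better than they generalise.
* Only the 188D descriptor family is implemented (no PSSM, k-mer or
  pseudo-AAC encodings) and only ANOVA+IFS selection (no wrapper or
  embedded selectors).
* The SVM backend's behaviour under extreme imbalance (1 : 60) is
  documented as sensitive rather than tuned; no class weighting is applied
  by default.
* Model files are R serialisations with an embedded format version; they
  are not portable across descriptor schemas.
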