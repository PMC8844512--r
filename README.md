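# aquapred

Sequence-based identification of aquaporins — the conserved water-channel
membrane proteins whose expression tracks tumour grade in several cancers —
from amino-acid sequence alone. The package is aimed at protein-function
annotators and machine-learning practitioners who need a fully reproducible
descriptor → feature-selection → classifier pipeline for a binary protein
family question, with every stage exposed as a tested R function and as a
command-line tool.

## Method

Each protein sequence is encoded into the **188-dimensional global protein
sequence descriptor**:

* features 1–20: amino-acid composition, `f_a = count(a) / L`;
* features 21–188: for each of 8 physicochemical properties
  (hydrophobicity, normalized van der Waals volume, polarity,
  polarizability, charge, surface tension, secondary structure, solvent
  accessibility), the 20 amino acids are split into 3 groups and 21 CTD
  statistics are computed — 3 **C**omposition (group frequencies), 3
  **T**ransition (cross-group adjacency frequencies over L−1 pairs) and 15
  **D**istribution values (normalized position of the first, 25%, 50%, 75%
  and last residue of each group), giving 8 × (3+3+15) = 168 features.

Feature index 21 is the hydrophobic-group composition and index 26 the
neutral↔hydrophobic transition of the hydrophobicity property — the two
features that dominate aquaporin discrimination, consistent with the
six-transmembrane-helix architecture of the family.

Features are ranked by the two-class ANOVA F-statistic
`F = MSB / MSW` and an **incremental feature selection** (IFS) sweep picks
the rank-prefix size maximizing stratified k-fold cross-validated accuracy.
Classification defaults to a 500-tree random forest; naive Bayes, RBF SVM,
gradient boosting (xgboost), logistic regression and decision tree backends
share the same interface. Performance is reported as Sn, Sp, Acc (percent),
MCC and rank-based AUROC.

A synthetic sequence generator (`gen_benchmark()`) produces
transmembrane-like positives (six hydrophobic segments of ~20 residues
separated by polar loops) and composition-matched negatives so the whole
pipeline can be exercised and validated without external data.

## Worked example

```r
library(aquapred)

bench <- gen_benchmark(synth_config())          # 150 positives + 150 negatives
fm <- encode_matrix(bench$records)              # 300 x 188 feature matrix

ranking <- anova_f(fm)
ranking
#> <feature_ranking> 188 features; top:
#>   rank                        feature         F
#> 1    1   hydrophobicity.C.hydrophobic 2719.6225
#> 2    2                 polarity.C.low 2035.4146
#> 3    3         surface_tension.C.high 1204.4110
#> 4    4 solvent_accessibility.C.buried 1093.3966
#> 5    5 hydrophobicity.T.polar_neutral  795.0045

cv <- stratified_kfold(fm, classifier_spec("random_forest"), k = 10, seed = 42)
round(cv$mean, 4)
#>       Sn       Sp      Acc      MCC    AUROC
#> 100.0000  99.3333  99.6667   0.9935   0.9991
```

The top-ranked feature is the hydrophobic-group composition (global index
21): the generator injects its class signal through hydrophobic-segment
enrichment, and the ANOVA ranking recovers exactly that property. The CV
row reads as: all positives recovered (Sn), 1 of 150 negatives
misclassified (Sp), 99.7% overall accuracy, near-perfect rank separation
(AUROC).

From the shell, the same pipeline is available as subcommands
(`system.file("cli", "aquapred", package = "aquapred")`):

```sh
aquapred synth  --n-pos 150 --n-neg 150 --seed 42 --out bench
aquapred encode --pos bench_pos.fasta --neg bench_neg.fasta --out matrix.csv
aquapred ifs    --matrix matrix.csv --d-grid 1,5,10,54,188 --out run
aquapred predict --model run_model.rds --fasta query.fasta --out pred.tsv
```

Real datasets should be redundancy-reduced upstream (e.g. CD-HIT at 90%
identity); the package performs exact-duplicate removal only.

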