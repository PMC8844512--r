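Package: aquapred
Title: Aquaporin Prediction from Protein Sequences via 188D CTD Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-based identification of aquaporin (water channel)
    proteins. Encodes protein sequences into the 188-dimensional global
    protein sequence descriptor (20 amino-acid composition features plus
    8 physicochemical properties x 21 composition/transition/distribution
    features), ranks features by the two-class ANOVA F-statistic, searches
    optimal feature subsets by incremental feature selection under
    cross-validated accuracy, and trains and evaluates six classifier
    families (random forest, naive Bayes, SVM, gradient boosting, logistic
    regression, decision tree) with sensitivity, specificity, accuracy,
    Matthews correlation and AUROC. Includes class-ratio dataset assembly,
    a synthetic transmembrane-protein sequence generator for end-to-end
    testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    randomForest,
    e1071,
    rpart,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
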