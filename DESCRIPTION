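Package: alde
Title: Active Learning-Assisted Directed Evolution on Combinatorial Protein Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch Bayesian optimization over combinatorial protein-variant
    design spaces. Provides sequence-fitness landscape handling (loading,
    normalization, synthetic generation with tunable epistasis), numeric
    variant encodings (one-hot, physicochemical descriptors, precomputed
    embedding tables), uncertainty-aware surrogate models (exact Gaussian
    processes, deep kernel learning, boosting and deep neural network
    ensembles) behind a single predictive contract, batch acquisition rules
    (greedy, upper confidence bound, Thompson sampling via random Fourier
    features or ensemble-member draws), end-to-end campaign simulators
    (active-learning loops, directed-evolution greedy walks, random and
    single-round machine-learning baselines), and uncertainty-calibration
    diagnostics (calibration curves, miscalibration area, Spearman
    correlation between uncertainty and error).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
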