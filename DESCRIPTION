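Package: lymphspread
Title: Hidden Markov Modelling of Lymphatic Metastatic Progression in
    Oropharyngeal Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models ipsilateral lymphatic spread of oropharyngeal squamous
    cell carcinoma as a hidden Markov model over binary lymph node levels
    (LNLs I, II, III, IV, V, VII).  A directed acyclic spread graph
    parameterizes per-time-step spread probabilities from the primary tumor
    and between levels; diagnoses are linked to the hidden state through the
    sensitivity and specificity of the imaging modality, and the unobserved
    time of diagnosis is marginalized over a binomial prior that depends on
    T-category.  The package provides the cohort likelihood (including
    incomplete diagnoses), affine-invariant ensemble MCMC for posterior
    inference, model evidence via thermodynamic integration over power
    posteriors for comparing spread graphs, personalized occult-metastasis
    risk prediction, and a generative cohort simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
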