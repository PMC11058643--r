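Package: molcvae
Title: Conditional Variational Autoencoder for SMILES-Based Molecular Generation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A predictor-encoder-decoder conditional variational autoencoder
    for de novo molecular design. Three gated recurrent unit (GRU) networks
    jointly learn continuous property prediction (logP, molecular weight,
    QED) and autoregressive SMILES generation, so that molecule libraries
    with user-specified property values can be sampled directly from the
    conditional distribution without a separate optimization loop. Includes
    SMILES tokenization and encoding, dataset-construction filters for
    drug-like pretraining corpora and bioactivity-filtered fine-tuning sets,
    training with Adam and early stopping, fine-tuning from a checkpoint,
    property-conditioned library generation, validity/uniqueness/novelty
    metrics, ECFP4 Tanimoto similarity screening, and a synthetic fixture
    generator for download-free testing. Chemistry (canonicalization,
    descriptors, fingerprints) is delegated to the RDKit toolkit through a
    bundled Python helper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
SystemRequirements: Python (>= 3.8) with rdkit on PATH as 'python'
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
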