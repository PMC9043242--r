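Package: gftbilstm
Title: Graph Spectral Recurrent Networks for EEG Source Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs extended cortical source activations from scalp EEG
    by combining a graph Fourier decomposition of the source space with a
    bidirectional long short-term memory (BiLSTM) sequence regressor. The
    source mesh is treated as an undirected graph; the eigenvectors of its
    Laplacian provide a spatial frequency basis, and a BiLSTM is trained to
    map multichannel EEG to the low-frequency graph Fourier coefficients of
    the source signal, from which source maps are recovered by the inverse
    transform. Includes a simulator for patch-source EEG with autoregressive
    temporal dynamics and controlled signal-to-noise ratio, classical linear
    inverse operators (MNE, dSPM, sLORETA) as benchmarks, and ROC-AUC /
    localization-error evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
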