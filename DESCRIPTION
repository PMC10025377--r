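Package: prewnpls
Title: Penalized Recursive Exponentially Weighted N-way Partial Least Squares
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Online-adaptive tensor regression for neural signal decoding.
    Implements recursive exponentially weighted N-way partial least squares
    (REW-NPLS) on streamed blocks of temporal-frequency-spatial feature
    tensors, and its group-wise sparse extension (PREW-NPLS) in which the
    rank-1 PARAFAC step of each model update is penalized with an Lp
    (p = 0, 0.5, 1) norm or pseudo-norm on selected tensor modes, yielding
    slice-wise (for example per-electrode) sparsity. Includes exact scalar
    proximal operators for the three penalties, Morlet continuous-wavelet
    feature tensorization of multichannel time series, a synthetic session
    generator with known sparse multilinear ground truth, and the
    pseudo-online evaluation protocol (cosine-similarity summaries, sparsity
    index, penalization-parameter sweeps, paired signed-rank comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
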