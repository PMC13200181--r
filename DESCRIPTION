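Package: specnmf
Title: Model-Free Non-Negative Matrix Factorization for Time-Resolved
    Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deconvolves time-resolved spectroscopic data matrices into
    non-negative component spectra and kinetic traces without assuming a
    kinetic model.  A truncated singular value decomposition provides an
    exact low-rank representation of the data; the family of exact
    non-negative factorizations is then parametrized by an invertible
    transformation matrix whose entries are optimized by multi-start
    Nelder-Mead search against a penalty objective (non-negativity of both
    factors plus minimal spectral overlap).  Includes a bounded refinement
    step driven by user-declared exclusive and absence spectral windows,
    simulators for benchmark kinetic scenarios (arbitrary smooth traces,
    branched first-order and mixed-order reaction systems with Lorentzian
    component spectra), optional Savitzky-Golay smoothing and spline
    baseline subtraction, and evaluation tools that match recovered
    components to a known ground truth and refit rate constants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    pracma,
    signal,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
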