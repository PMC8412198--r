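Package: gpcomm
Title: Compositional Gaussian Process Models of Pattern Communication
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how structured function patterns survive a
    describe-and-redraw communication channel. Implements a compositional
    Gaussian process kernel grammar (linear, radial basis and periodic base
    kernels combined by sums and products, at most three non-repeating
    components) and a spectral-mixture alternative; marginal-likelihood model
    search with gradient-based hyperparameter optimization; pattern sampling
    and spectral-entropy/wavelet matching of compositional and
    noncompositional stimulus sets; reconstruction scoring by spline
    resampling, absolute error and Haar-wavelet distance; lexical metrics for
    free-text pattern descriptions; a synthetic communication-game simulator
    with known ground truth; and mixed-effects regressions linking model
    likelihoods to communicability with BIC-approximate Bayes factors.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, lme4, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
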