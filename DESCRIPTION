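Package: cleftsim
Title: Paired First-Passage-Time Simulation of Neurotransmitter Transport
    Across Synaptic Clefts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the drift-diffusion of charged neurotransmitters
    (glutamate) across one-dimensional synaptic clefts with overdamped
    Langevin dynamics, an electrostatic drift force and a localized
    soft-wall force preventing return to the pre-synaptic membrane.
    Records first-passage times at the post-synaptic boundary for pairs of
    simultaneously released neurotransmitters in two clefts and quantifies
    the persistence of arrival-time correlations through the distribution
    of their first-passage-time difference.  Provides closed-form drifted
    Wiener-process (inverse-Gaussian) benchmarks for the first-passage
    density, its moments, and the standard deviation of the paired
    difference, plus parameter sweeps over diffusion coefficients and
    trans-cleft voltages with reproducible seeded output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
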