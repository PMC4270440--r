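Package: animatphi
Title: Evolution and Integrated-Information Analysis of Logic-Gate Animats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates the evolution of small logic-gate agents ("animats")
    in block-catching perceptual categorization tasks and quantifies the
    causal structure of their Markov-brain networks with the measures of
    integrated information theory (IIT 3.0): cause-effect repertoires,
    earth-mover's distances with a Hamming ground metric, mechanism-level
    integrated information (phi) and concepts, conceptual structures,
    system-level integrated conceptual information (big Phi), and main
    complexes. Includes a genetic algorithm with line-of-descent tracing,
    genome encoding of hidden Markov gates, task environments of graded
    complexity, observational Shannon information measures, and the
    statistical comparisons used to relate causal structure to fitness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
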