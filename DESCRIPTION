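Package: hybridkin
Title: Single-Molecule FRET Kinetics of RNase H on RNA:DNA Hybrids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to simulate and analyse single-molecule FRET experiments
    probing how RNase H recognises and degrades structural variants of
    RNA:DNA hybrids. Provides a continuous-time Markov simulator of
    enzyme-substrate binding, bound-state inter-site diffusion and
    processive or distributive RNA degradation; rendering of simulated
    state paths into noisy framed donor/acceptor intensity traces;
    trajectory idealization by fixed thresholds or Gaussian hidden Markov
    models with dwell-time extraction; transition density plots, binding
    frequencies and the dwell-time dissociation-constant estimator; and
    degradation-time measurement, pause detection and
    processive-versus-distributive classification from the concentration
    dependence of degradation times.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
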