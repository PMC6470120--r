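Package: ciuevol
Title: Optimality Models for the Evolution of Collective Infectious Units
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying when viruses are favoured to transmit their
    genomes in groups, as collective infectious units (CIUs), rather than as
    single virions. Implements an optimality model in which the fitness of a
    pure strategy of infectious-unit size k combines a saturating
    group-benefit success curve, a geometric packaging-efficiency multiplier
    on the genome budget, and a load of defective and defective-interfering
    progeny genomes. Provides an exact binomial-mixture computation of
    effective infection success, a Monte-Carlo cross-check, an integer
    evolutionarily-stable-strategy search over unit size, and two-dimensional
    parameter sweeps with tabular and heatmap output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
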