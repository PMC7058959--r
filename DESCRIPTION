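Package: polysweep
Title: Hard-Sweep Signals in Autopolyploid Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying how ploidy (2x, 4x,
    8x) reshapes the population-genomic footprint of a hard selective sweep.
    Provides Wright-Fisher allele-frequency trajectories for arbitrary even
    ploidy under a one-parameter dosage-dependent dominance model, a
    structured-coalescent haplotype simulator conditioned on a sweep
    trajectory (with recombination, a two-population split demography and
    ploidy-scaled mutation and recombination rates, emitting ms-format
    output), windowed sweep statistics (nucleotide diversity, Tajima's D,
    Hudson's F_ST, iHS, XP-EHH), and peak summaries (magnitude, breadth,
    area, area-under-peak, persistence curves, coefficient-of-variation
    bootstraps), plus an experiment driver that runs parameter grids
    reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
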