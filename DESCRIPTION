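Package: strstutter
Title: Markov Chain Modelling of In Vitro STR Stutter Noise and Exhaustive Genotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models the in vitro slippage ("stutter") noise that PCR amplification
    imprints on short tandem repeats (STRs) as a discrete-time Markov chain over
    repeat number, with a contraction-biased, length-linear one-cycle kernel
    ('Linear1up3dw'). Provides calibration of per-repeat-class kernel parameters
    against multi-timepoint amplification histograms by quasi-Newton minimisation
    of a summed squared 1-correlation distance, an exhaustive mono- and biallelic
    genotyper that scores measured repeat-number histograms against predicted
    stutter patterns over all candidate alleles, amplification times and mixture
    proportions, a reference-tree fitness metric for validating genotypes against
    a known cell lineage tree, a molecule-level branching-process PCR stutter
    simulator, and a flank-anchored repeat-number caller for amplicon reads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
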