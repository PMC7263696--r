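Package: RecScreen
Title: Fluctuation Analysis and Replica-Pinning Screen Scoring for
    Direct-Repeat Recombination
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative machinery for genome-scale yeast
    direct-repeat recombination screens. Implements Luria-Delbruck
    distribution mathematics (Ma-Sandri-Sarkar recursion) and forward
    simulation of recombinant accumulation during clonal growth;
    recombination-rate estimation from fluctuation tests by the
    Lea-Coulson method of the median, with two-stage hit triage (rate
    cutoff followed by a one-sided Student's t-test); scoring of
    high-density replica-pinning colony arrays into per-strain
    recombinant frequencies with circularity and relative-area filters;
    a screen simulator that generates synthetic colony and fluctuation
    tables with the assumed statistical structure; and screen
    integration statistics (frequency distributions, cutoff
    classification, hypergeometric gene-set overlap, ortholog
    summaries), with the published hit tables shipped as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, graphics, tools, yaml, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
biocViews: Genetics, CellBiology, Software
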