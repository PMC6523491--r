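Package: ltrdyn
Title: Insertion-Time Dating and Evolutionary Dynamics of LTR Retrotransposons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Characterization of full-length long terminal repeat (LTR)
    retrotransposons and their evolutionary dynamics in plant genomes.
    Implements insertion-time dating from LTR-pair divergence under the
    Kimura two-parameter model (T = K/2r), family classification by the
    80-80-80 rule, structural signal detection (TG...CA boundaries,
    primer-binding sites against a tRNA database, polypurine tracts,
    target-site duplications, boundary position matrices), Nei-Gojobori
    dN/dS selection screening on reverse-transcriptase domains,
    neighbor-joining RT phylogenies with bootstrap support and lineage
    assignment, exponential deletion (half-life) modelling, and
    genomic-context classification of insertions. A synthetic-element
    generator provides ground truth (true age, priming tRNA, omega,
    family membership, insertion context) for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    seqinr,
    withr
Config/testthat/edition: 3
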