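Package: panplastome
Title: Pan-Plastome Structure, Variant Typology, and Population Genetics
Version: 0.1.0
Authors@R:
    person("panplastome", "developers", email = "panplastome@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis of complete chloroplast genomes sampled
    across many accessions of one species. Detects the quadripartite
    LSC/IRb/SSC/IRa architecture of circular plastomes and canonicalizes
    their orientation; calls merged variant events from a whole-plastome
    multiple alignment and classifies them with a four-way typology (SNV,
    InDel, block substitution, mixed); collapses haplotypes and computes
    haplotype and nucleotide diversity, Tamura-Nei (TN93) distances,
    pairwise Fst, PCA coordinates and neighbor-joining trees; builds
    minimum-spanning and median-joining haplotype networks; screens
    sliding windows and clade-diagnostic sites for marker candidates; and
    ships a seeded plastome-population simulator that emits machine
    readable truth for end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
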