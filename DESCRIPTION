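Package: ssrCID
Title: SSR Fingerprinting and Cultivar Identification Diagrams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for DNA fingerprinting of clonal plant cultivars with
    co-dominant microsatellite (SSR) markers. Computes per-locus marker
    statistics (major allele frequency, allele and genotype counts, observed
    heterozygosity, polymorphism information content, probability of
    identity), combines probabilities of identity across independent loci,
    selects core marker panels by discriminating power, builds Nei-distance
    UPGMA dendrograms, and constructs cultivar identification diagrams
    (CIDs): genotype-keyed decision trees that identify a cultivar with the
    smallest possible marker subset. Ships transcribed genotype and marker
    tables for 66 clonal tea (Camellia sinensis) cultivars typed at
    long-core-motif SSR loci, and a Hardy-Weinberg population simulator for
    validating the statistics on data with known allele frequencies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
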