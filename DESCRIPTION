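Package: asvoverlap
Title: Community-Overlap Partitioning and Distance Phylogenetics for
    Amplicon Sequence Variant Tables
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing gut microbial communities between host
    groups using amplicon sequence variant (ASV) count tables.  Implements
    the sample-depth, taxonomy, and prevalence/abundance filters commonly
    applied to denoised 16S rRNA data; a per-group partition of community
    abundance into unique, shared, and increased components that closes to
    100 percent per group; a random-split permutation null for the shared
    fraction within one group; a Dirichlet-multinomial synthetic community
    generator with known ground truth; a distance-phylogenetics chain
    (complete deletion of gapped columns, Tamura-Nei composite-likelihood
    distances, neighbor joining, Newick output); and a calculator
    contrasting lifetime gut-bacterial reproductive events with human
    reproductive rates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
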