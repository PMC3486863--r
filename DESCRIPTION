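Package: rnacensus
Title: Taxonomy-Aware Census of RNA Family Distribution Across the Domains of Life
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a comparative census of non-coding RNA family
    distribution across Archaea, Bacteria, Eukaryota and viruses from
    Rfam-style annotation tables. Provides NCBI-taxonomy-dump loading and
    domain/division resolution, bitscore-margin vetting of putative false
    positive annotations in multi-domain families, presence/absence matrices
    at family or clan level, four-set Venn partitioning, broad-distribution
    classification against major within-domain taxonomic divisions,
    Dollo-parsimony character mapping of families on a species phylogeny,
    discovery curves from family and sequence-record dates, and a
    ground-truthed simulator of Rfam-like inputs with gain, Dollo loss,
    interdomain horizontal transfer, sampling bias and marginal false
    positives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
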