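Package: prophagecomp
Title: Comparative Analysis of Prophage Catalogs in Prokaryotic Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of prophage catalogs predicted
    from prokaryotic genome collections: prediction filtering and catalog
    summaries, taxon-level prophage-enrichment testing with bootstrapped
    genus subsampling, pathogen-versus-unassigned enrichment with a
    leave-one-out genus-contribution analysis, greedy identity/coverage
    clustering of prophages into viral clusters with host-range
    classification, reciprocal-best-hit average amino-acid identity (AAI)
    relatedness networks, fragment-based average nucleotide identity (ANI),
    and k-mer usage-bias profiles for phage-host association. A synthetic
    catalog generator with planted, recoverable structure makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
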