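Package: replifid
Title: Replication-Fidelity Assays: Fluctuation Tests, Embedded-Ribonucleotide
    Gel Quantification, and Mutation Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for characterizing bacterial DNA-replication
    fidelity. Implements maximum-likelihood estimation of mutation rates from
    Luria-Delbruck fluctuation assays under the Ma-Sandri-Sarkar mutant-count
    distribution, including partial plating, profile-likelihood confidence
    intervals, likelihood-ratio comparison of strains and Benjamini-Hochberg
    adjustment; quantification of genome-embedded ribonucleotides from
    alkaline-gel densitometry profiles (ladder calibration, fragment-size
    distributions, corrected mean fragment size, breakpoints per genome);
    and tabulation of rpoB rifampicin-resistance base-substitution spectra
    (six base-pair classes, transitions versus transversions, hotspots).
    Seeded synthetic-data generators emulate all three raw input kinds with
    known ground truth so every pipeline stage can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
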