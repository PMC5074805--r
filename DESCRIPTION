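Package: tprhairpin
Title: Tracing Tetratricopeptide Repeat Origins from Helical Hairpins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect tetratricopeptide repeat (TPR)-like helical
    hairpins in non-repetitive protein sequences and to turn such a hairpin
    into a foldable three-repeat TPR by rule-based consensus design.
    Implements position-specific profile scanning with empirical
    (Gumbel-calibrated) p-values and a simulated-null false discovery rate,
    Kabsch superposition with average-structure RMSD filtering of candidate
    hairpins, hydrophobicity screening of repeat-interface positions,
    column-pair mutual information for coevolving alignment positions,
    a per-repeat mutation grammar assembling designed constructs,
    neighbor-joining phylogenies of fixed-length repeat units with bootstrap
    support, and two-state linear-extrapolation fits of chemical and thermal
    denaturation curves. Synthetic-data generators provide ground-truth
    fixtures for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ape,
    minpack.lm,
    jsonlite,
    yaml,
    Biostrings,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
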