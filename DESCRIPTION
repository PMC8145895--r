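Package: ncaadelta
Title: Delta-Mass Clustering and Discovery of Non-Coded Amino Acids from
    Open-Search Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of wildcard (open modification) database
    search results for the discovery of non-coded amino acids (ncAAs):
    filtering of peptide-spectrum matches, partition of per-residue mass
    shifts into 1-Da windows, Gaussian mixture clustering with BIC model
    selection, Gaussian regression of each cluster for peak mass, SD and
    goodness of fit, annotation of clustered delta masses against a
    monoisotopic catalog of post-translational modifications and amino
    acid substitutions (including single-nucleotide codon reachability),
    and spectral-count differential testing of modified sites between two
    conditions. Includes a synthetic PSM generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    mclust,
    minpack.lm
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
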