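Package: mesodemog
Title: Demographic History of Maternal Lineages from mtDNA Control-Region Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for reconstructing the demographic history of human
    populations from mitochondrial control-region (HVRI/HVRII) sequence data.
    Includes a coalescent simulator under piecewise-constant female effective
    population size (Nef) with HKY+Gamma sequence evolution; haplogroup
    assignment from diagnostic motifs and gene-counting frequency tables;
    within-population diversity and neutrality statistics (haplotype and
    nucleotide diversity, Tajima's D, Fu's FS); between-population structure
    (pairwise Phi-st, hierarchical AMOVA with permutation tests, Mantel test,
    classical MDS, shared-haplotype counts); a Bayesian skyline reconstruction
    of Nef(t) by MCMC on coalescent intervals; and inter-generational growth
    rates (IGR) with extrema and trend-inversion detection mapped onto
    Mesoamerican chronological periods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    geosphere,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
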