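Package: ldforest
Title: Multilocus GWAS with Latent-Tree LD Maps and Embedded Random Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Case-control genome-wide association analysis that exploits
    linkage disequilibrium through ensembles of "trees inside trees":
    each meta-node of a bagged random forest embeds an extremely
    randomized tree grown on a block or cluster of SNPs, and the split is
    made on the meta-variable given by the embedded tree's leaf case
    probabilities.  Cluster maps come either from contiguous blocks or
    from the first layer of a forest of latent tree models (FLTM) learned
    by mutual-information clustering plus EM on latent class models.
    Includes a single-SNP contingency-test baseline, genotype quality
    control, a haplotype-block case-control simulator with planted causal
    variants, and an evaluation harness (top-k causal recovery,
    cross-validated AUC, importance-distribution comparison, top-100
    intersections).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
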