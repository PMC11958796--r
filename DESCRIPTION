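Package: mclandscape
Title: Compositional Landscape Analysis of Replicated Microbial Community Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing replicated trajectories of bacterial communities
    through compositional space: community-class detection by partition-around-medoids
    clustering of Jensen-Shannon distances scored with the Calinski-Harabasz index,
    ANOSIM permutation tests, rigid-body (Kabsch) superposition of starting onto final
    abundance matrices with a shuffled-matrix null, attractor geometry via
    resampled-median class centroids and border distances, a bootstrap propensity
    statistic linking individual amplicon sequence variants to trajectory fates, and
    tipping-point classification from summed group abundances. Includes a
    Dirichlet-multinomial community simulator with planted ground truth so the whole
    pipeline runs end-to-end on synthetic ASV tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    vegan,
    mclust,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
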