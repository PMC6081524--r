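Package: swarmlda
Title: Swarm-Optimized Topic Models and Diversity-Based Ensemble Pruning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage text categorization toolkit for bag-of-words corpora.
    Stage one calibrates the hyperparameters of latent Dirichlet allocation
    (number of topics, Dirichlet concentrations, Gibbs sweep budget) with
    population metaheuristics (genetic algorithm, particle swarm, firefly,
    cuckoo search, bat algorithm) using internal cluster-validity indices
    (BIC, Calinski-Harabasz, Davies-Bouldin, Silhouette) as the fitness of a
    candidate configuration. Stage two prunes a library of base classifiers
    by computing pairwise diversity measures (Q-statistic, correlation,
    disagreement, double fault, kappa) on a validation oracle matrix,
    averaging them into a combined diversity matrix, clustering classifiers
    in diversity space with a metaheuristic clustering algorithm, keeping the
    most accurate member of each cluster, and combining the survivors by
    majority vote. Includes a collapsed Gibbs sampler, a synthetic corpus
    generator implementing the LDA generative process, a stratified tenfold
    6/2/2 evaluation protocol, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    class
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
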