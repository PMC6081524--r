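#' Cluster classifiers in diversity space with a metaheuristic
#'
#' Each classifier is represented by its row of the combined diversity
#' matrix, an L-dimensional feature vector describing how it differs from
#' every library member. An optimizer agent encodes `k` cluster centres in
#' that space; its fitness is the negative total Euclidean distance of
#' classifiers to their nearest centre, so maximization produces compact
#' groups of similarly-behaving classifiers. Centres are parameterized as
#' medoids -- an agent is a vector of `k` row indices (continuous during the
#' search, rounded at decode), each naming the classifier row that serves as
#' a centre. Anchoring centres to actual data rows keeps the search space
#' `k`-dimensional regardless of the library size; a free `k * L`-coordinate
#' encoding leaves the optimizers wandering a mostly empty box in which
#' almost all centres attract nothing. The final assignment maps each
#' classifier to its nearest centre (ties to the smallest index); empty and
#' duplicate clusters are dropped. `k >= L` is clamped to `L - 1` with a
#' warning (clustering into as many groups as members would make pruning a
#' no-op).
#'
#' @param combined a [combine_matrices()] result.
#' @param params an [optimizer_params()]; defaults to firefly with the
#'   clustering-stage parameter set (alpha 0.6, gamma 0.3, delta 0.95).
#' @param k requested number of clusters (default 20).
#' @param seed integer RNG seed for the optimizer.
#' @return a list of class `swarmlda_clustering` with `assignment` (1-based
#'   compact cluster ids, named by classifier), `centroids`,
#'   `n_clusters_effective` and `objective` (total distance, smaller is
#'   better).
#' @export
cluster_classifiers <- function(combined,
                                params = optimizer_params("fa", stage = "clustering"),
                                k = 20L, seed = 1L) {
  if (!inherits(combined, "swarmlda_combined_diversity")) {
    stop_fmt("'combined' must be a combined diversity matrix")
  }
  feats <- combined$values
  L <- nrow(feats)
  if (L < 2L) stop_fmt("need at least two classifiers to cluster")
  k <- assert_scalar_int(k, "k", min = 2)
  if (k >= L) {
    warn_fmt("k = %d >= %d classifiers; clamping to %d", k, L, L - 1L)
    k <- L - 1L
  }
  D <- as.matrix(stats::dist(feats))
  assign_nearest <- function(medoids) {
    dd <- D[, medoids, drop = FALSE]
    idx <- max.col(-dd, ties.method = "first")
    list(idx = idx, dist = dd[cbind(seq_len(L), idx)])
  }
  decode_medoids <- function(vec) pmin(pmax(round(vec), 1L), L)
  fitness_fn <- function(vec) {
    -sum(assign_nearest(decode_medoids(vec))$dist)
  }
  res <- optimize_metaheuristic(fitness_fn, lower = rep(1, k),
                                upper = rep(L, k), params, seed = seed)
  medoids <- decode_medoids(res$best_vector)
  asg <- assign_nearest(medoids)
  centroids <- feats[medoids, , drop = FALSE]
  used <- sort(unique(asg$idx))
  compact <- match(asg$idx, used)
  names(compact) <- rownames(feats)
  structure(list(assignment = compact,
                 centroids = centroids[used, , drop = FALSE],
                 n_clusters_effective = length(used),
                 objective = sum(asg$dist),
                 optimizer = res),
            class = "swarmlda_clustering")
}

#' Select the pruned ensemble
#'
#' From each non-empty cluster, keeps the classifier with the highest
#' validation accuracy (ties broken toward the smallest classifier index).
#'
#' @param clustering a [cluster_classifiers()] result.
#' @param oracle the [build_oracle_matrix()] the clustering was derived from.
#' @return a list of class `swarmlda_pruned_ensemble` with `member_indices`
#'   (into the oracle's classifier order), `member_names` and `tie_policy`.
#' @export
prune_ensemble <- function(clustering, oracle) {
  if (!inherits(clustering, "swarmlda_clustering")) {
    stop_fmt("'clustering' must come from cluster_classifiers()")
  }
  if (length(clustering$assignment) != length(oracle$accuracies)) {
    stop_fmt("clustering covers %d classifiers but oracle has %d",
             length(clustering$assignment), length(oracle$accuracies))
  }
  members <- vapply(seq_len(clustering$n_clusters_effective), function(cl) {
    in_cl <- which(clustering$assignment == cl)
    in_cl[which.max(oracle$accuracies[in_cl])]  # which.max: first max = smallest index
  }, integer(1))
  members <- sort(unique(members))
  structure(list(member_indices = members,
                 member_names = oracle$names[members],
                 tie_policy = "highest validation accuracy, ties to smallest classifier index"),
            class = "swarmlda_pruned_ensemble")
}

#' Majority vote over ensemble member predictions
#'
#' Per instance, the most frequent predicted class wins. Ties are broken
#' toward the class with the largest training-set prior, then toward the
#' smallest class id.
#'
#' @param predictions L x m matrix of predicted labels (one row per ensemble
#'   member, one column per instance).
#' @param class_priors optional named numeric vector of training-set class
#'   proportions; names are class labels as character.
#' @return integer vector of m voted labels.
#' @export
majority_vote <- function(predictions, class_priors = NULL) {
  predictions <- rbind(predictions)
  if (nrow(predictions) < 1L) stop_fmt("need at least one ensemble member")
  apply(predictions, 2, function(col) {
    tab <- table(col)
    top <- as.integer(names(tab)[tab == max(tab)])
    if (length(top) > 1L && !is.null(class_priors)) {
      pri <- class_priors[as.character(top)]
      pri[is.na(pri)] <- -Inf
      top <- top[pri == max(pri)]
    }
    min(top)
  })
}
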