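# combined diversity matrix with two duplicate pairs: {1,2} and {3,4}
paired_combined <- function() {
  v <- matrix(0.8, 4, 4)
  v[1, 2] <- v[2, 1] <- 0
  v[3, 4] <- v[4, 3] <- 0
  diag(v) <- 0
  dimnames(v) <- list(paste0("c", 1:4), paste0("c", 1:4))
  structure(list(values = v, component_measures = "dis"),
            class = "swarmlda_combined_diversity")
}

test_that("duplicate pairs are co-clustered, matching exhaustive enumeration", {
  comb <- paired_combined()
  # exhaustive 2-partition search minimizing total distance to cluster means
  feats <- comb$values
  parts <- list(c(1, 1, 2, 2), c(1, 2, 1, 2), c(1, 2, 2, 1))
  obj <- vapply(parts, function(p) {
    sum(vapply(1:4, function(i) {
      cent <- colMeans(feats[p == p[i], , drop = FALSE])
      sqrt(sum((feats[i, ] - cent)^2))
    }, 0))
  }, 0)
  best_part <- parts[[which.min(obj)]]
  expect_equal(best_part, c(1, 1, 2, 2))  # pairs together is optimal

  clust <- cluster_classifiers(
    comb, params = optimizer_params("fa", stage = "clustering",
                                    population_size = 20, n_iterations = 40),
    k = 2, seed = 1)
  a <- unname(clust$assignment)
  expect_equal(a[1], a[2])
  expect_equal(a[3], a[4])
  expect_false(a[1] == a[3])
})

test_that("k at or above the library size is clamped with a warning", {
  comb <- paired_combined()
  expect_warning(
    clust <- cluster_classifiers(comb, k = 10, seed = 1,
                                 params = optimizer_params("fa", stage = "clustering",
                                                           population_size = 6,
                                                           n_iterations = 5)),
    "clamping"
  )
  expect_lte(clust$n_clusters_effective, 3)
  expect_length(clust$assignment, 4)
})

test_that("the clustering trace is elitist", {
  comb <- paired_combined()
  clust <- cluster_classifiers(comb, k = 2, seed = 3,
                               params = optimizer_params("pso", stage = "clustering",
                                                         population_size = 8,
                                                         n_iterations = 10))
  expect_false(is.unsorted(clust$optimizer$history))
  expect_equal(clust$objective, -clust$optimizer$best_fitness)
})

test_that("pruning keeps the most accurate member of each cluster", {
  oracle <- random_oracle(L = 6, n = 30, seed = 8)
  oracle$accuracies <- c(0.7, 0.9, 0.8, 0.6, 0.9, 0.5)
  clustering <- structure(list(
    assignment = setNames(c(1L, 1L, 1L, 2L, 2L, 2L), oracle$names),
    centroids = matrix(0, 2, 6), n_clusters_effective = 2L,
    objective = 0), class = "swarmlda_clustering")
  pruned <- prune_ensemble(clustering, oracle)
  expect_equal(pruned$member_indices, c(2L, 5L))  # argmax per cluster

  # all-singleton clustering keeps everything
  singletons <- structure(list(
    assignment = setNames(1:6, oracle$names), centroids = matrix(0, 6, 6),
    n_clusters_effective = 6L, objective = 0), class = "swarmlda_clustering")
  expect_equal(prune_ensemble(singletons, oracle)$member_indices, 1:6)

  # random clusterings: brute-force per-cluster argmax
  set.seed(13)
  for (rep in 1:10) {
    asg <- sample(1:3, 6, replace = TRUE)
    asg <- match(asg, sort(unique(asg)))
    cl <- structure(list(assignment = setNames(asg, oracle$names),
                         centroids = matrix(0, max(asg), 6),
                         n_clusters_effective = max(asg), objective = 0),
                    class = "swarmlda_clustering")
    expected <- sort(vapply(seq_len(max(asg)), function(g) {
      cand <- which(asg == g)
      cand[which.max(oracle$accuracies[cand])]
    }, integer(1)))
    expect_equal(prune_ensemble(cl, oracle)$member_indices, expected)
  }
})

test_that("majority voting follows the stated tie policies", {
  # unanimous members
  expect_equal(majority_vote(rbind(c(1, 2), c(1, 2), c(1, 2))), c(1, 2))
  # strict majority
  expect_equal(majority_vote(rbind(1, 1, 2)), 1)
  # two-way tie resolved by the larger training prior
  expect_equal(majority_vote(rbind(0, 1), class_priors = c("0" = 0.3, "1" = 0.7)), 1)
  expect_equal(majority_vote(rbind(0, 1), class_priors = c("0" = 0.7, "1" = 0.3)), 0)
  # tie with equal priors falls back to the smallest class id
  expect_equal(majority_vote(rbind(0, 1), class_priors = c("0" = 0.5, "1" = 0.5)), 0)
  expect_equal(majority_vote(rbind(0, 1)), 0)
})

test_that("fixture classifiers are deterministic and the kNN member matches class::knn", {
  sp <- pipeline_split()
  lib <- fixture_classifier_library()
  expect_gte(length(lib), 12)
  expect_equal(anyDuplicated(vapply(lib, `[[`, "", "name")), 0L)
  for (spec in lib[c(1, 3, 7, 10)]) {
    p1 <- spec$predict(spec$fit(sp$theta_train, sp$y_train), sp$theta_val)
    p2 <- spec$predict(spec$fit(sp$theta_train, sp$y_train), sp$theta_val)
    expect_identical(p1, p2)
  }
  skip_if_not_installed("class")
  knn1 <- swarmlda:::make_knn(1)
  ours <- knn1$predict(knn1$fit(sp$theta_train, sp$y_train), sp$theta_val)
  ref <- as.integer(as.character(class::knn(sp$theta_train, sp$theta_val,
                                            factor(sp$y_train), k = 1)))
  expect_equal(mean(ours == ref), 1, tolerance = 0.01)
})
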