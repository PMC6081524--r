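test_that("decode rounds the integer dimensions and is idempotent", {
  cfg <- decode_config(c(5.4, 0.1, 0.01, 200.7))
  expect_equal(cfg$k, 5L)
  expect_equal(cfg$alpha, 0.1)
  expect_equal(cfg$beta, 0.01)
  expect_equal(cfg$n_iter, 201L)

  lower <- c(2, 0.01, 0.01, 50)
  cfg_lo <- decode_config(lower)
  expect_equal(unclass(cfg_lo)[c("k", "alpha", "beta", "n_iter")],
               list(k = 2L, alpha = 0.01, beta = 0.01, n_iter = 50L))
  again <- decode_config(c(cfg$k, cfg$alpha, cfg$beta, cfg$n_iter))
  expect_equal(unclass(again), unclass(cfg))
})

test_that("fitness honours the sign contract and the degenerate sentinel", {
  cc <- std_synth()$labeled$corpus
  cfg <- lda_config(4, 0.1, 0.05, 30)
  model <- fit_lda(cc, cfg, seed = 1)
  part <- dominant_topic_partition(model)
  pts <- document_points(cc)
  expect_equal(lda_config_fitness(cc, cfg, "db", lda_seed = 1),
               -davies_bouldin(pts, part))
  expect_equal(lda_config_fitness(cc, cfg, "si", lda_seed = 1),
               silhouette_index(pts, part))
  expect_equal(lda_config_fitness(cc, cfg, "ch", lda_seed = 1),
               calinski_harabasz(pts, part))
  expect_equal(lda_config_fitness(cc, cfg, "bic", lda_seed = 1),
               -bic_score(pts, part))
  # k = 1 puts every document in one cluster: repelled by the sentinel
  expect_equal(lda_config_fitness(cc, lda_config(1, 0.1, 0.05, 5), "si", 1),
               -1e18)
})

test_that("the fitness argmax matches the raw-index arg-extremum on a grid", {
  cc <- std_synth()$labeled$corpus
  ks <- c(2, 4, 5)  # configurations whose partitions use every topic
  for (index in c("si", "db")) {
    fitness <- vapply(ks, function(k) {
      lda_config_fitness(cc, lda_config(k, 0.1, 0.01, 60), index, lda_seed = 1)
    }, 0)
    expect_true(all(fitness > -1e17))  # none degenerate on this grid
    raw <- vapply(ks, function(k) {
      m <- fit_lda(cc, lda_config(k, 0.1, 0.01, 60), seed = 1)
      validity_score(document_points(cc), dominant_topic_partition(m), index)$value
    }, 0)
    if (index == "si") expect_equal(which.max(fitness), which.max(raw))
    else expect_equal(which.max(fitness), which.min(raw))
  }
})

test_that("a candidate leaving topics unused is repelled by the sentinel", {
  cc <- std_synth()$labeled$corpus
  # k far above the generative topic count: most topics dominate nothing
  m <- fit_lda(cc, lda_config(40, 0.1, 0.01, 60), seed = 1)
  expect_lt(length(unique(dominant_topic_partition(m))), 40)
  expect_equal(lda_config_fitness(cc, lda_config(40, 0.1, 0.01, 60), "si", 1),
               -1e18)
})

test_that("the true topic count outscores a gross overfit under silhouette", {
  cc <- std_synth()$labeled$corpus
  f5 <- lda_config_fitness(cc, lda_config(5, 0.1, 0.01, 200), "si", lda_seed = 1)
  f40 <- lda_config_fitness(cc, lda_config(40, 0.1, 0.01, 200), "si", lda_seed = 1)
  expect_gt(f5, f40)
})

test_that("a pinned k bound is returned unchanged and the trace is monotone", {
  cc <- corpus_subset(std_synth()$labeled$corpus, 1:60)
  spec <- lda_search_spec(
    index_name = "si",
    params = optimizer_params("pso", population_size = 4, n_iterations = 3),
    k_bounds = c(5, 5), n_iter_bounds = c(10, 20),
    lda_seed = 1, opt_seed = 1)
  res <- search_lda_config(cc, spec)
  expect_equal(res$config$k, 5L)
  expect_false(is.unsorted(res$result$history))
  expect_true(all(res$evaluations$k == 5))
  expect_s3_class(res$evaluations, "data.frame")
})

test_that("the search caches duplicate decoded configurations", {
  cc <- corpus_subset(std_synth()$labeled$corpus, 1:50)
  spec <- lda_search_spec(
    index_name = "si",
    params = optimizer_params("ba", population_size = 6, n_iterations = 5),
    k_bounds = c(2, 4), n_iter_bounds = c(10, 12),
    lda_seed = 1, opt_seed = 2)
  res <- search_lda_config(cc, spec)
  # the log holds only distinct configurations, fewer than total evaluations
  key <- with(res$evaluations, paste(k, alpha, beta, n_iter))
  expect_equal(anyDuplicated(key), 0L)
  expect_lte(nrow(res$evaluations), res$result$n_evaluations)
})

test_that("represent_corpus produces leak-free train/test topic features", {
  gen <- std_synth()
  cc <- gen$labeled$corpus
  rep1 <- represent_corpus(corpus_subset(cc, 1:150), corpus_subset(cc, 151:200),
                           lda_config(5, 0.1, 0.01, 200), seed = 1)
  expect_lt(max(abs(rowSums(rep1$theta_train) - 1)), 1e-9)
  expect_lt(max(abs(rowSums(rep1$theta_test) - 1)), 1e-9)

  # nearest-centroid on theta features recovers the dominant-topic labels
  nc <- swarmlda:::make_nearest_centroid()
  st <- nc$fit(rep1$theta_train, gen$labeled$labels[1:150])
  acc <- mean(nc$predict(st, rep1$theta_test) == gen$labeled$labels[151:200])
  expect_gte(acc, 0.8)

  # k = 1: both representations collapse to the all-ones column
  rep_k1 <- represent_corpus(corpus_subset(cc, 1:20), corpus_subset(cc, 21:30),
                             lda_config(1, 0.5, 0.5, 5), seed = 1)
  expect_true(all(rep_k1$theta_train == 1) && all(rep_k1$theta_test == 1))
})
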