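# the worked 4-point instance: two tight pairs 10 apart
four_points <- function() {
  list(points = rbind(c(0, 0), c(0, 2), c(10, 0), c(10, 2)),
       labels = c(1, 1, 2, 2))
}

test_that("indices reproduce the worked 4-point instance", {
  fp <- four_points()
  expect_equal(calinski_harabasz(fp$points, fp$labels), 50)
  expect_equal(davies_bouldin(fp$points, fp$labels), 0.2)
  b <- (10 + sqrt(104)) / 2
  expect_equal(silhouette_index(fp$points, fp$labels), (b - 2) / b)
  expect_equal(round(silhouette_index(fp$points, fp$labels), 4), 0.8020)
})

test_that("CH, DB, SI and BIC match the loop oracles on random instances", {
  for (seed in 1:50) {
    inst <- random_instance(seed)
    expect_equal(calinski_harabasz(inst$points, inst$labels),
                 oracle_ch(inst$points, inst$labels), tolerance = 1e-9)
    expect_equal(davies_bouldin(inst$points, inst$labels),
                 oracle_db(inst$points, inst$labels), tolerance = 1e-9)
    expect_equal(silhouette_index(inst$points, inst$labels),
                 oracle_si(inst$points, inst$labels), tolerance = 1e-9)
    expect_equal(bic_score(inst$points, inst$labels),
                 oracle_bic(inst$points, inst$labels), tolerance = 1e-9)
  }
})

test_that("silhouette agrees with the cluster package", {
  skip_if_not_installed("cluster")
  # conventions coincide when no cluster is a singleton (the cluster package
  # scores singletons 0; here a singleton has a = 0 and hence s = 1)
  set.seed(7)
  labels <- rep(1:3, each = 5)
  points <- matrix(rnorm(30), 15, 2) + 2 * labels
  ref <- mean(cluster::silhouette(labels, dist(points))[, "sil_width"])
  expect_equal(silhouette_index(points, labels), ref, tolerance = 1e-9)
})

test_that("indices are invariant to translation, scaling and relabelling", {
  inst <- random_instance(12)
  shifted <- sweep(inst$points, 2, rnorm(ncol(inst$points)), "+")
  scaled <- inst$points * 3.7
  relab <- max(inst$labels) + 1 - inst$labels
  expect_equal(calinski_harabasz(shifted, inst$labels),
               calinski_harabasz(inst$points, inst$labels), tolerance = 1e-9)
  expect_equal(calinski_harabasz(scaled, inst$labels),
               calinski_harabasz(inst$points, inst$labels), tolerance = 1e-9)
  expect_equal(davies_bouldin(inst$points, relab),
               davies_bouldin(inst$points, inst$labels), tolerance = 1e-12)
  perm <- sample(nrow(inst$points))
  expect_equal(silhouette_index(inst$points[perm, ], inst$labels[perm]),
               silhouette_index(inst$points, inst$labels), tolerance = 1e-12)
})

test_that("index ranges and monotonicity properties hold", {
  inst <- random_instance(23)
  si <- silhouette_index(inst$points, inst$labels)
  expect_gte(si, -1); expect_lte(si, 1)
  expect_gte(davies_bouldin(inst$points, inst$labels), 0)
  expect_gte(calinski_harabasz(inst$points, inst$labels), 0)

  # two singleton clusters at distance 1: perfect silhouette
  expect_equal(silhouette_index(rbind(0, 1), c(1, 2)), 1)

  # moving clusters apart decreases DB
  fp <- four_points()
  farther <- fp$points; farther[3:4, 1] <- 100
  expect_lt(davies_bouldin(farther, fp$labels),
            davies_bouldin(fp$points, fp$labels))

  # interleaving one tight blob into two clusters gives a poor silhouette
  blob <- cbind(seq(0, 0.7, by = 0.1), 0)
  expect_lt(silhouette_index(blob, rep(c(1, 2), 4)), 0.2)
})

test_that("degenerate partitions are flagged, not fatal", {
  pts <- matrix(rnorm(20), 10, 2)
  expect_true(is.na(calinski_harabasz(pts, rep(1, 10))))
  expect_true(is.na(davies_bouldin(pts, rep(1, 10))))
  expect_true(is.na(silhouette_index(pts, rep(1, 10))))
  # identical points: floored variance keeps BIC finite and deterministic
  same <- matrix(1, 6, 2)
  b1 <- bic_score(same, rep(1, 6))
  expect_true(is.finite(b1))
  expect_identical(b1, bic_score(same, rep(1, 6)))
  # coincident centroids: DB degenerates to +Inf
  expect_equal(davies_bouldin(rbind(c(0, 0), c(2, 2), c(0, 2), c(2, 0)),
                              c(1, 1, 2, 2)), Inf)
  # zero within-cluster scatter: CH degenerates to +Inf
  expect_equal(calinski_harabasz(rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5)),
                                 c(1, 1, 2, 2)), Inf)

  sc <- validity_score(pts, rep(1, 10), "ch")
  expect_true(sc$degenerate)
  expect_false(validity_score(four_points()$points, four_points()$labels, "si")$degenerate)
})

test_that("duplicating every point increases the BIC complexity penalty", {
  inst <- random_instance(31)
  d <- ncol(inst$points); K <- length(unique(inst$labels)); v <- K * d + 1
  n1 <- nrow(inst$points)
  expect_gt(v * log(2 * n1), v * log(n1))
  # and the full score reflects the doubled sample in its penalty term
  dup <- rbind(inst$points, inst$points)
  bic_dup <- bic_score(dup, c(inst$labels, inst$labels))
  expect_true(is.finite(bic_dup))
})
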