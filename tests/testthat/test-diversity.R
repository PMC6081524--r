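test_that("pair counts match direct tallies", {
  ri <- c(1, 1, 1, 1, 1, 1, 1, 1, 0, 0)
  rj <- c(1, 1, 1, 1, 1, 1, 0, 0, 1, 1)
  expect_equal(pair_counts(ri, rj), list(n11 = 6L, n10 = 2L, n01 = 2L, n00 = 0L))
  same <- c(rep(1, 7), rep(0, 3))
  expect_equal(pair_counts(same, same), list(n11 = 7L, n10 = 0L, n01 = 0L, n00 = 3L))
  expect_error(pair_counts(ri, rj[-1]), "length")

  set.seed(1)
  a <- rbinom(200, 1, 0.6); b <- rbinom(200, 1, 0.4)
  pc <- pair_counts(a, b)
  expect_equal(pc, oracle_pair_counts(a, b))
  expect_equal(pc$n11 + pc$n10 + pc$n01 + pc$n00, 200L)
})

test_that("diversity measures reproduce the worked contingency examples", {
  cnt <- list(n11 = 6, n10 = 2, n01 = 2, n00 = 0)
  expect_equal(diversity_measure(cnt, "q"), -1)
  expect_equal(diversity_measure(cnt, "dis"), 0.4)
  expect_equal(diversity_measure(cnt, "df"), 0)
  expect_equal(diversity_measure(cnt, "rho"), -0.25)

  ident <- list(n11 = 7, n10 = 0, n01 = 0, n00 = 3)
  expect_equal(diversity_measure(ident, "q"), 1)
  expect_equal(diversity_measure(ident, "dis"), 0)
  expect_equal(diversity_measure(ident, "rho"), 1)
  expect_equal(diversity_measure(ident, "kappa"), 1)

  opposite <- list(n11 = 0, n10 = 5, n01 = 5, n00 = 0)
  expect_equal(diversity_measure(opposite, "dis"), 1)
  expect_equal(diversity_measure(opposite, "q"), -1)

  expect_error(diversity_measure(cnt, "nope"))
})

test_that("measure ranges hold and degenerate denominators return 0", {
  set.seed(4)
  for (i in 1:50) {
    cnt <- as.list(setNames(as.integer(rmultinom(1, 40, runif(4))),
                            c("n11", "n10", "n01", "n00")))
    for (m in c("q", "rho", "kappa")) {
      v <- diversity_measure(cnt, m)
      expect_gte(v, -1); expect_lte(v, 1)
    }
    for (m in c("dis", "df")) {
      v <- diversity_measure(cnt, m)
      expect_gte(v, 0); expect_lte(v, 1)
    }
  }
  all_correct <- list(n11 = 10, n10 = 0, n01 = 0, n00 = 0)
  expect_equal(diversity_measure(all_correct, "rho"), 0)
  expect_equal(diversity_measure(all_correct, "q"), 0)
  expect_equal(diversity_measure(all_correct, "kappa"), 0)
})

test_that("all-pairs matrices are symmetric and match the loop oracle", {
  oracle <- random_oracle(L = 6, n = 30, seed = 42)
  for (m in c("q", "rho", "dis", "df", "kappa")) {
    dm <- diversity_matrix(oracle, m)
    expect_true(isSymmetric(dm$values))
    for (i in 1:6) for (j in 1:6) {
      expect_equal(dm$values[i, j],
                   oracle_diversity(oracle_pair_counts(oracle$correct[i, ],
                                                       oracle$correct[j, ]), m),
                   tolerance = 1e-12)
    }
  }
  # duplicated classifiers agree perfectly everywhere
  dup <- random_oracle(L = 2, n = 25, seed = 1)
  dup$correct[2, ] <- dup$correct[1, ]
  q2 <- diversity_matrix(dup, "q")
  expect_equal(q2$values[1, 2], 1)
  expect_equal(q2$values[2, 1], q2$values[1, 2])
})

test_that("combining normalizes, flips similarity measures and averages", {
  # single disagreement component with off-diagonal values {0.2, 0.4, 0.6}
  vals <- matrix(0, 3, 3)
  vals[1, 2] <- vals[2, 1] <- 0.2
  vals[1, 3] <- vals[3, 1] <- 0.4
  vals[2, 3] <- vals[3, 2] <- 0.6
  comb <- combine_matrices(list(manual_diversity_matrix(vals, "dis")))
  expect_equal(comb$values[1, 2], 0)
  expect_equal(comb$values[1, 3], 0.5)
  expect_equal(comb$values[2, 3], 1)
  expect_true(all(diag(comb$values) == 0))

  oracle <- random_oracle(L = 6, n = 40, seed = 9)
  mats <- lapply(c("q", "rho", "dis", "df"), diversity_matrix, oracle = oracle)
  comb4 <- combine_matrices(mats)
  expect_equal(comb4$values, oracle_combine(mats), tolerance = 1e-12)
  expect_true(all(comb4$values >= 0 & comb4$values <= 1))
  # invariant to component order
  comb4r <- combine_matrices(rev(mats))
  expect_equal(comb4r$values, comb4$values, tolerance = 1e-12)

  # a constant component carries no ranking signal
  const <- manual_diversity_matrix(matrix(1, 3, 3), "q")
  expect_warning(cc <- combine_matrices(list(const)), "constant")
  expect_equal(cc$values[1, 2], 0.5)
})

test_that("duplicate classifiers sit at the combined-diversity minimum", {
  oracle <- random_oracle(L = 6, n = 40, seed = 5)
  oracle$correct[2, ] <- oracle$correct[1, ]
  oracle$accuracies <- rowMeans(oracle$correct)
  mats <- lapply(c("q", "rho", "dis", "df"), diversity_matrix, oracle = oracle)
  comb <- combine_matrices(mats)
  off <- comb$values[upper.tri(comb$values)]
  expect_equal(comb$values[1, 2], min(off))
})

test_that("subset enumeration is complete and deterministically ordered", {
  five <- enumerate_measure_subsets(c("q", "rho", "dis", "df", "kappa"))
  expect_length(five, 31)
  expect_identical(five[[1]], "q")
  expect_identical(five[[3]], c("q", "rho"))
  expect_identical(five[[31]], c("q", "rho", "dis", "df", "kappa"))
  expect_equal(anyDuplicated(vapply(five, paste, "", collapse = "|")), 0L)
  expect_length(enumerate_measure_subsets("dis"), 1)
  expect_length(enumerate_measure_subsets(c("a", "b", "c")), 7)
})

test_that("oracle construction records correctness and survives failures", {
  x_train <- matrix(rnorm(40), 20, 2)
  y_train <- rep(0:1, each = 10)
  x_val <- matrix(rnorm(40), 20, 2)
  y_val <- rep(0L, 20)
  always0 <- classifier_spec("always0",
                             fit = function(x, y) NULL,
                             predict = function(s, x) rep(0L, nrow(x)))
  always0b <- classifier_spec("always0b", always0$fit, always0$predict)
  broken <- classifier_spec("broken",
                            fit = function(x, y) stop("boom"),
                            predict = function(s, x) NULL)
  knn1 <- swarmlda:::make_knn(1)
  expect_warning(
    oracle <- build_oracle_matrix(list(always0, broken, knn1, always0b),
                                  x_train, y_train, x_val, y_val),
    "broken"
  )
  expect_equal(nrow(oracle$correct), 3)
  expect_true(all(oracle$correct["always0", ] == 1))
  expect_equal(oracle$accuracies[["always0"]], 1)
  # identical classifiers produce identical rows
  expect_equal(unname(oracle$correct[1, ]), unname(oracle$correct[3, ]))
  # accuracies equal an independent recount from stored predictions
  for (i in seq_len(nrow(oracle$correct))) {
    expect_equal(oracle$accuracies[[i]],
                 mean(oracle$predictions[i, ] == y_val))
  }
  expect_error(build_oracle_matrix(list(broken, broken), x_train, y_train,
                                   x_val, y_val))
})
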