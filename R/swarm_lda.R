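#' Search specification for LDA hyperparameter calibration
#'
#' Defines the bounded box over the configuration vector `[k, alpha, beta,
#' n_iter]`, the cluster-validity index used as fitness, and the
#' metaheuristic that explores the box. Default bounds keep the search at
#' desk scale: `k` in \[2, 100\], `alpha` and `beta` in \[0.01, 1\], `n_iter`
#' in \[50, 500\]; all are overridable.
#'
#' @param index_name fitness index: `"bic"`, `"ch"`, `"db"` or `"si"`.
#' @param params an [optimizer_params()] (stage `"lda"`).
#' @param k_bounds,alpha_bounds,beta_bounds,n_iter_bounds length-2 numeric
#'   bounds; `k_bounds[1]` must be at least 2 so a partition is possible.
#' @param lda_seed seed used for every Gibbs fit inside the fitness (one fit
#'   per candidate keeps the fitness deterministic in the candidate vector).
#' @param opt_seed seed for the metaheuristic.
#' @return an object of class `swarmlda_lda_search_spec`.
#' @export
lda_search_spec <- function(index_name = "si",
                            params = optimizer_params("ba", stage = "lda"),
                            k_bounds = c(2, 100),
                            alpha_bounds = c(0.01, 1),
                            beta_bounds = c(0.01, 1),
                            n_iter_bounds = c(50, 500),
                            lda_seed = 1L, opt_seed = 1L) {
  index_name <- match.arg(tolower(index_name), c("bic", "ch", "db", "si"))
  for (b in list(k_bounds, alpha_bounds, beta_bounds, n_iter_bounds)) {
    if (length(b) != 2L || b[1] > b[2] || any(b <= 0)) {
      stop_fmt("each bounds argument must be positive with lower <= upper")
    }
  }
  if (k_bounds[1] < 2) stop_fmt("k lower bound must be at least 2")
  structure(list(index_name = index_name, params = params,
                 lower = c(k_bounds[1], alpha_bounds[1], beta_bounds[1], n_iter_bounds[1]),
                 upper = c(k_bounds[2], alpha_bounds[2], beta_bounds[2], n_iter_bounds[2]),
                 lda_seed = assert_scalar_int(lda_seed, "lda_seed"),
                 opt_seed = assert_scalar_int(opt_seed, "opt_seed")),
            class = "swarmlda_lda_search_spec")
}

#' Decode an optimizer position into an LDA configuration
#'
#' `k` and `n_iter` are rounded to the nearest integer; `alpha` and `beta`
#' pass through unchanged. Idempotent on already-integral coordinates.
#'
#' @param vector numeric length-4 position `[k, alpha, beta, n_iter]`.
#' @return an [lda_config()].
#' @export
decode_config <- function(vector) {
  if (length(vector) != 4L) stop_fmt("configuration vector must have length 4")
  lda_config(k = round(vector[1]), alpha = vector[2], beta = vector[3],
             n_iter = round(vector[4]))
}

# Sentinel for partitions a validity index cannot rate (e.g. all documents
# dominated by one topic). Large finite so optimizer arithmetic stays clean.
FITNESS_SENTINEL <- -1e18

#' Fixed document representation used to rate candidate partitions
#'
#' Length-normalized term-frequency rows of the corpus. Internal validity
#' indices require a data representation that does not change with the
#' candidate model: rating each candidate's partition inside that candidate's
#' own topic space rewards low-dimensional embeddings per se (fewer topics
#' always look tighter), collapsing any search to the smallest admissible
#' `k`. Holding the points fixed in term space makes the indices compare
#' partitions, not embeddings.
#'
#' @param cc a [corpus()].
#' @return a dense M x V matrix of per-document term frequencies.
#' @export
document_points <- function(cc) {
  as.matrix(cc$counts / Matrix::rowSums(cc$counts))
}

#' Fitness of one LDA configuration
#'
#' Fits LDA with the candidate configuration, partitions documents by
#' dominant topic, scores that partition of the fixed [document_points()]
#' with the chosen validity index, and orients the score so that larger is
#' always better: CH and SI are returned as-is, BIC and DB negated.
#'
#' A candidate is rated only when its partition genuinely has `k` clusters:
#' if some topics dominate no document the fitted model is effectively a
#' smaller model mislabelled with a larger `k` (the indices cannot see the
#' unused topics, so every `k` above the effective cluster count would tie
#' and the calibrated `k` would be meaningless). Such candidates -- and any
#' partition an index cannot rate (`NA`/`-Inf` on the fitness scale,
#' including the single-cluster case) -- map to a large negative sentinel so
#' the optimizer is repelled rather than crashed.
#'
#' @param cc a [corpus()].
#' @param config an [lda_config()].
#' @param index_name `"bic"`, `"ch"`, `"db"` or `"si"`.
#' @param lda_seed seed for the Gibbs fit.
#' @param points optional precomputed [document_points()] matrix (avoids
#'   re-densifying the corpus on every candidate).
#' @return scalar fitness (larger is better).
#' @export
lda_config_fitness <- function(cc, config, index_name = "si", lda_seed = 1L,
                               points = NULL) {
  if (is.null(points)) points <- document_points(cc)
  model <- fit_lda(cc, config, seed = lda_seed)
  part <- dominant_topic_partition(model)
  if (length(unique(part)) < 2L || length(unique(part)) < config$k) {
    return(FITNESS_SENTINEL)
  }
  sc <- validity_score(points, part, index_name)
  fitness <- if (sc$higher_is_better) sc$value else -sc$value
  if (is.na(fitness)) return(FITNESS_SENTINEL)
  if (fitness == Inf) return(-FITNESS_SENTINEL)
  if (fitness == -Inf) return(FITNESS_SENTINEL)
  fitness
}

#' Search the LDA configuration space
#'
#' Wraps [optimize_metaheuristic()] around [lda_config_fitness()]: candidate
#' positions are decoded with [decode_config()], and a per-run cache keyed by
#' the decoded configuration avoids refitting duplicates (rounding of `k` and
#' `n_iter` makes collisions common).
#'
#' @param cc a [corpus()].
#' @param spec an [lda_search_spec()].
#' @return a list with `config` (the best decoded [lda_config()]), `result`
#'   (the raw optimizer output) and `evaluations` (a data.frame log of every
#'   distinct configuration evaluated, with its fitness).
#' @export
search_lda_config <- function(cc, spec) {
  if (!inherits(spec, "swarmlda_lda_search_spec")) {
    stop_fmt("'spec' must be an lda_search_spec")
  }
  cache <- new.env(parent = emptyenv())
  log_rows <- list()
  points <- document_points(cc)
  fitness_fn <- function(x) {
    cfg <- decode_config(x)
    key <- sprintf("%d|%.12g|%.12g|%d", cfg$k, cfg$alpha, cfg$beta, cfg$n_iter)
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- lda_config_fitness(cc, cfg, spec$index_name, spec$lda_seed,
                              points = points)
    cache[[key]] <- val
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      k = cfg$k, alpha = cfg$alpha, beta = cfg$beta, n_iter = cfg$n_iter,
      fitness = val)
    val
  }
  res <- optimize_metaheuristic(fitness_fn, spec$lower, spec$upper,
                                spec$params, seed = spec$opt_seed)
  list(config = decode_config(res$best_vector), result = res,
       evaluations = do.call(rbind, log_rows))
}

#' Topic-space representation of a train/test split
#'
#' Fits LDA on the training corpus and folds the test documents into the
#' trained topic space with the topics frozen, so no test information reaches
#' the topic model.
#'
#' @param train_corpus,test_corpus [corpus()] objects over the same
#'   vocabulary; `test_corpus` may be `NULL`.
#' @param config an [lda_config()].
#' @param seed seed for the fit; the fold-in uses `seed + 1`.
#' @param fold_in_sweeps Gibbs sweeps used for the fold-in.
#' @return a list with `theta_train`, `theta_test` (`NULL` if no test
#'   corpus) and `model`.
#' @export
represent_corpus <- function(train_corpus, test_corpus, config, seed = 1L,
                             fold_in_sweeps = 50L) {
  model <- fit_lda(train_corpus, config, seed = seed)
  theta_test <- NULL
  if (!is.null(test_corpus)) {
    theta_test <- fold_in(model, test_corpus, n_sweeps = fold_in_sweeps,
                          seed = seed + 1L)
  }
  list(theta_train = model$theta, theta_test = theta_test, model = model)
}
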