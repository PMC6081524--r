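#' Stratified tenfold plan with 6/2/2 rotations
#'
#' Instances are shuffled within class and dealt round-robin into ten folds,
#' so every fold mirrors the class distribution as closely as integer counts
#' allow. Five rotations then move a sliding window over the folds: rotation
#' `r` (0-based) tests on folds `{2r, 2r+1}`, validates on folds
#' `{(2r+2) mod 10, (2r+3) mod 10}` and trains on the remaining six, so each
#' fold serves as a test fold exactly once across the five rotations.
#'
#' @param labels per-instance class labels (length >= 10).
#' @param seed integer RNG seed for the within-class shuffle.
#' @return a list of class `swarmlda_fold_plan` with `folds` (list of 10
#'   disjoint index vectors) and `rotations` (list of 5 lists with `train`,
#'   `val`, `test` instance indices).
#' @export
make_fold_plan <- function(labels, seed = 1L) {
  n <- length(labels)
  if (n < 10L) stop_fmt("need at least 10 instances for a tenfold plan")
  if (min(table(labels)) < 10L) {
    warn_fmt("some class has fewer than 10 instances; stratification is best-effort")
  }
  fold_of <- integer(n)
  local_seed(seed, {
    offset <- 0L
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold_of[idx] <- ((offset + seq_along(idx) - 1L) %% 10L) + 1L
      offset <- offset + length(idx)
    }
  })
  folds <- lapply(1:10, function(f) which(fold_of == f))
  rotations <- lapply(0:4, function(r) {
    test_f <- c(2L * r, 2L * r + 1L)
    val_f <- c((2L * r + 2L) %% 10L, (2L * r + 3L) %% 10L)
    train_f <- setdiff(0:9, c(test_f, val_f))
    list(train = sort(unlist(folds[train_f + 1L])),
         val = sort(unlist(folds[val_f + 1L])),
         test = sort(unlist(folds[test_f + 1L])))
  })
  structure(list(folds = folds, rotations = rotations),
            class = "swarmlda_fold_plan")
}

#' Classification metrics
#'
#' `accuracy` is the fraction of exact matches. `macro_f` computes, per class
#' in the union of true and predicted labels, one-versus-all precision and
#' recall and their harmonic mean F (any 0/0 is taken as 0), then averages F
#' unweighted over classes. `micro_f` pools true positives, false positives
#' and false negatives over all classes before forming F; for single-label
#' multiclass prediction this equals accuracy.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @return a scalar in \[0, 1\].
#' @name classification_metrics
NULL

check_pair <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop_fmt("label vectors differ in length")
  if (length(y_true) == 0L) stop_fmt("empty label vectors")
}

#' @rdname classification_metrics
#' @export
accuracy <- function(y_true, y_pred) {
  check_pair(y_true, y_pred)
  mean(y_true == y_pred)
}

#' @rdname classification_metrics
#' @export
macro_f <- function(y_true, y_pred) {
  check_pair(y_true, y_pred)
  classes <- sort(unique(c(y_true, y_pred)))
  f <- vapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  mean(f)
}

#' @rdname classification_metrics
#' @export
micro_f <- function(y_true, y_pred) {
  check_pair(y_true, y_pred)
  classes <- sort(unique(c(y_true, y_pred)))
  tp <- sum(vapply(classes, function(cl) sum(y_true == cl & y_pred == cl), numeric(1)))
  fp <- sum(vapply(classes, function(cl) sum(y_true != cl & y_pred == cl), numeric(1)))
  fn <- sum(vapply(classes, function(cl) sum(y_true == cl & y_pred != cl), numeric(1)))
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

#' Row-subset of a corpus
#'
#' @param cc a [corpus()].
#' @param idx integer document indices.
#' @return a [corpus()] over the same vocabulary.
#' @export
corpus_subset <- function(cc, idx) {
  corpus(cc$counts[idx, , drop = FALSE], cc$terms, cc$doc_ids[idx])
}

#' Run the full two-stage categorization pipeline
#'
#' For each rotation of the tenfold 6/2/2 plan: (1) the LDA configuration is
#' either taken as fixed or searched on the training split with
#' [search_lda_config()]; (2) train, validation and test documents are
#' represented in topic space (validation and test by fold-in with frozen
#' topics); (3) the classifier library is trained on the training
#' representation and its correctness oracle built on validation; (4)
#' diversity matrices for the configured measures are combined and the
#' classifiers clustered and pruned; (5) the pruned ensemble votes on the
#' test split. Metrics are reported per rotation and as their mean.
#'
#' @param lc a [labeled_corpus()] with at least two classes.
#' @param lda an [lda_config()] (fixed) or [lda_search_spec()] (searched per
#'   rotation).
#' @param classifiers list of [classifier_spec()]; defaults to the fixture
#'   library.
#' @param measures diversity measures to combine; default the four-measure
#'   set `q`, `rho`, `dis`, `df`.
#' @param clustering_params [optimizer_params()] for the classifier
#'   clustering stage.
#' @param n_clusters requested classifier clusters (clamped below the
#'   library size).
#' @param seeds named list of integer seeds: `folds`, `lda`, `clustering`.
#' @param fold_in_sweeps Gibbs sweeps for representing held-out documents.
#' @param single_split run only the first rotation instead of all five.
#' @return a list of class `swarmlda_eval_report` with aggregate `accuracy`,
#'   `macro_f`, `micro_f`, a `per_rotation` data.frame, `ensemble_size`
#'   (mean over rotations) and `lda_config` (last rotation's configuration).
#' @export
run_pipeline <- function(lc, lda,
                         classifiers = fixture_classifier_library(),
                         measures = c("q", "rho", "dis", "df"),
                         clustering_params = optimizer_params("fa", stage = "clustering"),
                         n_clusters = 20L,
                         seeds = list(folds = 1L, lda = 1L, clustering = 1L),
                         fold_in_sweeps = 50L,
                         single_split = FALSE) {
  if (!inherits(lc, "swarmlda_labeled_corpus") || is.null(lc$labels)) {
    stop_fmt("run_pipeline needs a labelled corpus")
  }
  if (length(unique(lc$labels)) < 2L) stop_fmt("need at least two classes")
  fixed <- inherits(lda, "swarmlda_lda_config")
  if (!fixed && !inherits(lda, "swarmlda_lda_search_spec")) {
    stop_fmt("'lda' must be an lda_config or an lda_search_spec")
  }
  if (fixed && lda$k < 2L) {
    warn_fmt("k = %d yields a constant document representation; classification will be near chance", lda$k)
  }
  plan <- make_fold_plan(lc$labels, seed = seeds$folds)
  rotations <- if (single_split) plan$rotations[1L] else plan$rotations
  rows <- list()
  last_config <- NULL
  for (r in seq_along(rotations)) {
    rot <- rotations[[r]]
    row <- tryCatch({
      train_cc <- corpus_subset(lc$corpus, rot$train)
      val_cc <- corpus_subset(lc$corpus, rot$val)
      test_cc <- corpus_subset(lc$corpus, rot$test)
      y_train <- lc$labels[rot$train]
      y_val <- lc$labels[rot$val]
      y_test <- lc$labels[rot$test]

      config <- if (fixed) lda else search_lda_config(train_cc, lda)$config
      last_config <- config
      model <- fit_lda(train_cc, config, seed = seeds$lda)
      theta_train <- model$theta
      theta_val <- fold_in(model, val_cc, n_sweeps = fold_in_sweeps,
                           seed = seeds$lda + 1L)
      theta_test <- fold_in(model, test_cc, n_sweeps = fold_in_sweeps,
                            seed = seeds$lda + 2L)

      oracle <- build_oracle_matrix(classifiers, theta_train, y_train,
                                    theta_val, y_val)
      combined <- combine_matrices(lapply(measures, diversity_matrix,
                                          oracle = oracle))
      clust <- cluster_classifiers(combined, params = clustering_params,
                                   k = n_clusters, seed = seeds$clustering + r)
      pruned <- prune_ensemble(clust, oracle)

      member_specs <- classifiers[match(pruned$member_names,
                                        vapply(classifiers, `[[`, "", "name"))]
      preds <- t(vapply(member_specs, function(spec) {
        as.integer(spec$predict(spec$fit(theta_train, y_train), theta_test))
      }, integer(nrow(theta_test))))
      priors <- table(y_train) / length(y_train)
      voted <- majority_vote(preds, stats::setNames(as.numeric(priors),
                                                    names(priors)))
      data.frame(rotation = r,
                 accuracy = accuracy(y_test, voted),
                 macro_f = macro_f(y_test, voted),
                 micro_f = micro_f(y_test, voted),
                 ensemble_size = length(pruned$member_indices),
                 complete = TRUE)
    }, error = function(e) {
      warn_fmt("rotation %d failed: %s", r, conditionMessage(e))
      data.frame(rotation = r, accuracy = NA_real_, macro_f = NA_real_,
                 micro_f = NA_real_, ensemble_size = NA_integer_,
                 complete = FALSE)
    })
    rows[[r]] <- row
  }
  per_rotation <- do.call(rbind, rows)
  ok <- per_rotation$complete
  structure(list(
    accuracy = mean(per_rotation$accuracy[ok]),
    macro_f = mean(per_rotation$macro_f[ok]),
    micro_f = mean(per_rotation$micro_f[ok]),
    per_rotation = per_rotation,
    ensemble_size = mean(per_rotation$ensemble_size[ok]),
    lda_config = last_config
  ), class = "swarmlda_eval_report")
}

#' @export
print.swarmlda_eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> accuracy %.4f, macro-F %.4f, micro-F %.4f ",
                     "(mean over %d rotation(s); mean ensemble size %.1f)\n"),
              x$accuracy, x$macro_f, x$micro_f, nrow(x$per_rotation),
              x$ensemble_size))
  invisible(x)
}
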