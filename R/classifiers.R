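#' Base-classifier contract
#'
#' The ensemble stages are agnostic to the classification algorithms behind
#' them: any model obeying this fit/predict contract can be registered. `fit`
#' receives a numeric feature matrix (here, document-topic rows) and an
#' integer label vector and returns an opaque fitted state; `predict`
#' receives that state and a feature matrix and returns one label per row.
#' Classifiers must be deterministic given their own declared seed.
#'
#' @param name unique classifier name.
#' @param fit function `(x, y) -> state`.
#' @param predict function `(state, x) -> labels`.
#' @return an object of class `swarmlda_classifier`.
#' @export
classifier_spec <- function(name, fit, predict) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_fmt("classifier name must be a non-empty string")
  }
  if (!is.function(fit) || !is.function(predict)) {
    stop_fmt("fit and predict must be functions")
  }
  structure(list(name = name, fit = fit, predict = predict),
            class = "swarmlda_classifier")
}

# deterministic plurality vote: most frequent value, ties to smallest label
plurality <- function(v) {
  tab <- table(v)
  as.integer(names(tab)[which.max(tab)])
}

fit_centroids <- function(x, y) {
  classes <- sort(unique(y))
  cent <- do.call(rbind, lapply(classes, function(cl) {
    colMeans(x[y == cl, , drop = FALSE])
  }))
  list(classes = classes, centroids = cent)
}

predict_centroids <- function(state, x) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(state$centroids))) -
    2 * x %*% t(state$centroids) +
    outer(rep(1, nrow(x)), rowSums(state$centroids^2))
  state$classes[max.col(-d2, ties.method = "first")]
}

make_nearest_centroid <- function(name = "nearest_centroid") {
  classifier_spec(name, fit_centroids, predict_centroids)
}

make_multinomial <- function(name = "multinomial_lik", smooth = 0.01) {
  classifier_spec(
    name,
    fit = function(x, y) {
      classes <- sort(unique(y))
      prof <- do.call(rbind, lapply(classes, function(cl) {
        s <- colSums(x[y == cl, , drop = FALSE]) + smooth
        s / sum(s)
      }))
      prior <- vapply(classes, function(cl) mean(y == cl), numeric(1))
      list(classes = classes, log_prof = log(prof), log_prior = log(prior))
    },
    predict = function(state, x) {
      score <- x %*% t(state$log_prof) +
        outer(rep(1, nrow(x)), state$log_prior)
      state$classes[max.col(score, ties.method = "first")]
    }
  )
}

make_knn <- function(k, name = paste0("knn", k)) {
  classifier_spec(
    name,
    fit = function(x, y) list(x = x, y = y, k = k),
    predict = function(state, x) {
      d2 <- outer(rowSums(x^2), rep(1, nrow(state$x))) -
        2 * x %*% t(state$x) + outer(rep(1, nrow(x)), rowSums(state$x^2))
      apply(d2, 1, function(row) {
        nn <- order(row)[seq_len(min(state$k, length(row)))]
        plurality(state$y[nn])
      })
    }
  )
}

make_stump <- function(feature, name = paste0("stump_f", feature)) {
  classifier_spec(
    name,
    fit = function(x, y) {
      j <- min(feature, ncol(x))
      v <- x[, j]
      cuts <- sort(unique(v))
      cands <- if (length(cuts) > 1L) (head(cuts, -1) + cuts[-1]) / 2 else cuts
      if (length(cands) > 64L) {
        cands <- stats::quantile(v, probs = seq(0.02, 0.98, length.out = 64),
                                 names = FALSE)
      }
      best <- NULL; best_acc <- -1
      for (thr in cands) {
        left <- v <= thr
        if (!any(left) || all(left)) next
        lab_l <- plurality(y[left]); lab_r <- plurality(y[!left])
        acc <- mean(ifelse(left, lab_l, lab_r) == y)
        if (acc > best_acc) {
          best_acc <- acc
          best <- list(j = j, thr = thr, lab_l = lab_l, lab_r = lab_r)
        }
      }
      if (is.null(best)) {  # constant feature: predict overall majority
        best <- list(j = j, thr = Inf, lab_l = plurality(y), lab_r = plurality(y))
      }
      best
    },
    predict = function(state, x) {
      ifelse(x[, state$j] <= state$thr, state$lab_l, state$lab_r)
    }
  )
}

make_random_projection_centroid <- function(proj_seed, out_dim = 2L,
                                            name = paste0("rproj_centroid_s", proj_seed)) {
  classifier_spec(
    name,
    fit = function(x, y) {
      proj <- local_seed(proj_seed,
                         matrix(stats::rnorm(ncol(x) * out_dim), ncol(x), out_dim))
      st <- fit_centroids(x %*% proj, y)
      st$proj <- proj
      st
    },
    predict = function(state, x) predict_centroids(state, x %*% state$proj)
  )
}

#' Built-in fixture classifier library
#'
#' Twelve distinct base classifiers over numeric features, standing in for a
#' large heterogeneous model library: a multinomial-likelihood classifier, a
#' nearest-centroid classifier, k-nearest-neighbour for k in {1, 3, 5, 7},
#' three single-feature decision stumps, and three seeded
#' random-projection-plus-centroid variants. All are deterministic; the
#' projection classifiers derive their projections from fixed seeds.
#'
#' @param proj_seeds integer seeds for the three random-projection variants.
#' @return a list of [classifier_spec()] objects.
#' @export
fixture_classifier_library <- function(proj_seeds = c(11L, 23L, 47L)) {
  c(
    list(make_multinomial(), make_nearest_centroid()),
    lapply(c(1L, 3L, 5L, 7L), make_knn),
    lapply(1:3, make_stump),
    lapply(proj_seeds, make_random_projection_centroid)
  )
}

#' Fixture library with duplicate groups
#'
#' A small library built as groups of behaviourally identical classifiers
#' (same algorithm registered under several names), used to exercise the
#' pruning stage: duplicates have zero pairwise diversity and a working
#' pruner keeps at most one member per group.
#'
#' @param group_sizes integer vector; one group per element.
#' @return a list of [classifier_spec()] objects with names
#'   `"<base>_dup<i>"`.
#' @export
duplicate_group_library <- function(group_sizes = c(3L, 3L, 3L)) {
  constructors <- list(
    function(nm) make_multinomial(name = nm),
    function(nm) make_nearest_centroid(name = nm),
    function(nm) make_knn(3L, name = nm)
  )
  out <- list()
  for (g in seq_along(group_sizes)) {
    ctor <- constructors[[((g - 1L) %% length(constructors)) + 1L]]
    for (i in seq_len(group_sizes[g])) {
      out[[length(out) + 1L]] <- ctor(sprintf("group%d_dup%d", g, i))
    }
  }
  out
}
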