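#' Build the validation oracle matrix
#'
#' Fits every classifier on the training split and records, for each
#' validation instance, whether its prediction was correct. The resulting
#' binary classifier-by-instance matrix is the raw material of all pairwise
#' diversity measures. A classifier whose `fit` or `predict` raises an error
#' is excluded with a warning; at least two must survive.
#'
#' @param classifiers list of [classifier_spec()] objects.
#' @param x_train,y_train training features and labels.
#' @param x_val,y_val validation features and labels.
#' @return a list of class `swarmlda_oracle` with `correct` (L x n binary
#'   matrix, rownames = classifier names), `accuracies` (row means),
#'   `predictions` (L x n label matrix) and `names`.
#' @export
build_oracle_matrix <- function(classifiers, x_train, y_train, x_val, y_val) {
  if (length(classifiers) < 2L) stop_fmt("need at least two classifiers")
  if (nrow(x_train) == 0L || nrow(x_val) == 0L) {
    stop_fmt("train and validation sets must be nonempty")
  }
  nm <- vapply(classifiers, `[[`, "", "name")
  if (anyDuplicated(nm)) stop_fmt("classifier names must be unique")
  rows <- list()
  preds <- list()
  for (spec in classifiers) {
    res <- tryCatch({
      state <- spec$fit(x_train, y_train)
      p <- spec$predict(state, x_val)
      stopifnot(length(p) == length(y_val))
      p
    }, error = function(e) {
      warn_fmt("classifier '%s' failed and is excluded: %s",
               spec$name, conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      rows[[spec$name]] <- as.integer(res == y_val)
      preds[[spec$name]] <- res
    }
  }
  if (length(rows) < 2L) stop_fmt("fewer than two classifiers survived fitting")
  correct <- do.call(rbind, rows)
  structure(list(correct = correct,
                 accuracies = rowMeans(correct),
                 predictions = do.call(rbind, preds),
                 names = rownames(correct)),
            class = "swarmlda_oracle")
}

#' Joint correctness counts for a classifier pair
#'
#' Counts the 2x2 contingency of two classifiers' correctness over the
#' validation set: `n11` both correct, `n10` first correct only, `n01`
#' second correct only, `n00` both wrong.
#'
#' @param row_i,row_j equal-length binary (0/1) vectors.
#' @return a list with integer `n11`, `n10`, `n01`, `n00`.
#' @export
pair_counts <- function(row_i, row_j) {
  if (length(row_i) != length(row_j)) stop_fmt("rows differ in length")
  i <- as.logical(row_i); j <- as.logical(row_j)
  list(n11 = sum(i & j), n10 = sum(i & !j),
       n01 = sum(!i & j), n00 = sum(!i & !j))
}

MEASURE_NAMES <- c("q", "rho", "dis", "df", "kappa")

#' Pairwise diversity measure on joint correctness counts
#'
#' Implements the five measures on the 2x2 correct/incorrect table of a
#' classifier pair (n the validation size):
#' \itemize{
#'   \item `q` -- Q-statistic \eqn{(n_{11}n_{00}-n_{01}n_{10})/(n_{11}n_{00}+n_{01}n_{10})}
#'   \item `rho` -- phi correlation coefficient, same numerator over
#'     \eqn{\sqrt{(n_{11}+n_{10})(n_{01}+n_{00})(n_{11}+n_{01})(n_{10}+n_{00})}}
#'   \item `dis` -- disagreement \eqn{(n_{01}+n_{10})/n}
#'   \item `df` -- double fault \eqn{n_{00}/n}
#'   \item `kappa` -- Cohen's kappa on the 2x2 table,
#'     \eqn{(p_o-p_e)/(1-p_e)}
#' }
#' A vanishing denominator always comes with a vanishing numerator here and
#' is returned as 0 (no association measurable).
#'
#' @param counts a [pair_counts()] result.
#' @param measure one of `"q"`, `"rho"`, `"dis"`, `"df"`, `"kappa"`.
#' @return scalar value; `q`, `rho`, `kappa` lie in \[-1, 1\], `dis` and
#'   `df` in \[0, 1\].
#' @export
diversity_measure <- function(counts, measure) {
  measure <- match.arg(tolower(measure), MEASURE_NAMES)
  n11 <- counts$n11; n10 <- counts$n10; n01 <- counts$n01; n00 <- counts$n00
  n <- n11 + n10 + n01 + n00
  if (n <= 0) stop_fmt("empty contingency table")
  num <- n11 * n00 - n01 * n10
  switch(measure,
    q = {
      den <- n11 * n00 + n01 * n10
      if (den == 0) 0 else num / den
    },
    rho = {
      den <- sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
      if (den == 0) 0 else num / den
    },
    dis = (n01 + n10) / n,
    df = n00 / n,
    kappa = {
      p_o <- (n11 + n00) / n
      p_e <- ((n11 + n10) * (n11 + n01) + (n01 + n00) * (n10 + n00)) / n^2
      if (1 - p_e == 0) 0 else (p_o - p_e) / (1 - p_e)
    }
  )
}

#' All-pairs diversity matrix
#'
#' Applies [diversity_measure()] to every classifier pair of an oracle
#' matrix. The diagonal carries each measure's self-comparison value (1 for
#' `q`/`rho`/`kappa`, 0 for `dis`, the classifier's error rate for `df`).
#'
#' @param oracle a [build_oracle_matrix()] result.
#' @param measure measure name, see [diversity_measure()].
#' @return an object of class `swarmlda_diversity_matrix` with `measure` and
#'   the symmetric L x L `values`.
#' @export
diversity_matrix <- function(oracle, measure) {
  measure <- match.arg(tolower(measure), MEASURE_NAMES)
  L <- nrow(oracle$correct)
  vals <- matrix(0, L, L, dimnames = list(oracle$names, oracle$names))
  for (i in seq_len(L)) {
    for (j in i:L) {
      v <- diversity_measure(pair_counts(oracle$correct[i, ], oracle$correct[j, ]),
                             measure)
      vals[i, j] <- v
      vals[j, i] <- v
    }
  }
  structure(list(measure = measure, values = vals),
            class = "swarmlda_diversity_matrix")
}

#' Combine diversity matrices by normalized averaging
#'
#' Each component matrix is min-max normalized over its off-diagonal entries
#' to \[0, 1\]; measures for which large values mean similarity (`q`, `rho`,
#' `df`, `kappa`) are flipped as `1 - normalized` so that in every component
#' larger means more diverse; `dis` already points that way. The combined
#' value is the arithmetic mean across components, with the diagonal forced
#' to zero -- a classifier is not diverse from itself. A component whose
#' off-diagonal entries are all equal carries no ranking information and
#' contributes a uniform 0.5 (with a warning).
#'
#' @param matrices list of [diversity_matrix()] results over the same
#'   classifiers.
#' @return an object of class `swarmlda_combined_diversity` with `values`
#'   (L x L, entries in \[0, 1\], zero diagonal) and `component_measures`.
#' @export
combine_matrices <- function(matrices) {
  if (length(matrices) < 1L) stop_fmt("need at least one diversity matrix")
  L <- nrow(matrices[[1L]]$values)
  for (m in matrices) {
    if (!inherits(m, "swarmlda_diversity_matrix") || nrow(m$values) != L) {
      stop_fmt("all components must be diversity matrices over the same classifiers")
    }
  }
  off <- upper.tri(matrix(0, L, L)) | lower.tri(matrix(0, L, L))
  acc <- matrix(0, L, L)
  for (m in matrices) {
    v <- m$values
    rng <- range(v[off])
    if (diff(rng) == 0) {
      warn_fmt("'%s' matrix is constant off-diagonal; contributing 0.5 uniformly",
               m$measure)
      norm <- matrix(0.5, L, L)
    } else {
      norm <- (v - rng[1]) / diff(rng)
      if (m$measure != "dis") norm <- 1 - norm  # similarity-type: flip
    }
    acc <- acc + norm
  }
  combined <- acc / length(matrices)
  diag(combined) <- 0
  dimnames(combined) <- dimnames(matrices[[1L]]$values)
  structure(list(values = combined,
                 component_measures = vapply(matrices, `[[`, "", "measure")),
            class = "swarmlda_combined_diversity")
}

#' Enumerate all non-empty subsets of a measure list
#'
#' Binary-counter order: subset `i` contains element `j` iff bit `j` of `i`
#' is set, for `i = 1 .. 2^m - 1`. With the five shipped diversity measures
#' this yields the 31 candidate measure combinations the pruning stage can
#' evaluate.
#'
#' @param measures character vector of measure names.
#' @return list of character vectors, all `2^length(measures) - 1` non-empty
#'   subsets in deterministic order.
#' @export
enumerate_measure_subsets <- function(measures = MEASURE_NAMES) {
  m <- length(measures)
  if (m < 1L) stop_fmt("need at least one measure")
  lapply(seq_len(2^m - 1L), function(i) {
    measures[bitwAnd(i, 2^(seq_len(m) - 1L)) > 0L]
  })
}
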