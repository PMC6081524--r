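#' Internal cluster-validity indices
#'
#' Four internal indices rate a hard partition of points using only the data:
#' the Bayesian information criterion of a spherical-Gaussian cluster model
#' (`bic_score`, smaller is better), the Calinski-Harabasz ratio of between-
#' to within-cluster scatter (`calinski_harabasz`, higher is better), the
#' Davies-Bouldin index (`davies_bouldin`, smaller is better) and the
#' Silhouette index (`silhouette`, higher is better). In the LDA calibration
#' stage the points are the rows of the document-topic matrix and the
#' partition is the dominant-topic assignment.
#'
#' Degenerate situations are reported rather than hidden: indices requiring
#' at least two clusters return `NA` on a single-cluster partition; zero
#' within-cluster scatter makes `calinski_harabasz` return `Inf` (perfect
#' separation); coincident centroids make `davies_bouldin` return `Inf`
#' (worst case). The fitness wrapper maps these onto the optimizer's scale.
#'
#' @param points numeric N x d matrix of observations.
#' @param partition vector of N cluster labels (any type; empty labels are
#'   ignored).
#' @return a single numeric value (possibly `NA` or `Inf` as described).
#' @name cluster_validity
NULL

partition_pieces <- function(points, partition) {
  points <- as.matrix(points)
  if (nrow(points) == 0L) stop_fmt("no points")
  if (length(partition) != nrow(points)) {
    stop_fmt("partition length %d does not match %d points",
             length(partition), nrow(points))
  }
  f <- factor(partition)
  sizes <- as.integer(table(f))
  centroids <- rowsum(points, f) / sizes
  list(points = points, f = f, sizes = sizes, centroids = centroids,
       K = nlevels(f), N = nrow(points), d = ncol(points))
}

#' @rdname cluster_validity
#' @export
bic_score <- function(points, partition) {
  pp <- partition_pieces(points, partition)
  resid <- pp$points - pp$centroids[as.integer(pp$f), , drop = FALSE]
  sigma2 <- max(sum(resid^2) / (pp$N * pp$d), 1e-8)
  log_lik <- -pp$N * pp$d / 2 * log(2 * pi * sigma2) - sum(resid^2) / (2 * sigma2)
  v <- pp$K * pp$d + 1  # K cluster means plus the shared variance
  -log_lik + v * log(pp$N)
}

#' @rdname cluster_validity
#' @export
calinski_harabasz <- function(points, partition) {
  pp <- partition_pieces(points, partition)
  if (pp$K < 2L) return(NA_real_)
  if (pp$N <= pp$K) stop_fmt("need more points than clusters")
  grand <- colMeans(pp$points)
  trace_b <- sum(pp$sizes * rowSums(sweep(pp$centroids, 2, grand)^2))
  resid <- pp$points - pp$centroids[as.integer(pp$f), , drop = FALSE]
  trace_w <- sum(resid^2)
  if (trace_w == 0) return(Inf)
  (trace_b / (pp$K - 1)) / (trace_w / (pp$N - pp$K))
}

#' @rdname cluster_validity
#' @export
davies_bouldin <- function(points, partition) {
  pp <- partition_pieces(points, partition)
  if (pp$K < 2L) return(NA_real_)
  resid <- pp$points - pp$centroids[as.integer(pp$f), , drop = FALSE]
  scatter <- as.numeric(rowsum(sqrt(rowSums(resid^2)), pp$f)) / pp$sizes
  cd <- as.matrix(stats::dist(pp$centroids))
  ratio <- outer(scatter, scatter, "+") / cd
  diag(ratio) <- -Inf
  if (any(cd[upper.tri(cd)] == 0)) return(Inf)
  mean(apply(ratio, 1, max))
}

#' @rdname cluster_validity
#' @export
silhouette_index <- function(points, partition) {
  pp <- partition_pieces(points, partition)
  if (pp$K < 2L) return(NA_real_)
  D <- as.matrix(stats::dist(pp$points))
  ind <- stats::model.matrix(~ f - 1, data = list(f = pp$f))
  sums <- D %*% ind                      # N x K: summed distance to each cluster
  own <- as.integer(pp$f)
  n_own <- pp$sizes[own]
  a <- ifelse(n_own > 1L, sums[cbind(seq_len(pp$N), own)] / (n_own - 1L), 0)
  means <- sweep(sums, 2, pp$sizes, "/")
  means[cbind(seq_len(pp$N), own)] <- Inf
  b <- apply(means, 1, min)
  denom <- pmax(a, b)
  s <- ifelse(denom > 0, (b - a) / denom, 0)
  mean(s)
}

#' Score a partition with a named validity index
#'
#' Dispatch wrapper used by the LDA-configuration fitness: computes one of
#' the four indices and records its direction and any degenerate outcome.
#'
#' @inheritParams cluster_validity
#' @param index_name one of `"bic"`, `"ch"`, `"db"`, `"si"`.
#' @return a list with `index_name`, `value`, `higher_is_better` and
#'   `degenerate` (`TRUE` when the value is `NA` or infinite).
#' @export
validity_score <- function(points, partition, index_name = c("bic", "ch", "db", "si")) {
  index_name <- match.arg(tolower(index_name), c("bic", "ch", "db", "si"))
  value <- switch(index_name,
    bic = bic_score(points, partition),
    ch = calinski_harabasz(points, partition),
    db = davies_bouldin(points, partition),
    si = silhouette_index(points, partition)
  )
  list(index_name = index_name, value = value,
       higher_is_better = index_name %in% c("ch", "si"),
       degenerate = is.na(value) || is.infinite(value))
}
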