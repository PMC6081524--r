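#' @useDynLib swarmlda, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods as is new
#' @importFrom stats rgamma rnorm runif setNames
#' @importFrom utils combn head
NULL

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

assert_scalar_int <- function(x, name, min = -Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min) {
    stop_fmt("'%s' must be a single integer >= %s", name, format(min))
  }
  as.integer(x)
}

assert_scalar_pos <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x <= 0) {
    stop_fmt("'%s' must be a single positive number", name)
  }
  as.numeric(x)
}

#' Adjusted Rand index between two partitions
#'
#' Contingency-table form of the adjusted Rand index, used to compare a
#' dominant-topic partition against known ground-truth topic labels of a
#' synthetic corpus. This is diagnostic tooling, not a clustering fitness.
#'
#' @param a,b integer (or factor) label vectors of equal length.
#' @return ARI in \[-1, 1\]; 1 for identical partitions up to relabelling.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_fmt("label vectors differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
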