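#' LDA configuration
#'
#' The four tunables of Gibbs-sampled LDA that the calibration stage searches
#' over: the number of topics `k`, the per-document topic concentration
#' `alpha` (larger values smooth topic mixtures), the per-topic term
#' concentration `beta`, and the number of full Gibbs sweeps `n_iter`.
#'
#' @param k integer number of topics, >= 1.
#' @param alpha,beta positive Dirichlet concentrations.
#' @param n_iter integer number of Gibbs sweeps, >= 1.
#' @return an object of class `swarmlda_lda_config`.
#' @export
lda_config <- function(k, alpha, beta, n_iter) {
  structure(list(
    k = assert_scalar_int(k, "k", min = 1),
    alpha = assert_scalar_pos(alpha, "alpha"),
    beta = assert_scalar_pos(beta, "beta"),
    n_iter = assert_scalar_int(n_iter, "n_iter", min = 1)
  ), class = "swarmlda_lda_config")
}

#' @export
print.swarmlda_lda_config <- function(x, ...) {
  cat(sprintf("<lda_config> k=%d alpha=%g beta=%g n_iter=%d\n",
              x$k, x$alpha, x$beta, x$n_iter))
  invisible(x)
}

#' Fit LDA by collapsed Gibbs sampling
#'
#' Topic assignments are initialized uniformly at random, then `n_iter` full
#' sweeps of the collapsed conditional
#' \deqn{p(z_i = t \mid \cdot) \propto (n_{d,t}^{-i}+\alpha)\,
#'       (n_{t,w}^{-i}+\beta)/(n_t^{-i}+V\beta)}
#' are run. Point estimates are taken from the final state:
#' \eqn{\theta_{d,t} = (n_{d,t}+\alpha)/(N_d+k\alpha)} and
#' \eqn{\phi_{t,w} = (n_{t,w}+\beta)/(n_t+V\beta)}. No burn-in discarding or
#' sample averaging is applied; the fit is deterministic for a fixed seed.
#'
#' @param cc a [corpus()].
#' @param config an [lda_config()].
#' @param seed integer RNG seed governing initialization and all sweeps.
#' @return an object of class `swarmlda_topic_model` with row-stochastic
#'   `theta` (M x k) and `phi` (k x V), per-token assignments `z` (0-based,
#'   in [corpus_tokens()] order), the `config` and the `seed`.
#' @export
fit_lda <- function(cc, config, seed = 1L) {
  if (!is_corpus(cc)) stop_fmt("'cc' must be a swarmlda_corpus")
  if (!inherits(config, "swarmlda_lda_config")) stop_fmt("'config' must be an lda_config")
  seed <- assert_scalar_int(seed, "seed")
  tok <- corpus_tokens(cc)
  n_tok <- length(tok$doc)
  if (config$k > n_tok) {
    stop_fmt("k = %d exceeds the corpus token count %d", config$k, n_tok)
  }
  M <- nrow(cc$counts); V <- ncol(cc$counts); k <- config$k
  res <- local_seed(seed, {
    z0 <- sample.int(k, n_tok, replace = TRUE) - 1L
    cgs_fit(tok$doc, tok$word, M, V, k, config$alpha, config$beta,
            config$n_iter, z0)
  })
  nd <- Matrix::rowSums(cc$counts)
  theta <- (res$ndt + config$alpha) / (nd + k * config$alpha)
  phi <- (res$ntw + config$beta) / (res$nt + V * config$beta)
  structure(list(theta = theta, phi = phi, z = res$z,
                 ndt = res$ndt, config = config, seed = seed),
            class = "swarmlda_topic_model")
}

#' @export
print.swarmlda_topic_model <- function(x, ...) {
  cat(sprintf("<topic_model> %d docs x %d topics over %d terms (n_iter=%d, seed=%d)\n",
              nrow(x$theta), ncol(x$theta), ncol(x$phi), x$config$n_iter, x$seed))
  invisible(x)
}

#' Corpus log-likelihood at the fitted point estimates
#'
#' Evaluates \eqn{\sum_d \sum_{tokens} \log \sum_t \theta_{d,t}\phi_{t,w}},
#' i.e. the log-probability of the observed tokens under the mixture implied
#' by the fitted `theta` and `phi`.
#'
#' @param model a fitted [fit_lda()] model.
#' @param cc the corpus to score; its vocabulary size must match the model.
#' @return a finite number, non-positive since every token probability is at
#'   most 1.
#' @export
corpus_log_likelihood <- function(model, cc) {
  if (!inherits(model, "swarmlda_topic_model")) stop_fmt("'model' must be a topic_model")
  if (!is_corpus(cc)) stop_fmt("'cc' must be a swarmlda_corpus")
  if (ncol(cc$counts) != ncol(model$phi)) {
    stop_fmt("corpus has %d terms but model was fit on %d",
             ncol(cc$counts), ncol(model$phi))
  }
  if (nrow(cc$counts) != nrow(model$theta)) {
    stop_fmt("corpus has %d documents but model theta has %d rows",
             nrow(cc$counts), nrow(model$theta))
  }
  tm <- methods::as(cc$counts, "TsparseMatrix")
  p <- rowSums(model$theta[tm@i + 1L, , drop = FALSE] *
                 t(model$phi)[tm@j + 1L, , drop = FALSE])
  sum(tm@x * log(p))
}

#' Partition documents by dominant topic
#'
#' Assigns each document to its highest-probability topic (argmax of its
#' `theta` row), breaking ties toward the smallest topic index. Topics that
#' dominate no document simply do not appear among the cluster labels.
#'
#' @param model a fitted [fit_lda()] model.
#' @return integer vector of 1-based cluster labels, one per document.
#' @export
dominant_topic_partition <- function(model) {
  if (!inherits(model, "swarmlda_topic_model")) stop_fmt("'model' must be a topic_model")
  max.col(model$theta, ties.method = "first")
}

#' Represent new documents in a trained topic space
#'
#' Runs Gibbs sweeps over the new documents' tokens only, with the trained
#' topic--term distributions `phi` held fixed, then reads off
#' \eqn{\theta_{d,t} = (n_{d,t}+\alpha)/(N_d+k\alpha)}. This is the standard
#' fold-in: held-out documents never influence the topics.
#'
#' @param model a fitted [fit_lda()] model.
#' @param new_corpus a [corpus()] over the same vocabulary.
#' @param n_sweeps number of Gibbs sweeps over the new tokens.
#' @param seed integer RNG seed.
#' @return a row-stochastic matrix with one row per new document.
#' @export
fold_in <- function(model, new_corpus, n_sweeps = 50L, seed = 1L) {
  if (!inherits(model, "swarmlda_topic_model")) stop_fmt("'model' must be a topic_model")
  if (!is_corpus(new_corpus)) stop_fmt("'new_corpus' must be a swarmlda_corpus")
  if (ncol(new_corpus$counts) != ncol(model$phi)) {
    stop_fmt("vocabulary mismatch: corpus has %d terms, model %d",
             ncol(new_corpus$counts), ncol(model$phi))
  }
  n_sweeps <- assert_scalar_int(n_sweeps, "n_sweeps", min = 1)
  seed <- assert_scalar_int(seed, "seed")
  k <- ncol(model$theta)
  alpha <- model$config$alpha
  tok <- corpus_tokens(new_corpus)
  M <- nrow(new_corpus$counts)
  ndt <- local_seed(seed, {
    z0 <- sample.int(k, length(tok$doc), replace = TRUE) - 1L
    cgs_fold_in(tok$doc, tok$word, M, model$phi, alpha, n_sweeps, z0)
  })
  nd <- Matrix::rowSums(new_corpus$counts)
  (ndt + alpha) / (nd + k * alpha)
}

#' Serialize / restore a topic model as plain text
#'
#' Writes `theta.tsv`, `phi.tsv` and `config.yaml` into a directory.
#'
#' @param model a fitted [fit_lda()] model.
#' @param dir directory to create/write into.
#' @return `save_topic_model` returns the directory invisibly;
#'   `load_topic_model` returns a `swarmlda_topic_model` (without the
#'   per-token `z` state, which is not serialized).
#' @export
save_topic_model <- function(model, dir) {
  if (!inherits(model, "swarmlda_topic_model")) stop_fmt("'model' must be a topic_model")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(model$theta, file.path(dir, "theta.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(model$phi, file.path(dir, "phi.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  yaml::write_yaml(c(unclass(model$config), seed = model$seed),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname save_topic_model
#' @export
load_topic_model <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  theta <- as.matrix(utils::read.table(file.path(dir, "theta.tsv"), sep = "\t"))
  phi <- as.matrix(utils::read.table(file.path(dir, "phi.tsv"), sep = "\t"))
  dimnames(theta) <- NULL; dimnames(phi) <- NULL
  structure(list(theta = theta, phi = phi, z = NULL, ndt = NULL,
                 config = lda_config(cfg$k, cfg$alpha, cfg$beta, cfg$n_iter),
                 seed = cfg$seed),
            class = "swarmlda_topic_model")
}
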