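#' Specification of a synthetic corpus
#'
#' Parameters of the LDA generative process used to simulate a corpus:
#' `k_true` topics over a `V`-term vocabulary, `M` documents of exactly
#' `doc_len` tokens, with symmetric Dirichlet concentrations `alpha` (topic
#' mixture per document) and `beta` (term distribution per topic).
#'
#' @param k_true,V,M,doc_len positive integer sizes.
#' @param alpha,beta positive Dirichlet concentrations.
#' @param seed integer RNG seed; the generator is bit-identical for a fixed
#'   spec.
#' @return an object of class `swarmlda_synth_spec`.
#' @export
synth_spec <- function(k_true, V, M, doc_len, alpha, beta, seed = 1L) {
  out <- list(
    k_true = assert_scalar_int(k_true, "k_true", min = 1),
    V = assert_scalar_int(V, "V", min = 1),
    M = assert_scalar_int(M, "M", min = 1),
    doc_len = assert_scalar_int(doc_len, "doc_len", min = 1),
    alpha = assert_scalar_pos(alpha, "alpha"),
    beta = assert_scalar_pos(beta, "beta"),
    seed = assert_scalar_int(seed, "seed")
  )
  structure(out, class = "swarmlda_synth_spec")
}

# One draw from a symmetric Dirichlet via normalized gamma variates.
rdirichlet_sym <- function(n, dim, concentration) {
  g <- matrix(stats::rgamma(n * dim, shape = concentration, rate = 1),
              nrow = n, ncol = dim)
  # guard against all-zero rows at extreme concentrations
  zero <- rowSums(g) == 0
  if (any(zero)) {
    hot <- sample.int(dim, sum(zero), replace = TRUE)
    g[cbind(which(zero), hot)] <- 1
  }
  g / rowSums(g)
}

#' Generate a synthetic corpus from the LDA generative process
#'
#' Draws topic--term distributions `phi_k ~ Dirichlet(beta * 1_V)`, then for
#' each document a topic mixture `theta_d ~ Dirichlet(alpha * 1_k)` and
#' `doc_len` tokens via `z ~ Categorical(theta_d)`, `w ~ Categorical(phi_z)`.
#' The class label of a document is its dominant topic (0-based), giving the
#' classification stages a label signal aligned with the representation the
#' pipeline learns.
#'
#' @param spec a [synth_spec()].
#' @return a list with `labeled` (a [labeled_corpus()]) and `truth`, a list
#'   holding `theta_true` (M x k row-stochastic), `phi_true` (k x V
#'   row-stochastic), `z_true` (per-token topic ids, 0-based, parallel to
#'   [corpus_tokens()] order) and `dominant_topic` (per-document argmax of
#'   `theta_true`, 0-based).
#' @export
generate_synthetic_corpus <- function(spec) {
  if (!inherits(spec, "swarmlda_synth_spec")) stop_fmt("'spec' must be a synth_spec")
  local_seed(spec$seed, {
    k <- spec$k_true; V <- spec$V; M <- spec$M; L <- spec$doc_len
    phi <- rdirichlet_sym(k, V, spec$beta)
    theta <- rdirichlet_sym(M, k, spec$alpha)
    z <- integer(M * L)
    w <- integer(M * L)
    for (d in seq_len(M)) {
      idx <- ((d - 1L) * L + 1L):(d * L)
      zd <- sample.int(k, L, replace = TRUE, prob = theta[d, ])
      wd <- integer(L)
      for (t in unique(zd)) {
        sel <- zd == t
        wd[sel] <- sample.int(V, sum(sel), replace = TRUE, prob = phi[t, ])
      }
      z[idx] <- zd
      w[idx] <- wd
    }
    doc <- rep(seq_len(M), each = L)
    m <- Matrix::sparseMatrix(i = doc, j = w, x = 1, dims = c(M, V))
    dominant <- max.col(theta, ties.method = "first") - 1L
    if (length(unique(dominant)) < k) {
      warn_fmt("only %d of %d topics appear as a dominant topic",
               length(unique(dominant)), k)
    }
    terms <- sprintf("w%0*d", nchar(V), seq_len(V))
    cc <- corpus(m, terms)
    # reorder token-level truth to the canonical corpus_tokens() order
    ord <- order(doc - 1L, w - 1L)
    list(
      labeled = labeled_corpus(cc, dominant),
      truth = list(theta_true = theta, phi_true = phi,
                   z_true = z[ord] - 1L, dominant_topic = dominant)
    )
  })
}
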