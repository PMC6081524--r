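#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for LDA. Tokens are flattened (doc, word) pairs,
// both 0-based. z_init supplies the initial per-token topic assignment
// (0-based); the caller draws it from R's RNG so that a single seed governs
// the whole fit. Sampling consumes unif_rand(), i.e. R's RNG stream.
//
// Full conditional for token i in document d with word w:
//   p(z_i = t | .) propto (n_dt^{-i} + alpha) * (n_tw^{-i} + beta) / (n_t^{-i} + V beta)
//
// Count arrays are laid out topic-contiguous (stride K) so the inner loop
// over topics walks three contiguous buffers.
// [[Rcpp::export]]
List cgs_fit(IntegerVector doc, IntegerVector word, int n_docs, int n_terms,
             int n_topics, double alpha, double beta, int n_iter,
             IntegerVector z_init) {
  const int T = doc.size();
  const int K = n_topics;
  IntegerVector z = clone(z_init);
  std::vector<int> ndt((size_t)n_docs * K, 0);  // [d*K + t]
  std::vector<int> ntw((size_t)n_terms * K, 0); // [w*K + t]
  std::vector<int> nt(K, 0);
  for (int i = 0; i < T; ++i) {
    ndt[(size_t)doc[i] * K + z[i]]++;
    ntw[(size_t)word[i] * K + z[i]]++;
    nt[z[i]]++;
  }
  std::vector<double> p(K);
  const double vbeta = n_terms * beta;
  for (int iter = 0; iter < n_iter; ++iter) {
    for (int i = 0; i < T; ++i) {
      const int d = doc[i], w = word[i];
      int t = z[i];
      int* nd = &ndt[(size_t)d * K];
      int* nw = &ntw[(size_t)w * K];
      nd[t]--; nw[t]--; nt[t]--;
      double tot = 0.0;
      for (int j = 0; j < K; ++j) {
        p[j] = (nd[j] + alpha) * (nw[j] + beta) / (nt[j] + vbeta);
        tot += p[j];
      }
      double u = unif_rand() * tot;
      double cum = 0.0;
      t = K - 1;
      for (int j = 0; j < K; ++j) {
        cum += p[j];
        if (u < cum) { t = j; break; }
      }
      z[i] = t;
      nd[t]++; nw[t]++; nt[t]++;
    }
  }
  // repack counts as R matrices (doc x topic, topic x term)
  IntegerMatrix ndt_out(n_docs, K);
  for (int d = 0; d < n_docs; ++d)
    for (int t = 0; t < K; ++t) ndt_out(d, t) = ndt[(size_t)d * K + t];
  IntegerMatrix ntw_out(K, n_terms);
  for (int w = 0; w < n_terms; ++w)
    for (int t = 0; t < K; ++t) ntw_out(t, w) = ntw[(size_t)w * K + t];
  return List::create(_["z"] = z, _["ndt"] = ndt_out, _["ntw"] = ntw_out,
                      _["nt"] = IntegerVector(nt.begin(), nt.end()));
}

// Fold new documents into a trained topic space: Gibbs sweeps over the new
// tokens only, with the topic-term distributions phi frozen.
//   p(z_i = t | .) propto (n_dt^{-i} + alpha) * phi(t, w)
// [[Rcpp::export]]
IntegerMatrix cgs_fold_in(IntegerVector doc, IntegerVector word, int n_docs,
                          NumericMatrix phi, double alpha, int n_sweeps,
                          IntegerVector z_init) {
  const int T = doc.size();
  const int K = phi.nrow();
  const int V = phi.ncol();
  IntegerVector z = clone(z_init);
  std::vector<int> ndt((size_t)n_docs * K, 0);
  for (int i = 0; i < T; ++i) ndt[(size_t)doc[i] * K + z[i]]++;
  // phi transposed to word-major for contiguous access
  std::vector<double> phiw((size_t)V * K);
  for (int w = 0; w < V; ++w)
    for (int t = 0; t < K; ++t) phiw[(size_t)w * K + t] = phi(t, w);
  std::vector<double> p(K);
  for (int iter = 0; iter < n_sweeps; ++iter) {
    for (int i = 0; i < T; ++i) {
      const int d = doc[i], w = word[i];
      int t = z[i];
      int* nd = &ndt[(size_t)d * K];
      const double* ph = &phiw[(size_t)w * K];
      nd[t]--;
      double tot = 0.0;
      for (int j = 0; j < K; ++j) {
        p[j] = (nd[j] + alpha) * ph[j];
        tot += p[j];
      }
      double u = unif_rand() * tot;
      double cum = 0.0;
      t = K - 1;
      for (int j = 0; j < K; ++j) {
        cum += p[j];
        if (u < cum) { t = j; break; }
      }
      z[i] = t;
      nd[t]++;
    }
  }
  IntegerMatrix ndt_out(n_docs, K);
  for (int d = 0; d < n_docs; ++d)
    for (int t = 0; t < K; ++t) ndt_out(d, t) = ndt[(size_t)d * K + t];
  return ndt_out;
}
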