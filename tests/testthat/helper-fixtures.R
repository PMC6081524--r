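# Shared synthetic fixtures, built once per test run (cached in this env).
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# the standard topic-recovery corpus: 5 topics, 200 docs x 50 tokens
std_synth <- function() {
  cached("std", function() {
    generate_synthetic_corpus(synth_spec(k_true = 5, V = 100, M = 200,
                                         doc_len = 50, alpha = 0.1,
                                         beta = 0.01, seed = 7))
  })
}

# the standard classification fixture: 5 classes, 500 docs x 60 tokens
pipeline_synth <- function() {
  cached("pipeline", function() {
    generate_synthetic_corpus(synth_spec(k_true = 5, V = 150, M = 500,
                                         doc_len = 60, alpha = 0.1,
                                         beta = 0.01, seed = 11))
  })
}

# topic model fitted at the true configuration of std_synth()
std_model <- function() {
  cached("std_model", function() {
    fit_lda(std_synth()$labeled$corpus, lda_config(5, 0.1, 0.01, 300), seed = 1)
  })
}

# topic-space representation of a 6/2/2 split of pipeline_synth()
pipeline_split <- function() {
  cached("pipeline_split", function() {
    gen <- pipeline_synth()
    plan <- make_fold_plan(gen$labeled$labels, seed = 1)
    rot <- plan$rotations[[1]]
    cc <- gen$labeled$corpus
    model <- fit_lda(corpus_subset(cc, rot$train), lda_config(5, 0.1, 0.01, 200),
                     seed = 1)
    list(
      rot = rot,
      y_train = gen$labeled$labels[rot$train],
      y_val = gen$labeled$labels[rot$val],
      y_test = gen$labeled$labels[rot$test],
      theta_train = model$theta,
      theta_val = fold_in(model, corpus_subset(cc, rot$val), seed = 2),
      theta_test = fold_in(model, corpus_subset(cc, rot$test), seed = 3)
    )
  })
}

# validation oracle for the fixture library on the pipeline split
std_oracle <- function() {
  cached("std_oracle", function() {
    sp <- pipeline_split()
    build_oracle_matrix(fixture_classifier_library(), sp$theta_train, sp$y_train,
                        sp$theta_val, sp$y_val)
  })
}

random_oracle <- function(L = 6, n = 30, seed = 42) {
  set.seed(seed)
  correct <- matrix(rbinom(L * n, 1, runif(L, 0.3, 0.9)), L, n,
                    dimnames = list(paste0("c", 1:L), NULL))
  structure(list(correct = correct, accuracies = rowMeans(correct),
                 predictions = NULL, names = rownames(correct)),
            class = "swarmlda_oracle")
}
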