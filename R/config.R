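PIPELINE_SCHEMA <- list(
  corpus = c("prefix", "matrix", "vocab", "labels"),
  lda = c("mode", "k", "alpha", "beta", "n_iter", "index", "algorithm",
          "population_size", "n_iterations", "k_bounds", "alpha_bounds",
          "beta_bounds", "n_iter_bounds"),
  pruning = c("measures", "algorithm", "k", "population_size", "n_iterations",
              "params"),
  classifiers = character(0),
  seeds = c("synth", "folds", "lda", "opt", "clustering"),
  fold_in_sweeps = character(0),
  single_split = character(0),
  output = character(0)
)

check_keys <- function(cfg, schema = PIPELINE_SCHEMA, path = "") {
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown)) {
    stop_fmt("unknown configuration key%s: %s",
             if (length(unknown) > 1) "s" else "",
             paste0(path, unknown, collapse = ", "))
  }
  for (key in names(cfg)) {
    allowed <- schema[[key]]
    if (length(allowed) && is.list(cfg[[key]])) {
      sub <- setdiff(names(cfg[[key]]), allowed)
      if (length(sub)) {
        stop_fmt("unknown configuration key%s: %s",
                 if (length(sub) > 1) "s" else "",
                 paste0(path, key, ".", sub, collapse = ", "))
      }
    }
  }
  invisible(TRUE)
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML pipeline configuration, rejects unknown keys (naming the
#' offending key path), and fills defaults: a searched LDA stage defaults to
#' the bat algorithm with the Silhouette index; the pruning stage defaults to
#' firefly clustering with its shipped parameter set (alpha 0.6, gamma 0.3,
#' delta 0.95, k = 20) and the four-measure combination `q`, `rho`, `dis`,
#' `df`; all seeds default to 1.
#'
#' @param path YAML file path.
#' @return a validated list of class `swarmlda_pipeline_config` with every
#'   default resolved (suitable for [save_config()] round trips).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_fmt("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  as_pipeline_config(raw)
}

#' @rdname load_config
#' @param cfg a (possibly partial) configuration list.
#' @export
as_pipeline_config <- function(cfg) {
  if (is.null(cfg)) cfg <- list()
  check_keys(cfg)
  lda <- cfg$lda
  if (is.null(lda)) lda <- list()
  if (is.null(lda$mode)) lda$mode <- if (!is.null(lda$k)) "fixed" else "search"
  if (!lda$mode %in% c("fixed", "search")) {
    stop_fmt("lda.mode must be 'fixed' or 'search'")
  }
  if (lda$mode == "fixed") {
    for (f in c("k", "alpha", "beta", "n_iter")) {
      if (is.null(lda[[f]])) stop_fmt("fixed LDA configuration requires lda.%s", f)
    }
  } else {
    if (is.null(lda$index)) lda$index <- "si"
    if (is.null(lda$algorithm)) lda$algorithm <- "ba"
    if (is.null(lda$population_size)) lda$population_size <- 20L
    if (is.null(lda$n_iterations)) lda$n_iterations <- 20L
    if (is.null(lda$k_bounds)) lda$k_bounds <- c(2, 100)
    if (is.null(lda$alpha_bounds)) lda$alpha_bounds <- c(0.01, 1)
    if (is.null(lda$beta_bounds)) lda$beta_bounds <- c(0.01, 1)
    if (is.null(lda$n_iter_bounds)) lda$n_iter_bounds <- c(50, 500)
  }
  pruning <- cfg$pruning
  if (is.null(pruning)) pruning <- list()
  if (is.null(pruning$measures)) pruning$measures <- c("q", "rho", "dis", "df")
  pruning$measures <- vapply(pruning$measures,
                             function(m) match.arg(tolower(m), MEASURE_NAMES), "")
  names(pruning$measures) <- NULL
  if (is.null(pruning$algorithm)) pruning$algorithm <- "fa"
  if (is.null(pruning$k)) pruning$k <- 20L
  if (is.null(pruning$population_size)) pruning$population_size <- 20L
  if (is.null(pruning$n_iterations)) pruning$n_iterations <- 20L
  if (is.null(pruning$params)) pruning$params <- list()
  # resolve the full clustering optimizer parameter set so the manifest is
  # self-contained
  resolved <- do.call(optimizer_params,
                      c(list(algorithm = pruning$algorithm, stage = "clustering",
                             population_size = pruning$population_size,
                             n_iterations = pruning$n_iterations),
                        pruning$params))
  pruning$params <- unclass(resolved)[setdiff(names(unclass(resolved)),
                                              c("algorithm", "stage",
                                                "population_size", "n_iterations"))]
  classifiers <- cfg$classifiers
  if (is.null(classifiers)) classifiers <- "fixture"
  if (!classifiers %in% c("fixture", "duplicate_groups")) {
    stop_fmt("classifiers must be 'fixture' or 'duplicate_groups'")
  }
  seeds <- cfg$seeds
  if (is.null(seeds)) seeds <- list()
  for (s in c("synth", "folds", "lda", "opt", "clustering")) {
    if (is.null(seeds[[s]])) seeds[[s]] <- 1L
    seeds[[s]] <- assert_scalar_int(seeds[[s]], paste0("seeds.", s))
  }
  seeds <- seeds[c("synth", "folds", "lda", "opt", "clustering")]
  out <- list(
    corpus = cfg$corpus,
    lda = lda,
    pruning = pruning,
    classifiers = classifiers,
    seeds = seeds,
    fold_in_sweeps = if (is.null(cfg$fold_in_sweeps)) 50L else
      assert_scalar_int(cfg$fold_in_sweeps, "fold_in_sweeps", min = 1),
    single_split = isTRUE(cfg$single_split),
    output = cfg$output
  )
  structure(out, class = "swarmlda_pipeline_config")
}

#' Write a pipeline configuration to YAML
#'
#' Inverse of [load_config()]: a dumped configuration loads back to an
#' identical resolved configuration.
#'
#' @param cfg a `swarmlda_pipeline_config`.
#' @param path output YAML path.
#' @return the path, invisibly.
#' @export
save_config <- function(cfg, path) {
  if (!inherits(cfg, "swarmlda_pipeline_config")) {
    stop_fmt("'cfg' must be a pipeline config")
  }
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Materialize the config's pieces into runnable objects.
config_lda_stage <- function(cfg) {
  if (cfg$lda$mode == "fixed") {
    lda_config(cfg$lda$k, cfg$lda$alpha, cfg$lda$beta, cfg$lda$n_iter)
  } else {
    lda_search_spec(
      index_name = cfg$lda$index,
      params = optimizer_params(cfg$lda$algorithm, stage = "lda",
                                population_size = cfg$lda$population_size,
                                n_iterations = cfg$lda$n_iterations),
      k_bounds = cfg$lda$k_bounds, alpha_bounds = cfg$lda$alpha_bounds,
      beta_bounds = cfg$lda$beta_bounds, n_iter_bounds = cfg$lda$n_iter_bounds,
      lda_seed = cfg$seeds$lda, opt_seed = cfg$seeds$opt
    )
  }
}

config_classifiers <- function(cfg) {
  switch(cfg$classifiers,
         fixture = fixture_classifier_library(),
         duplicate_groups = duplicate_group_library())
}

config_clustering_params <- function(cfg) {
  do.call(optimizer_params,
          c(list(algorithm = cfg$pruning$algorithm, stage = "clustering",
                 population_size = cfg$pruning$population_size,
                 n_iterations = cfg$pruning$n_iterations),
            cfg$pruning$params))
}
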