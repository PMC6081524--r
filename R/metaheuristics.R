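#' Parameters of a population metaheuristic
#'
#' Builds the parameter set for one of the five optimizers: genetic algorithm
#' (`"ga"`), particle swarm (`"pso"`), firefly (`"fa"`), cuckoo search
#' (`"csa"`) or bat algorithm (`"ba"`). Defaults follow the shipped
#' configuration for each stage of the pipeline: `stage = "lda"` gives the
#' hyperparameter-calibration defaults (e.g. firefly alpha 0.8, gamma 0.5,
#' delta 0.85; cuckoo p_a 0.5; bat loudness 0.4, pulse rate 0.4), while
#' `stage = "clustering"` gives the ensemble-pruning defaults (firefly alpha
#' 0.6, gamma 0.3, delta 0.95; cuckoo p_a 0.3; bat loudness 0.5, pulse rate
#' 0.5; PSO inertia 0.70 with c1 = c2 = 1.5). Both stages default to a
#' population of 20 evolved for 20 iterations.
#'
#' @param algorithm one of `"ga"`, `"pso"`, `"fa"`, `"csa"`, `"ba"`.
#' @param stage `"lda"` or `"clustering"`; selects the default set.
#' @param population_size,n_iterations population and generation budget.
#' @param ... algorithm-specific overrides: GA `crossover_prob`,
#'   `mutation_prob`; PSO `inertia_weight`, `individual_weight` (c1),
#'   `social_weight` (c2); FA `alpha`, `gamma`, `delta`; CSA `p_a`; BA
#'   `loudness`, `pulse_rate`, `fq_min`, `fq_max`.
#' @return an object of class `swarmlda_optimizer_params`.
#' @export
optimizer_params <- function(algorithm = c("ga", "pso", "fa", "csa", "ba"),
                             stage = c("lda", "clustering"),
                             population_size = 20L, n_iterations = 20L, ...) {
  algorithm <- match.arg(tolower(algorithm[1L]), c("ga", "pso", "fa", "csa", "ba"))
  stage <- match.arg(stage)
  defaults <- switch(algorithm,
    ga = list(crossover_prob = 0.6, mutation_prob = 0.033),
    pso = if (stage == "lda") {
      list(inertia_weight = 0.33, individual_weight = 0.34, social_weight = 0.33)
    } else {
      list(inertia_weight = 0.70, individual_weight = 1.5, social_weight = 1.5)
    },
    fa = if (stage == "lda") list(alpha = 0.8, gamma = 0.5, delta = 0.85)
         else list(alpha = 0.6, gamma = 0.3, delta = 0.95),
    csa = list(p_a = if (stage == "lda") 0.5 else 0.3),
    ba = if (stage == "lda") {
      list(loudness = 0.4, pulse_rate = 0.4, fq_min = 0, fq_max = 2)
    } else {
      list(loudness = 0.5, pulse_rate = 0.5, fq_min = 0, fq_max = 2)
    }
  )
  extra <- list(...)
  unknown <- setdiff(names(extra), names(defaults))
  if (length(unknown)) {
    stop_fmt("unknown %s parameter(s): %s", algorithm,
             paste(unknown, collapse = ", "))
  }
  defaults[names(extra)] <- extra
  probs <- intersect(names(defaults),
                     c("crossover_prob", "mutation_prob", "p_a", "pulse_rate"))
  for (p in probs) {
    if (defaults[[p]] < 0 || defaults[[p]] > 1) stop_fmt("'%s' must lie in [0,1]", p)
  }
  structure(c(list(
    algorithm = algorithm, stage = stage,
    population_size = assert_scalar_int(population_size, "population_size", min = 2),
    n_iterations = assert_scalar_int(n_iterations, "n_iterations", min = 1)
  ), defaults), class = "swarmlda_optimizer_params")
}

#' @export
print.swarmlda_optimizer_params <- function(x, ...) {
  specific <- unclass(x)
  specific <- specific[setdiff(names(specific),
                               c("algorithm", "stage", "population_size", "n_iterations"))]
  cat(sprintf("<optimizer_params> %s (%s stage), pop %d, %d iterations\n  %s\n",
              toupper(x$algorithm), x$stage, x$population_size, x$n_iterations,
              paste(names(specific), unlist(specific), sep = "=", collapse = ", ")))
  invisible(x)
}

clip_box <- function(x, lower, upper) pmin(pmax(x, lower), upper)

# Mantegna Levy step with stability exponent 1.5, one draw per dimension.
levy_step <- function(d, exponent = 1.5) {
  sigma_u <- (gamma(1 + exponent) * sin(pi * exponent / 2) /
                (gamma((1 + exponent) / 2) * exponent * 2^((exponent - 1) / 2)))^(1 / exponent)
  u <- stats::rnorm(d, sd = sigma_u)
  v <- stats::rnorm(d)
  u / abs(v)^(1 / exponent)
}

#' Maximize a fitness function over a box with a population metaheuristic
#'
#' All five algorithms share the same contract: the population is initialized
#' uniformly at random inside the box, exactly `n_iterations` generation
#' updates are run, every candidate is clipped to the box before evaluation,
#' the best solution ever seen is tracked elitistically, and the whole run is
#' deterministic for a fixed seed. A fitness evaluating to `NA`/`NaN` is
#' treated as `-Inf` with a warning.
#'
#' @param fitness_fn function of a numeric vector returning a scalar fitness
#'   (larger is better).
#' @param lower,upper numeric vectors of per-dimension box bounds,
#'   elementwise `lower < upper`.
#' @param params an [optimizer_params()].
#' @param seed integer RNG seed.
#' @return a list with `best_vector`, `best_fitness`, `history` (best fitness
#'   after each iteration, non-decreasing) and `n_evaluations`.
#' @export
optimize_metaheuristic <- function(fitness_fn, lower, upper, params, seed = 1L) {
  if (!inherits(params, "swarmlda_optimizer_params")) {
    stop_fmt("'params' must be optimizer_params")
  }
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  # equal bounds pin a dimension to a constant (used e.g. to fix k)
  if (length(lower) != length(upper) || any(lower > upper) || all(lower == upper)) {
    stop_fmt("bounds must satisfy lower <= upper with at least one free dimension")
  }
  seed <- assert_scalar_int(seed, "seed")
  n_eval <- 0L
  evaluate <- function(x) {
    n_eval <<- n_eval + 1L
    val <- fitness_fn(x)
    if (length(val) != 1L || is.na(val) || is.nan(val)) {
      warn_fmt("fitness returned NA/NaN; treating as -Inf")
      return(-Inf)
    }
    as.numeric(val)
  }
  D <- length(lower)
  range <- upper - lower
  np <- params$population_size

  local_seed(seed, {
    pop <- matrix(stats::runif(np * D, rep(lower, each = np), rep(upper, each = np)),
                  nrow = np)
    fit <- apply(pop, 1, evaluate)
    gi <- which.max(fit)
    gbest <- pop[gi, ]; gfit <- fit[gi]
    history <- numeric(params$n_iterations)

    step_fn <- switch(params$algorithm,
      ga = {
        function(iter) {
          elite_i <- which.max(fit)
          children <- matrix(0, np, D)
          children[1, ] <- pop[elite_i, ]
          for (ci in 2:np) {
            pick <- function() {
              cand <- sample.int(np, 2L)
              cand[which.max(fit[cand])]
            }
            p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
            child <- if (stats::runif(1) < params$crossover_prob) {
              mask <- stats::runif(D) < 0.5
              ifelse(mask, p1, p2)
            } else p1
            mut <- stats::runif(D) < params$mutation_prob
            if (any(mut)) {
              child[mut] <- child[mut] + stats::rnorm(sum(mut), sd = 0.1 * range[mut])
            }
            children[ci, ] <- clip_box(child, lower, upper)
          }
          pop <<- children
          fit <<- apply(pop, 1, evaluate)
        }
      },
      pso = {
        vel <- matrix(0, np, D)
        pbest <- pop; pfit <- fit
        function(iter) {
          for (i in seq_len(np)) {
            r1 <- stats::runif(D); r2 <- stats::runif(D)
            vel[i, ] <<- params$inertia_weight * vel[i, ] +
              params$individual_weight * r1 * (pbest[i, ] - pop[i, ]) +
              params$social_weight * r2 * (gbest - pop[i, ])
            pop[i, ] <<- clip_box(pop[i, ] + vel[i, ], lower, upper)
            fit[i] <<- evaluate(pop[i, ])
            if (fit[i] > pfit[i]) { pbest[i, ] <<- pop[i, ]; pfit[i] <<- fit[i] }
          }
        }
      },
      fa = {
        walk_scale <- params$alpha
        # gamma is interpreted per squared box diagonal so that the
        # attractiveness decay is invariant to the scale and dimension of the
        # search space (with a raw gamma, exp(-gamma r^2) vanishes in high
        # dimension and the swarm degenerates to a random walk)
        gamma_scaled <- params$gamma / max(sum(range^2), 1e-12)
        function(iter) {
          fit_old <- fit
          for (i in seq_len(np)) {
            brighter <- which(fit_old > fit_old[i])
            if (length(brighter)) {
              for (j in brighter) {
                r2 <- sum((pop[i, ] - pop[j, ])^2)
                beta <- exp(-gamma_scaled * r2)
                pop[i, ] <<- pop[i, ] + beta * (pop[j, ] - pop[i, ]) +
                  walk_scale * (stats::runif(D) - 0.5) * range
              }
            } else {
              pop[i, ] <<- pop[i, ] + walk_scale * (stats::runif(D) - 0.5) * range
            }
            pop[i, ] <<- clip_box(pop[i, ], lower, upper)
            fit[i] <<- evaluate(pop[i, ])
          }
          walk_scale <<- walk_scale * params$delta
        }
      },
      csa = {
        function(iter) {
          for (i in seq_len(np)) {
            step <- levy_step(D)
            cand <- clip_box(pop[i, ] + 0.01 * step * (pop[i, ] - gbest),
                             lower, upper)
            cfit <- evaluate(cand)
            j <- sample.int(np, 1L)
            if (cfit > fit[j]) { pop[j, ] <<- cand; fit[j] <<- cfit }
          }
          n_drop <- floor(params$p_a * np)
          if (n_drop > 0) {
            worst <- order(fit)[seq_len(n_drop)]
            for (i in worst) {
              pop[i, ] <<- lower + stats::runif(D) * range
              fit[i] <<- evaluate(pop[i, ])
            }
          }
        }
      },
      ba = {
        vel <- matrix(0, np, D)
        function(iter) {
          for (i in seq_len(np)) {
            fq <- params$fq_min + (params$fq_max - params$fq_min) * stats::runif(1)
            vel[i, ] <<- vel[i, ] + (pop[i, ] - gbest) * fq
            cand <- pop[i, ] + vel[i, ]
            if (stats::runif(1) > params$pulse_rate) {
              cand <- gbest + 0.05 * stats::rnorm(D) * range * params$loudness
            }
            cand <- clip_box(cand, lower, upper)
            cfit <- evaluate(cand)
            if (cfit > fit[i] && stats::runif(1) < params$loudness) {
              pop[i, ] <<- cand; fit[i] <<- cfit
            }
          }
        }
      }
    )

    for (iter in seq_len(params$n_iterations)) {
      step_fn(iter)
      bi <- which.max(fit)
      if (fit[bi] > gfit) { gbest <- pop[bi, ]; gfit <- fit[bi] }
      history[iter] <- gfit
    }
    list(best_vector = gbest, best_fitness = gfit, history = history,
         n_evaluations = n_eval)
  })
}
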