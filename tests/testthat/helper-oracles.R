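# Independent straight-line oracles used to verify the package's vectorized
# implementations. Deliberately written as plain loops over the definitions.

oracle_ch <- function(points, labels) {
  points <- as.matrix(points)
  cl <- sort(unique(labels))
  K <- length(cl); N <- nrow(points)
  grand <- colMeans(points)
  trace_b <- 0; trace_w <- 0
  for (c in cl) {
    idx <- which(labels == c)
    cent <- colMeans(points[idx, , drop = FALSE])
    trace_b <- trace_b + length(idx) * sum((cent - grand)^2)
    for (i in idx) trace_w <- trace_w + sum((points[i, ] - cent)^2)
  }
  (trace_b / (K - 1)) / (trace_w / (N - K))
}

oracle_db <- function(points, labels) {
  points <- as.matrix(points)
  cl <- sort(unique(labels))
  K <- length(cl)
  cents <- lapply(cl, function(c) colMeans(points[labels == c, , drop = FALSE]))
  scatter <- vapply(seq_along(cl), function(ci) {
    idx <- which(labels == cl[ci])
    mean(vapply(idx, function(i) sqrt(sum((points[i, ] - cents[[ci]])^2)), 0))
  }, 0)
  total <- 0
  for (i in seq_len(K)) {
    worst <- -Inf
    for (j in seq_len(K)) {
      if (i == j) next
      d <- sqrt(sum((cents[[i]] - cents[[j]])^2))
      worst <- max(worst, (scatter[i] + scatter[j]) / d)
    }
    total <- total + worst
  }
  total / K
}

oracle_si <- function(points, labels) {
  points <- as.matrix(points)
  N <- nrow(points)
  dmat <- as.matrix(dist(points))
  s <- numeric(N)
  for (i in seq_len(N)) {
    own <- which(labels == labels[i])
    a <- if (length(own) > 1) mean(dmat[i, setdiff(own, i)]) else 0
    b <- Inf
    for (c in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(dmat[i, labels == c]))
    }
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

oracle_bic <- function(points, labels) {
  points <- as.matrix(points)
  N <- nrow(points); d <- ncol(points)
  cl <- sort(unique(labels))
  ss <- 0
  for (c in cl) {
    idx <- which(labels == c)
    cent <- colMeans(points[idx, , drop = FALSE])
    for (i in idx) ss <- ss + sum((points[i, ] - cent)^2)
  }
  sigma2 <- max(ss / (N * d), 1e-8)
  log_lik <- 0
  for (c in cl) {
    idx <- which(labels == c)
    cent <- colMeans(points[idx, , drop = FALSE])
    for (i in idx) {
      log_lik <- log_lik - d / 2 * log(2 * pi * sigma2) -
        sum((points[i, ] - cent)^2) / (2 * sigma2)
    }
  }
  -log_lik + (length(cl) * d + 1) * log(N)
}

oracle_pair_counts <- function(ri, rj) {
  n11 <- n10 <- n01 <- n00 <- 0L
  for (t in seq_along(ri)) {
    if (ri[t] == 1 && rj[t] == 1) n11 <- n11 + 1L
    else if (ri[t] == 1 && rj[t] == 0) n10 <- n10 + 1L
    else if (ri[t] == 0 && rj[t] == 1) n01 <- n01 + 1L
    else n00 <- n00 + 1L
  }
  list(n11 = n11, n10 = n10, n01 = n01, n00 = n00)
}

oracle_diversity <- function(cnt, measure) {
  n11 <- cnt$n11; n10 <- cnt$n10; n01 <- cnt$n01; n00 <- cnt$n00
  n <- n11 + n10 + n01 + n00
  switch(measure,
    q = (n11 * n00 - n01 * n10) / (n11 * n00 + n01 * n10),
    rho = (n11 * n00 - n01 * n10) /
      sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00)),
    dis = (n01 + n10) / n,
    df = n00 / n,
    kappa = {
      p_o <- (n11 + n00) / n
      p_e <- ((n11 + n10) * (n11 + n01) + (n01 + n00) * (n10 + n00)) / n^2
      (p_o - p_e) / (1 - p_e)
    })
}

oracle_combine <- function(mats) {
  L <- nrow(mats[[1]]$values)
  off <- !diag(TRUE, L)
  acc <- matrix(0, L, L)
  for (m in mats) {
    v <- m$values
    lo <- min(v[off]); hi <- max(v[off])
    norm <- if (hi == lo) matrix(0.5, L, L) else {
      nm <- (v - lo) / (hi - lo)
      if (m$measure == "dis") nm else 1 - nm
    }
    acc <- acc + norm
  }
  out <- acc / length(mats)
  diag(out) <- 0
  out
}

oracle_accuracy <- function(yt, yp) {
  hit <- 0
  for (i in seq_along(yt)) if (yt[i] == yp[i]) hit <- hit + 1
  hit / length(yt)
}

oracle_macro_f <- function(yt, yp) {
  cl <- sort(unique(c(yt, yp)))
  fs <- numeric(0)
  for (c in cl) {
    tp <- fp <- fn <- 0
    for (i in seq_along(yt)) {
      if (yt[i] == c && yp[i] == c) tp <- tp + 1
      if (yt[i] != c && yp[i] == c) fp <- fp + 1
      if (yt[i] == c && yp[i] != c) fn <- fn + 1
    }
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    fs <- c(fs, if (p + r > 0) 2 * p * r / (p + r) else 0)
  }
  mean(fs)
}

oracle_micro_f <- function(yt, yp) {
  cl <- sort(unique(c(yt, yp)))
  TP <- FP <- FN <- 0
  for (c in cl) {
    for (i in seq_along(yt)) {
      if (yt[i] == c && yp[i] == c) TP <- TP + 1
      if (yt[i] != c && yp[i] == c) FP <- FP + 1
      if (yt[i] == c && yp[i] != c) FN <- FN + 1
    }
  }
  p <- if (TP + FP > 0) TP / (TP + FP) else 0
  r <- if (TP + FN > 0) TP / (TP + FN) else 0
  if (p + r > 0) 2 * p * r / (p + r) else 0
}

# random labelled point clouds for the index-equivalence checks
random_instance <- function(seed) {
  set.seed(seed)
  N <- sample(8:30, 1)
  d <- sample(2:5, 1)
  K <- sample(2:4, 1)
  labels <- c(seq_len(K), sample.int(K, N - K, replace = TRUE))  # no empty cluster
  points <- matrix(rnorm(N * d), N, d) + 2 * labels
  list(points = points, labels = labels)
}

# manually assembled topic model (for tests of functions that only consume
# theta/phi)
manual_model <- function(theta, phi, alpha = 0.1, beta = 0.01) {
  structure(list(theta = theta, phi = phi, z = NULL, ndt = NULL,
                 config = lda_config(ncol(theta), alpha, beta, 1), seed = 1L),
            class = "swarmlda_topic_model")
}

manual_diversity_matrix <- function(values, measure) {
  structure(list(measure = measure, values = values),
            class = "swarmlda_diversity_matrix")
}
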