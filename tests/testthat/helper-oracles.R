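# Independent oracles and small fixture builders used across the suite.

# Brute-force pair classification: enumerate all N(N-1)/2 unordered pairs.
brute_pair_counts <- function(truth, clustering) {
  n <- length(truth)
  a <- b <- c_ <- d <- 0
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        same_class <- truth[i] == truth[j]
        same_clust <- clustering[i] == clustering[j]
        if (same_class && same_clust) a <- a + 1
        else if (!same_class && same_clust) b <- b + 1
        else if (same_class && !same_clust) c_ <- c_ + 1
        else d <- d + 1
      }
    }
  }
  list(a = a, b = b, c = c_, d = d)
}

# Coarse grid-search log-likelihood oracle for the Gamma-Gaussian mixture:
# the best point on a fixed grid is a lower bound the EM fit must reach.
grid_loglik_gamma_gaussian <- function(x) {
  best <- -Inf
  mu_grid <- stats::quantile(x, c(0.5, 0.7, 0.9))
  for (lam in c(0.1, 0.3, 0.5, 0.7, 0.9))
    for (alpha in c(0.5, 1, 2, 4))
      for (beta in c(0.5, 1, 2, 4))
        for (mu in mu_grid)
          for (s in c(0.5, 1, 2)) {
            ll <- sum(log(lam * stats::dgamma(x, alpha, beta) +
                            (1 - lam) * stats::dnorm(x, mu, s)))
            if (is.finite(ll) && ll > best) best <- ll
          }
  best
}

# Spreadsheet-style recomputation of the stability index from a feature
# table: independent of the package's rank/aggregation code.
brute_index <- function(ft, use_f = "f_stat" %in% names(ft)) {
  cols <- c("lambda", "sigma2", "omega_star", if (use_f) "f_stat")
  g <- nrow(ft)
  scaled <- sapply(cols, function(cl) {
    v <- ft[[cl]]
    r <- rank(v, ties.method = "average")
    (r - 1) / (g - 1)
  })
  rowMeans(1 - scaled)
}

# A tiny valid feature table with hand-assigned values (no NAs, no ties).
make_feature_table <- function(lambda, sigma2, omega_star, f_stat = NULL,
                               mu = NULL, omega = NULL) {
  g <- length(lambda)
  ft <- data.frame(gene_id = sprintf("g%02d", seq_len(g)),
                   lambda = lambda, sigma2 = sigma2,
                   mu = if (is.null(mu)) seq(5, 8, length.out = g) else mu,
                   omega = if (is.null(omega)) rep(0.1, g) else omega,
                   omega_star = omega_star, valid = TRUE,
                   stringsAsFactors = FALSE)
  if (!is.null(f_stat)) ft$f_stat <- f_stat
  class(ft) <- c("seg_features", "data.frame")
  ft
}

# Random partition of n items into at most k groups (all groups occupied
# is not required; labels are arbitrary).
random_partition <- function(n, k) sample.int(k, n, replace = TRUE)

# Small raw-scale matrix fixture with controllable zero pattern.
make_matrix <- function(values, genes = NULL, cells = NULL) {
  values <- as.matrix(values)
  expression_matrix(values,
                    gene_ids = genes %||% sprintf("g%d", seq_len(nrow(values))),
                    cell_ids = cells %||% sprintf("c%d", seq_len(ncol(values))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
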