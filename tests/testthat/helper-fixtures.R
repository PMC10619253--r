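# shared fixtures and small independent oracles

toy_counts <- function(m, sample_prefix = "s", taxon_prefix = "t") {
  m <- as.matrix(m)
  dimnames(m) <- list(paste0(sample_prefix, seq_len(nrow(m))),
                      paste0(taxon_prefix, seq_len(ncol(m))))
  storage.mode(m) <- "double"
  m
}

small_config <- function(seed = 1, ...) {
  args <- list(n_cohorts = 1, cohort_sizes = 200, survey_years = 2015,
               n_genera = 40, n_keystones = 3, hub_degree = 4, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simulation_config, args)
}

# logistic-normal-multinomial draw with an explicit latent correlation
# matrix; independent of the package generator
lnm_counts <- function(n, sigma, mu = NULL, depth = 2e4, seed = 1) {
  set.seed(seed)
  p <- ncol(sigma)
  if (is.null(mu)) mu <- rnorm(p, 0, 1)
  z <- matrix(rnorm(n * p), n, p) %*% chol(sigma)
  y <- sweep(z, 2, mu, "+")
  prob <- exp(y - apply(y, 1, max))
  prob <- prob / rowSums(prob)
  cnt <- t(vapply(seq_len(n), function(i) rmultinom(1, depth, prob[i, ])[, 1],
                  integer(p)))
  toy_counts(cnt, taxon_prefix = "g")
}

# hand-rolled Benjamini-Hochberg, written from the definition
hand_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# power-iteration oracle for the leading eigenpair of a symmetric
# non-negative matrix; iterates on the shifted matrix A + cI (same
# eigenvectors, all eigenvalues positive) so convergence cannot stall on
# near-bipartite graphs where lambda_2 ~ -lambda_1
power_iteration <- function(A, tol = 1e-14, max_iter = 100000) {
  c_shift <- max(rowSums(abs(A))) + 1
  B <- A + diag(c_shift, nrow(A))
  v <- rep(1, nrow(A)) / sqrt(nrow(A))
  for (i in seq_len(max_iter)) {
    w <- B %*% v
    w <- w / sqrt(sum(w^2))
    if (max(abs(w - v)) < tol) { v <- w; break }
    v <- w
  }
  v <- as.numeric(v)
  if (v[which.max(abs(v))] < 0) v <- -v
  lambda <- as.numeric(t(v) %*% A %*% v / sum(v^2))
  list(vector = v / max(v), lambda = lambda)
}

# pseudo-F from a distance matrix, written independently from first
# principles (used by the exhaustive PERMANOVA oracle)
oracle_pseudo_f <- function(dm, groups) {
  n <- nrow(dm)
  a <- length(unique(groups))
  d2 <- dm^2
  ss_t <- sum(d2[upper.tri(d2)]) / n
  ss_w <- 0
  for (g in unique(groups)) {
    i <- which(groups == g)
    ss_w <- ss_w + sum(d2[i, i][upper.tri(d2[i, i])]) / length(i)
  }
  ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
}
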