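# Co-abundance network inference, keystone calling, and the keystone index.

coab_network <- function(taxa, A, r = NULL, method) {
  dimnames(A) <- list(taxa, taxa)
  diag(A) <- 0
  structure(list(taxa = taxa, A = A, r = r, method = method, modules = NULL),
            class = "coab_network")
}

#' @export
print.coab_network <- function(x, ...) {
  ne <- sum(x$A[upper.tri(x$A)] != 0)
  cat(sprintf("coab_network (%s): %d taxa, %d edges\n",
              x$method, length(x$taxa), ne))
  invisible(x)
}

#' Number of edges in a co-abundance network
#' @param net a `coab_network`.
#' @return integer edge count.
#' @export
n_edges <- function(net) sum(net$A[upper.tri(net$A)] != 0)

#' Write a network as an edge-list TSV
#' @param net a `coab_network`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_edgelist_tsv <- function(net, path) {
  ij <- which(upper.tri(net$A) & net$A != 0, arr.ind = TRUE)
  df <- data.frame(taxon_a = net$taxa[ij[, 1]], taxon_b = net$taxa[ij[, 2]],
                   weight = net$A[ij], method = net$method,
                   stringsAsFactors = FALSE)
  if (!is.null(net$r)) df$association <- net$r[ij]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pearson co-abundance network on CLR data
#'
#' Pairwise Pearson correlations between CLR-transformed genus profiles
#' (zeros handled upstream by multiplicative replacement).  An edge is kept
#' iff |r| > `r_threshold` and the BH-adjusted p-value (t-test on r, across
#' all pairs) is below `fdr_alpha`.  Edge weights are |r|; the signed
#' correlation is retained in the `r` field.
#'
#' @param clr samples x taxa CLR matrix (from [clr_transform()] on a
#'   [multiplicative_impute()]d composition).
#' @param r_threshold minimum correlation magnitude (default 0.3).
#' @param fdr_alpha BH false-discovery level (default 0.05).
#' @return a `coab_network`.
#' @export
pearson_network <- function(clr, r_threshold = 0.3, fdr_alpha = 0.05) {
  if (!is.matrix(clr) || nrow(clr) < 3L)
    stop("`clr` must be a matrix with >= 3 samples")
  const <- apply(clr, 2, function(x) var(x) == 0 || !is.finite(var(x)))
  if (any(const)) {
    warning("excluding constant taxa: ",
            paste(colnames(clr)[const], collapse = ", "))
    clr <- clr[, !const, drop = FALSE]
  }
  n <- nrow(clr)
  r <- cor(clr)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  keep <- fdr_edge_mask(r, p, r_threshold, fdr_alpha)
  A <- abs(r) * keep
  coab_network(colnames(clr), A, r = r * keep, method = "pearson_clr")
}

# BH over the upper triangle; edge kept iff |r| > thr AND adjusted p < alpha
fdr_edge_mask <- function(r, p, r_threshold, fdr_alpha) {
  ut <- upper.tri(r)
  padj <- matrix(NA_real_, nrow(r), ncol(r))
  padj[ut] <- p.adjust(p[ut], method = "BH")
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  keep <- abs(r) > r_threshold & padj < fdr_alpha
  keep[is.na(keep)] <- FALSE
  diag(keep) <- FALSE
  keep
}

# --- SparCC ----------------------------------------------------------------

# basis-variance solve from the log-ratio variance matrix under the sparse
# correlation approximation, with iterative exclusion of the strongest pairs
sparcc_rho <- function(logfrac, n_iterations, exclusion_threshold) {
  p <- ncol(logfrac)
  C <- cov(logfrac)
  v <- diag(C)
  Tm <- outer(v, v, "+") - 2 * C            # T_ij = var(log x_i / x_j)
  M <- matrix(TRUE, p, p); diag(M) <- FALSE # pairs entering the linear system

  solve_rho <- function() {
    Amat <- diag(rowSums(M)) + M
    t_vec <- rowSums(Tm * M)
    w <- tryCatch(solve(Amat, t_vec), error = function(e)
      stop("SparCC basis system singular after exclusions: ",
           conditionMessage(e)))
    w <- pmax(w, 1e-12)
    den <- 2 * sqrt(outer(w, w))
    rho <- (outer(w, w, "+") - Tm) / den
    rho <- pmin(pmax(rho, -1), 1)
    diag(rho) <- 1
    rho
  }

  rho <- solve_rho()
  for (it in seq_len(n_iterations)) {
    cand <- abs(rho) * M
    m <- max(cand)
    if (m <= exclusion_threshold) break
    ij <- which(cand == m, arr.ind = TRUE)[1, ]
    # never disconnect a component entirely from the system
    if (sum(M[ij[1], ]) <= 3 || sum(M[ij[2], ]) <= 3) break
    M[ij[1], ij[2]] <- M[ij[2], ij[1]] <- FALSE
    rho <- solve_rho()
  }
  rho
}

#' SparCC co-abundance network
#'
#' Sparse correlations for compositional data: basis variances are solved
#' from the matrix of log-ratio variances T_ij = var(log x_i / x_j) under
#' the approximation that most correlations are small, the strongest pairs
#' being iteratively excluded from the system and the basis re-solved;
#' correlations are rho_ij = (w_i + w_j - T_ij) / (2 sqrt(w_i w_j)).
#' Fractions use a pseudocount (default 1) rather than Dirichlet resampling.
#' P-values come from a permutation null (columns of the count table shuffled
#' independently `n_bootstrap` times) summarized by a normal approximation,
#' which keeps p-value resolution adequate for FDR control across all pairs
#' at a feasible number of permutations.  Edges are kept iff
#' |rho| > `r_threshold` and BH-adjusted p < `fdr_alpha`.
#'
#' @param table samples x taxa counts matrix (>= 3 taxa; the method assumes
#'   correlations are sparse).
#' @param r_threshold minimum correlation magnitude (default 0.2).
#' @param fdr_alpha BH false-discovery level (default 0.05).
#' @param n_iterations maximum strong-pair exclusion rounds (default 20).
#' @param exclusion_threshold |rho| above which a pair may be excluded from
#'   the basis system (default 0.1).
#' @param n_bootstrap number of column permutations for the null (default
#'   100).
#' @param seed optional integer seed.
#' @param pseudocount added to counts before closing to fractions.
#' @return a `coab_network` (field `r` holds signed rho for kept edges;
#'   attribute `rho` the full estimated correlation matrix).
#' @export
sparcc <- function(table, r_threshold = 0.2, fdr_alpha = 0.05,
                   n_iterations = 20, exclusion_threshold = 0.1,
                   n_bootstrap = 100, seed = NULL, pseudocount = 1) {
  assert_count_table(table)
  if (ncol(table) < 3L) stop("SparCC needs >= 3 taxa")
  maybe_set_seed(seed)
  frac <- (table + pseudocount) / rowSums(table + pseudocount)
  logfrac <- log(frac)
  rho <- sparcc_rho(logfrac, n_iterations, exclusion_threshold)

  # permutation null: shuffle each taxon independently, Welford-accumulate
  p <- ncol(table)
  mean_b <- matrix(0, p, p); m2_b <- matrix(0, p, p)
  for (b in seq_len(n_bootstrap)) {
    perm <- apply(logfrac, 2, sample)
    rb <- sparcc_rho(perm, n_iterations, exclusion_threshold)
    dlt <- rb - mean_b
    mean_b <- mean_b + dlt / b
    m2_b <- m2_b + dlt * (rb - mean_b)
  }
  sd_b <- sqrt(m2_b / (n_bootstrap - 1))
  sd_b[sd_b <= 0 | !is.finite(sd_b)] <- .Machine$double.eps
  z <- (rho - mean_b) / sd_b
  pv <- 2 * pnorm(-abs(z))
  keep <- fdr_edge_mask(rho, pv, r_threshold, fdr_alpha)
  net <- coab_network(colnames(table), abs(rho) * keep, r = rho * keep,
                      method = "sparcc")
  attr(net, "rho") <- rho
  net
}

# --- SPIEC-EASI (neighborhood selection + StARS) ---------------------------

# per-node lasso selections over a shared lambda path; returns a
# p x p x nlambda logical array (OR-rule symmetrized)
mb_selections <- function(X, lambda_path) {
  p <- ncol(X)
  nl <- length(lambda_path)
  sel <- array(FALSE, c(p, p, nl))
  for (j in seq_len(p)) {
    fit <- glmnet::glmnet(X[, -j, drop = FALSE], X[, j],
                          lambda = lambda_path, standardize = TRUE,
                          thresh = 1e-4)
    B <- as.matrix(fit$beta) != 0             # (p-1) x n_fitted
    if (ncol(B) < nl)                          # glmnet may stop early
      B <- cbind(B, matrix(B[, ncol(B)], nrow(B), nl - ncol(B)))
    sel[j, -j, ] <- B
  }
  for (l in seq_len(nl)) sel[, , l] <- sel[, , l] | t(sel[, , l])
  sel
}

#' Sparse inverse-covariance network (neighborhood selection with StARS)
#'
#' Infers conditional-dependence edges between taxa on CLR-transformed
#' counts (pseudocount 1): each taxon is lasso-regressed on all others over
#' a decreasing penalty path, edges are symmetrized by the OR rule, and the
#' penalty is chosen by StARS stability selection: the data are subsampled
#' (80\% without replacement, `n_subsamples` times), per-penalty edge
#' instability is averaged over all pairs, monotonized, and the least
#' regularized penalty whose instability stays below `stars_threshold` is
#' selected.  The stability-selected graph needs no further edge
#' thresholding.
#'
#' @param table samples x taxa counts matrix (>= 20 samples).
#' @param variant `"mb"` (neighborhood selection; the only implemented
#'   variant).
#' @param nlambda length of the penalty path (default 20).
#' @param lambda_min_ratio smallest penalty as a fraction of the largest
#'   (default 0.1).
#' @param stars_threshold StARS instability bound (default 0.05).
#' @param n_subsamples number of StARS subsamples (default 50).
#' @param subsample_ratio subsample fraction (default 0.8).
#' @param seed optional integer seed.
#' @param pseudocount added to counts before the CLR (default 1).
#' @return a `coab_network` with edge weights the mean |lasso coefficient|
#'   of the two regression directions; attribute `lambda_selected` records
#'   the chosen penalty.
#' @export
spieceasi <- function(table, variant = "mb", nlambda = 20,
                      lambda_min_ratio = 0.1, stars_threshold = 0.05,
                      n_subsamples = 50, subsample_ratio = 0.8,
                      seed = NULL, pseudocount = 1) {
  assert_count_table(table)
  variant <- match.arg(variant, "mb")
  n <- nrow(table); p <- ncol(table)
  if (n < 20L) stop("need >= 20 samples for stability selection")
  maybe_set_seed(seed)

  X <- clr_transform(table, pseudocount = pseudocount)
  X <- scale(X)
  X[!is.finite(X)] <- 0                       # constant taxa carry no signal
  R <- cor(X); diag(R) <- 0; R[!is.finite(R)] <- 0
  lmax <- max(abs(R))
  if (lmax <= 0) lmax <- 1e-3
  path <- exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))

  m <- floor(subsample_ratio * n)
  freq <- array(0, c(p, p, nlambda))
  for (b in seq_len(n_subsamples)) {
    idx <- sample(n, m)
    freq <- freq + mb_selections(X[idx, , drop = FALSE], path)
  }
  theta <- freq / n_subsamples
  ut <- upper.tri(theta[, , 1])
  D <- vapply(seq_len(nlambda),
              function(l) mean(2 * theta[, , l][ut] * (1 - theta[, , l][ut])),
              numeric(1))
  Dbar <- cummax(D)                            # path runs sparse -> dense
  ok <- which(Dbar <= stars_threshold)
  l_star <- if (length(ok)) max(ok) else 1L

  # final fit on the full data at the selected penalty
  W <- matrix(0, p, p)
  for (j in seq_len(p)) {
    fit <- glmnet::glmnet(X[, -j, drop = FALSE], X[, j], lambda = path,
                          standardize = TRUE, thresh = 1e-4)
    bj <- numeric(p)
    l_avail <- min(l_star, ncol(fit$beta))
    bj[-j] <- as.numeric(fit$beta[, l_avail])
    W[j, ] <- bj
  }
  sel <- (W != 0) | (t(W) != 0)                # OR rule
  A <- (abs(W) + abs(t(W))) / 2 * sel
  if (!any(sel)) warning("stability-selected graph is empty")
  net <- coab_network(colnames(table), A, r = sign(W + t(W)) * A,
                      method = "spieceasi")
  attr(net, "lambda_selected") <- path[l_star]
  attr(net, "instability_path") <- Dbar
  net
}

# --- modules, centrality, keystones ---------------------------------------

as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(abs(net$A), mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Module detection by greedy modularity agglomeration
#'
#' Hierarchical agglomeration (fast-greedy modularity optimization) on
#' absolute edge weights; isolated nodes form singletons.
#'
#' @param net a `coab_network`.
#' @return the network with a `modules` field (named integer cluster ids).
#' @export
detect_modules <- function(net) {
  stopifnot(inherits(net, "coab_network"))
  g <- as_igraph(net)
  cl <- igraph::cluster_fast_greedy(g)
  net$modules <- setNames(igraph::membership(cl)[net$taxa], net$taxa)
  net
}

#' Eigenvector centrality of a co-abundance network
#'
#' Solves A c = lambda c on absolute edge weights and returns the entries of
#' the eigenvector belonging to the largest eigenvalue.  The leading
#' eigenpair is computed on the largest connected component (where it is
#' non-negative by Perron-Frobenius); nodes outside that component get
#' centrality zero.  The vector is sign-fixed non-negative and normalized to
#' maximum 1.
#'
#' @param net a `coab_network`.
#' @return named numeric centrality vector with attribute `"lambda"` (the
#'   leading eigenvalue); all-zero (with a warning) for an edgeless network.
#' @export
eigenvector_centrality <- function(net) {
  stopifnot(inherits(net, "coab_network"))
  A <- abs(net$A)
  cent <- setNames(numeric(length(net$taxa)), net$taxa)
  if (all(A == 0)) {
    warning("network has no edges; centrality is zero everywhere")
    attr(cent, "lambda") <- 0
    return(cent)
  }
  g <- as_igraph(net)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  idx <- which(comp$membership == big)
  e <- eigen(A[idx, idx, drop = FALSE], symmetric = TRUE)
  v <- e$vectors[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  v[v < 0] <- 0                                # clip numerical noise
  cent[idx] <- v / max(v)
  attr(cent, "lambda") <- e$values[1]
  cent
}

#' Call keystone taxa from centrality
#'
#' Keystones are nodes whose eigenvector centrality lies strictly above the
#' empirical 95\% quantile of the network's centrality values (linear
#' interpolation quantile; ties at the quantile are excluded).
#'
#' @param net a `coab_network`, or a named centrality vector.
#' @param quantile quantile cutoff (default 0.95).
#' @return character vector of keystone taxon ids.
#' @export
call_keystones <- function(net, quantile = 0.95) {
  cent <- if (inherits(net, "coab_network")) eigenvector_centrality(net) else net
  if (is.null(names(cent))) stop("centrality vector must be named")
  q <- stats::quantile(cent, quantile, names = FALSE, type = 7)
  names(cent)[cent > q]
}

#' Combine keystone sets across inference methods
#'
#' @param sets list of keystone taxon-id vectors, one per method.
#' @param rule `"majority"` (in at least half the methods, the default;
#'   >= 2 of 3), `"any"` (union), or `"all"` (intersection).
#' @return combined character vector.
#' @export
combine_methods <- function(sets, rule = c("majority", "any", "all")) {
  rule <- match.arg(rule)
  if (!length(sets)) return(character(0))
  all_taxa <- unique(unlist(sets))
  votes <- vapply(all_taxa,
                  function(t) sum(vapply(sets, function(s) t %in% s, TRUE)),
                  1L)
  switch(rule,
         any = all_taxa,
         all = all_taxa[votes == length(sets)],
         majority = all_taxa[votes > length(sets) / 2])
}

#' Keystone taxa shared across cohorts
#'
#' Strict intersection of the per-cohort (combined) keystone sets.
#'
#' @param cohort_sets list (one per cohort, >= 2) of keystone id vectors.
#' @return character vector; empty (with a warning) if no taxon is shared.
#' @export
shared_keystones <- function(cohort_sets) {
  if (length(cohort_sets) < 2L) stop("need keystone sets from >= 2 cohorts")
  shared <- Reduce(intersect, cohort_sets)
  if (!length(shared))
    warning("no keystone taxon is shared across all cohorts")
  shared
}

#' Keystone taxa index
#'
#' Per-sample total abundance of the shared keystone taxa on the CLR scale:
#' counts get a pseudo-count of 1, are CLR-transformed, and the CLR values of
#' the shared keystones are summed.  When cohort labels are supplied the
#' index is additionally z-scored within cohort (SD units).
#'
#' @param table samples x taxa counts matrix (the unfiltered table; keystone
#'   taxa must be among its columns).
#' @param keystones non-empty character vector of shared keystone ids.
#' @param cohort optional cohort label per sample.
#' @return data frame: sample_id, index, and index_z when `cohort` is given.
#' @export
keystone_index <- function(table, keystones, cohort = NULL) {
  assert_count_table(table)
  if (!length(keystones)) stop("empty shared keystone set: no index defined")
  missing <- setdiff(keystones, colnames(table))
  if (length(missing))
    stop("keystone taxa absent from the table: ",
         paste(missing, collapse = ", "))
  clr <- clr_transform(table, pseudocount = 1)
  idx <- rowSums(clr[, keystones, drop = FALSE])
  out <- data.frame(sample_id = rownames(table), index = idx,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(cohort)) out$index_z <- zscore_by_cohort(idx, cohort)
  out
}

#' Rank genera by their Spearman correlation with observed richness
#'
#' Spearman correlation of each genus's relative abundance with per-sample
#' observed richness, BH-adjusted across genera and ranked by the
#' coefficient (rank 1 = strongest positive correlate).  Keystone taxa can
#' be flagged to read off their ranks.
#'
#' @param table samples x taxa counts matrix (>= 10 samples).
#' @param richness per-sample observed richness (e.g.
#'   [observed_richness()]), aligned with the table rows.
#' @param keystones optional keystone ids to flag.
#' @return data frame: taxon, rho, p_value, p_adjusted, rank, is_keystone,
#'   ordered by decreasing rho.
#' @export
rank_richness_correlates <- function(table, richness, keystones = NULL) {
  assert_count_table(table)
  if (nrow(table) < 10L) stop("need >= 10 samples")
  if (length(richness) != nrow(table))
    stop("`richness` must align with the table rows")
  rel <- table / rowSums(table)
  res <- apply(rel, 2, function(x) {
    ct <- suppressWarnings(cor.test(x, richness, method = "spearman",
                                    exact = FALSE))
    c(ct$estimate, ct$p.value)
  })
  out <- data.frame(taxon = colnames(table), rho = res[1, ],
                    p_value = res[2, ], stringsAsFactors = FALSE,
                    row.names = NULL)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out <- out[order(-out$rho), ]
  out$rank <- seq_len(nrow(out))
  out$is_keystone <- out$taxon %in% keystones
  out
}
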