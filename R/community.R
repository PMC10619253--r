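#' Bray-Curtis dissimilarity
#'
#' d(a, b) = sum |x_ai - x_bi| / sum (x_ai + x_bi), computed at the genus
#' level on relative abundances by default (so sequencing depth cancels).
#'
#' @param table samples x taxa counts matrix.
#' @param normalize divide each row by its total before computing distances
#'   (default TRUE).
#' @return a `dist` object with sample labels.
#' @export
bray_curtis <- function(table, normalize = TRUE) {
  assert_count_table(table)
  assert_flag(normalize, "normalize")
  depth <- rowSums(table)
  if (any(depth <= 0))
    stop("all-zero sample(s): ",
         paste(head(rownames(table)[depth <= 0]), collapse = ", "))
  x <- if (normalize) table / depth else table
  vegan::vegdist(x, method = "bray")
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centers -d^2/2, eigen-decomposes, and scales eigenvectors by the
#' square root of their (positive) eigenvalues.  Negative eigenvalues are
#' reported but contribute no coordinates; the explained fraction of each
#' retained axis is its eigenvalue over the sum of positive eigenvalues.
#' Axis signs are fixed by forcing each axis's largest-magnitude loading
#' positive, so output is deterministic.
#'
#' @param d a `dist` or symmetric distance matrix.
#' @param n_axes number of axes to return (default 2); truncated with a
#'   warning if it exceeds the number of positive eigenvalues.
#' @return object of class `pcoa_result`: list with `coordinates`
#'   (samples x axes), `eigenvalues` (all, non-increasing), and
#'   `explained_fraction` (per retained axis).
#' @export
pcoa <- function(d, n_axes = 2) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  fit <- suppressWarnings(cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  n_pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  if (n_axes > n_pos) {
    warning("only ", n_pos, " positive eigenvalues; truncating axes")
    n_axes <- n_pos
  }
  coords <- fit$points[, seq_len(n_axes), drop = FALSE]
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("PCoA", seq_len(n_axes))
  structure(list(coordinates = coords,
                 eigenvalues = eig,
                 explained_fraction = eig[seq_len(n_axes)] / sum(eig[eig > 0])),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("PCoA:", nrow(x$coordinates), "samples,", ncol(x$coordinates), "axes\n")
  cat("explained:", paste0(sprintf("%.1f%%", 100 * x$explained_fraction),
                           collapse = ", "), "\n")
  invisible(x)
}

# within-group sum of squared distances divided by group size, summed over
# groups (Anderson's direct-from-distances formulation)
permanova_ss <- function(d2, groups) {
  ss_w <- 0
  for (g in unique(groups)) {
    i <- which(groups == g)
    ss_w <- ss_w + sum(d2[i, i]) / (2 * length(i))
  }
  ss_w
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance computed directly from
#' the distance matrix: total sum of squares SS_T = sum_{i<j} d_ij^2 / n,
#' within-group SS_W summed per group, pseudo-F =
#' (SS_B / (a - 1)) / (SS_W / (n - a)).  The p-value uses the add-one
#' convention p = (1 + #\{F_perm >= F_obs\}) / (1 + n_permutations), so it is
#' never zero.
#'
#' @param d a `dist` or symmetric distance matrix.
#' @param groups group label per sample (>= 2 groups, each with >= 2
#'   samples).
#' @param n_permutations number of label permutations (default 999).
#' @param seed optional integer seed for the permutation stream.
#' @return object of class `permanova_result`: list with `pseudo_F`, `R2`,
#'   `p_value`, `n_permutations`, `n`, `n_groups`.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = NULL) {
  dm <- as.matrix(stats::as.dist(d))
  n <- nrow(dm)
  groups <- as.character(groups)
  if (length(groups) != n) stop("`groups` must have one label per sample")
  tab <- base::table(groups)
  if (length(tab) < 2L || any(tab < 2L))
    stop("need >= 2 groups with >= 2 samples each")
  a <- length(tab)
  maybe_set_seed(seed)

  d2 <- dm^2
  ss_t <- sum(d2) / (2 * n)
  f_stat <- function(g) {
    ss_w <- permanova_ss(d2, g)
    ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
  }
  f_obs <- f_stat(groups)
  hits <- 0L
  for (b in seq_len(n_permutations))
    if (f_stat(sample(groups)) >= f_obs) hits <- hits + 1L
  ss_w <- permanova_ss(d2, groups)
  structure(list(pseudo_F = f_obs,
                 R2 = (ss_t - ss_w) / ss_t,
                 p_value = (1 + hits) / (1 + n_permutations),
                 n_permutations = n_permutations,
                 n = n, n_groups = a),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: F = %.3f, R2 = %.4f, p = %.4g (%d permutations, n = %d)\n",
              x$pseudo_F, x$R2, x$p_value, x$n_permutations, x$n))
  invisible(x)
}

#' Pairwise PERMANOVA with Benjamini-Hochberg adjustment
#'
#' Runs one PERMANOVA per pair of groups on the restricted distance
#' submatrix and adjusts the p-values across pairs with the BH procedure
#' (adjusted p < 0.05 is the conventional significance rule).
#'
#' @inheritParams permanova
#' @return data frame: group1, group2, pseudo_F, R2, p_value, p_adjusted, n.
#' @export
pairwise_permanova <- function(d, groups, n_permutations = 999, seed = NULL) {
  dm <- as.matrix(stats::as.dist(d))
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) < 2L) stop("need >= 2 groups")
  maybe_set_seed(seed)
  pairs <- combn(lev, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    i <- groups %in% c(g1, g2)
    res <- permanova(dm[i, i], groups[i], n_permutations = n_permutations)
    data.frame(group1 = g1, group2 = g2, pseudo_F = res$pseudo_F,
               R2 = res$R2, p_value = res$p_value, n = res$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out
}
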