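#' Alpha-diversity indices
#'
#' Per-sample diversity on a genus count table: `observed_richness()` counts
#' taxa with count > 0; `shannon()` is H = -sum p_i log p_i over present taxa
#' (natural log by default); `pielou()` is H / log(richness), undefined
#' (`NA`) for single-taxon samples; `faith_pd()` is the sum of branch lengths
#' of the minimal rooted subtree spanning the present taxa (root included).
#'
#' By convention these run on the unfiltered (pre-prevalence-filter) table,
#' since rare taxa carry the richness signal; no rarefaction is applied by
#' default (sequencing depth enters the association models as a covariate
#' instead), but see `rarefy_counts()` for a robustness mode.
#'
#' @param table samples x taxa counts matrix.
#' @return a named numeric vector, one value per sample.
#' @examples
#' m <- matrix(c(3, 0, 2, 1, 1, 2), 2, 3, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("a", "b", "c")))
#' observed_richness(m)
#' shannon(m)
#' @export
observed_richness <- function(table) {
  assert_count_table(table)
  rowSums(table > 0)
}

#' @param log_base base of the logarithm (default natural).
#' @rdname observed_richness
#' @export
shannon <- function(table, log_base = exp(1)) {
  assert_count_table(table)
  depth <- rowSums(table)
  if (any(depth <= 0)) stop("sample depth must be > 0 for Shannon diversity")
  p <- table / depth
  H <- -rowSums(ifelse(p > 0, p * log(p, base = log_base), 0))
  setNames(H, rownames(table))
}

#' @rdname observed_richness
#' @export
pielou <- function(table) {
  H <- shannon(table)
  S <- observed_richness(table)
  if (any(S < 1)) stop("Pielou's evenness requires richness >= 1")
  J <- ifelse(S > 1, H / log(S), NA_real_)
  setNames(J, rownames(table))
}

#' @param tree a phylo object, a Newick string, or a path to a Newick file.
#'   Every taxon with a nonzero count must be a leaf of the tree.
#' @rdname observed_richness
#' @export
faith_pd <- function(table, tree) {
  assert_count_table(table)
  tree <- as_phylo(tree)
  present <- colnames(table)[colSums(table > 0) > 0]
  missing <- setdiff(present, tree$tip.label)
  if (length(missing))
    stop("taxa absent from the tree: ", paste(head(missing, 10), collapse = ", "))
  res <- picante::pd(table[, colnames(table) %in% tree$tip.label, drop = FALSE],
                     tree, include.root = TRUE)
  setNames(res$PD, rownames(table))
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L) {
    if (file.exists(tree)) return(ape::read.tree(tree))
    return(ape::read.tree(text = tree))
  }
  stop("`tree` must be a phylo object, a Newick string, or a Newick file path")
}

#' Standardize values within cohorts
#'
#' Z-scores a per-sample quantity independently within each cohort
#' ((x - cohort mean) / cohort SD, SD with the n-1 denominator), so effect
#' sizes downstream are in per-cohort SD units.
#'
#' @param values numeric vector.
#' @param cohort cohort label per value.
#' @return numeric vector of z-scores (cohort means 0, SDs 1).
#' @export
zscore_by_cohort <- function(values, cohort) {
  if (length(values) != length(cohort))
    stop("`values` and `cohort` lengths differ")
  out <- rep(NA_real_, length(values))
  for (cl in unique(cohort)) {
    i <- which(cohort == cl)
    ok <- i[!is.na(values[i])]
    if (length(ok) < 2L)
      stop("cohort ", cl, " has fewer than 2 non-missing values")
    s <- sd(values[ok])
    if (!is.finite(s) || s == 0)
      stop("cohort ", cl, " has zero variance; z-score undefined")
    out[i] <- (values[i] - mean(values[ok])) / s
  }
  names(out) <- names(values)
  out
}

#' All four alpha-diversity indices at once
#'
#' @param table samples x taxa counts matrix.
#' @param tree optional phylogeny (required for Faith PD; skipped when NULL).
#' @return data frame: sample_id, observed_otus, shannon, pielou, and
#'   faith_pd when a tree is given.
#' @export
alpha_diversity <- function(table, tree = NULL) {
  out <- data.frame(sample_id = rownames(table),
                    observed_otus = as.numeric(observed_richness(table)),
                    shannon = as.numeric(shannon(table)),
                    pielou = as.numeric(pielou(table)),
                    stringsAsFactors = FALSE)
  if (!is.null(tree)) out$faith_pd <- as.numeric(faith_pd(table, tree))
  out
}

#' Rarefy counts to a common depth (robustness mode)
#'
#' Subsamples each row without replacement to `depth` reads.  Not applied by
#' default anywhere in the pipeline; provided for sensitivity checks of the
#' diversity indices.
#'
#' @param table samples x taxa counts matrix.
#' @param depth target depth; defaults to the minimum row sum.
#' @param seed integer RNG seed.
#' @return rarefied counts matrix.
#' @export
rarefy_counts <- function(table, depth = NULL, seed = NULL) {
  assert_count_table(table)
  maybe_set_seed(seed)
  if (is.null(depth)) depth <- min(rowSums(table))
  if (any(rowSums(table) < depth))
    stop("some samples are shallower than the target depth")
  out <- table
  for (i in seq_len(nrow(table))) {
    pool <- rep(seq_len(ncol(table)), table[i, ])
    draw <- sample(pool, depth)
    out[i, ] <- tabulate(draw, nbins = ncol(table))
  }
  out
}
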