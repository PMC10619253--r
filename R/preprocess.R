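#' Filter samples on sequencing depth, birth-year availability, and
#' antibiotic use
#'
#' Standard cohort inclusion rules: samples are retained when their
#' sequencing depth is at least `min_depth` (default 5000 reads), their birth
#' year is known (needed for exposure classification), and they report no
#' recent antibiotic use.  One reason is logged per excluded sample, in the
#' order antibiotics > missing birth year > low depth.
#'
#' @param table samples x taxa counts matrix.
#' @param metadata data frame with `sample_id` and, where used, `depth`,
#'   `birth_year`, `antibiotic_use` columns; must cover all samples.
#' @param min_depth minimum sequencing depth; samples strictly below it are
#'   excluded.  Depth is taken from `metadata$depth` when present, otherwise
#'   from the row sums of `table`.
#' @param require_birth_year exclude samples with missing `birth_year`.
#' @param exclude_antibiotics exclude samples with `antibiotic_use == 1`.
#' @return a list with `counts` (the retained sub-matrix) and
#'   `exclusion_log` (data frame: sample_id, reason).
#' @export
filter_samples <- function(table, metadata, min_depth = 5000,
                           require_birth_year = TRUE,
                           exclude_antibiotics = TRUE) {
  assert_count_table(table)
  assert_flag(require_birth_year, "require_birth_year")
  assert_flag(exclude_antibiotics, "exclude_antibiotics")
  ids <- rownames(table)
  if (!all(ids %in% metadata$sample_id))
    stop("metadata does not cover all samples: ",
         paste(head(setdiff(ids, metadata$sample_id)), collapse = ", "))
  md <- metadata[match(ids, metadata$sample_id), , drop = FALSE]

  depth <- if ("depth" %in% names(md)) md$depth else rowSums(table)
  reason <- rep(NA_character_, length(ids))
  if (exclude_antibiotics && "antibiotic_use" %in% names(md))
    reason[is.na(reason) & !is.na(md$antibiotic_use) & md$antibiotic_use == 1] <-
      "antibiotic_use"
  if (require_birth_year) {
    by <- if ("birth_year" %in% names(md)) md$birth_year else NA
    reason[is.na(reason) & is.na(by)] <- "missing_birth_year"
  }
  reason[is.na(reason) & depth < min_depth] <- "low_depth"

  keep <- is.na(reason)
  if (!any(keep)) {
    dominant <- names(sort(base::table(reason), decreasing = TRUE))[1]
    stop("no samples retained; dominant exclusion reason: ", dominant)
  }
  list(counts = table[keep, , drop = FALSE],
       exclusion_log = data.frame(sample_id = ids[!keep],
                                  reason = reason[!keep],
                                  stringsAsFactors = FALSE))
}

#' Filter rare taxa by prevalence
#'
#' Retains taxa present (count > 0) in at least `min_prevalence` of samples;
#' taxa detected in strictly fewer are dropped (the boundary prevalence is
#' retained).  The sample set is unchanged.
#'
#' @param table samples x taxa counts matrix.
#' @param min_prevalence fraction in \[0, 1\] (default 0.10).
#' @return the filtered counts matrix.
#' @export
filter_prevalence <- function(table, min_prevalence = 0.10) {
  assert_count_table(table)
  if (!is.numeric(min_prevalence) || length(min_prevalence) != 1L ||
      is.na(min_prevalence) || min_prevalence < 0 || min_prevalence > 1)
    stop("`min_prevalence` must be a fraction in [0, 1]")
  prev <- colMeans(table > 0)
  table[, prev >= min_prevalence, drop = FALSE]
}

#' Multiplicative zero replacement
#'
#' Converts counts to relative abundances and replaces each zero by a small
#' per-sample delta (by default 0.65 times the sample's smallest nonzero
#' relative abundance), rescaling the nonzero parts multiplicatively so every
#' row still sums to one.  Ratios among originally nonzero parts are
#' preserved, which is what makes the result safe for log-ratio analysis.
#'
#' @param table samples x taxa counts matrix (or non-negative abundances).
#' @param delta_fraction multiplier on the sample's smallest nonzero relative
#'   abundance used as the imputed value (default 0.65).
#' @return samples x taxa matrix of strictly positive compositions
#'   (rows sum to 1).
#' @export
multiplicative_impute <- function(table, delta_fraction = 0.65) {
  assert_count_table(table)
  depth <- rowSums(table)
  if (any(depth <= 0))
    stop("all-zero sample(s) present (",
         paste(head(rownames(table)[depth <= 0]), collapse = ", "),
         "); filter samples before imputation")
  comp <- table / depth
  out <- comp
  for (i in seq_len(nrow(comp))) {
    z <- comp[i, ] == 0
    if (!any(z)) next
    delta <- delta_fraction * min(comp[i, !z])
    out[i, z] <- delta
    out[i, !z] <- comp[i, !z] * (1 - sum(z) * delta)
  }
  out
}

#' Centered log-ratio transform
#'
#' `clr(x)_ij = log x_ij - mean_k log x_ik`; every row of the result sums to
#' zero, and the transform is invariant to multiplying a sample by a positive
#' constant.  Two zero-handling modes coexist deliberately: pass a strictly
#' positive composition (e.g. from [multiplicative_impute()]) with
#' `pseudocount = NULL`, or pass raw counts with a `pseudocount` (the
#' keystone-index path uses `pseudocount = 1`).
#'
#' @param x samples x taxa matrix: strictly positive composition, or raw
#'   counts when `pseudocount` is given.
#' @param pseudocount value added to every entry before closure, or `NULL`.
#' @return samples x taxa matrix of CLR values.
#' @export
clr_transform <- function(x, pseudocount = NULL) {
  if (!is.matrix(x) || !is.numeric(x)) stop("`x` must be a numeric matrix")
  if (!is.null(pseudocount)) {
    if (pseudocount <= 0) stop("`pseudocount` must be positive")
    x <- x + pseudocount
  }
  if (any(x <= 0))
    stop("nonpositive entries: impute zeros first or supply a pseudocount")
  lx <- log(x / rowSums(x))
  sweep(lx, 1, rowMeans(lx), "-")
}
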