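#' Pipeline configuration
#'
#' One object holding every stage parameter of the end-to-end analysis, with
#' defaults at the study's stated values: depth filter 5000 reads, 10%
#' prevalence filter, Pearson |r| > 0.3 and SparCC |rho| > 0.2 edge rules at
#' FDR 0.05, 999 PERMANOVA permutations, and the 95% centrality quantile for
#' keystone calling.
#'
#' @param simulation a [simulation_config()] (the pipeline's input when no
#'   paths are given).
#' @param min_depth sample depth filter.
#' @param min_prevalence taxon prevalence filter.
#' @param pearson_r,sparcc_r edge magnitude thresholds.
#' @param fdr_alpha FDR level for network edges.
#' @param n_permutations PERMANOVA permutations.
#' @param keystone_quantile centrality quantile for keystone calling.
#' @param combine_rule method-combination rule ([combine_methods()]).
#' @param covariate_model adjustment model for group contrasts.
#' @param sparcc_bootstrap SparCC permutation count.
#' @param stars_subsamples,spieceasi_nlambda StARS stability-selection
#'   subsamples and penalty-path length.
#' @param pcoa_axes number of principal coordinates carried into the models.
#' @param seed integer; drives every stage's RNG.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            min_depth = 5000, min_prevalence = 0.10,
                            pearson_r = 0.3, sparcc_r = 0.2,
                            fdr_alpha = 0.05, n_permutations = 999,
                            keystone_quantile = 0.95,
                            combine_rule = "majority",
                            covariate_model = "model1",
                            sparcc_bootstrap = 100,
                            stars_subsamples = 50,
                            spieceasi_nlambda = 20,
                            pcoa_axes = 2, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Validate pipeline inputs
#'
#' Checks id consistency between counts and metadata, value ranges,
#' birth-year plausibility, required covariate columns, and tree leaf
#' coverage, distinguishing fatal errors from warnings.
#'
#' @param counts list of per-cohort counts matrices.
#' @param metadata list of per-cohort metadata data frames.
#' @param tree optional phylogeny (phylo/Newick).
#' @param model covariate model whose columns must exist.
#' @return object of class `validation_report`: list with `errors`,
#'   `warnings`, `valid`.
#' @export
validate_inputs <- function(counts, metadata, tree = NULL, model = "model1") {
  errors <- character(0); warnings <- character(0)
  need <- switch(model,
                 model1 = c("age", "sex", "bmi", "hypoglycemic", "hypolipidemic"),
                 model2 = c("age", "sex", "bmi", "hypoglycemic", "hypolipidemic",
                            "depth"),
                 character(0))
  for (nm in names(counts)) {
    ct <- counts[[nm]]; md <- metadata[[nm]]
    ok <- tryCatch({ assert_count_table(ct, nm); TRUE },
                   error = function(e) { errors <<- c(errors,
                     paste0(nm, ": ", conditionMessage(e))); FALSE })
    if (!ok) next
    if (any(ct != round(ct)))
      warnings <- c(warnings, paste0(nm, ": non-integer counts"))
    if (!"sample_id" %in% names(md)) {
      errors <- c(errors, paste0(nm, ": metadata lacks sample_id"))
      next
    }
    miss <- setdiff(rownames(ct), md$sample_id)
    if (length(miss))
      errors <- c(errors, paste0(nm, ": sample id(s) missing from metadata: ",
                                 paste(head(miss, 5), collapse = ", ")))
    missing_cols <- setdiff(need, names(md))
    if (length(missing_cols))
      errors <- c(errors, paste0(nm, ": metadata lacks column(s) ",
                                 paste(missing_cols, collapse = ", "),
                                 " required by ", model))
    if ("birth_year" %in% names(md)) {
      by <- md$birth_year[!is.na(md$birth_year)]
      if (length(by) && (any(by < 1900) || any(by > 2010)))
        warnings <- c(warnings, paste0(nm, ": implausible birth years"))
    } else warnings <- c(warnings, paste0(nm, ": no birth_year column"))
  }
  if (!is.null(tree)) {
    tr <- tryCatch(as_phylo(tree), error = function(e) {
      errors <<- c(errors, paste0("tree: ", conditionMessage(e))); NULL })
    if (!is.null(tr)) {
      all_taxa <- unique(unlist(lapply(counts, colnames)))
      absent <- setdiff(all_taxa, tr$tip.label)
      if (length(absent))
        errors <- c(errors, paste0("tree lacks taxa: ",
                                   paste(head(absent, 5), collapse = ", ")))
      extra <- setdiff(tr$tip.label, all_taxa)
      if (length(extra))
        warnings <- c(warnings, paste0("tree has ", length(extra),
                                       " leaves not in any table (ignored)"))
    }
  }
  structure(list(errors = errors, warnings = warnings,
                 valid = length(errors) == 0L),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation:", if (x$valid) "OK" else "FAILED", "\n")
  for (e in x$errors) cat("  error:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

stage_seed <- function(seed, offset) (as.integer(seed) + offset) %% .Machine$integer.max

#' Run the full study replica
#'
#' Orchestrates the whole analysis on a synthetic dataset (or pre-loaded
#' counts/metadata): sample and prevalence filtering, exposure
#' classification, alpha diversity, Bray-Curtis community structure
#' (PCoA and the E1-vs-control PERMANOVA on the two-group submatrix),
#' three-method co-abundance networks with keystone calling, the shared
#' keystone-taxa index, the covariate-adjusted association grid, and
#' random-effects pooling across cohorts.  When the input is synthetic the
#' report includes a recovered-vs-planted comparison (keystone
#' recall/precision and the planted effect sizes).
#'
#' @param config a [pipeline_config()].
#' @param dataset optional `synthetic_dataset` (or a list with `counts`,
#'   `metadata`, `tree`); simulated from `config$simulation` when NULL.
#' @param outdir optional directory; when given, intermediate tables
#'   (TSV/Newick) and the JSON report are written there.
#' @return the report: a list with per-cohort keystone sets, the shared set,
#'   all effect estimates, pooled results, PERMANOVA/PCoA summaries, and the
#'   ground-truth comparison when available.
#' @export
run_pipeline <- function(config = pipeline_config(), dataset = NULL,
                         outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(dataset)) dataset <- simulate_cohorts(config$simulation)
  val <- validate_inputs(dataset$counts, dataset$metadata, dataset$tree,
                         model = config$covariate_model)
  if (!val$valid)
    stop("input validation failed:\n  ", paste(val$errors, collapse = "\n  "))

  cohorts <- names(dataset$counts)
  keyset_by_method <- keyset_combined <- list()
  grids <- list()
  permanova_e1 <- list()
  pcoa_explained <- list()
  filtered <- list()

  for (ci in seq_along(cohorts)) {
    nm <- cohorts[ci]
    fs <- filter_samples(dataset$counts[[nm]], dataset$metadata[[nm]],
                         min_depth = config$min_depth)
    ct <- fs$counts
    md <- dataset$metadata[[nm]]
    md <- md[match(rownames(ct), md$sample_id), , drop = FALSE]
    filtered[[nm]] <- list(counts = ct, metadata = md,
                           exclusion_log = fs$exclusion_log)

    ctp <- filter_prevalence(ct, config$min_prevalence)
    comp <- multiplicative_impute(ctp)
    clr_net <- clr_transform(comp)

    nets <- list(
      pearson = pearson_network(clr_net, r_threshold = config$pearson_r,
                                fdr_alpha = config$fdr_alpha),
      sparcc = sparcc(ctp, r_threshold = config$sparcc_r,
                      fdr_alpha = config$fdr_alpha,
                      n_bootstrap = config$sparcc_bootstrap,
                      seed = stage_seed(config$seed, 1000L + ci)),
      spieceasi = spieceasi(ctp, n_subsamples = config$stars_subsamples,
                            nlambda = config$spieceasi_nlambda,
                            seed = stage_seed(config$seed, 2000L + ci)))
    ksets <- lapply(nets, call_keystones, quantile = config$keystone_quantile)
    keyset_by_method[[nm]] <- ksets
    keyset_combined[[nm]] <- combine_methods(ksets, rule = config$combine_rule)

    groups <- classify_exposure(md$birth_year)
    sub <- groups %in% c("E1", "NE2")
    permanova_e1[[nm]] <- if (sum(groups[sub] == "E1") >= 2 &&
                              sum(groups[sub] == "NE2") >= 2) {
      d <- bray_curtis(ct[sub, , drop = FALSE])
      permanova(d, droplevels(groups[sub]),
                n_permutations = config$n_permutations,
                seed = stage_seed(config$seed, 3000L + ci))
    } else NULL
    pcoa_explained[[nm]] <-
      pcoa(bray_curtis(ct), n_axes = config$pcoa_axes)$explained_fraction
  }

  shared <- shared_keystones(keyset_combined)

  for (nm in cohorts) {
    f <- filtered[[nm]]
    grids[[nm]] <- run_grid(f$counts, f$metadata, tree = dataset$tree,
                            keystones = if (length(shared)) shared else NULL,
                            cohort = nm, model = config$covariate_model)
  }
  estimates <- do.call(rbind, grids)
  rownames(estimates) <- NULL

  lin <- estimates[!estimates$outcome %in% "t2d", , drop = FALSE]
  logi <- estimates[estimates$outcome %in% "t2d", , drop = FALSE]
  pooled <- list(
    linear = if (nrow(lin)) pool_grid(lin),
    t2d = if (nrow(logi)) pool_grid(logi, exponentiate = TRUE))

  truth_comparison <- NULL
  if (!is.null(dataset$truth)) {
    tk <- dataset$truth$keystones
    rec <- vapply(keyset_combined,
                  function(s) length(intersect(s, tk)) / length(tk), 1)
    prec <- vapply(keyset_combined,
                   function(s) if (length(s)) length(intersect(s, tk)) / length(s)
                               else NA_real_, 1)
    truth_comparison <- list(
      planted_keystones = tk,
      recall_by_cohort = rec, precision_by_cohort = prec,
      shared_recall = length(intersect(shared, tk)) / length(tk),
      shared_precision = if (length(shared))
        length(intersect(shared, tk)) / length(shared) else NA_real_,
      planted_delta = dataset$truth$famine_effect_delta,
      planted_t2d_beta = dataset$truth$t2d_beta_index)
  }

  report <- list(
    config = config,
    n_samples = vapply(filtered, function(f) nrow(f$counts), 1L),
    exclusions = lapply(filtered, function(f) f$exclusion_log),
    keystones_by_method = keyset_by_method,
    keystones_combined = keyset_combined,
    shared_keystones = shared,
    permanova_e1_vs_control = permanova_e1,
    pcoa_explained = pcoa_explained,
    estimates = estimates,
    pooled = pooled,
    truth_comparison = truth_comparison)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write.table(estimates, file.path(outdir, "effect_estimates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      report[c("n_samples", "keystones_by_method", "keystones_combined",
               "shared_keystones", "pcoa_explained", "truth_comparison")],
      file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA,
      force = TRUE)
  }
  report
}
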