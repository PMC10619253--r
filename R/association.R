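# Covariate-adjusted linear and logistic association models.

effect_row <- function(cohort, outcome, term, beta, se, p, n,
                       model = "model1", scheme = "none") {
  data.frame(cohort = cohort, outcome = outcome, term = term,
             beta = beta, se = se,
             ci_low = beta - qnorm(0.975) * se,
             ci_high = beta + qnorm(0.975) * se,
             p_value = p, n = n, model = model, scheme = scheme,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Covariate columns for the standard adjustment models
#'
#' `model1` adjusts for age, sex, BMI, and use of hypoglycemic and
#' hypolipidemic medications; `model2` additionally adjusts for sequencing
#' depth plus any dietary/lifestyle columns present in the metadata;
#' `unadjusted` uses none.
#'
#' @param metadata per-sample data frame.
#' @param model `"model1"`, `"model2"`, or `"unadjusted"`.
#' @return a data frame of covariates (zero columns for `unadjusted`).
#' @export
covariate_set <- function(metadata, model = c("model1", "model2", "unadjusted")) {
  model <- match.arg(model)
  base_cols <- c("age", "sex", "bmi", "hypoglycemic", "hypolipidemic")
  cols <- switch(model,
    unadjusted = character(0),
    model1 = base_cols,
    model2 = c(base_cols, "depth",
               intersect(c("fruit", "vegetable", "fish", "red_meat", "dairy",
                           "alcohol", "smoking"), names(metadata))))
  missing <- setdiff(cols, names(metadata))
  if (length(missing))
    stop("metadata lacks covariate column(s): ", paste(missing, collapse = ", "))
  metadata[, cols, drop = FALSE]
}

#' Linear group contrasts against a reference group
#'
#' Ordinary least-squares fit of a (typically per-cohort z-scored) outcome on
#' reference-coded group indicators plus covariates; one effect estimate (in
#' SD units when the outcome is standardized) per non-reference group, with
#' normal-approximation 95% CIs.  Rows with missing values are dropped
#' (complete-case).
#'
#' @param outcome numeric per-sample outcome.
#' @param groups group label per sample.
#' @param covariates data frame of numeric covariates, or NULL.
#' @param reference reference group code (default `"NE2"`).
#' @param cohort cohort tag stored in the result.
#' @param outcome_name label stored in the result.
#' @param model,scheme labels stored in the result.
#' @return data frame of effect estimates (one row per non-reference group):
#'   cohort, outcome, term, beta, se, ci_low, ci_high, p_value, n.
#' @export
linear_group_contrast <- function(outcome, groups, covariates = NULL,
                                  reference = "NE2", cohort = NA_character_,
                                  outcome_name = "outcome",
                                  model = "model1", scheme = "none") {
  groups <- as.character(groups)
  if (!reference %in% groups) stop("reference group `", reference, "` is empty")
  df <- data.frame(.y = outcome,
                   .g = stats::relevel(factor(groups), ref = reference))
  if (!is.null(covariates) && ncol(covariates) > 0)
    df <- cbind(df, covariates)
  df <- df[complete.cases(df), , drop = FALSE]
  fit <- lm(.y ~ ., data = df)
  cf <- coef(fit)
  if (anyNA(cf))
    stop("collinear terms in the design: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  sm <- summary(fit)$coefficients
  gterms <- grep("^\\.g", rownames(sm), value = TRUE)
  out <- lapply(gterms, function(tm)
    effect_row(cohort, outcome_name,
               paste0(sub("^\\.g", "", tm), "_vs_", reference),
               sm[tm, 1], sm[tm, 2],
               2 * pnorm(-abs(sm[tm, 1] / sm[tm, 2])), nrow(df),
               model, scheme))
  do.call(rbind, out)
}

#' Logistic regression of a binary outcome on a standardized exposure
#'
#' Maximum-likelihood logistic fit of the outcome (e.g. type 2 diabetes) on
#' the exposure variable plus covariates; the coefficient is a log-odds per
#' unit (per SD for standardized exposures), reported with Wald 95% CI and
#' the odds ratio.
#'
#' @param exposure numeric per-sample exposure (per-SD scaling is the
#'   caller's responsibility).
#' @param outcome binary 0/1 outcome; both classes must be present.
#' @param covariates data frame of covariates, or NULL.
#' @param cohort,term,model,scheme labels stored in the result.
#' @return one-row data frame: beta (log-odds), se, ci_low, ci_high,
#'   p_value, n, odds_ratio, or_ci_low, or_ci_high.
#' @export
logistic_outcome <- function(exposure, outcome, covariates = NULL,
                             cohort = NA_character_, term = "per_sd",
                             model = "model1", scheme = "none") {
  df <- data.frame(.y = outcome, .x = exposure)
  if (!is.null(covariates) && ncol(covariates) > 0)
    df <- cbind(df, covariates)
  df <- df[complete.cases(df), , drop = FALSE]
  if (length(unique(df$.y)) < 2L)
    stop("outcome has a single class after complete-case filtering")
  sep_flag <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_flag <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep_flag || !fit$converged || any(abs(coef(fit)) > 30, na.rm = TRUE))
    stop("(quasi-)complete separation: logistic estimates unbounded; ",
         "check the exposure/outcome cross-tabulation")
  cf <- coef(fit)
  if (anyNA(cf))
    stop("collinear terms in the design: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  sm <- summary(fit)$coefficients
  out <- effect_row(cohort, "t2d", term, sm[".x", 1], sm[".x", 2],
                    2 * pnorm(-abs(sm[".x", 1] / sm[".x", 2])), nrow(df),
                    model, scheme)
  out$odds_ratio <- exp(out$beta)
  out$or_ci_low <- exp(out$ci_low)
  out$or_ci_high <- exp(out$ci_high)
  out
}

#' Full per-cohort association grid
#'
#' Executes, within one cohort, the standard contrast grid: each diversity
#' index (z-scored) against the exposure groups; the first two principal
#' coordinates against the groups; the keystone index against the groups;
#' and the logistic models of type 2 diabetes on each diversity index and on
#' the keystone index.  Regrouping schemes from [regroup_exposure()] and the
#' exclude-T2D sensitivity are applied when requested.  Cells whose fit is
#' infeasible (e.g. an empty reference after exclusion) are skipped and
#' logged as attribute `"skipped"`.
#'
#' @param counts samples x taxa counts matrix for the cohort (unfiltered).
#' @param metadata cohort metadata (sample_id, birth_year, age, sex, bmi,
#'   hypoglycemic, hypolipidemic, depth, t2d, ...), covering all samples.
#' @param tree optional phylogeny for Faith PD.
#' @param keystones optional shared keystone ids (enables the index models).
#' @param cohort cohort tag.
#' @param indices which diversity indices to test.
#' @param model covariate model for the group contrasts (the T2D models
#'   adjust for age, sex, and BMI).
#' @param schemes character vector from `"none"`, `"exclude_t2d"`,
#'   `"post1978_reference"`, `"control_plus_E4_reference"`,
#'   `"utero_combined"`.
#' @param pcoa_axes number of principal coordinates to test.
#' @return tidy data frame of effect estimates, one row per estimate.
#' @export
run_grid <- function(counts, metadata, tree = NULL, keystones = NULL,
                     cohort = "cohort1",
                     indices = c("observed_otus", "shannon", "pielou",
                                 "faith_pd"),
                     model = "model1", schemes = "none", pcoa_axes = 2) {
  assert_count_table(counts)
  md <- metadata[match(rownames(counts), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stop("metadata does not cover all samples")
  if (is.null(tree)) indices <- setdiff(indices, "faith_pd")

  div <- alpha_diversity(counts, tree)
  pc <- pcoa(bray_curtis(counts), n_axes = pcoa_axes)
  ki <- if (length(keystones)) keystone_index(counts, keystones) else NULL
  base_groups <- classify_exposure(md$birth_year)
  cov_t2d <- md[, c("age", "sex", "bmi"), drop = FALSE]

  rows <- list()
  skipped <- character(0)
  add <- function(expr, what) {
    r <- tryCatch(expr, error = function(e) {
      skipped <<- c(skipped, paste0(what, ": ", conditionMessage(e)))
      NULL
    })
    if (!is.null(r)) rows[[length(rows) + 1L]] <<- r
  }

  for (scheme in schemes) {
    keep <- rep(TRUE, nrow(md))
    groups <- base_groups
    reference <- "NE2"
    if (scheme == "exclude_t2d") {
      keep <- md$t2d == 0
    } else if (scheme != "none") {
      groups <- regroup_exposure(base_groups, scheme = scheme,
                                 birth_year = md$birth_year)
      reference <- attr(groups, "reference")
    }
    mds <- md[keep, , drop = FALSE]
    grs <- as.character(groups)[keep]
    covs <- covariate_set(mds, model)

    outcomes <- lapply(indices, function(ix) div[[ix]][keep])
    names(outcomes) <- indices
    for (ax in seq_len(ncol(pc$coordinates)))
      outcomes[[paste0("pcoa", ax)]] <- pc$coordinates[keep, ax]
    if (!is.null(ki)) outcomes$keystone_index <- ki$index[keep]

    for (nm in names(outcomes)) {
      y <- outcomes[[nm]]
      zs <- tryCatch(as.numeric(scale(y)), error = function(e) y)
      add(linear_group_contrast(zs, grs, covs, reference = reference,
                                cohort = cohort, outcome_name = nm,
                                model = model, scheme = scheme),
          paste(scheme, nm, "group contrast"))
      if (scheme == "none")
        add(logistic_outcome(zs, mds$t2d, cov_t2d[keep, , drop = FALSE],
                             cohort = cohort,
                             term = paste0(nm, "_per_sd"),
                             model = "age_sex_bmi", scheme = scheme),
            paste(scheme, nm, "t2d model"))
    }
  }
  if (!length(rows)) {
    out <- data.frame(cohort = character(0), outcome = character(0),
                      term = character(0), beta = numeric(0), se = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      p_value = numeric(0), n = integer(0),
                      model = character(0), scheme = character(0))
    attr(out, "skipped") <- skipped
    return(out)
  }
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cl in setdiff(all_cols, names(r))) r[[cl]] <- NA_real_
    r[, all_cols, drop = FALSE]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
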