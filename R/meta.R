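#' DerSimonian-Laird random-effects meta-analysis
#'
#' Pools per-cohort effect estimates (all on the same scale; odds ratios must
#' be supplied as log-odds) with the moment-based DerSimonian-Laird
#' between-study variance: fixed-effect weights w = 1/se^2, heterogeneity
#' Q = sum w (b - b_fixed)^2, tau^2 = max(0, (Q - (k-1)) /
#' (sum w - sum w^2 / sum w)), random-effects weights w* = 1/(se^2 + tau^2),
#' pooled beta = sum w* b / sum w*, pooled variance = 1 / sum w* (exactly),
#' Wald 95% CI, and I^2 = max(0, (Q - (k-1)) / Q).
#'
#' @param beta numeric effect estimates (k >= 2), or a data frame of effect
#'   estimates with `beta` and `se` columns (e.g. from
#'   [linear_group_contrast()]).
#' @param se standard errors (ignored when `beta` is a data frame).
#' @param labels optional study labels.
#' @param exponentiate also report the pooled estimate and CI on the
#'   exponential (odds-ratio) scale.
#' @return object of class `meta_result`: list with `k`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `p_value`, `tau2`, `Q`, `I2`, and when
#'   `exponentiate` the `odds_ratio` with its CI.
#' @examples
#' pool_random_effects(c(-0.3, -0.25, -0.35), c(0.1, 0.08, 0.12))
#' @export
pool_random_effects <- function(beta, se = NULL, labels = NULL,
                                exponentiate = FALSE) {
  if (is.data.frame(beta)) {
    se <- beta$se
    if (is.null(labels) && "cohort" %in% names(beta)) labels <- beta$cohort
    beta <- beta$beta
  }
  k <- length(beta)
  if (k < 2L) stop("random-effects pooling needs k >= 2 estimates")
  if (length(se) != k) stop("`beta` and `se` lengths differ")
  if (any(!is.finite(beta)) || any(!is.finite(se)) || any(se <= 0))
    stop("estimates must be finite with positive standard errors")

  w <- 1 / se^2
  b_fixed <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - b_fixed)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  w_star <- 1 / (se^2 + tau2)
  b <- sum(w_star * beta) / sum(w_star)
  v <- 1 / sum(w_star)
  res <- list(k = k, beta = b, se = sqrt(v),
              ci_low = b - qnorm(0.975) * sqrt(v),
              ci_high = b + qnorm(0.975) * sqrt(v),
              p_value = 2 * pnorm(-abs(b / sqrt(v))),
              tau2 = tau2, Q = Q,
              I2 = max(0, (Q - (k - 1)) / Q),
              labels = labels, estimates = beta, ses = se)
  if (exponentiate) {
    res$odds_ratio <- exp(b)
    res$or_ci_low <- exp(res$ci_low)
    res$or_ci_high <- exp(res$ci_high)
  }
  structure(res, class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("random-effects pool (k = %d): beta = %.3f [%.3f, %.3f], p = %.3g\n",
              x$k, x$beta, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("  tau2 = %.4f, Q = %.3f, I2 = %.1f%%\n", x$tau2, x$Q, 100 * x$I2))
  if (!is.null(x$odds_ratio))
    cat(sprintf("  OR = %.3f [%.3f, %.3f]\n",
                x$odds_ratio, x$or_ci_low, x$or_ci_high))
  invisible(x)
}

#' Pool a grid of effect estimates across cohorts
#'
#' Groups a tidy effect-estimate table (e.g. rbind-ed [run_grid()] outputs
#' from several cohorts) by outcome/term/model/scheme and pools each group
#' with [pool_random_effects()].
#'
#' @param estimates tidy data frame with cohort, outcome, term, beta, se,
#'   model, scheme columns.
#' @param exponentiate report odds-ratio scale too (for logistic rows).
#' @return data frame, one row per pooled contrast: outcome, term, model,
#'   scheme, k, beta, se, ci_low, ci_high, p_value, tau2, I2 (plus
#'   odds_ratio columns when `exponentiate`).
#' @export
pool_grid <- function(estimates, exponentiate = FALSE) {
  key <- interaction(estimates$outcome, estimates$term, estimates$model,
                     estimates$scheme, drop = TRUE)
  rows <- lapply(split(estimates, key), function(df) {
    if (nrow(df) < 2L) return(NULL)
    m <- pool_random_effects(df$beta, df$se, labels = df$cohort,
                             exponentiate = exponentiate)
    out <- data.frame(outcome = df$outcome[1], term = df$term[1],
                      model = df$model[1], scheme = df$scheme[1],
                      k = m$k, beta = m$beta, se = m$se,
                      ci_low = m$ci_low, ci_high = m$ci_high,
                      p_value = m$p_value, tau2 = m$tau2, I2 = m$I2,
                      stringsAsFactors = FALSE)
    if (exponentiate) {
      out$odds_ratio <- m$odds_ratio
      out$or_ci_low <- m$or_ci_low
      out$or_ci_high <- m$or_ci_high
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
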