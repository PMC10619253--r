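test_that("linear contrast without covariates equals the difference of group means", {
  y <- c(1, 2, 3, 7, 8, 9, 4, 5)
  g <- c(rep("NE2", 3), rep("E1", 3), rep("E4", 2))
  res <- linear_group_contrast(y, g, reference = "NE2")
  expect_equal(res$beta[res$term == "E1_vs_NE2"], mean(y[4:6]) - mean(y[1:3]))
  expect_equal(res$beta[res$term == "E4_vs_NE2"], mean(y[7:8]) - mean(y[1:3]))
  expect_equal(res$n, c(8, 8))
  expect_true(all(res$ci_low <= res$beta & res$beta <= res$ci_high))
  expect_error(linear_group_contrast(y, g, reference = "NE1"), "empty")
})

test_that("collinear covariates are rejected by name", {
  set.seed(61)
  y <- rnorm(40)
  g <- rep(c("NE2", "E1"), 20)
  covs <- data.frame(age = rnorm(40))
  covs$age_copy <- covs$age
  expect_error(linear_group_contrast(y, g, covs), "collinear.*age_copy")
})

test_that("logistic beta on a binary predictor equals the 2x2 closed form", {
  # saturated 2x2 with cells a=40, b=60, c=25, d=75
  x <- rep(c(1, 1, 0, 0), c(40, 60, 25, 75))
  yy <- rep(c(1, 0, 1, 0), c(40, 60, 25, 75))
  res <- logistic_outcome(x, yy)
  expect_equal(res$beta, log((40 * 75) / (60 * 25)), tolerance = 1e-6)
  expect_equal(res$odds_ratio, (40 / 60) / (25 / 75), tolerance = 1e-6)
  expect_equal(res$n, 200)

  # independent exposure: OR near 1
  set.seed(62)
  x2 <- rnorm(3000)
  y2 <- rbinom(3000, 1, 0.3)
  res2 <- logistic_outcome(x2, y2)
  expect_lt(abs(res2$beta), 3 * res2$se)
  expect_equal(res2$odds_ratio, 1, tolerance = 0.15)

  # complete separation is an error, not a silent estimate
  xs <- c(rep(0, 20), rep(1, 20))
  ys <- c(rep(0, 20), rep(1, 20))
  expect_error(logistic_outcome(xs, ys), "separation")
  expect_error(logistic_outcome(x2, rep(1, 3000)), "single class")
})

test_that("covariate sets resolve model tags and missing columns fail loudly", {
  md <- data.frame(age = 1:4, sex = 0:3 %% 2, bmi = 22:25,
                   hypoglycemic = 0, hypolipidemic = 0, depth = 5e4)
  expect_equal(names(covariate_set(md, "model1")),
               c("age", "sex", "bmi", "hypoglycemic", "hypolipidemic"))
  expect_true("depth" %in% names(covariate_set(md, "model2")))
  expect_equal(ncol(covariate_set(md, "unadjusted")), 0L)
  expect_error(covariate_set(md[, -3], "model1"), "bmi")
})

test_that("the per-cohort grid enumerates the full contrast set", {
  # force all ten groups to be present with >= 24 samples each; multi-year
  # groups get two birth years so age is not collinear with the indicators
  years <- rep(c(1938, 1940, 1943, 1945, 1948, 1951, 1953, 1955, 1956, 1958,
                 1959, 1959, 1960, 1960, 1961, 1961, 1962, 1964, 1970, 1980),
               each = 12)
  n <- length(years)
  cfg <- simulation_config(n_cohorts = 1, cohort_sizes = n, survey_years = 2015,
                           n_genera = 40, n_keystones = 3, hub_degree = 4,
                           depth_lognormal_params = c(log(3000), 0.4),
                           seed = 17)
  sim <- simulate_cohorts(cfg)
  ct <- sim$counts[[1]]
  md <- sim$metadata[[1]]
  md$birth_year <- years
  md$age <- 2015 - years

  gr <- run_grid(ct, md, tree = sim$tree, keystones = sim$truth$keystones,
                 cohort = "c1")
  div_lin <- gr[gr$outcome %in% c("observed_otus", "shannon", "pielou",
                                  "faith_pd") & grepl("_vs_NE2$", gr$term), ]
  # 4 diversity indices x 9 non-reference groups = 36 rows per cohort
  # (x 3 cohorts = the 108-row grid)
  expect_equal(nrow(div_lin), 36L)
  expect_equal(sort(unique(sub("_vs_NE2$", "", div_lin$term))),
               sort(setdiff(exposure_levels(), "NE2")))
  # one T2D logistic row per outcome (4 diversity + 2 PCoA + index)
  expect_equal(sum(gr$outcome == "t2d"), 7L)
  expect_true(all(is.finite(gr$beta) & gr$se > 0))

  # the exclusion scheme drops T2D participants before the contrasts
  gr_ex <- run_grid(ct, md, keystones = NULL, cohort = "c1",
                    indices = "observed_otus", schemes = "exclude_t2d")
  expect_true(all(gr_ex$n == sum(md$t2d == 0)))
  expect_false(any(gr_ex$outcome == "t2d"))

  # regrouping schemes change the reference group label
  gr_re <- run_grid(ct, md, keystones = NULL, cohort = "c1",
                    indices = "shannon", schemes = "control_plus_E4_reference")
  expect_true(all(grepl("_vs_REF_NE2_E4$", gr_re$term)))
})

test_that("adjusted and unadjusted estimates agree without confounding", {
  set.seed(63)
  n <- 600
  g <- sample(c("NE2", "E1"), n, replace = TRUE)
  covs <- data.frame(age = rnorm(n, 50, 8), sex = rbinom(n, 1, 0.5),
                     bmi = rnorm(n, 23, 3), hypoglycemic = rbinom(n, 1, 0.05),
                     hypolipidemic = rbinom(n, 1, 0.05))
  y <- -0.4 * (g == "E1") + rnorm(n)
  adj <- linear_group_contrast(y, g, covs)
  raw <- linear_group_contrast(y, g, NULL)
  expect_equal(adj$beta, raw$beta, tolerance = 0.05)
})

test_that("normal-approximation confidence intervals cover a planted effect", {
  set.seed(64)
  hits <- 0L
  for (r in 1:200) {
    n <- 120
    g <- rep(c("NE2", "E1"), each = n / 2)
    y <- -0.5 * (g == "E1") + rnorm(n)
    res <- linear_group_contrast(y, g)
    if (res$ci_low <= -0.5 && -0.5 <= res$ci_high) hits <- hits + 1L
  }
  # binomial(200, 0.95): 190 +/- 3 * sqrt(200 * .95 * .05) ~ [181, 199]
  expect_gte(hits, 180)
})
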