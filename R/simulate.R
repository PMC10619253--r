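#' Configuration for the multi-cohort synthetic generator
#'
#' Bundles every parameter of the synthetic study: cohort structure, the
#' planted hub co-abundance network, the planted early-life exposure effects,
#' and the disease model.  Defaults describe three cohorts of adults surveyed
#' in the mid-2010s whose birth years span 1930-1990, with a depressed
#' keystone/diversity signal confined to participants born in 1959 (exposed
#' to famine through the first 1000 days of life) and a type 2 diabetes
#' outcome whose log-odds decrease with the keystone index.
#'
#' @param n_cohorts number of cohorts.
#' @param cohort_sizes integer vector of per-cohort sample sizes
#'   (length `n_cohorts`).
#' @param n_genera number of genera.
#' @param n_keystones number of planted hub (keystone) genera.
#' @param hub_degree number of satellite genera correlated with each hub.
#' @param latent_correlation hub-satellite correlation on the latent
#'   log-abundance scale, in (0, 1).
#' @param hub_backbone_loading loading of every hub on a shared latent
#'   factor; gives hubs a mutual correlation of `hub_backbone_loading^2`
#'   so the planted network has a connected keystone core, as observed in
#'   real co-abundance networks.
#' @param birth_year_range integer `c(first, last)` birth year.
#' @param survey_years integer vector, year each cohort was sampled
#'   (age = survey year - birth year).
#' @param famine_effect_delta shift (in latent SD units) subtracted from the
#'   keystone latent means of samples born in 1959.
#' @param diversity_effect fraction of a 1959-born sample's rare taxa forced
#'   to zero, planting a richness deficit.
#' @param t2d_beta_index log-odds of type 2 diabetes per SD of the true
#'   (latent) keystone index.
#' @param t2d_base_rate baseline type 2 diabetes probability.
#' @param depth_lognormal_params `c(meanlog, sdlog)` of the per-sample
#'   sequencing-depth lognormal.
#' @param birth_year_weights optional non-negative weights over the birth
#'   years in `birth_year_range` (default uniform).
#' @param seed integer; one RNG stream drives the whole dataset, so an
#'   identical config yields a bit-identical dataset.
#' @return an object of class `simulation_config`.
#' @seealso [simulate_cohorts()]
#' @export
simulation_config <- function(n_cohorts = 3,
                              cohort_sizes = c(500, 500, 500),
                              n_genera = 300,
                              n_keystones = 6,
                              hub_degree = 10,
                              latent_correlation = 0.7,
                              hub_backbone_loading = 0.8,
                              birth_year_range = c(1930, 1990),
                              survey_years = c(2016, 2015, 2015),
                              famine_effect_delta = 0.8,
                              diversity_effect = 0.1,
                              t2d_beta_index = -0.14,
                              t2d_base_rate = 0.12,
                              depth_lognormal_params = c(meanlog = log(4e4), sdlog = 0.3),
                              birth_year_weights = NULL,
                              seed = 1L) {
  cfg <- list(n_cohorts = as.integer(n_cohorts),
              cohort_sizes = as.integer(cohort_sizes),
              n_genera = as.integer(n_genera),
              n_keystones = as.integer(n_keystones),
              hub_degree = as.integer(hub_degree),
              latent_correlation = latent_correlation,
              hub_backbone_loading = hub_backbone_loading,
              birth_year_range = as.integer(birth_year_range),
              survey_years = as.integer(survey_years),
              famine_effect_delta = famine_effect_delta,
              diversity_effect = diversity_effect,
              t2d_beta_index = t2d_beta_index,
              t2d_base_rate = t2d_base_rate,
              depth_lognormal_params = depth_lognormal_params,
              birth_year_weights = birth_year_weights,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    if (n_cohorts < 1L || n_genera < 1L || n_keystones < 1L || hub_degree < 1L)
      stop("all counts in a simulation_config must be >= 1")
    if (length(cohort_sizes) != n_cohorts)
      stop("`cohort_sizes` must have length `n_cohorts`")
    if (any(cohort_sizes < 1L)) stop("all cohort sizes must be >= 1")
    if (length(survey_years) != n_cohorts)
      stop("`survey_years` must have length `n_cohorts`")
    if (n_keystones >= n_genera) stop("`n_keystones` must be < `n_genera`")
    if (n_keystones * hub_degree >= n_genera)
      stop("infeasible hub structure: n_keystones * hub_degree must be < n_genera")
    if (latent_correlation <= 0 || latent_correlation >= 1)
      stop("`latent_correlation` must lie in (0, 1)")
    if (hub_backbone_loading < 0 || hub_backbone_loading >= 1)
      stop("`hub_backbone_loading` must lie in [0, 1)")
    if (t2d_base_rate <= 0 || t2d_base_rate >= 1)
      stop("`t2d_base_rate` must lie in (0, 1)")
    if (diversity_effect < 0 || diversity_effect > 1)
      stop("`diversity_effect` must lie in [0, 1]")
    if (diff(birth_year_range) < 0) stop("`birth_year_range` must be increasing")
    if (!is.null(birth_year_weights)) {
      nyr <- diff(birth_year_range) + 1L
      if (length(birth_year_weights) != nyr || any(birth_year_weights < 0))
        stop("`birth_year_weights` must be non-negative, one per birth year")
    }
  })
  invisible(cfg)
}

# analytic correlation matrix implied by the hub/satellite factor model
true_correlation_matrix <- function(taxa, hubs, sat_of, a, b) {
  p <- length(taxa)
  rho <- diag(p)
  dimnames(rho) <- list(taxa, taxa)
  hub_idx <- match(hubs, taxa)
  # hub-hub
  rho[hub_idx, hub_idx] <- b^2
  for (h in seq_along(hubs)) {
    s <- match(sat_of[[h]], taxa)
    i <- hub_idx[h]
    rho[i, s] <- rho[s, i] <- a               # own hub vs satellite
    rho[s, s] <- a^2                           # satellites sharing a hub
    for (h2 in seq_along(hubs)) {
      if (h2 == h) next
      s2 <- match(sat_of[[h2]], taxa)
      rho[s, s2] <- a^2 * b^2                  # satellites of different hubs
      rho[hub_idx[h2], s] <- rho[s, hub_idx[h2]] <- a * b^2
    }
  }
  diag(rho) <- 1
  rho
}

#' Simulate a multi-cohort microbiome study with planted effects
#'
#' Draws, per cohort, latent genus log-abundances from a hub-structured
#' logistic-normal model, converts them to compositions by softmax, and
#' samples sparse overdispersed counts by a multinomial at a lognormal
#' sequencing depth.  Samples born in 1959 have their keystone latent means
#' reduced by `famine_effect_delta` and a `diversity_effect` fraction of
#' their rare taxa zeroed (so the planted deficit shows up in observed
#' richness, not just mean shifts).  Type 2 diabetes is drawn from a
#' logistic model on the standardized true keystone index plus small age and
#' BMI nuisance terms.
#'
#' @param config a [simulation_config()].
#' @return an object of class `synthetic_dataset`: a list with `counts`
#'   (per-cohort integer matrices, samples x genera), `metadata` (per-cohort
#'   data frames with sample_id, cohort, birth_year, age, sex, bmi,
#'   antibiotic_use, hypoglycemic, hypolipidemic, depth, t2d), `tree`
#'   (Newick string over all genera), `truth` (planted keystone/satellite
#'   ids, the analytic latent correlation matrix, the planted effect sizes,
#'   and per-cohort latent keystone sums), and the `config`.
#' @examples
#' cfg <- simulation_config(cohort_sizes = c(40, 40, 40), n_genera = 40,
#'                          n_keystones = 3, hub_degree = 4, seed = 7)
#' sim <- simulate_cohorts(cfg)
#' sapply(sim$counts, dim)
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  validate_simulation_config(config)
  set.seed(config$seed)

  p <- config$n_genera
  K <- config$n_keystones
  taxa <- sprintf("g%03d", seq_len(p))
  hubs <- sort(sample(taxa, K))
  pool <- setdiff(taxa, hubs)
  sat_of <- list()
  for (h in seq_len(K)) {
    sat_of[[h]] <- sort(sample(pool, config$hub_degree))
    pool <- setdiff(pool, sat_of[[h]])
  }
  names(sat_of) <- hubs
  network_taxa <- c(hubs, unlist(sat_of))
  a <- config$latent_correlation
  b <- config$hub_backbone_loading
  rho_true <- true_correlation_matrix(taxa, hubs, sat_of, a, b)

  # baseline log-abundance profile; hubs sit at a modest abundance
  mu <- rnorm(p, 0, 1.5)
  names(mu) <- taxa
  mu[hubs] <- rnorm(K, stats::median(mu) + 0.5, 0.2)

  years <- seq(config$birth_year_range[1], config$birth_year_range[2])
  wts <- config$birth_year_weights
  if (is.null(wts)) wts <- rep(1, length(years))

  counts <- metadata <- keystone_latent <- vector("list", config$n_cohorts)
  names(counts) <- names(metadata) <- names(keystone_latent) <-
    sprintf("cohort%d", seq_len(config$n_cohorts))

  for (cidx in seq_len(config$n_cohorts)) {
    n <- config$cohort_sizes[cidx]
    offset <- rnorm(p, 0, 0.5)                 # cohort compositional shift
    mu_c <- mu + offset

    # latent z via the factor model (unit marginal variances)
    g  <- rnorm(n)
    Fh <- matrix(rnorm(n * K), n, K)
    z  <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, taxa))
    zhub <- b * g + sqrt(1 - b^2) * Fh         # n x K
    z[, hubs] <- zhub
    for (h in seq_len(K))
      z[, sat_of[[h]]] <- a * zhub[, h] +
        sqrt(1 - a^2) * matrix(rnorm(n * config$hub_degree), n)

    birth_year <- sample(years, n, replace = TRUE, prob = wts)
    exposed <- birth_year == 1959L

    y <- sweep(z, 2, mu_c, "+")
    if (any(exposed))
      y[exposed, hubs] <- y[exposed, hubs] - config$famine_effect_delta

    prob <- exp(y - apply(y, 1, max))
    prob <- prob / rowSums(prob)

    # plant the richness deficit: zero a fraction of each exposed sample's
    # rare (low-mean, non-network) taxa before the multinomial draw
    rare_pool <- setdiff(taxa, network_taxa)
    rare_pool <- rare_pool[mu_c[rare_pool] <= stats::median(mu_c[rare_pool])]
    if (config$diversity_effect > 0 && any(exposed) && length(rare_pool) > 1) {
      n_zero <- ceiling(config$diversity_effect * length(rare_pool))
      for (i in which(exposed)) {
        drop <- sample(rare_pool, n_zero)
        prob[i, drop] <- 0
      }
      prob <- prob / rowSums(prob)
    }

    depth <- pmax(1000L, as.integer(round(rlnorm(n,
      config$depth_lognormal_params[1], config$depth_lognormal_params[2]))))
    cnt <- t(vapply(seq_len(n),
                    function(i) rmultinom(1, depth[i], prob[i, ])[, 1],
                    integer(p)))
    dimnames(cnt) <- list(sprintf("%s_s%04d", names(counts)[cidx], seq_len(n)), taxa)

    age <- config$survey_years[cidx] - birth_year
    sex <- rbinom(n, 1, 0.55)
    bmi <- rnorm(n, 23.5, 3.5)
    idx_raw <- rowSums(y[, hubs, drop = FALSE])
    idx_z <- as.numeric(scale(idx_raw))
    lp <- qlogis(config$t2d_base_rate) + config$t2d_beta_index * idx_z +
      0.03 * (age - mean(age)) + 0.05 * (bmi - mean(bmi))
    t2d <- rbinom(n, 1, plogis(lp))

    metadata[[cidx]] <- data.frame(
      sample_id = rownames(cnt),
      cohort = names(counts)[cidx],
      birth_year = birth_year,
      age = age, sex = sex, bmi = bmi,
      antibiotic_use = rbinom(n, 1, 0.03),
      hypoglycemic = rbinom(n, 1, 0.06),
      hypolipidemic = rbinom(n, 1, 0.08),
      depth = depth, t2d = t2d,
      stringsAsFactors = FALSE)
    counts[[cidx]] <- cnt
    keystone_latent[[cidx]] <- setNames(idx_raw, rownames(cnt))
  }

  structure(list(
    counts = counts,
    metadata = metadata,
    tree = simulate_tree(taxa, seed = config$seed),
    truth = list(keystones = hubs, satellites = sat_of,
                 correlation = rho_true,
                 famine_effect_delta = config$famine_effect_delta,
                 t2d_beta_index = config$t2d_beta_index,
                 keystone_latent = keystone_latent),
    config = config), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", length(x$counts), "cohorts,",
      ncol(x$counts[[1]]), "genera,",
      sum(vapply(x$counts, nrow, 1L)), "samples\n")
  cat("planted keystones:", paste(x$truth$keystones, collapse = " "), "\n")
  invisible(x)
}

#' Simulate a random genus phylogeny
#'
#' Random bifurcating tree with positive branch lengths whose leaf set is
#' exactly `genus_ids`, for Faith's phylogenetic diversity on synthetic data.
#'
#' @param genus_ids character vector of unique genus ids (>= 2).
#' @param seed integer RNG seed.
#' @return a Newick string.
#' @export
simulate_tree <- function(genus_ids, seed = 1L) {
  if (length(genus_ids) < 2L) stop("need at least 2 genera to build a tree")
  if (anyDuplicated(genus_ids)) stop("duplicate genus ids")
  set.seed(as.integer(seed))
  tr <- ape::rtree(length(genus_ids), tip.label = genus_ids)
  ape::write.tree(tr)
}

#' Write a synthetic dataset to disk
#'
#' Per-cohort counts and metadata as TSV, the phylogeny as Newick, and the
#' ground-truth record as JSON.
#'
#' @param dataset a `synthetic_dataset`.
#' @param outdir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_synthetic <- function(dataset, outdir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(dataset$counts)) {
    pc <- file.path(outdir, paste0(nm, "_counts.tsv"))
    write_count_tsv(dataset$counts[[nm]], pc)
    pm <- file.path(outdir, paste0(nm, "_metadata.tsv"))
    write.table(dataset$metadata[[nm]], pm, sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths <- c(paths, pc, pm)
  }
  pt <- file.path(outdir, "tree.nwk")
  writeLines(dataset$tree, pt)
  truth <- dataset$truth
  truth$correlation <- NULL                    # large; recomputable from config
  truth$keystone_latent <- NULL
  pg <- file.path(outdir, "ground_truth.json")
  jsonlite::write_json(truth, pg, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, pt, pg))
}
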