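test_that("Pearson network keeps exactly the edges a brute-force oracle keeps", {
  # planted 3-taxon correlated block among 7 noise taxa
  set.seed(11)
  n <- 500
  z <- rnorm(n)
  X <- cbind(sapply(1:3, function(i) sqrt(0.8) * z + sqrt(0.2) * rnorm(n)),
             matrix(rnorm(n * 7), n, 7))
  colnames(X) <- paste0("t", 1:10)
  rownames(X) <- paste0("s", seq_len(n))
  net <- pearson_network(X, r_threshold = 0.3, fdr_alpha = 0.05)

  # oracle: loop over pairs with cor.test + hand BH
  pairs <- t(combn(10, 2))
  r_o <- p_o <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    ct <- cor.test(X[, pairs[k, 1]], X[, pairs[k, 2]])
    r_o[k] <- unname(ct$estimate); p_o[k] <- ct$p.value
  }
  keep_o <- abs(r_o) > 0.3 & hand_bh(p_o) < 0.05
  edges_o <- sort(paste(pairs[keep_o, 1], pairs[keep_o, 2]))
  ij <- which(upper.tri(net$A) & net$A != 0, arr.ind = TRUE)
  edges_net <- sort(paste(ij[, 1], ij[, 2]))
  expect_identical(edges_net, edges_o)
  expect_setequal(edges_o, c("1 2", "1 3", "2 3"))   # the planted block

  # duplicated taxon: r = 1 edge survives
  Xd <- cbind(X[, 1:4], dup = X[, 1])
  netd <- pearson_network(Xd)
  expect_equal(netd$A["t1", "dup"], 1)

  # independent Gaussians: (near-)zero edge density
  set.seed(12)
  Xn <- matrix(rnorm(500 * 20), 500, 20,
               dimnames = list(NULL, paste0("n", 1:20)))
  expect_lte(n_edges(pearson_network(Xn)), 1)

  # constant column excluded with a warning
  Xc <- cbind(X[, 1:3], const = rep(1, n))
  expect_warning(netc <- pearson_network(Xc), "constant")
  expect_false("const" %in% netc$taxa)
})

test_that("SparCC estimates are symmetric, calibrated on nulls, and recover a planted pair", {
  # null: independent compositions -> empty network at the 0.2 threshold
  set.seed(31)
  ct0 <- lnm_counts(200, diag(30), depth = 5e3, seed = 31)
  net0 <- sparcc(ct0, n_bootstrap = 50, seed = 1)
  rho0 <- attr(net0, "rho")
  expect_equal(rho0, t(rho0))
  expect_equal(unname(diag(rho0)), rep(1, 30))
  expect_lte(n_edges(net0), 2)
  expect_lt(max(abs(rho0[upper.tri(rho0)])), 0.35)

  # planted pair with latent correlation 0.9 among 50 background taxa
  sigma <- diag(52)
  sigma[1, 2] <- sigma[2, 1] <- 0.9
  ct1 <- lnm_counts(300, sigma, depth = 2e4, seed = 7)
  net1 <- sparcc(ct1, n_bootstrap = 50, seed = 2)
  rho1 <- attr(net1, "rho")
  expect_gt(rho1["g1", "g2"], 0.5)
  expect_gt(net1$A["g1", "g2"], 0)           # edge kept
  # and that pair is the strongest association in the matrix
  off <- abs(rho1); diag(off) <- 0
  expect_equal(max(off), off["g1", "g2"])

  expect_error(sparcc(toy_counts(matrix(1, 5, 2))), ">= 3 taxa")
})

test_that("neighborhood-selection network is deterministic, null-calibrated, and finds hub neighbors", {
  # determinism
  set.seed(41)
  ct <- lnm_counts(120, diag(15), depth = 1e4, seed = 41)
  n1 <- suppressWarnings(spieceasi(ct, n_subsamples = 8, nlambda = 8, seed = 5))
  n2 <- suppressWarnings(spieceasi(ct, n_subsamples = 8, nlambda = 8, seed = 5))
  expect_identical(n1$A, n2$A)

  # independent taxa -> empty or near-empty graph
  expect_lte(n_edges(n1), 3)

  # planted hub with 5 strong partial correlations, n = 400
  p <- 30
  prec <- diag(p)
  for (j in 2:6) { prec[1, j] <- prec[j, 1] <- -0.32 }
  sigma <- solve(prec)
  dsig <- sqrt(diag(sigma))
  sigma <- sigma / outer(dsig, dsig)
  ct_hub <- lnm_counts(400, sigma, depth = 2e4, seed = 17)
  net <- spieceasi(ct_hub, n_subsamples = 15, nlambda = 15, seed = 3)
  truth <- paste0("g", 2:6)
  found <- net$taxa[net$A["g1", ] > 0]
  expect_true(all(truth %in% found))         # every true neighbor recovered
  # and the true neighbors dominate the hub's edge weights (the CLR
  # closure adds weak induced edges, which must rank below the truth)
  top5 <- names(sort(net$A["g1", ], decreasing = TRUE))[1:5]
  jac <- length(intersect(top5, truth)) / length(union(top5, truth))
  expect_gte(jac, 0.6)
})

test_that("eigenvector centrality matches a power-iteration oracle and known shapes", {
  # weighted 5-node toy graph
  A <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  A["a", "b"] <- A["b", "a"] <- 0.9
  A["a", "c"] <- A["c", "a"] <- 0.5
  A["b", "c"] <- A["c", "b"] <- 0.3
  A["c", "d"] <- A["d", "c"] <- 0.7
  A["d", "e"] <- A["e", "d"] <- 0.2
  net <- coab_network(letters[1:5], A, method = "pearson_clr")
  cent <- eigenvector_centrality(net)
  oracle <- power_iteration(A)
  expect_equal(as.numeric(cent), oracle$vector, tolerance = 1e-8)
  expect_equal(attr(cent, "lambda"), oracle$lambda, tolerance = 1e-8)

  # complete graph: all equal; star: center maximal
  K <- matrix(1, 4, 4) - diag(4)
  dimnames(K) <- list(paste0("k", 1:4), paste0("k", 1:4))
  ck <- eigenvector_centrality(coab_network(paste0("k", 1:4), K,
                                            method = "pearson_clr"))
  expect_equal(as.numeric(ck), rep(1, 4))
  S <- matrix(0, 5, 5, dimnames = list(paste0("v", 1:5), paste0("v", 1:5)))
  S[1, 2:5] <- S[2:5, 1] <- 1
  cs <- eigenvector_centrality(coab_network(paste0("v", 1:5), S,
                                            method = "pearson_clr"))
  expect_equal(names(which.max(cs)), "v1")
  expect_equal(max(cs), 1)

  # disconnected: centrality zero outside the largest component
  D <- matrix(0, 6, 6, dimnames = list(paste0("d", 1:6), paste0("d", 1:6)))
  D[1, 2] <- D[2, 1] <- D[2, 3] <- D[3, 2] <- D[1, 3] <- D[3, 1] <- 1
  D[5, 6] <- D[6, 5] <- 1
  cd <- eigenvector_centrality(coab_network(paste0("d", 1:6), D,
                                            method = "pearson_clr"))
  expect_true(all(cd[4:6] == 0))
  expect_true(all(cd[1:3] > 0))

  # edgeless network: all zero, with warning
  E0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(c0 <- eigenvector_centrality(
    coab_network(letters[1:3], E0, method = "pearson_clr")), "no edges")
  expect_true(all(c0 == 0))
})

test_that("keystone calling follows the strict 95% quantile rule", {
  # 100 distinct values -> exactly 5 above the 95% quantile
  cent <- setNames(seq(0.01, 1, length.out = 100), paste0("t", 1:100))
  ks <- call_keystones(cent)
  expect_equal(length(ks), 5L)
  expect_setequal(ks, paste0("t", 96:100))

  # ties at the quantile are excluded; all-equal -> empty set
  expect_equal(call_keystones(setNames(rep(0.5, 20), paste0("t", 1:20))),
               character(0))

  # hand-built 20 values: quantile(type 7) check
  set.seed(2)
  v <- setNames(round(runif(20), 3), paste0("x", 1:20))
  q <- as.numeric(quantile(v, 0.95))
  expect_setequal(call_keystones(v), names(v)[v > q])
})

test_that("module detection matches a restricted brute-force modularity oracle", {
  # two 5-cliques joined by a single edge
  A <- matrix(0, 10, 10, dimnames = list(paste0("m", 1:10), paste0("m", 1:10)))
  A[1:5, 1:5] <- 1; A[6:10, 6:10] <- 1; diag(A) <- 0
  A[5, 6] <- A[6, 5] <- 1
  net <- detect_modules(coab_network(paste0("m", 1:10), A,
                                     method = "pearson_clr"))
  expect_equal(length(unique(net$modules)), 2L)
  expect_equal(length(unique(net$modules[1:5])), 1L)
  expect_equal(length(unique(net$modules[6:10])), 1L)

  # oracle: enumerate all 2-block partitions, compute modularity directly
  m2 <- sum(A) # = 2m
  deg <- rowSums(A)
  modularity_of <- function(member) {
    q <- 0
    for (i in 1:10) for (j in 1:10)
      if (member[i] == member[j])
        q <- q + A[i, j] - deg[i] * deg[j] / m2
    q / m2
  }
  best <- -Inf; best_member <- NULL
  for (code in 0:(2^9 - 1)) {               # node 1 fixed in block 0
    member <- c(0, as.integer(intToBits(code))[1:9])
    q <- modularity_of(member)
    if (q > best) { best <- q; best_member <- member }
  }
  expect_equal(sort(unname(tapply(1:10, best_member, paste, collapse = ","))),
               sort(unname(tapply(1:10, net$modules, paste, collapse = ","))))

  # empty graph -> all singletons
  E0 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  net0 <- detect_modules(coab_network(letters[1:4], E0, method = "sparcc"))
  expect_equal(length(unique(net0$modules)), 4L)
})

test_that("method combination and cross-cohort sharing are plain set arithmetic", {
  sets <- list(c("a", "b"), c("b", "c"), "b")
  expect_equal(combine_methods(sets, "majority"), "b")
  expect_setequal(combine_methods(sets, "any"), c("a", "b", "c"))
  expect_equal(combine_methods(sets, "all"), "b")
  expect_equal(combine_methods(list(c("a", "b"), c("b", "c"), c("a", "c")),
                               "all"), character(0))
  same <- list(c("x", "y"), c("y", "x"), c("x", "y"))
  expect_setequal(combine_methods(same, "majority"), c("x", "y"))
  expect_setequal(combine_methods(same, "all"), c("x", "y"))
  expect_error(combine_methods(sets, "bogus"))

  expect_setequal(shared_keystones(list(c("a", "b", "c"),
                                        c("b", "c", "d"),
                                        c("c", "b"))), c("b", "c"))
  expect_equal(suppressWarnings(
    shared_keystones(list(c("a"), character(0)))), character(0))
  expect_warning(shared_keystones(list("a", "b")), "no keystone")
  expect_error(shared_keystones(list("a")), ">= 2 cohorts")
})

test_that("keystone index is the summed pseudo-count CLR of shared keystones", {
  ct <- toy_counts(matrix(c(0, 9, 3,
                            5, 5, 5), 2, 3, byrow = TRUE))
  ki <- keystone_index(ct, "t1")
  # counts+1 = (1,10,4): CLR of taxon 1 = log 1 - mean(log(1,10,4))
  expect_equal(ki$index[1], log(1) - mean(log(c(1, 10, 4))))
  expect_equal(ki$index[2], 0)               # equal counts -> CLR zero

  # monotone: raising one keystone's count raises the index
  ct2 <- ct; ct2[1, 1] <- 7
  expect_gt(keystone_index(ct2, "t1")$index[1], ki$index[1])

  # multi-keystone index is the sum of single-keystone indices
  k12 <- keystone_index(ct, c("t1", "t2"))
  expect_equal(k12$index,
               keystone_index(ct, "t1")$index + keystone_index(ct, "t2")$index)

  # z-scoring by cohort
  ct4 <- toy_counts(matrix(rpois(40, 6) + 1, 4, 10))
  kiz <- keystone_index(ct4, c("t1", "t2"), cohort = c("a", "a", "b", "b"))
  expect_equal(mean(kiz$index_z[1:2]), 0)
  expect_error(keystone_index(ct, character(0)), "empty")
  expect_error(keystone_index(ct, "nope"), "absent")
})

test_that("richness correlates rank against an independent Spearman oracle", {
  set.seed(51)
  ct <- lnm_counts(12, diag(8), depth = 300, seed = 51)
  rich <- observed_richness(ct)
  res <- rank_richness_correlates(ct, rich, keystones = "g2")
  rel <- ct / rowSums(ct)
  # oracle: Pearson correlation of ranks, column by column
  for (k in seq_len(nrow(res))) {
    tx <- res$taxon[k]
    expect_equal(res$rho[k], cor(rank(rel[, tx]), rank(rich)),
                 tolerance = 1e-12)
  }
  expect_equal(res$rank, seq_len(nrow(res)))
  expect_equal(order(res$rho, decreasing = TRUE), seq_len(nrow(res)))
  expect_true(res$is_keystone[res$taxon == "g2"])

  # a genus whose relative abundance tracks richness exactly gets rank 1
  # with rho = 1: equal row totals, t1 count proportional to richness
  k <- c(1:8, 2, 4, 6, 8, 3, 7)              # presence count of t2..t9
  ct2 <- matrix(0L, 14, 10)
  for (i in 1:14) {
    ct2[i, 1 + seq_len(k[i])] <- 1           # k[i] controller taxa present
    ct2[i, 1] <- 10L * k[i]                  # the tracking genus
    ct2[i, 10] <- 1000L - 10L * k[i] - k[i]  # filler keeps totals equal
  }
  ct2 <- toy_counts(ct2)
  res2 <- rank_richness_correlates(ct2, observed_richness(ct2))
  expect_equal(res2$taxon[1], "t1")
  expect_equal(res2$rho[1], 1)
  expect_equal(res2$rank[res2$taxon == "t1"], 1L)

  expect_error(rank_richness_correlates(ct[1:5, ], rich[1:5]), ">= 10")
})
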