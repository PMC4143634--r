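test_that("pairwise r2: identity, perfect anticorrelation, null level", {
  set.seed(41)
  g <- rbinom(500, 2, 0.3)
  expect_equal(pairwise_r2(g, g), 1)
  expect_equal(pairwise_r2(g, 2 - g), 1)
  expect_error(pairwise_r2(g, rep(1, 500)), "constant")
  # independent variants: r2 concentrates near 1/n
  dos <- vapply(runif(30, 0.1, 0.5), function(f) rbinom(500, 2, f),
                numeric(500))
  pairs <- combn(30, 2)
  r2 <- apply(pairs, 2, function(p) pairwise_r2(dos[, p[1]], dos[, p[2]]))
  expect_gte(mean(r2 < 0.05), 0.95)
})

test_that("LD pruning removes duplicates and missing-data variants", {
  set.seed(42)
  n <- 80
  g1 <- rbinom(n, 2, 0.4); g2 <- rbinom(n, 2, 0.3)
  gmiss <- rbinom(n, 2, 0.3); gmiss[5] <- NA
  gm <- toy_genotypes(cbind(g1, g1, g2, gmiss))
  kept <- ld_prune(gm, r2_max = 0.99)
  expect_true(1 %in% kept)
  expect_false(2 %in% kept)     # duplicated column pruned
  expect_false(4 %in% kept)     # any missing dosage excluded up front
  # permissive threshold keeps every complete, varying variant
  expect_equal(ld_prune(gm, r2_max = 1), c(1, 2, 3))
})

test_that("mutually independent variants largely survive pruning at lenient r2", {
  set.seed(43)
  dos <- vapply(runif(60, 0.2, 0.5), function(f) rbinom(400, 2, f),
                numeric(400))
  kept <- ld_prune(toy_genotypes(dos), r2_max = 0.05)
  expect_gte(length(kept), 45)
})

test_that("principal components are centred and recover subpopulations", {
  set.seed(44)
  cfg <- cohort_config(n_subjects = 200, n_subpops = 2, fst = 0.1,
                       n_common_variants = 300, n_rv_clusters = 0,
                       rvs_per_cluster = 0, seed = 44)
  g <- simulate_genotypes(cfg)
  complete <- which(colSums(is.na(g$genotypes$dosage)) == 0 &
                      apply(g$genotypes$dosage, 2, var) > 0)
  pcs <- compute_pcs(subset_variants(g$genotypes, complete), k = 5)
  expect_equal(unname(colMeans(pcs)), rep(0, 5), tolerance = 1e-8)
  lab <- g$truth$subjects$subpop
  expect_gt(abs(cor(pcs[, 1], lab)), 0.9)
  expect_equal(ncol(compute_pcs(subset_variants(g$genotypes, complete),
                                k = 0)), 0)
})

test_that("urn weights: uniform reduction, clipping, stratification monotonicity", {
  set.seed(45)
  status <- rep(c(1, 2), 50)
  u0 <- fit_urn_weights(status, matrix(nrow = 100, ncol = 0))
  expect_equal(length(unique(round(u0$weights, 12))), 1)
  # fitted probabilities at the boundary are clipped to finite odds
  x <- c(rep(-5, 50), rep(5, 50))
  st <- c(rep(1, 50), rep(2, 50))
  u1 <- fit_urn_weights(st, cbind(x))
  expect_true(all(is.finite(u1$weights) & u1$weights > 0))
  # confounded cohort: the high-risk subpopulation gets larger weights
  cfg <- cohort_config(n_subjects = 300, n_subpops = 2, fst = 0.1,
                       subpop_shift = c(-1, 1), n_common_variants = 300,
                       n_rv_clusters = 0, rvs_per_cluster = 0, seed = 46)
  co <- simulate_cohort(cfg)
  qc <- apply_qc(co$genotypes, co$subjects, hwe_alpha = 0)
  complete <- which(colSums(is.na(qc$genotypes$dosage)) == 0 &
                      apply(qc$genotypes$dosage, 2, var) > 0)
  pcs <- compute_pcs(subset_variants(qc$genotypes, complete), k = 5)
  u2 <- fit_urn_weights(qc$subjects$affection, pcs)
  lab <- co$truth$subjects$subpop
  expect_gt(mean(u2$weights[lab == 2]), mean(u2$weights[lab == 1]))
})

test_that("case-set sampler: symmetry and direct two-subject law", {
  set.seed(47)
  # equal weights, N=4, K=2: all six subsets equally likely
  draws <- rcase_sets(rep(1, 4), 2, 12000)
  expect_true(all(colSums(draws) == 2))
  key <- apply(draws, 2, paste, collapse = "")
  freq <- table(key) / ncol(draws)
  expect_equal(length(freq), 6)
  expect_true(all(abs(freq - 1 / 6) < 0.02))
  # N=2, K=1, weights (1,3): subject 2 selected with probability 3/4
  d2 <- rcase_sets(c(1, 3), 1, 20000)
  expect_equal(mean(d2[2, ]), 0.75, tolerance = 0.02)
  expect_error(rcase_sets(c(1, 1), 2, 1), "K must be")
  expect_error(rcase_sets(c(1, 0), 1, 1), "positive")
})

test_that("sampler marginals match conditional-Bernoulli enumeration", {
  set.seed(48)
  w <- c(0.3, 0.9, 1.4, 2.2, 0.6, 1.1, 3.0)
  K <- 3
  subsets <- combn(7, K)
  probs <- apply(subsets, 2, function(s) prod(w[s]))
  probs <- probs / sum(probs)
  marg <- vapply(1:7, function(j)
    sum(probs[apply(subsets, 2, function(s) j %in% s)]), 0)
  draws <- rcase_sets(w, K, 40000)
  expect_true(all(colSums(draws) == K))
  expect_equal(unname(rowMeans(draws)), marg, tolerance = 0.015)
})

test_that("uniform-weight urn permutation reproduces the plain permutation", {
  set.seed(49)
  cfg <- calib_config(seed = 49, rvs = 15)
  co <- simulate_cohort(cfg)
  qc <- apply_qc(co$genotypes, co$subjects, hwe_alpha = 0)
  idx <- co$truth$variants$id[co$truth$variants$class == "common_index"][1]
  w <- extract_window(qc$genotypes, idx, 25000)
  st <- qc$subjects$affection
  urn <- structure(list(weights = rep(1, length(st)), fitted_p = NULL,
                        pc_scores = NULL, k = 0, converged = TRUE),
                   class = "urn_model")
  p1 <- calpha_permutation(qc$genotypes, w, st, B = 400, seed = 123)
  p2 <- stratified_permutation(qc$genotypes, w, st, urn, B = 400,
                               seed = 123)
  expect_identical(p1$p_permutation, p2$p_permutation)
})
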