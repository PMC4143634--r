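test_that("configuration invariants are enforced", {
  expect_error(cohort_config(rv_effect_mix = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(cohort_config(rv_freq_range = c(0.01, 0.06)),
               "cannot yield")
  expect_error(cohort_config(n_rv_clusters = 2, window_layout =
                               data.frame(index_position = c(2e6, 1e6),
                                          cluster_span_bp = 1e4)),
               "strictly increasing")
  expect_error(cohort_config(subpop_shift = c(0, 0, 0)), "one entry per")
})

test_that("degenerate ancestral frequencies give degenerate genotypes", {
  expect_equal(bn_subpop_freqs(0, 0.3, 3), c(0, 0, 0))
  expect_equal(bn_subpop_freqs(1, 0.3, 2), c(1, 1))
  expect_equal(bn_subpop_freqs(0.37, 0, 4), rep(0.37, 4))
})

test_that("without structure, sample frequencies track ancestral frequencies", {
  cfg <- cohort_config(n_subjects = 2000, n_subpops = 1, fst = 0,
                       n_common_variants = 150, n_rv_clusters = 1,
                       rvs_per_cluster = 5, seed = 61)
  g <- simulate_genotypes(cfg)
  f_hat <- colMeans(g$genotypes$dosage) / 2
  f_true <- g$truth$variants$f_ancestral
  se <- sqrt(f_true * (1 - f_true) / (2 * cfg$n_subjects))
  expect_gte(mean(abs(f_hat - f_true) <= 3 * se), 0.98)
})

test_that("higher fst yields larger subpopulation frequency divergence", {
  base <- list(n_subjects = 50, n_subpops = 2, n_common_variants = 200,
               n_rv_clusters = 0, rvs_per_cluster = 0, seed = 62)
  g_lo <- simulate_genotypes(do.call(cohort_config, c(base, fst = 0.01)))
  g_hi <- simulate_genotypes(do.call(cohort_config, c(base, fst = 0.3)))
  div <- function(g) mean(abs(g$truth$subpop_freqs[, 1] -
                                g$truth$subpop_freqs[, 2]))
  expect_gt(div(g_hi), div(g_lo))
})

test_that("rare-variant clusters land rare and near their index, with the mix", {
  cfg <- cohort_config(seed = 63)
  g <- simulate_genotypes(cfg)
  tv <- g$truth$variants
  rv <- tv[grepl("^rv_", tv$class), ]
  expect_equal(nrow(rv), cfg$n_rv_clusters * cfg$rvs_per_cluster)
  expect_true(all(rv$f_ancestral < 0.05))
  lay <- cfg$window_layout
  expect_true(all(abs(rv$pos - lay$index_position[rv$cluster]) <=
                    lay$cluster_span_bp / 2 + 1))
  # deterministic largest-remainder apportionment of 30 RVs at 0.5/0.2/0.3
  counts <- table(rv$class[rv$cluster == 1])
  expect_equal(unname(counts[c("rv_deleterious", "rv_protective",
                               "rv_neutral")]), c(15, 6, 9),
               ignore_attr = TRUE)
  expect_equal(sort(unique(tv$log_odds[tv$class == "rv_deleterious"])),
               log(3))
})

test_that("intercept calibration hits the target case fraction", {
  cfg <- cohort_config(n_subjects = 10000, n_subpops = 1, fst = 0,
                       n_common_variants = 10, n_rv_clusters = 1,
                       rvs_per_cluster = 5,
                       rv_effect_mix = c(0, 0, 1), or_common = 1,
                       covariate_effects = c(sex = 0, age = 0, smoke = 0,
                                             med = 0),
                       seed = 64)
  co <- simulate_cohort(cfg)
  aff <- apply(co$subjects[, paste0("htn_v", 1:4)], 1,
               function(v) any(v == 1, na.rm = TRUE))
  expect_lt(abs(mean(aff) - cfg$case_fraction_target), 0.02)
  # with a flat liability the calibrated intercept is the target log-odds
  expect_equal(attr(co$subjects, "intercept"),
               qlogis(cfg$case_fraction_target), tolerance = 1e-6)
})

test_that("a planted common-variant effect is recovered by logistic refit", {
  cfg <- cohort_config(n_subjects = 5000, n_subpops = 1, fst = 0,
                       n_common_variants = 5, n_rv_clusters = 1,
                       rvs_per_cluster = 2, rv_effect_mix = c(0, 0, 1),
                       or_common = 3, seed = 65)
  co <- simulate_cohort(cfg)
  qc <- apply_qc(co$genotypes, co$subjects, hwe_alpha = 0)
  idx <- co$truth$variants$id[co$truth$variants$class == "common_index"][1]
  j <- match(idx, qc$genotypes$variants$id)
  r <- fit_single_marker(minor_dosage(qc$genotypes, j)[, 1],
                         qc$subjects$affection,
                         covariate_matrix(qc$subjects))
  expect_lt(abs(r$beta - log(3)), 2 * r$se)
})

test_that("generation is deterministic under a fixed master seed", {
  a <- simulate_cohort(cohort_config(seed = 66))
  b <- simulate_cohort(cohort_config(seed = 66))
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$truth$variants, b$truth$variants)
})

test_that("fixtures round-trip and genes alternate across clusters", {
  co <- simulate_cohort(cohort_config(seed = 67))
  d <- tempfile()
  p <- write_fixture(co, d)
  expect_error(write_fixture(co, d), "overwrite")
  gm <- read_vcf(p$vcf)
  expect_identical(unname(gm$dosage), unname(co$genotypes$dosage))
  expect_identical(gm$variants$pos, co$genotypes$variants$pos)
  subj <- read_subjects(p$subjects)
  expect_equal(subj$id, co$subjects$id)

  track <- read_gene_track(p$bed)
  lay <- co$config$window_layout
  in_gene <- vapply(lay$index_position, classify_gene_membership,
                    TRUE, track = track)
  expect_equal(sum(in_gene), 5)          # odd clusters in genes
  expect_equal(sum(!in_gene), 5)
  expect_equal(in_gene, rep(c(TRUE, FALSE), 5))
  # empty track: everything classified not-in-gene
  empty <- tempfile(fileext = ".bed"); file.create(empty)
  tr0 <- read_gene_track(empty)
  expect_true(all(!vapply(lay$index_position, classify_gene_membership,
                          TRUE, track = tr0)))
})
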