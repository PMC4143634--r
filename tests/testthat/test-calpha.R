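test_that("C-alpha statistic matches hand-computed values", {
  expect_equal(calpha_T(list(y = 1, n = 2, p0 = 0.5)), -0.5)
  expect_equal(calpha_T(list(y = 2, n = 2, p0 = 0.5)), 0.5)
  # perfectly balanced counts leave only the negative variance terms
  n <- c(4, 10, 20); p0 <- 0.5
  expect_equal(calpha_T(list(y = n * p0, n = n, p0 = p0)),
               -sum(n * p0 * (1 - p0)))
})

test_that("closed-form T equals the brute-force accumulator exhaustively", {
  p0 <- 60 / 94
  worst <- 0
  for (m in 1:4) {
    grid <- as.matrix(expand.grid(rep(list(2:4), m)))
    for (r in seq_len(nrow(grid))) {
      n <- grid[r, ]
      ygrid <- as.matrix(expand.grid(lapply(n, function(ni) 0:ni)))
      for (q in seq_len(nrow(ygrid))) {
        y <- ygrid[q, ]
        worst <- max(worst, abs(calpha_T(list(y = y, n = n, p0 = p0)) -
                                  calpha_T_brute(y, n, p0)))
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("variance enumeration: frozen value, additivity, grouped fast path", {
  expect_equal(calpha_variance(2, 0.5), 0.25)  # enumerate u in {0,1,2}
  set.seed(12)
  for (i in 1:10) {
    n <- sample(2:12, sample(1:8, 1), replace = TRUE)
    p0 <- runif(1, 0.2, 0.8)
    expect_equal(calpha_variance(n, p0), calpha_var_naive(n, p0),
                 tolerance = 1e-12)
    expect_equal(calpha_variance(c(n, n), p0), 2 * calpha_variance(n, p0),
                 tolerance = 1e-12)
  }
})

test_that("enumerated variance matches the Monte-Carlo variance of T", {
  set.seed(13)
  n <- c(2, 2, 3, 5, 5, 5, 8); p0 <- 0.6
  reps <- 1e5
  Ts <- rowSums(vapply(seq_along(n), function(i) {
    y <- rbinom(reps, n[i], p0)
    (y - n[i] * p0)^2 - n[i] * p0 * (1 - p0)
  }, numeric(reps)))
  expect_equal(var(Ts), calpha_variance(n, p0), tolerance = 0.02)
})

test_that("asymptotic Z and one-sided p", {
  z <- calpha_z(-0.5, 0.25)
  expect_equal(z$z, -1)
  expect_equal(calpha_z(0, 1)$p_asymptotic, 0.5)
  expect_error(calpha_z(1, 0), "positive")
})

test_that("Z is approximately standard normal under the null for many variants", {
  set.seed(14)
  m <- 200; p0 <- 0.5; reps <- 2000
  n <- sample(2:6, m, replace = TRUE)
  cv <- calpha_variance(n, p0)
  zs <- vapply(seq_len(reps), function(r) {
    y <- rbinom(m, n, p0)
    calpha_T(list(y = y, n = n, p0 = p0)) / sqrt(cv)
  }, 0)
  expect_lt(abs(mean(zs)), 0.05)
  expect_lt(abs(sd(zs) - 1), 0.1)
})

test_that("case allele counts follow the case-share definition of p0", {
  set.seed(15)
  n <- 94
  status <- c(rep(2, 60), rep(1, 34))
  dos <- cbind(rbinom(n, 2, 0.3),                      # index CV
               c(rep(1, 4), rep(0, n - 4)),            # 4 copies, all cases
               c(rep(0, n - 3), 2, 1, 0),              # 3 copies, controls
               c(rep(0, n - 1), 1))                    # singleton
  gm <- toy_genotypes(dos, pos = c(1000, 1100, 1200, 1300))
  w <- extract_window(gm, "t001", 1000)
  expect_equal(w$members, c("t002", "t003"))  # singleton dropped
  inp <- case_allele_counts(gm, w, status)
  expect_equal(inp$p0, 60 / 94)
  expect_equal(inp$n, c(4, 3))
  expect_equal(inp$y, c(4, 0))   # all carriers of t003 are controls
})

test_that("label symmetry: swapping cases and controls mirrors T", {
  set.seed(16)
  y <- c(3, 1, 0); n <- c(4, 2, 3); p0 <- 0.4
  expect_equal(calpha_T(list(y = y, n = n, p0 = p0)),
               calpha_T(list(y = n - y, n = n, p0 = 1 - p0)))
})

test_that("permutation p-value formula: floor and tie behaviour", {
  n <- 40
  status <- rep(c(2, 1), n / 2)
  dos <- cbind(rbinom(n, 2, 0.3),
               c(rep(1, 2), rep(0, n - 2)), c(rep(0, n - 2), rep(1, 2)))
  gm <- toy_genotypes(dos, pos = c(1000, 1100, 1200))
  w <- extract_window(gm, "t001", 1000)
  # sampler that always returns the observed labels: every T_b ties T_obs
  obs_sampler <- function(B) matrix(as.numeric(status == 2), n, B)
  r <- calpha_permutation(gm, w, status, B = 1000, sampler = obs_sampler)
  expect_equal(r$p_permutation, 1)
  # sampler that puts every case on a non-carrier: permuted T constant and
  # (at p0 != 1/2) strictly below the all-carriers-are-cases observed T, so
  # the p-value sits on the floor 1/(B+1)
  carriers <- which(rowSums(dos[, 2:3]) > 0)
  status2 <- rep(1, n)
  status2[c(carriers, setdiff(seq_len(n), carriers)[1:(10 - length(carriers))])] <- 2
  cold <- rep(0, n); cold[setdiff(seq_len(n), carriers)[1:10]] <- 1
  cold_sampler <- function(B) matrix(cold, n, B)
  r2 <- calpha_permutation(gm, w, status2, B = 1000,
                           sampler = cold_sampler)
  expect_equal(r2$p_permutation, 1 / 1001)
})

test_that("permutation p-values sit on the (b+1)/(B+1) grid and are calibrated", {
  B <- 99
  ps <- vapply(1:100, function(r) {
    cfg <- calib_config(seed = 3000 + r, n_subjects = 80, rvs = 12)
    co <- simulate_cohort(cfg)
    qc <- apply_qc(co$genotypes, co$subjects, hwe_alpha = 0)
    idx <- co$truth$variants$id[co$truth$variants$class == "common_index"][1]
    w <- extract_window(qc$genotypes, idx, 25000)
    if (!w$applicable) return(NA_real_)
    st <- qc$subjects$affection
    if (length(unique(st)) < 2) return(NA_real_)
    calpha_permutation(qc$genotypes, w, st, B = B,
                       seed = 9000 + r)$p_permutation
  }, 0)
  ps <- ps[!is.na(ps)]
  expect_gt(length(ps), 80)
  expect_true(all(abs(ps * (B + 1) - round(ps * (B + 1))) < 1e-9))
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps), 0.65)
})
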