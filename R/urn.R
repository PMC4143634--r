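#' Pairwise r-squared between two dosage vectors
#'
#' Squared Pearson correlation of dosages over shared non-missing subjects
#' (the composite-LD convention; no phasing is attempted).
#'
#' @param g1,g2 dosage vectors of equal length.
#' @return r-squared in \[0, 1\].
#' @export
pairwise_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (stats::sd(g1[ok]) == 0 || stats::sd(g2[ok]) == 0)
    stop("constant dosage vector")
  stats::cor(g1[ok], g2[ok])^2
}

#' Greedy LD pruning
#'
#' Builds a quasi-independent variant panel for principal components:
#' variants with any missing dosage are dropped first ("no missing
#' alleles"), then a deterministic left-to-right scan keeps a variant only
#' if its r-squared with every previously kept variant within a trailing
#' comparison set (the last `lag` kept variants) is at or below `r2_max`.
#' Monomorphic variants can never be scored and are dropped.
#'
#' @param x a `genotype_matrix`.
#' @param r2_max pruning threshold (default 0.01).
#' @param lag size of the trailing comparison set (default 500 kept
#'   variants; effectively "all previous" at typical panel sizes).
#' @return integer vector of kept variant indices (into `x`).
#' @export
ld_prune <- function(x, r2_max = 0.01, lag = 500) {
  d <- x$dosage
  complete <- colSums(is.na(d)) == 0
  varying <- complete & apply(d, 2, function(v) stats::var(v) > 0)
  idx <- unname(which(varying))
  if (length(idx) == 0) return(integer())
  ds <- scale(d[, idx, drop = FALSE])   # r2 = squared cor of scaled cols
  nsub <- nrow(d)
  kept <- integer()
  for (k in seq_along(idx)) {
    cmp <- utils::tail(kept, lag)
    if (length(cmp) == 0) { kept <- c(kept, k); next }
    r <- crossprod(ds[, cmp, drop = FALSE], ds[, k]) / (nsub - 1)
    if (all(r^2 <= r2_max)) kept <- c(kept, k)
  }
  idx[kept]
}

#' Principal components of a genotype panel
#'
#' Columns are centred and scaled by `sqrt(2 f (1 - f))`, the binomial
#' standard deviation at the variant's allele frequency `f`, then the top-k
#' left singular vectors (scaled by their singular values) are returned as
#' subject scores. Signs are fixed by making each column's
#' largest-magnitude entry positive, so scores are reproducible across
#' platforms.
#'
#' @param x a `genotype_matrix`, typically restricted to an LD-pruned panel
#'   (see [ld_prune()] and [subset_variants()]).
#' @param k number of components (default 5).
#' @return numeric matrix of subject scores, up to k columns (fewer, with a
#'   warning, if the panel rank is smaller).
#' @export
compute_pcs <- function(x, k = 5) {
  if (k == 0) return(matrix(nrow = n_subjects(x), ncol = 0))
  d <- x$dosage
  if (anyNA(d)) stop("PCA panel must have no missing dosages")
  f <- colMeans(d) / 2
  keep <- f > 0 & f < 1
  d <- d[, keep, drop = FALSE]; f <- f[keep]
  if (ncol(d) < k)
    warning("panel has fewer informative variants than requested components")
  z <- sweep(sweep(d, 2, 2 * f), 2, sqrt(2 * f * (1 - f)), "/")
  sv <- svd(z, nu = min(k, min(dim(z))), nv = 0)
  ncomp <- min(k, sum(sv$d > sqrt(.Machine$double.eps) * max(sv$d)))
  if (ncomp < k) warning("panel rank ", ncomp, " < k = ", k,
                         "; returning ", ncomp, " components")
  u <- sv$u[, seq_len(ncomp), drop = FALSE]
  scores <- u %*% diag(sv$d[seq_len(ncomp)], ncomp)
  for (j in seq_len(ncomp)) {
    if (scores[which.max(abs(scores[, j])), j] < 0)
      scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(ncomp))
  rownames(scores) <- x$subjects
  scores
}

#' Fit biased-urn selection weights
#'
#' Logistic regression of case status on principal components plus clinical
#' covariates gives each subject a fitted case probability `pi_j`; the urn
#' weight is the odds `w_j = pi_j / (1 - pi_j)`, clipped to
#' \[1e-6, 1 - 1e-6\] before the odds transform. Subjects in strata with a
#' higher background case rate thus receive larger weights, and permuted
#' case sets preserve the stratification structure. With an intercept-only
#' model all weights are equal and urn sampling reduces to the uniform
#' permutation.
#'
#' @param status affection codes in \{1, 2\}.
#' @param pc_scores subjects x k score matrix (see [compute_pcs()]); may
#'   have zero columns.
#' @param covariates optional covariate matrix (see [covariate_matrix()]).
#' @return list of class `urn_model`: `weights`, `fitted_p`, `pc_scores`,
#'   `k`, `converged`.
#' @export
fit_urn_weights <- function(status, pc_scores, covariates = NULL) {
  if (!all(status %in% c(1, 2))) stop("status codes must be 1 or 2")
  y <- as.numeric(status == 2)
  if (all(y == 1) || all(y == 0)) stop("both statuses must be present")
  X <- cbind(pc_scores, covariates)
  fit <- if (is.null(X) || ncol(X) == 0) {
    suppressWarnings(stats::glm(y ~ 1, family = stats::binomial()))
  } else {
    suppressWarnings(stats::glm(y ~ X, family = stats::binomial()))
  }
  pi_hat <- pmin(pmax(stats::fitted(fit), 1e-6), 1 - 1e-6)
  structure(list(weights = pi_hat / (1 - pi_hat), fitted_p = pi_hat,
                 pc_scores = pc_scores,
                 k = if (is.null(pc_scores)) 0 else ncol(pc_scores),
                 converged = fit$converged),
            class = "urn_model")
}

#' @export
print.urn_model <- function(x, ...) {
  cat(sprintf("<urn_model> %d subjects, %d PCs, weights in [%.3g, %.3g]%s\n",
              length(x$weights), x$k, min(x$weights), max(x$weights),
              if (!x$converged) " (fit did not converge)" else ""))
  invisible(x)
}

# log elementary-symmetric-polynomial table for weights w:
# logE[j, k+1] = log e_k(w_j, ..., w_N), computed by backward recursion.
esp_log_table <- function(logw, K) {
  N <- length(logw)
  logE <- matrix(-Inf, N + 1, K + 1)
  logE[, 1] <- 0                       # e_0 = 1
  for (j in N:1) {
    kmax <- min(K, N - j + 1)
    for (k in seq_len(kmax)) {
      a <- logE[j + 1, k + 1]
      b <- logw[j] + logE[j + 1, k]
      m <- max(a, b)
      logE[j, k + 1] <- if (is.finite(m)) m + log(exp(a - m) + exp(b - m)) else -Inf
    }
  }
  logE
}

#' Draw fixed-size case sets from the multivariate Fisher noncentral
#' hypergeometric distribution
#'
#' Samples subsets S of exactly `K` subjects with probability proportional
#' to the product of the selected subjects' weights (the conditional
#' Bernoulli law). Sampling is exact and sequential: subject j is selected
#' with probability `w_j e_\{k-1\}(w_\{j+1..N\}) / e_k(w_\{j..N\})`, using a
#' log-space elementary-symmetric-polynomial table — no rejection step, so
#' every draw has exactly `K` cases by construction. With equal weights this
#' is the uniform distribution over K-subsets.
#'
#' @param weights positive, finite per-subject weights.
#' @param K number of cases to label, between 1 and N - 1.
#' @param B number of draws.
#' @return N x B 0/1 matrix; each column is one case-indicator vector with
#'   column sum `K`.
#' @export
rcase_sets <- function(weights, K, B = 1) {
  N <- length(weights)
  if (!all(is.finite(weights) & weights > 0))
    stop("weights must be positive and finite")
  if (K < 1 || K > N - 1) stop("K must be between 1 and N-1")
  logw <- log(weights)
  logE <- esp_log_table(logw, K)
  out <- matrix(0L, N, B)
  k <- rep(K, B)                     # cases still to place, per draw
  for (j in seq_len(N)) {
    active <- which(k > 0)
    if (length(active) == 0) break
    # P(take j | k left) = w_j e_{k-1}(w_{j+1..N}) / e_k(w_{j..N});
    # equals 1 exactly when the remaining subjects must all be taken
    p_sel <- exp(logw[j] + logE[j + 1, k[active]] - logE[j, k[active] + 1])
    sel <- active[stats::runif(length(active)) < p_sel]
    out[j, sel] <- 1L
    k[sel] <- k[sel] - 1L
  }
  out
}

#' Build a case-set sampler from an urn model
#' @param urn an `urn_model`.
#' @param K case count each draw must contain.
#' @return function(B) returning an N x B 0/1 indicator matrix, suitable as
#'   the `sampler` argument of [calpha_permutation()].
#' @export
urn_sampler <- function(urn, K) {
  force(urn); force(K)
  function(B) rcase_sets(urn$weights, K, B)
}

#' Stratification-adjusted permutation p-value
#'
#' The biased-urn analogue of [calpha_permutation()]: `B` case relabelings
#' are drawn from the weighted urn (case count fixed at its observed
#' value), T is recomputed for each, and `p = (1 + #\{T_b >= T_obs\}) /
#' (1 + B)`.
#'
#' @param x a `genotype_matrix`.
#' @param window a `window_spec`.
#' @param status affection codes in \{1, 2\}.
#' @param urn an `urn_model` fitted on these subjects.
#' @param B number of urn samples (default 1000).
#' @param seed optional integer seed.
#' @return a `calpha_result`.
#' @export
stratified_permutation <- function(x, window, status, urn, B = 1000,
                                   seed = NULL) {
  stopifnot(inherits(urn, "urn_model"),
            length(urn$weights) == length(status))
  K <- sum(status == 2)
  calpha_permutation(x, window, status, B = B,
                     sampler = urn_sampler(urn, K), seed = seed)
}
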