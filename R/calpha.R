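#' Per-variant case allele counts for the C-alpha test
#'
#' For each rare variant in a window, `n` is the total number of
#' minor-allele copies observed across all subjects and `y` the number of
#' those copies carried by cases. `p0` is the proportion of cases among all
#' subjects: under the null every minor-allele copy falls in a case with
#' probability `p0`, so the `y` are binomial(`n`, `p0`). A homozygous
#' carrier contributes two copies. Missing dosages contribute to neither
#' count.
#'
#' @param x a `genotype_matrix`.
#' @param window a `window_spec` from [extract_window()].
#' @param status affection codes in \{1, 2\} (2 = case).
#' @return list of class `calpha_input`: `y`, `n`, `p0`, `n_cases`,
#'   `n_subjects`.
#' @export
case_allele_counts <- function(x, window, status) {
  stopifnot(inherits(window, "window_spec"))
  if (!all(status %in% c(1, 2))) stop("status codes must be 1 or 2")
  n_case <- sum(status == 2)
  if (n_case == 0 || n_case == length(status))
    stop("both cases and controls are required")
  md <- minor_dosage(x, window$member_idx)
  md[is.na(md)] <- 0
  n <- colSums(md)
  y <- colSums(md[status == 2, , drop = FALSE])
  structure(list(y = unname(y), n = unname(n),
                 p0 = n_case / length(status),
                 n_cases = n_case, n_subjects = length(status)),
            class = "calpha_input")
}

#' C-alpha overdispersion statistic
#'
#' `T = sum_i [ (y_i - n_i p0)^2 - n_i p0 (1 - p0) ]`: the excess of the
#' squared deviation of each variant's case count from its binomial
#' expectation over the binomial variance. Under the null (every variant's
#' case share equals `p0`) T has mean zero; a mixture of deleterious and
#' protective variants inflates it.
#'
#' @param input a `calpha_input`, or a list with `y`, `n`, `p0`.
#' @return the statistic T.
#' @export
calpha_T <- function(input) {
  y <- input$y; n <- input$n; p0 <- input$p0
  stopifnot(length(y) == length(n), all(y >= 0), all(y <= n),
            p0 > 0, p0 < 1)
  sum((y - n * p0)^2 - n * p0 * (1 - p0))
}

#' Null variance of the C-alpha statistic
#'
#' Exact enumeration: `c = sum_i sum_u Bin(u; n_i, p0) [ (u - n_i p0)^2 -
#' n_i p0 (1-p0) ]^2`, evaluated once per distinct copy count `n_i` (windows
#' typically hold many variants with identical totals).
#'
#' @param n vector of total minor-allele copy counts (each at least 2;
#'   singletons are removed upstream).
#' @param p0 null case share, in (0, 1).
#' @return nonnegative variance `c`.
#' @export
calpha_variance <- function(n, p0) {
  stopifnot(all(n >= 0), p0 > 0, p0 < 1)
  tab <- table(n)
  vals <- as.numeric(names(tab))
  per <- vapply(vals, function(ni) {
    u <- 0:ni
    w <- stats::dbinom(u, ni, p0)
    sum(w * ((u - ni * p0)^2 - ni * p0 * (1 - p0))^2)
  }, 0)
  sum(per * as.numeric(tab))
}

#' Asymptotic C-alpha Z and p-value
#'
#' `Z = T / sqrt(c)`; p is the upper-tail standard normal probability
#' (one-sided: the mixture alternative inflates T upward only). Kept as a
#' diagnostic alongside the permutation p-value, which is the primary
#' result.
#'
#' @param T the C-alpha statistic.
#' @param c its null variance (must be positive).
#' @return list `z`, `p_asymptotic`.
#' @export
calpha_z <- function(T, c) {
  if (c <= 0) stop("variance must be positive")
  z <- T / sqrt(c)
  list(z = z, p_asymptotic = stats::pnorm(z, lower.tail = FALSE))
}

# T for B relabelings at once: P is an n_subjects x B 0/1 case-indicator
# matrix; md is the NA-zeroed minor-dosage matrix (subjects x m).
calpha_T_batch <- function(md, n, p0, P) {
  Y <- crossprod(md, P)                    # m x B case copy counts
  colSums((Y - n * p0)^2 - n * p0 * (1 - p0))
}

#' Permutation p-value for the C-alpha statistic
#'
#' Recomputes T under `B` case/control relabelings that keep the case count
#' fixed, and returns `p = (1 + #\{T_b >= T_obs\}) / (1 + B)` (one-sided,
#' ties counting against rejection, the add-one rule keeping p off zero).
#' By default relabelings are uniform draws of case sets; passing a
#' `sampler` (such as the one from [urn_sampler()]) substitutes any
#' fixed-size weighted scheme — the biased-urn stratification adjustment
#' uses exactly this hook.
#'
#' @param x a `genotype_matrix`.
#' @param window a `window_spec` (must be applicable).
#' @param status affection codes in \{1, 2\}.
#' @param B number of permutations (default 1000).
#' @param sampler optional function(B) returning an n_subjects x B 0/1
#'   case-indicator matrix with column sums equal to the observed case
#'   count; default: uniform case sets via equal-weight urn sampling.
#' @param seed optional integer seed applied before drawing.
#' @return list of class `calpha_result`: `T`, `c`, `z`, `p_asymptotic`,
#'   `p_permutation`, `B`, `n_rv`, `applicable`.
#' @export
calpha_permutation <- function(x, window, status, B = 1000, sampler = NULL,
                               seed = NULL) {
  stopifnot(B >= 1)
  if (!window$applicable) {
    return(structure(list(T = NA_real_, c = NA_real_, z = NA_real_,
                          p_asymptotic = NA_real_, p_permutation = NA_real_,
                          B = B, n_rv = window$n_rv, applicable = FALSE),
                     class = "calpha_result"))
  }
  inp <- case_allele_counts(x, window, status)
  T_obs <- calpha_T(inp)
  cv <- calpha_variance(inp$n, inp$p0)
  az <- if (cv > 0) calpha_z(T_obs, cv) else list(z = NA_real_,
                                                  p_asymptotic = NA_real_)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sampler)) {
    w <- rep(1, length(status))
    sampler <- function(nb) rcase_sets(w, inp$n_cases, nb)
  }
  md <- minor_dosage(x, window$member_idx)
  md[is.na(md)] <- 0
  P <- sampler(B)
  stopifnot(nrow(P) == length(status), ncol(P) == B)
  Tb <- calpha_T_batch(md, inp$n, inp$p0, P)
  p_perm <- (1 + sum(Tb >= T_obs)) / (1 + B)
  structure(list(T = T_obs, c = cv, z = az$z,
                 p_asymptotic = az$p_asymptotic, p_permutation = p_perm,
                 B = B, n_rv = window$n_rv, applicable = TRUE),
            class = "calpha_result")
}

#' @export
print.calpha_result <- function(x, ...) {
  if (!x$applicable) {
    cat(sprintf("<calpha_result> %d RV(s): n/a (fewer than 2 rare variants)\n",
                x$n_rv))
  } else {
    cat(sprintf(
      "<calpha_result> %d RVs: T = %.4g, c = %.4g, Z = %.3f, perm p = %.4g (B = %d)\n",
      x$n_rv, x$T, x$c, x$z, x$p_permutation, x$B))
  }
  invisible(x)
}
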