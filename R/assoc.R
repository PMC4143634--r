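#' Covariate matrix for association and urn models
#'
#' Builds the clinical covariate design used throughout: smoking and
#' medication 1/2 codes mapped to 0/1, age at first visit in years, and a
#' male indicator. Requires the collapsed codes added by [apply_qc()].
#'
#' @param subjects subject data.frame with `smoking`, `medication`, `age1`,
#'   `sex` columns.
#' @return numeric matrix with columns `smoke`, `med`, `age`, `sexM`.
#' @export
covariate_matrix <- function(subjects) {
  stopifnot(all(c("smoking", "medication", "age1", "sex") %in%
                  names(subjects)))
  cbind(smoke = as.numeric(subjects$smoking == 2),
        med = as.numeric(subjects$medication == 2),
        age = subjects$age1,
        sexM = as.numeric(subjects$sex == "M"))
}

#' Single-marker logistic association test
#'
#' Fits `status ~ dosage + covariates` by iteratively reweighted least
#' squares (convergence tolerance 1e-8) and returns the Wald test on the
#' dosage coefficient, the log-odds per minor-allele copy. Subjects with any
#' missing dosage, status or covariate are dropped (complete-case).
#' Non-convergence or (quasi-)separation yields a flagged result with
#' missing p-value rather than a silently unreliable one.
#'
#' @param dosage minor-allele dosage vector.
#' @param status affection codes in \{1, 2\} (2 = case).
#' @param covariates optional numeric covariate matrix (rows = subjects).
#' @param test "wald" (default) or "lrt" for a likelihood-ratio test on the
#'   dosage term.
#' @return one-row data.frame: `beta`, `se`, `p`, `n_used`, `converged`.
#' @export
fit_single_marker <- function(dosage, status, covariates = NULL,
                              test = c("wald", "lrt")) {
  test <- match.arg(test)
  y <- as.numeric(status == 2)
  if (!all(status %in% c(1, 2, NA))) stop("status codes must be 1/2/NA")
  X <- if (is.null(covariates)) matrix(nrow = length(y), ncol = 0)
       else as.matrix(covariates)
  cc <- !is.na(dosage) & !is.na(y) & rowSums(is.na(X)) == 0
  d <- dosage[cc]; yy <- y[cc]; Xc <- X[cc, , drop = FALSE]
  bad <- function() data.frame(beta = NA_real_, se = NA_real_, p = NA_real_,
                               n_used = sum(cc), converged = FALSE)
  if (sum(yy == 1) < 2 || sum(yy == 0) < 2) return(bad())
  if (length(unique(d)) < 2) return(bad())
  dat <- data.frame(y = yy, dose = d)
  form <- y ~ dose
  if (ncol(Xc) > 0) {
    dat <- cbind(dat, as.data.frame(Xc))
    form <- stats::reformulate(c("dose", colnames(Xc)), response = "y")
  }
  fit <- suppressWarnings(
    stats::glm(form, family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = 1e-8, maxit = 50)))
  co <- summary(fit)$coefficients
  if (!fit$converged || !"dose" %in% rownames(co)) return(bad())
  beta <- co["dose", "Estimate"]; se <- co["dose", "Std. Error"]
  # quasi-separation heuristic: implausible coefficient or exploded SE
  if (!is.finite(se) || se > 50 || abs(beta) > 20) return(bad())
  p <- if (test == "wald") {
    co["dose", "Pr(>|z|)"]
  } else {
    fit0 <- suppressWarnings(stats::glm(
      stats::update(form, . ~ . - dose), family = stats::binomial(),
      data = dat, control = stats::glm.control(epsilon = 1e-8, maxit = 50)))
    stats::pchisq(fit0$deviance - fit$deviance, df = 1, lower.tail = FALSE)
  }
  data.frame(beta = beta, se = se, p = p, n_used = sum(cc), converged = TRUE)
}

#' Logistic scan over common variants
#'
#' Runs [fit_single_marker()] on every variant with MAF at or above
#' `maf_min`, adjusting for the clinical covariates (smoking, medication,
#' age at first visit, sex). No multiple-testing correction is applied: the
#' scan only ranks markers to pick window indices. Results are ordered by
#' ascending p-value (flagged fits last), ties broken by position then id.
#'
#' @param x a QC-filtered `genotype_matrix`.
#' @param subjects subject data.frame with collapsed codes (see
#'   [apply_qc()]).
#' @param maf_min common-variant MAF threshold (default 0.05).
#' @param covariates optional covariate matrix; by default
#'   [covariate_matrix()] of `subjects`.
#' @return data.frame: `id`, `chrom`, `pos`, `maf`, `beta`, `se`, `p`,
#'   `n_used`, `converged`, ordered by p.
#' @export
run_cv_scan <- function(x, subjects, maf_min = 0.05, covariates = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.null(covariates)) covariates <- covariate_matrix(subjects)
  maf <- variant_mafs(x)
  idx <- which(!is.na(maf) & maf >= maf_min)
  if (length(idx) == 0) {
    return(data.frame(id = character(), chrom = character(), pos = integer(),
                      maf = numeric(), beta = numeric(), se = numeric(),
                      p = numeric(), n_used = integer(),
                      converged = logical()))
  }
  md <- minor_dosage(x, idx)
  status <- subjects$affection
  rows <- lapply(seq_along(idx), function(k)
    fit_single_marker(md[, k], status, covariates))
  res <- do.call(rbind, rows)
  res <- cbind(x$variants[idx, c("id", "chrom", "pos")],
               maf = maf[idx], res)
  rownames(res) <- NULL
  ord <- order(res$p, res$pos, res$id, na.last = TRUE)
  res[ord, , drop = FALSE]
}

#' Select the top-k index markers from a scan
#'
#' The `k` converged results with smallest p-values; ties broken by genomic
#' position then id so selection is deterministic.
#'
#' @param results scan data.frame from [run_cv_scan()].
#' @param k number of index markers (default 10).
#' @return data.frame of the selected rows, in selection order.
#' @export
select_top_k <- function(results, k = 10) {
  ok <- results[results$converged & !is.na(results$p), , drop = FALSE]
  if (nrow(ok) < k) stop("only ", nrow(ok), " usable results; k = ", k)
  if (k == 0) return(ok[0, , drop = FALSE])
  ok <- ok[order(ok$p, ok$pos, ok$id), , drop = FALSE]
  out <- ok[seq_len(k), , drop = FALSE]
  rownames(out) <- NULL
  out
}
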