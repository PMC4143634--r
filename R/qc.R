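#' Collapse per-visit indicators to a 1/2 affection-style code
#'
#' Longitudinal binary indicators (up to four clinic visits) are collapsed to
#' a single status: any observed 1 gives code 2 ("yes at one or more
#' visits"), all observed 0 gives code 1, all missing gives `NA`. The same
#' rule is used for hypertension, smoking and blood-pressure medication.
#'
#' @param visits numeric vector of 0/1/NA indicators, at most 4 entries.
#' @return 1, 2 or `NA_real_`.
#' @export
collapse_any_visit <- function(visits) {
  if (length(visits) > 4) stop("at most 4 visit indicators expected")
  if (!all(visits %in% c(0, 1, NA)))
    stop("visit indicators must be 0, 1 or missing")
  obs <- visits[!is.na(visits)]
  if (length(obs) == 0) return(NA_real_)
  if (any(obs == 1)) 2 else 1
}

#' Minor allele frequency of a dosage vector
#'
#' ALT-allele frequency is computed over non-missing chromosomes; the
#' returned MAF is `min(f, 1 - f)`. Which allele is minor is reported so
#' that callers can count minor-allele copies (ties at f = 0.5 call the ALT
#' allele minor).
#'
#' @param dosages vector of ALT-allele counts in \{0, 1, 2, NA\}.
#' @return list with elements `maf` (in \[0, 0.5\]), `minor` ("alt" or
#'   "ref") and `f_alt` (raw ALT frequency).
#' @export
minor_allele_frequency <- function(dosages) {
  obs <- dosages[!is.na(dosages)]
  if (length(obs) == 0) stop("all dosages missing")
  f <- sum(obs) / (2 * length(obs))
  list(maf = min(f, 1 - f), minor = if (f <= 0.5) "alt" else "ref",
       f_alt = f)
}

#' Per-variant minor allele frequencies
#' @param x a `genotype_matrix`.
#' @return numeric vector of MAFs (NA where all dosages are missing).
#' @export
variant_mafs <- function(x) {
  nobs <- colSums(!is.na(x$dosage))
  f <- colSums(x$dosage, na.rm = TRUE) / (2 * nobs)
  maf <- pmin(f, 1 - f)
  maf[nobs == 0] <- NA_real_
  maf
}

#' Dosage matrix recoded to minor-allele counts
#'
#' Columns whose ALT frequency exceeds 0.5 are flipped (dosage -> 2 -
#' dosage) so every entry counts copies of the sample minor allele.
#'
#' @param x a `genotype_matrix`.
#' @param j optional variant index (default: all variants).
#' @return numeric matrix, subjects x selected variants.
#' @export
minor_dosage <- function(x, j = seq_len(n_variants(x))) {
  d <- x$dosage[, j, drop = FALSE]
  nobs <- colSums(!is.na(d))
  f <- colSums(d, na.rm = TRUE) / (2 * pmax(nobs, 1))
  flip <- which(f > 0.5)
  if (length(flip)) d[, flip] <- 2 - d[, flip, drop = FALSE]
  d
}

#' Hardy-Weinberg exact test
#'
#' Exact (conditional) test of Hardy-Weinberg proportions: given the
#' observed allele counts, the heterozygote count follows a known discrete
#' distribution under HWE; the two-sided p-value is the total probability of
#' all heterozygote counts whose probability does not exceed that of the
#' observed count. Monomorphic markers return p = 1. This is the field-
#' standard test at small sample sizes, where the chi-square approximation
#' is unreliable.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (major hom, het, minor hom —
#'   labels are symmetric).
#' @return exact two-sided p-value.
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotype required")
  na <- n_Aa + 2 * n_aa              # minor-allele count (wlog)
  nA <- n_Aa + 2 * n_AA
  if (na == 0 || nA == 0) return(1)
  rare <- min(na, nA)
  hets <- seq(rare %% 2, rare, by = 2) # feasible heterozygote counts
  # log P(n_het | allele counts) up to a constant
  lp <- vapply(hets, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    h * log(2) - lfactorial(h) - lfactorial(hom_r) - lfactorial(hom_c)
  }, 0)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  p_obs <- p[match(n_Aa, hets)]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

hwe_p_from_dosage <- function(dosages) {
  obs <- dosages[!is.na(dosages)]
  if (length(obs) == 0) return(NA_real_)
  hwe_exact_p(sum(obs == 0), sum(obs == 1), sum(obs == 2))
}

#' Apply data-cleaning rules to a cohort
#'
#' Implements the cleaning protocol: (i) variants with three or more alleles
#' (two or more ALT alleles) are excluded; (ii) variants failing the
#' Hardy-Weinberg exact test at `hwe_alpha` (computed on all subjects,
#' pooled, with missing dosages dropped per variant) are excluded; (iii)
#' per-visit hypertension/smoking/medication indicators are collapsed to 1/2
#' codes with the any-visit rule. Monomorphic variants are retained and
#' counted — they can never qualify as rare variants with two or more
#' minor-allele copies nor as common variants.
#'
#' @param x a `genotype_matrix`.
#' @param subjects subject data.frame (see [read_subjects()]).
#' @param hwe_alpha HWE exclusion threshold (default 0.01).
#' @return list of class `qc_result` with elements `genotypes` (filtered
#'   matrix), `subjects` (with `affection`, `smoking`, `medication` 1/2
#'   codes added) and `report` (a `qc_report`).
#' @export
apply_qc <- function(x, subjects, hwe_alpha = 0.01) {
  stopifnot(inherits(x, "genotype_matrix"))
  n_in <- n_variants(x)
  multi <- x$variants$n_alt_alleles >= 2
  keep1 <- !multi
  hwe_p <- rep(NA_real_, n_in)
  hwe_p[keep1] <- apply(x$dosage[, keep1, drop = FALSE], 2, hwe_p_from_dosage)
  hwe_fail <- keep1 & !is.na(hwe_p) & hwe_p < hwe_alpha
  keep <- keep1 & !hwe_fail
  out <- subset_variants(x, keep)
  maf <- variant_mafs(out)
  mono <- sum(maf == 0, na.rm = TRUE)

  subjects$affection <- apply(subjects[, paste0("htn_v", 1:4)], 1,
                              collapse_any_visit)
  subjects$smoking <- apply(subjects[, paste0("smoke_v", 1:4)], 1,
                            collapse_any_visit)
  subjects$medication <- apply(subjects[, paste0("med_v", 1:4)], 1,
                               collapse_any_visit)

  report <- structure(list(
    n_input = n_in,
    n_excluded_multiallelic = sum(multi),
    n_excluded_hwe = sum(hwe_fail),
    n_retained = sum(keep),
    n_monomorphic_retained = mono,
    hwe_alpha = hwe_alpha,
    hwe_p = hwe_p,
    maf = maf), class = "qc_report")
  structure(list(genotypes = out, subjects = subjects, report = report),
            class = "qc_result")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  input variants:        %d\n", x$n_input))
  cat(sprintf("  excluded multiallelic: %d\n", x$n_excluded_multiallelic))
  cat(sprintf("  excluded HWE p<%g:     %d\n", x$hwe_alpha, x$n_excluded_hwe))
  cat(sprintf("  retained:              %d (of which monomorphic: %d)\n",
              x$n_retained, x$n_monomorphic_retained))
  invisible(x)
}

#' Serialize a QC report to TSV
#' @param report a `qc_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(
    metric = c("n_input", "n_excluded_multiallelic", "n_excluded_hwe",
               "n_retained", "n_monomorphic_retained", "hwe_alpha"),
    value = c(report$n_input, report$n_excluded_multiallelic,
              report$n_excluded_hwe, report$n_retained,
              report$n_monomorphic_retained, report$hwe_alpha))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
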