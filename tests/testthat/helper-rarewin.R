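# shared fixture builders: everything is constructed in code at test time

# tiny genotype matrix from an explicit dosage matrix (subjects x variants)
toy_genotypes <- function(dos, pos = seq_len(ncol(dos)) * 100,
                          chrom = "chr3", n_alt = 1L) {
  m <- ncol(dos)
  genotype_matrix(
    dos,
    data.frame(chrom = chrom, pos = as.integer(pos),
               id = sprintf("t%03d", seq_len(m)),
               ref = "A", alt = ifelse(rep(n_alt, m) >= 2, "G,T", "G"),
               n_alt_alleles = as.integer(rep(n_alt, m))),
    sprintf("P%03d", seq_len(nrow(dos))))
}

# subject table skeleton with given collapsed-status intent
toy_subjects <- function(n, affected = rep(0, n)) {
  s <- data.frame(id = sprintf("P%03d", seq_len(n)),
                  sex = rep(c("M", "F"), length.out = n),
                  age1 = 40 + seq_len(n) %% 20)
  for (v in 1:4) {
    s[[paste0("htn_v", v)]] <- as.numeric(affected)
    s[[paste0("smoke_v", v)]] <- 0
    s[[paste0("med_v", v)]] <- 0
  }
  s
}

# write a small VCF from literal body lines
write_toy_vcf <- function(body, samples = c("S1", "S2", "S3")) {
  f <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"),
               body), f)
  f
}

# enumeration oracle for the HWE exact test: conditional pmf of the
# heterozygote count given allele counts, direct factorial arithmetic
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  na <- n_Aa + 2 * n_aa
  if (na == 0 || na == 2 * n) return(1)
  rare <- min(na, 2 * n - na)
  hets <- seq(rare %% 2, rare, by = 2)
  pr <- vapply(hets, function(h) {
    hr <- (rare - h) / 2
    hc <- n - h - hr
    2^h / (factorial(h) * factorial(hr) * factorial(hc))
  }, 0)
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(n_Aa, hets)] * (1 + 1e-7)])
}

# brute-force per-variant C-alpha accumulator (independent of the vector
# closed form in the package)
calpha_T_brute <- function(y, n, p0) {
  tot <- 0
  for (i in seq_along(y)) {
    e <- n[i] * p0
    tot <- tot + (y[i] - e)^2 - n[i] * p0 * (1 - p0)
  }
  tot
}

# naive (ungrouped) enumeration of the C-alpha variance
calpha_var_naive <- function(n, p0) {
  tot <- 0
  for (ni in n) {
    for (u in 0:ni) {
      tot <- tot + dbinom(u, ni, p0) *
        ((u - ni * p0)^2 - ni * p0 * (1 - p0))^2
    }
  }
  tot
}

# two-sided Fisher p by explicit hypergeometric enumeration
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0, k - n2); hi <- min(k, m)
  pr <- dhyper(lo:hi, m, n2, k)
  sum(pr[pr <= dhyper(a, m, n2, k) * (1 + 1e-7)])
}

# null cohort configuration for calibration studies: one rare-variant
# cluster, no genetic effects, optional stratification
calib_config <- function(seed, n_subjects = 103, n_subpops = 1, fst = 0,
                         subpop_shift = rep(0, n_subpops),
                         n_common = 5, rvs = 20,
                         mix = c(deleterious = 0, protective = 0,
                                 neutral = 1),
                         or_common = 1, n_rv_clusters = 1) {
  cohort_config(n_subjects = n_subjects, n_subpops = n_subpops, fst = fst,
                subpop_shift = subpop_shift,
                n_common_variants = n_common,
                n_rv_clusters = n_rv_clusters, rvs_per_cluster = rvs,
                rv_effect_mix = mix, or_common = or_common,
                seed = seed)
}
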