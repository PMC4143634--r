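#' Synthetic cohort configuration
#'
#' Describes a case-control sequencing cohort with latent population
#' structure: `n_subpops` subpopulations whose allele frequencies diverge
#' from a shared ancestral frequency under the Balding-Nichols model with
#' divergence `fst`; common variants, of which each rare-variant cluster's
#' index marker carries odds ratio `or_common`; and clusters of rare
#' variants (expected sample MAF below 0.05) mixing deleterious, protective
#' and neutral effects. Defaults emulate a small whole-genome hypertension
#' cohort: 103 unrelated subjects, roughly 60 cases to 34 controls, ten
#' index markers, and windows probed at 1/5/25 kb.
#'
#' @param n_subjects cohort size (default 103).
#' @param case_fraction_target target case share in (0,1); default 60/94.
#' @param n_subpops number of latent subpopulations (default 2).
#' @param fst Balding-Nichols divergence in \[0, 0.5\] (default 0.05).
#' @param n_common_variants total common variants, at least
#'   `n_rv_clusters` of which are cluster index markers (default 200).
#' @param n_rv_clusters number of rare-variant clusters (default 10).
#' @param rvs_per_cluster rare variants per cluster (default 30).
#' @param rv_effect_mix proportions (deleterious, protective, neutral),
#'   summing to 1 (default 0.5/0.2/0.3).
#' @param or_deleterious per-copy odds ratio of deleterious RVs, > 1
#'   (default 3).
#' @param or_protective per-copy odds ratio of protective RVs, in (0,1)
#'   (default 1/3).
#' @param or_common per-copy odds ratio of each cluster's index common
#'   variant (default 2.5, large enough to be detectable in a cohort of
#'   about a hundred subjects; other common variants are null).
#' @param rv_freq_range ancestral-frequency range for rare variants; the
#'   upper bound must be below 0.05 so the expected sample MAF is rare
#'   (default 0.002-0.03).
#' @param window_layout data.frame with columns `index_position`,
#'   `cluster_span_bp` (one row per cluster, positions strictly
#'   increasing); default: clusters every 2 Mb with 50 kb spans.
#' @param covariate_effects named log-odds for `sex` (male), `age` (per
#'   year, centred at 50), `smoke`, `med`.
#' @param subpop_shift per-subpopulation log-odds added to the liability
#'   (default all zero; nonzero values create stratification confounding).
#' @param n_visits clinic visits for longitudinal indicators (default 4).
#' @param seed master seed; each generation stage derives its own child
#'   stream so stages can be regenerated independently.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 103,
                          case_fraction_target = 60 / 94,
                          n_subpops = 2,
                          fst = 0.05,
                          n_common_variants = 200,
                          n_rv_clusters = 10,
                          rvs_per_cluster = 30,
                          rv_effect_mix = c(deleterious = 0.5,
                                            protective = 0.2,
                                            neutral = 0.3),
                          or_deleterious = 3,
                          or_protective = 1 / 3,
                          or_common = 2.5,
                          rv_freq_range = c(0.002, 0.03),
                          window_layout = NULL,
                          covariate_effects = c(sex = 0.3, age = 0.02,
                                                smoke = 0.3, med = 0.5),
                          subpop_shift = rep(0, n_subpops),
                          n_visits = 4,
                          seed = 1L) {
  stopifnot(n_subjects >= 2, case_fraction_target > 0,
            case_fraction_target < 1, n_subpops >= 1,
            fst >= 0, fst <= 0.5, n_rv_clusters >= 0,
            or_deleterious > 1, or_protective > 0, or_protective < 1,
            n_visits >= 1)
  if (abs(sum(rv_effect_mix) - 1) > 1e-12)
    stop("rv_effect_mix must sum to 1")
  if (length(rv_effect_mix) != 3 || any(rv_effect_mix < 0))
    stop("rv_effect_mix must be three nonnegative proportions")
  if (n_common_variants < n_rv_clusters)
    stop("need at least one common variant per cluster (the index)")
  if (max(rv_freq_range) >= 0.05)
    stop("requested rare-variant ancestral frequency cannot yield ",
         "MAF < 0.05 in expectation")
  if (length(subpop_shift) != n_subpops)
    stop("subpop_shift must have one entry per subpopulation")
  if (is.null(window_layout)) {
    window_layout <- data.frame(
      index_position = 1e6 + 2e6 * (seq_len(max(n_rv_clusters, 1)) - 1),
      cluster_span_bp = 5e4)[seq_len(n_rv_clusters), , drop = FALSE]
  }
  if (n_rv_clusters > 0) {
    stopifnot(nrow(window_layout) == n_rv_clusters,
              all(c("index_position", "cluster_span_bp") %in%
                    names(window_layout)))
    if (any(diff(window_layout$index_position) <= 0))
      stop("cluster index positions must be strictly increasing")
  }
  structure(list(n_subjects = n_subjects,
                 case_fraction_target = case_fraction_target,
                 n_subpops = n_subpops, fst = fst,
                 n_common_variants = n_common_variants,
                 n_rv_clusters = n_rv_clusters,
                 rvs_per_cluster = rvs_per_cluster,
                 rv_effect_mix = rv_effect_mix,
                 or_deleterious = or_deleterious,
                 or_protective = or_protective,
                 or_common = or_common,
                 rv_freq_range = rv_freq_range,
                 window_layout = window_layout,
                 covariate_effects = covariate_effects,
                 subpop_shift = subpop_shift,
                 n_visits = n_visits, seed = as.integer(seed)),
            class = "cohort_config")
}

# deterministic per-stage child seed from the master seed
child_seed <- function(seed, stage) {
  s <- (as.numeric(seed) * 48271 + as.numeric(stage) * 9973) %% 2147483647
  as.integer(max(s, 1))
}

#' Balding-Nichols subpopulation allele frequencies
#'
#' Each subpopulation's frequency is a beta draw with mean equal to the
#' ancestral frequency `f` and variance `fst * f * (1 - f)` (shape
#' parameters `f (1-fst)/fst` and `(1-f)(1-fst)/fst`). `fst = 0` and
#' degenerate frequencies (0 or 1) return the ancestral frequency for every
#' subpopulation.
#'
#' @param f ancestral allele frequency in \[0, 1\].
#' @param fst divergence parameter in \[0, 0.5\].
#' @param n_subpops number of subpopulations.
#' @return vector of `n_subpops` frequencies.
#' @export
bn_subpop_freqs <- function(f, fst, n_subpops) {
  stopifnot(f >= 0, f <= 1, fst >= 0, fst <= 0.5)
  if (fst == 0 || f == 0 || f == 1) return(rep(f, n_subpops))
  a <- f * (1 - fst) / fst
  b <- (1 - f) * (1 - fst) / fst
  stats::rbeta(n_subpops, a, b)
}

# largest-remainder apportionment of m variants to the three effect classes
mix_counts <- function(m, mix) {
  raw <- m * mix
  k <- floor(raw)
  left <- m - sum(k)
  if (left > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(left)]] <- k[ord[seq_len(left)]] + 1
  }
  k
}

#' Simulate genotypes with population structure
#'
#' Lays out common variants (cluster index markers at the configured
#' positions, the rest spread over the chromosome) and rare-variant
#' clusters within each cluster span, draws subpopulation allele
#' frequencies by [bn_subpop_freqs()], assigns subjects to subpopulations,
#' and draws genotypes under Hardy-Weinberg proportions within each
#' subpopulation. The ALT allele is the ancestral-minor allele for rare
#' variants by construction.
#'
#' @param config a [cohort_config()].
#' @return list: `genotypes` (a `genotype_matrix`), `truth` (a
#'   `truth_record` with per-variant frequencies, effect classes and
#'   log-odds, and per-subject subpopulation labels).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(child_seed(config$seed, 1L))
  n <- config$n_subjects
  subpop <- sample.int(config$n_subpops, n, replace = TRUE)

  lay <- config$window_layout
  chrom_end <- if (config$n_rv_clusters > 0)
    max(lay$index_position) + 1e6 else 2e6
  # common variants: cluster indices + background markers
  idx_pos <- if (config$n_rv_clusters > 0) lay$index_position else integer()
  n_bg <- config$n_common_variants - length(idx_pos)
  bg_pos <- sample.int(chrom_end, n_bg)
  repeat {                                    # positions must be unique
    clash <- bg_pos %in% idx_pos | duplicated(bg_pos)
    if (!any(clash)) break
    bg_pos[clash] <- sample.int(chrom_end, sum(clash))
  }
  bg_pos <- sort(bg_pos)
  cv <- data.frame(pos = c(idx_pos, bg_pos),
                   class = c(rep("common_index", length(idx_pos)),
                             rep("common_null", length(bg_pos))))
  # rare variants clustered around each index
  rv <- NULL
  if (config$n_rv_clusters > 0 && config$rvs_per_cluster > 0) {
    rv <- do.call(rbind, lapply(seq_len(config$n_rv_clusters), function(ci) {
      span <- lay$cluster_span_bp[ci]
      lo <- max(1, lay$index_position[ci] - span / 2)
      p <- sort(sample(setdiff(seq.int(lo, lo + span),
                               c(cv$pos, lay$index_position[ci])),
                       config$rvs_per_cluster))
      cls <- rep(c("rv_deleterious", "rv_protective", "rv_neutral"),
                 mix_counts(config$rvs_per_cluster, config$rv_effect_mix))
      data.frame(pos = p, class = sample(cls), cluster = ci)
    }))
  }
  vars <- data.frame(pos = c(cv$pos, if (is.null(rv)) integer() else rv$pos),
                     class = c(cv$class,
                               if (is.null(rv)) character() else rv$class),
                     cluster = c(rep(NA_integer_, nrow(cv)),
                                 if (is.null(rv)) integer() else rv$cluster))
  vars <- vars[order(vars$pos), , drop = FALSE]
  if (anyDuplicated(vars$pos)) stop("internal: duplicated positions")
  m <- nrow(vars)

  f_anc <- numeric(m)
  is_cv <- vars$class %in% c("common_index", "common_null")
  f_anc[is_cv] <- stats::runif(sum(is_cv), 0.1, 0.5)
  f_anc[!is_cv] <- stats::runif(sum(!is_cv), config$rv_freq_range[1],
                                config$rv_freq_range[2])
  # subpopulations in rows, variants in columns
  f_sub <- vapply(f_anc, bn_subpop_freqs, numeric(config$n_subpops),
                  fst = config$fst, n_subpops = config$n_subpops)
  if (config$n_subpops == 1) f_sub <- matrix(f_sub, nrow = 1)

  dos <- matrix(0, n, m)
  for (j in seq_len(m))
    dos[, j] <- stats::rbinom(n, 2, f_sub[cbind(subpop, rep(j, n))])

  log_odds <- numeric(m)
  log_odds[vars$class == "common_index"] <- log(config$or_common)
  log_odds[vars$class == "rv_deleterious"] <- log(config$or_deleterious)
  log_odds[vars$class == "rv_protective"] <- log(config$or_protective)

  vdf <- data.frame(chrom = "chr3", pos = as.integer(vars$pos),
                    id = sprintf("v%09d", vars$pos),
                    ref = "A", alt = "G", n_alt_alleles = 1L,
                    stringsAsFactors = FALSE)
  subjects <- sprintf("S%04d", seq_len(n))
  gm <- genotype_matrix(dos, vdf, subjects)
  truth <- structure(list(
    variants = data.frame(id = vdf$id, pos = vdf$pos, class = vars$class,
                          cluster = vars$cluster, log_odds = log_odds,
                          f_ancestral = f_anc,
                          stringsAsFactors = FALSE),
    subpop_freqs = t(f_sub),   # variants x subpopulations
    subjects = data.frame(id = subjects, subpop = subpop,
                          stringsAsFactors = FALSE)),
    class = "truth_record")
  list(genotypes = gm, truth = truth)
}

#' Simulate phenotypes and covariates on a genotype backbone
#'
#' Each subject's liability is `intercept + covariate terms + sum(log-odds
#' x ALT dosage) + subpopulation shift`; the intercept is calibrated by
#' root-finding so the expected case fraction matches
#' `case_fraction_target`. The collapsed (any-visit) affection status is
#' the primary phenotype, drawn Bernoulli at the logistic liability;
#' per-visit hypertension indicators are then derived from it (an affected
#' subject shows hypertension at each visit with probability 0.7, forced at
#' one visit at minimum; an unaffected subject at none), and likewise for
#' latent smoking (rate 0.35) and medication (rate 0.40) statuses that also
#' enter the liability.
#'
#' @param genotypes a `genotype_matrix` from [simulate_genotypes()].
#' @param truth the matching `truth_record`.
#' @param config the [cohort_config()] used to generate them.
#' @return subject data.frame with the columns [read_subjects()] documents.
#' @export
simulate_phenotypes <- function(genotypes, truth, config) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(truth, "truth_record"))
  if (!identical(genotypes$subjects, truth$subjects$id))
    stop("genotypes and truth are not aligned")
  set.seed(child_seed(config$seed, 2L))
  n <- n_subjects(genotypes)
  ce <- config$covariate_effects
  sex <- sample(c("M", "F"), n, replace = TRUE)
  age <- pmin(pmax(round(stats::rnorm(n, 50, 12)), 20), 85)
  smoke <- stats::rbinom(n, 1, 0.35)
  med <- stats::rbinom(n, 1, 0.40)
  g_eta <- as.vector(genotypes$dosage %*% truth$variants$log_odds)
  eta <- ce[["sex"]] * (sex == "M") + ce[["age"]] * (age - 50) +
    ce[["smoke"]] * smoke + ce[["med"]] * med + g_eta +
    config$subpop_shift[truth$subjects$subpop]
  target <- config$case_fraction_target
  fr <- function(b) mean(stats::plogis(b + eta)) - target
  if (fr(-30) > 0 || fr(30) < 0)
    stop("cannot calibrate intercept to the target case fraction")
  b0 <- stats::uniroot(fr, c(-30, 30), tol = 1e-8)$root
  affected <- stats::rbinom(n, 1, stats::plogis(b0 + eta))

  visits_from_status <- function(status01, p_visit = 0.7) {
    v <- matrix(0, length(status01), config$n_visits)
    on <- which(status01 == 1)
    if (length(on)) {
      v[on, ] <- stats::rbinom(length(on) * config$n_visits, 1, p_visit)
      none <- on[rowSums(v[on, , drop = FALSE]) == 0]
      if (length(none))
        v[cbind(none, sample.int(config$n_visits, length(none),
                                 replace = TRUE))] <- 1
    }
    v <- v[, seq_len(min(4, config$n_visits)), drop = FALSE]
    if (ncol(v) < 4) v <- cbind(v, matrix(NA, nrow(v), 4 - ncol(v)))
    v
  }
  htn <- visits_from_status(affected)
  smk <- visits_from_status(smoke)
  mdv <- visits_from_status(med)
  out <- data.frame(id = genotypes$subjects, sex = sex, age1 = age,
                    stringsAsFactors = FALSE)
  out[paste0("htn_v", 1:4)] <- as.data.frame(htn)
  out[paste0("smoke_v", 1:4)] <- as.data.frame(smk)
  out[paste0("med_v", 1:4)] <- as.data.frame(mdv)
  attr(out, "intercept") <- b0
  out
}

#' Simulate a complete cohort
#' @param config a [cohort_config()].
#' @return list of class `synth_cohort`: `genotypes`, `subjects`, `truth`,
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  g <- simulate_genotypes(config)
  subjects <- simulate_phenotypes(g$genotypes, g$truth, config)
  structure(list(genotypes = g$genotypes, subjects = subjects,
                 truth = g$truth, config = config),
            class = "synth_cohort")
}

#' Write a synthetic cohort to analysis-ready files
#'
#' Emits the cohort as a VCF (`cohort.vcf.gz`), a BED gene track
#' (`genes.bed`) in which rare-variant clusters are assigned alternately to
#' in-gene and not-in-gene spans (odd-numbered clusters get a gene covering
#' their index marker), the subject TSV (`subjects.tsv`) and the truth
#' tables (`truth_variants.tsv`, `truth_subjects.tsv`). Files round-trip
#' losslessly through [read_vcf()]/[read_gene_track()]/[read_subjects()].
#'
#' @param cohort a `synth_cohort`.
#' @param dir output directory (created if needed).
#' @param overwrite set TRUE to replace existing files (default: refuse).
#' @return named list of written paths, invisibly.
#' @export
write_fixture <- function(cohort, dir, overwrite = FALSE) {
  stopifnot(inherits(cohort, "synth_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(vcf = file.path(dir, "cohort.vcf.gz"),
                bed = file.path(dir, "genes.bed"),
                subjects = file.path(dir, "subjects.tsv"),
                truth_variants = file.path(dir, "truth_variants.tsv"),
                truth_subjects = file.path(dir, "truth_subjects.tsv"))
  existing <- unlist(paths)[file.exists(unlist(paths))]
  if (length(existing) && !overwrite)
    stop("refusing to overwrite without overwrite = TRUE: ",
         paste(basename(existing), collapse = ", "))
  write_vcf(cohort$genotypes, paths$vcf)
  cfg <- cohort$config
  lay <- cfg$window_layout
  gene_ci <- seq_len(cfg$n_rv_clusters)[seq_len(cfg$n_rv_clusters) %% 2 == 1]
  bed <- data.frame(chrom = character(), start = integer(), end = integer(),
                    name = character())
  if (length(gene_ci)) {
    half <- 2500
    bed <- data.frame(chrom = "chr3",
                      start = as.integer(lay$index_position[gene_ci] - half - 1),
                      end = as.integer(lay$index_position[gene_ci] + half),
                      name = sprintf("GENE%02d", gene_ci))
  }
  utils::write.table(bed, paths$bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_subjects(cohort$subjects, paths$subjects)
  utils::write.table(cohort$truth$variants, paths$truth_variants,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth$subjects, paths$truth_subjects,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
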