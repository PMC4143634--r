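#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Probability-mass rule: the p-value is the sum, over all tables with the
#' observed margins, of hypergeometric probabilities not exceeding the
#' observed table's probability (a relative tolerance of 1e-7 guards the
#' comparison against rounding).
#'
#' @param a,b,c,d cell counts, row-wise: (a, b) is the first row.
#' @return two-sided p-value.
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, a + b + c + d > 0)
  stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE))$p.value
}

#' Compare in-gene and not-in-gene window significance
#'
#' For each window size, windows are called significant when applicable
#' (two or more rare variants after singleton removal) and the permutation
#' p-value is below `alpha`; the resulting 2x2 table (gene membership by
#' significance) is tested with [fisher_exact_two_sided()]. Windows with
#' too few rare variants are excluded from the table by default
#' (`inapplicable_rule = "exclude"`) or counted as non-significant
#' (`"count-nonsignificant"`). A window size with no applicable window on
#' either side of the gene split is skipped with a warning.
#'
#' @param results data.frame with columns `width` (bp), `in_gene`
#'   (logical), `applicable` (logical) and `p_permutation`.
#' @param alpha significance threshold (default 0.05).
#' @param inapplicable_rule "exclude" or "count-nonsignificant".
#' @return data.frame of class `comparison_result`, one row per window
#'   size: counts `n_ingene_sig`, `n_ingene_nonsig`, `n_outgene_sig`,
#'   `n_outgene_nonsig`, plus `alpha`, `rule`, `fisher_p`.
#' @export
build_significance_tables <- function(results, alpha = 0.05,
                                      inapplicable_rule =
                                        c("exclude", "count-nonsignificant")) {
  inapplicable_rule <- match.arg(inapplicable_rule)
  stopifnot(all(c("width", "in_gene", "applicable", "p_permutation") %in%
                  names(results)))
  out <- lapply(sort(unique(results$width)), function(w) {
    r <- results[results$width == w, , drop = FALSE]
    if (inapplicable_rule == "exclude")
      r <- r[r$applicable, , drop = FALSE]
    if (sum(r$in_gene & r$applicable) == 0 ||
        sum(!r$in_gene & r$applicable) == 0) {
      warning("window size ", w,
              ": no applicable windows on one side; comparison skipped")
      return(NULL)
    }
    sig <- r$applicable & !is.na(r$p_permutation) & r$p_permutation < alpha
    a <- sum(r$in_gene & sig);   b <- sum(r$in_gene & !sig)
    cc <- sum(!r$in_gene & sig); d <- sum(!r$in_gene & !sig)
    data.frame(width = w, n_ingene_sig = a, n_ingene_nonsig = b,
               n_outgene_sig = cc, n_outgene_nonsig = d, alpha = alpha,
               rule = inapplicable_rule,
               fisher_p = fisher_exact_two_sided(a, b, cc, d))
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(width = numeric(), n_ingene_sig = integer(),
                      n_ingene_nonsig = integer(), n_outgene_sig = integer(),
                      n_outgene_nonsig = integer(), alpha = numeric(),
                      rule = character(), fisher_p = numeric())
  class(res) <- c("comparison_result", "data.frame")
  res
}

#' Published reference window results
#'
#' Window-level C-alpha results for the top-10 index markers (five in
#' genes, five not) of a chromosome-3 hypertension cohort of 103 unrelated
#' subjects, at 1/5/25 kb window sizes, shipped with the package as a
#' worked reference table. Permuted p-values printed as "n/a" (windows with
#' fewer than two rare variants after singleton removal) are returned as
#' `NA` with `applicable = FALSE`; a bound such as "<0.001" is returned as
#' half the bound.
#'
#' @return data.frame: `width`, `window_kb`, `marker`, `in_gene`,
#'   `assoc_p`, `n_rv`, `calpha_stat`, `p_permutation`, `applicable`.
#' @export
reference_window_results <- function() {
  path <- system.file("extdata", "reference_window_results.tsv",
                      package = "rarewin", mustWork = TRUE)
  r <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(perm_p = "character",
                                        calpha_stat = "character"))
  num <- function(s) {
    out <- rep(NA_real_, length(s))
    lt <- grepl("^<", s)
    out[lt] <- as.numeric(sub("^<", "", s[lt])) / 2
    plain <- !lt & s != "n/a"
    out[plain] <- as.numeric(s[plain])
    out
  }
  data.frame(width = r$window_kb * 1000, window_kb = r$window_kb,
             marker = as.character(r$marker), in_gene = r$in_gene == 1,
             assoc_p = r$assoc_p, n_rv = r$n_rv,
             calpha_stat = num(r$calpha_stat),
             p_permutation = num(r$perm_p),
             applicable = r$n_rv >= 2 & r$perm_p != "n/a",
             stringsAsFactors = FALSE)
}

default_pipeline_params <- list(widths = c(1000, 5000, 25000), top_k = 10,
                                maf_min = 0.05, maf_max = 0.05,
                                hwe_alpha = 0.01, B = 1000, n_pcs = 5,
                                r2_max = 0.01, alpha = 0.05, seed = 1,
                                inapplicable_rule = "exclude")

#' Pipeline configuration
#'
#' @param vcf,bed,subjects input paths (genotypes, gene track, subject
#'   table).
#' @param pca_vcf optional separate VCF for the PCA/urn panel; by default
#'   the QC-filtered analysis genotypes are used.
#' @param widths window half-widths in bp (default 1000, 5000, 25000).
#' @param top_k number of index markers (default 10).
#' @param maf_min common-variant MAF threshold for the scan (default 0.05).
#' @param maf_max rare-variant MAF threshold for windows (default 0.05).
#' @param hwe_alpha Hardy-Weinberg exclusion threshold (default 0.01).
#' @param B permutation count (default 1000 urn samples).
#' @param n_pcs principal components entering the urn weights (default 5).
#' @param r2_max LD-pruning threshold (default 0.01).
#' @param alpha significance threshold for the gene comparison (default
#'   0.05).
#' @param seed integer seed for the permutation stage.
#' @param inapplicable_rule handling of windows with fewer than 2 RVs in
#'   the comparison ("exclude" or "count-nonsignificant").
#' @param out_dir optional directory for report TSVs.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, bed, subjects, pca_vcf = NULL,
                            widths = c(1000, 5000, 25000), top_k = 10,
                            maf_min = 0.05, maf_max = 0.05,
                            hwe_alpha = 0.01, B = 1000, n_pcs = 5,
                            r2_max = 0.01, alpha = 0.05, seed = 1,
                            inapplicable_rule = "exclude", out_dir = NULL) {
  cfg <- list(vcf = vcf, bed = bed, subjects = subjects, pca_vcf = pca_vcf,
              widths = widths, top_k = top_k, maf_min = maf_min,
              maf_max = maf_max, hwe_alpha = hwe_alpha, B = B,
              n_pcs = n_pcs, r2_max = r2_max, alpha = alpha,
              seed = as.integer(seed),
              inapplicable_rule = inapplicable_rule, out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a flat key-value pipeline configuration file
#'
#' Lines of the form `key = value` (or `key<TAB>value`); `widths` may be
#' comma-separated. Unknown keys are an error. Keys not present take the
#' defaults of [pipeline_config()].
#'
#' @param path path to the configuration file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  ln <- readLines(path)
  ln <- trimws(ln[!grepl("^\\s*(#|$)", ln)])
  kv <- strsplit(ln, "\\s*=\\s*|\t+")
  if (any(lengths(kv) != 2)) stop("malformed config line")
  keys <- vapply(kv, `[`, "", 1); vals <- vapply(kv, `[`, "", 2)
  known <- names(formals(pipeline_config))
  if (length(bad <- setdiff(keys, known)))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  args <- stats::setNames(as.list(vals), keys)
  for (k in intersect(keys, c("top_k", "maf_min", "maf_max", "hwe_alpha",
                              "B", "n_pcs", "r2_max", "alpha", "seed")))
    args[[k]] <- as.numeric(args[[k]])
  if ("widths" %in% keys)
    args$widths <- as.numeric(strsplit(args$widths, ",")[[1]])
  do.call(pipeline_config, args)
}

#' Run the full windowed rare-variant analysis
#'
#' End-to-end driver: ingest, QC (multi-allelic and Hardy-Weinberg
#' exclusion, any-visit phenotype collapsing), covariate-adjusted logistic
#' scan of common variants, top-k index selection, rare-variant window
#' extraction at each width, C-alpha testing under biased-urn permutation
#' (weights from principal components of the LD-pruned panel plus clinical
#' covariates), and the in-gene versus not-in-gene Fisher comparison.
#' Subjects missing status or any covariate are dropped before the
#' urn/testing stage and the retained count reported. When `out_dir` is
#' set, Table-style window results (with the literal "n/a" for windows
#' holding fewer than two rare variants), comparison, scan, QC and urn
#' diagnostic TSVs plus a run log are written.
#'
#' @param config a `pipeline_config`, or the path to a key-value file for
#'   [read_pipeline_config()].
#' @return list of class `rarewin_report`: `windows` (per-window results),
#'   `comparisons`, `scan`, `top`, `qc_report`, `urn`, `n_urn_subjects`,
#'   `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  gm <- stage("ingest", read_vcf(config$vcf))
  track <- stage("ingest", read_gene_track(config$bed))
  subj <- stage("ingest", read_subjects(config$subjects))
  if (!identical(sort(gm$subjects), sort(subj$id)))
    stop("pipeline stage 'ingest' failed: VCF and subject table ids differ")
  subj <- subj[match(gm$subjects, subj$id), , drop = FALSE]

  qc <- stage("qc", apply_qc(gm, subj, hwe_alpha = config$hwe_alpha))
  scan <- stage("scan", run_cv_scan(qc$genotypes, qc$subjects,
                                    maf_min = config$maf_min))
  top <- stage("select", select_top_k(scan, k = config$top_k))

  cov <- covariate_matrix(qc$subjects)
  cc <- !is.na(qc$subjects$affection) & rowSums(is.na(cov)) == 0
  x <- subset_subjects(qc$genotypes, cc)
  status <- qc$subjects$affection[cc]
  covcc <- cov[cc, , drop = FALSE]

  urn <- stage("urn", {
    panel <- if (!is.null(config$pca_vcf))
      subset_subjects(read_vcf(config$pca_vcf), cc) else x
    pruned <- ld_prune(panel, r2_max = config$r2_max)
    pcs <- if (length(pruned) >= 1 && config$n_pcs > 0)
      suppressWarnings(compute_pcs(subset_variants(panel, pruned),
                                   k = config$n_pcs))
    else matrix(nrow = sum(cc), ncol = 0)
    fit_urn_weights(status, pcs, covcc)
  })

  rows <- list()
  for (i in seq_len(nrow(top))) {
    for (w in config$widths) {
      win <- stage("windows",
                   extract_window(x, top$id[i], half_width_bp = w,
                                  maf_max = config$maf_max, track = track))
      res <- stage("calpha",
                   stratified_permutation(x, win, status, urn, B = config$B,
                                          seed = child_seed(config$seed,
                                                            1000 + i * 100 + match(w, config$widths))))
      rows[[length(rows) + 1]] <- data.frame(
        marker = top$id[i], pos = top$pos[i], assoc_p = top$p[i],
        in_gene = win$in_gene, width = w, n_rv = win$n_rv,
        calpha_stat = res$T, z = res$z, p_permutation = res$p_permutation,
        applicable = res$applicable, stringsAsFactors = FALSE)
    }
  }
  windows <- do.call(rbind, rows)
  comparisons <- stage("compare",
                       build_significance_tables(windows,
                                                 alpha = config$alpha,
                                                 inapplicable_rule =
                                                   config$inapplicable_rule))
  report <- structure(list(windows = windows, comparisons = comparisons,
                           scan = scan, top = top, qc_report = qc$report,
                           urn = urn, n_urn_subjects = sum(cc),
                           config = config),
                      class = "rarewin_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Subset a genotype matrix by subject
#' @param x a `genotype_matrix`
#' @param i integer or logical index over subjects
#' @return a `genotype_matrix` restricted to the selected subjects.
#' @export
subset_subjects <- function(x, i) {
  genotype_matrix(x$dosage[i, , drop = FALSE], x$variants, x$subjects[i])
}

#' Write the report bundle as TSV files
#' @param report a `rarewin_report`.
#' @param dir output directory (created if needed).
#' @return vector of written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- report$windows
  wt$calpha_stat <- ifelse(wt$applicable, sprintf("%.4g", wt$calpha_stat),
                           "n/a")
  wt$p_permutation <- ifelse(wt$applicable,
                             sprintf("%.4g", wt$p_permutation), "n/a")
  f <- function(x, nm) {
    p <- file.path(dir, nm)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(f(wt[, c("marker", "pos", "assoc_p", "in_gene", "width",
                      "n_rv", "calpha_stat", "p_permutation")],
               "windows.tsv"),
             f(report$comparisons, "comparisons.tsv"),
             f(report$scan, "scan.tsv"))
  p <- file.path(dir, "qc_report.tsv")
  write_qc_report(report$qc_report, p)
  paths <- c(paths, p)
  subj_id <- rownames(report$urn$pc_scores)
  if (is.null(subj_id)) subj_id <- seq_along(report$urn$weights)
  urn_df <- data.frame(subject = subj_id,
                       fitted_p = report$urn$fitted_p,
                       weight = report$urn$weights)
  if (!is.null(report$urn$pc_scores) && ncol(report$urn$pc_scores) > 0)
    urn_df <- cbind(urn_df, report$urn$pc_scores)
  paths <- c(paths, f(urn_df, "urn_diagnostics.tsv"))
  log <- c(sprintf("rarewin %s | R %s",
                   as.character(utils::packageVersion("rarewin")),
                   paste(R.version$major, R.version$minor, sep = ".")),
           sprintf("seed: %d", report$config$seed),
           sprintf("urn-stage subjects: %d", report$n_urn_subjects),
           "config:",
           paste0("  ", names(report$config), " = ",
                  vapply(report$config, function(v)
                    paste(format(v), collapse = ","), "")))
  writeLines(log, file.path(dir, "run_log.txt"))
  invisible(c(paths, file.path(dir, "run_log.txt")))
}

#' @export
print.rarewin_report <- function(x, ...) {
  cat(sprintf("<rarewin_report> %d index markers x %d window sizes (%d urn-stage subjects)\n",
              nrow(x$top), length(x$config$widths), x$n_urn_subjects))
  print(x$comparisons)
  invisible(x)
}
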