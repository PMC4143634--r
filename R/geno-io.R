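#' Genotype matrix container
#'
#' A `genotype_matrix` holds a subjects-by-variants dosage matrix (count of
#' non-reference alleles, `NA` for missing calls) together with per-variant
#' metadata. Positions are 1-based and must be nondecreasing within a
#' chromosome. Dosages are ALT-allele counts at ingestion; minor/major status
#' is sample-dependent and resolved later by [minor_allele_frequency()].
#'
#' @param dosage numeric matrix, subjects in rows, variants in columns,
#'   entries in \{0, 1, 2, NA\}.
#' @param variants data.frame with columns `chrom`, `pos` (1-based integer),
#'   `id`, `ref`, `alt`, `n_alt_alleles`.
#' @param subjects character vector of unique subject ids, one per row of
#'   `dosage`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, variants, subjects) {
  dosage <- as.matrix(dosage)
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "id", "ref", "alt", "n_alt_alleles") %in%
                  names(variants)))
  if (nrow(dosage) != length(subjects))
    stop("dosage row count does not match number of subjects")
  if (ncol(dosage) != nrow(variants))
    stop("dosage column count does not match number of variants")
  if (anyDuplicated(subjects))
    stop("duplicated subject ids: ",
         paste(unique(subjects[duplicated(subjects)]), collapse = ", "))
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) stop("dosage entries must be 0, 1, 2 or NA")
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p)) stop("positions not nondecreasing on chromosome ", ch)
  }
  rownames(dosage) <- subjects
  colnames(dosage) <- variants$id
  structure(list(dosage = dosage,
                 variants = as.data.frame(variants, stringsAsFactors = FALSE),
                 subjects = as.character(subjects)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d subjects x %d variants\n",
              length(x$subjects), nrow(x$variants)))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$variants$chrom), collapse = ", ")))
  cat(sprintf("  missing dosages: %d\n", sum(is.na(x$dosage))))
  invisible(x)
}

#' Number of subjects / variants
#' @param x a `genotype_matrix`
#' @return integer count.
#' @export
n_subjects <- function(x) length(x$subjects)

#' @rdname n_subjects
#' @export
n_variants <- function(x) nrow(x$variants)

#' Subset a genotype matrix by variant index
#' @param x a `genotype_matrix`
#' @param j integer or logical index over variants
#' @return a `genotype_matrix` restricted to the selected variants.
#' @export
subset_variants <- function(x, j) {
  genotype_matrix(x$dosage[, j, drop = FALSE],
                  x$variants[j, , drop = FALSE],
                  x$subjects)
}

parse_gt_dosage <- function(gt) {
  # diploid GT field -> ALT-allele count; phased and unphased alike
  out <- rep(NA_real_, length(gt))
  gt <- sub(":.*$", "", gt)
  ok <- !is.na(gt) & gt != "."
  al <- strsplit(gt[ok], "[/|]")
  nall <- lengths(al)
  if (any(nall != 2))
    stop("malformed GT field (non-diploid): ",
         paste(utils::head(gt[ok][nall != 2], 3), collapse = ", "))
  a1 <- vapply(al, `[`, "", 1L)
  a2 <- vapply(al, `[`, "", 2L)
  if (!all(grepl("^([0-9]+|\\.)$", c(a1, a2))))
    stop("malformed GT allele code")
  d <- rep(NA_real_, sum(ok))
  known <- a1 != "." & a2 != "."
  d[known] <- (a1[known] != "0") + (a2[known] != "0")
  out[ok] <- d
  out
}

#' Read a VCF file into a genotype matrix
#'
#' Diploid GT fields are parsed to ALT-allele dosages; missing genotypes
#' (`./.`) become `NA`. Multi-allelic records (two or more ALT alleles) are
#' retained with `n_alt_alleles` recorded so downstream QC can exclude them;
#' any non-reference allele counts toward the dosage.
#'
#' @param path path to a VCF 4.x file (plain or gzipped) with GT fields.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  subjects <- colnames(gt)
  if (anyDuplicated(subjects))
    stop("duplicated subject ids in VCF header")
  dos <- apply(gt, 2, parse_gt_dosage)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1)
  alt <- fix[, "ALT"]
  variants <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"]),
    ref = fix[, "REF"],
    alt = alt,
    n_alt_alleles = lengths(strsplit(alt, ",", fixed = TRUE)),
    stringsAsFactors = FALSE)
  genotype_matrix(t(dos), variants, subjects)
}

#' Write a genotype matrix to VCF
#'
#' Emits a minimal VCF 4.2 with GT-only genotype columns (gzip-compressed,
#' as `.vcf.gz`). Dosage 0/1/2 is written as `0/0`, `0/1`, `1/1`; `NA` as
#' `./.`. Round-trips bit-exactly through [read_vcf()] for biallelic records.
#'
#' @param x a `genotype_matrix`.
#' @param path output path (written gzip-compressed; name it `.vcf.gz`).
#' @return the path written, invisibly.
#' @export
write_vcf <- function(x, path) {
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = n_variants(x), ncol = n_subjects(x))
  dv <- t(x$dosage)
  ok <- !is.na(dv)
  gt[ok] <- gt_code[dv[ok] + 1L]
  gt <- cbind(FORMAT = "GT", gt)
  colnames(gt) <- c("FORMAT", x$subjects)
  fix <- cbind(CHROM = as.character(x$variants$chrom),
               POS = as.character(x$variants$pos),
               ID = as.character(x$variants$id),
               REF = x$variants$ref, ALT = x$variants$alt,
               QUAL = ".", FILTER = ".", INFO = ".")
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  cls <- methods::getClass("vcfR", where = asNamespace("vcfR"))
  v <- methods::new(cls, meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Read a BED gene track
#'
#' BED intervals (0-based, half-open) are converted on import to 1-based
#' inclusive coordinates, the convention used throughout the package.
#' Overlapping intervals are permitted. A gene's span is expected to cover
#' its 5' to 3' untranslated region.
#'
#' @param path path to a BED file with at least 4 columns
#'   (chrom, start, end, name).
#' @return a data.frame of class `gene_track` with columns `gene_id`,
#'   `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_gene_track <- function(path) {
  empty <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) {
    class(empty) <- c("gene_track", "data.frame")
    return(empty)
  }
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0) {
    class(empty) <- c("gene_track", "data.frame")
    return(empty)
  }
  nm <- gr$name
  if (is.null(nm)) stop("BED file must have at least 4 columns (name field)")
  out <- data.frame(gene_id = nm,
                    chrom = as.character(GenomeInfoDb::seqnames(gr)),
                    start = BiocGenerics::start(gr),
                    end = BiocGenerics::end(gr),
                    stringsAsFactors = FALSE)
  if (any(out$start > out$end))
    stop("gene interval with start > end after coordinate conversion ",
         "(zero-width BED record?)")
  class(out) <- c("gene_track", "data.frame")
  out
}

subject_cols <- c("id", "sex", "age1",
                  paste0("htn_v", 1:4), paste0("smoke_v", 1:4),
                  paste0("med_v", 1:4))

#' Read the subject table
#'
#' Tab-separated subject phenotype/covariate file with columns `id`, `sex`
#' (M/F), `age1` (age at first visit, years) and per-visit binary indicators
#' `htn_v1..htn_v4`, `smoke_v1..smoke_v4`, `med_v1..med_v4` (0/1, empty for
#' missing). Collapsed 1/2 affection, smoking and medication codes are left
#' unset here; [apply_qc()] fills them with the any-visit rule.
#'
#' @param path path to the TSV file.
#' @return a data.frame with one row per subject.
#' @export
read_subjects <- function(path) {
  s <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  miss <- setdiff(subject_cols, names(s))
  if (length(miss)) stop("subject table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(s$id))
    stop("duplicated subject id: ",
         paste(unique(s$id[duplicated(s$id)]), collapse = ", "))
  if (!all(s$sex %in% c("M", "F", NA)))
    stop("unknown sex codes: ",
         paste(unique(setdiff(s$sex, c("M", "F"))), collapse = ", "))
  if (!is.numeric(s$age1)) stop("nonnumeric age at first visit")
  for (cl in setdiff(subject_cols, c("id", "sex", "age1"))) {
    v <- s[[cl]]
    if (!all(v %in% c(0, 1, NA)))
      stop("visit indicator column ", cl, " must be 0/1/missing")
  }
  s
}

#' Write a subject table
#' @param subjects data.frame as produced by [read_subjects()] or the
#'   cohort simulator.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_subjects <- function(subjects, path) {
  utils::write.table(subjects[, intersect(c(subject_cols,
                                            c("affection", "smoking", "medication")),
                                          names(subjects))],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
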