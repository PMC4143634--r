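#' Is a position inside any gene span?
#'
#' A marker counts as "in a gene" if its position lies anywhere within a
#' gene's 5'-to-3' UTR span, boundaries inclusive.
#'
#' @param pos 1-based position.
#' @param track a `gene_track` (see [read_gene_track()]).
#' @param chrom optional chromosome label; if supplied, only intervals on
#'   that chromosome are considered.
#' @return logical.
#' @export
classify_gene_membership <- function(pos, track, chrom = NULL) {
  if (nrow(track) == 0) return(FALSE)
  t <- track
  if (!is.null(chrom)) t <- t[t$chrom == chrom, , drop = FALSE]
  any(t$start <= pos & pos <= t$end)
}

#' Build the rare-variant window around an index marker
#'
#' Member variants are those whose position lies in the closed interval
#' `index_pos` plus/minus `half_width_bp` on the index chromosome, with
#' sample MAF below `maf_max` and at least two minor-allele copies in the
#' whole sample (singletons removed), excluding the index variant itself.
#' Windows with one or fewer members after filtering are flagged not
#' applicable: a C-alpha test on them is reported as "n/a".
#'
#' @param x a QC-filtered `genotype_matrix`.
#' @param index_id id of the index (common) variant, which must be present.
#' @param half_width_bp window half-width in base pairs (e.g. 1000 for the
#'   "1 kb" window).
#' @param maf_max rare-variant MAF threshold (default 0.05, exclusive).
#' @param track optional `gene_track` for the in-gene flag.
#' @return object of class `window_spec`: `index_id`, `index_pos`, `chrom`,
#'   `half_width`, `members` (variant ids, sorted by position), `n_rv`,
#'   `in_gene`, `applicable`.
#' @export
extract_window <- function(x, index_id, half_width_bp, maf_max = 0.05,
                           track = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  i <- match(index_id, x$variants$id)
  if (is.na(i)) stop("index variant not found: ", index_id)
  ipos <- x$variants$pos[i]
  ichrom <- x$variants$chrom[i]
  cand <- which(x$variants$chrom == ichrom &
                  abs(x$variants$pos - ipos) <= half_width_bp)
  cand <- setdiff(cand, i)
  if (length(cand)) {
    maf <- variant_mafs(subset_variants(x, cand))
    md <- minor_dosage(x, cand)
    ncopies <- colSums(md, na.rm = TRUE)
    cand <- cand[!is.na(maf) & maf < maf_max & ncopies >= 2]
  }
  cand <- cand[order(x$variants$pos[cand], x$variants$id[cand])]
  in_gene <- if (is.null(track)) NA else
    classify_gene_membership(ipos, track, chrom = ichrom)
  structure(list(index_id = index_id, index_pos = ipos, chrom = ichrom,
                 half_width = half_width_bp, maf_max = maf_max,
                 members = x$variants$id[cand], member_idx = cand,
                 n_rv = length(cand), in_gene = in_gene,
                 applicable = length(cand) >= 2),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> index %s @ %s:%d, +/-%d bp: %d RVs%s%s\n",
              x$index_id, x$chrom, x$index_pos, x$half_width, x$n_rv,
              if (isTRUE(x$in_gene)) " [in gene]" else "",
              if (!x$applicable) " (not applicable)" else ""))
  invisible(x)
}
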