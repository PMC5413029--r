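#' Construct a genotype cohort
#'
#' A `cohort` bundles a genotype dosage matrix with its SNP map, per-animal
#' breed labels and (optionally) a pedigree. It is the shared input of every
#' analysis stage: QC, ROH scanning, inbreeding, F_ST and Ne estimation.
#'
#' Genotypes are coded as copies of the counted allele (by convention the
#' cohort-wide minor allele at read time): 0, 1, 2 or `NA` for missing.
#' Coordinates are 1-based inclusive base pairs; all downstream intervals
#' (ROH, hotspots, signatures) are closed `[start_bp, end_bp]`.
#'
#' @param calls integer matrix, individuals x SNPs, values in `{0,1,2,NA}`.
#' @param individuals data.frame with columns `id` and `breed` (one row per
#'   matrix row). IDs must be unique.
#' @param snps data.frame with columns `snp_id`, `chrom` (integer autosome
#'   label), `bp` (1-based physical position) and optionally `cM` (genetic
#'   position; `NA` where unknown). One row per matrix column; within each
#'   chromosome positions must be strictly increasing.
#' @param pedigree optional pedigree table as returned by [read_pedigree()].
#' @param n_autosomes number of autosomes in the karyotype (26 for sheep).
#'
#' @return An object of class `cohort`: a list with elements `calls`,
#'   `individuals`, `snps`, `pedigree`, `n_autosomes`.
#' @export
new_cohort <- function(calls, individuals, snps, pedigree = NULL,
                       n_autosomes = 26L) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  if (!all(c("id", "breed") %in% names(individuals)))
    stop("individuals needs columns 'id' and 'breed'")
  if (!all(c("snp_id", "chrom", "bp") %in% names(snps)))
    stop("snps needs columns 'snp_id', 'chrom', 'bp'")
  if (is.null(snps$cM)) snps$cM <- NA_real_
  if (nrow(individuals) != nrow(calls) || nrow(snps) != ncol(calls))
    stop("calls dimensions do not match individual/SNP tables")
  if (anyDuplicated(individuals$id))
    stop("duplicate individual ids")
  bad <- calls[!is.na(calls) & !(calls %in% 0:2)]
  if (length(bad))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (nrow(snps) > 1) {
    for (ch in unique(snps$chrom)) {
      bp <- snps$bp[snps$chrom == ch]
      if (any(diff(bp) <= 0))
        stop(sprintf("SNP positions not strictly increasing on chromosome %s", ch))
      cm <- snps$cM[snps$chrom == ch]
      cm <- cm[!is.na(cm)]
      if (length(cm) > 1 && any(diff(cm) < 0))
        stop(sprintf("cM positions decrease on chromosome %s", ch))
    }
  }
  if (any(snps$bp < 1)) stop("bp positions must be >= 1")
  rownames(calls) <- individuals$id
  colnames(calls) <- snps$snp_id
  structure(
    list(calls = calls, individuals = individuals, snps = snps,
         pedigree = pedigree, n_autosomes = as.integer(n_autosomes)),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d individuals x %d SNPs, %d breed(s)%s\n",
              nrow(x$calls), ncol(x$calls),
              length(unique(x$individuals$breed)),
              if (is.null(x$pedigree)) "" else ", pedigree attached"))
  invisible(x)
}

#' Map breed label to individual indices
#'
#' @param cohort a [new_cohort()] object.
#' @return Named list of integer row indices, one element per breed.
#' @export
breed_index <- function(cohort) {
  split(seq_len(nrow(cohort$calls)), cohort$individuals$breed)
}

#' Subset a cohort
#'
#' @param cohort a cohort.
#' @param individuals row indices or logical vector (default all).
#' @param snps column indices or logical vector (default all).
#' @return The subset cohort; pedigree and autosome count carried over.
#' @export
subset_cohort <- function(cohort, individuals = NULL, snps = NULL) {
  i <- if (is.null(individuals)) seq_len(nrow(cohort$calls)) else individuals
  j <- if (is.null(snps)) seq_len(ncol(cohort$calls)) else snps
  new_cohort(cohort$calls[i, j, drop = FALSE],
             cohort$individuals[i, , drop = FALSE],
             cohort$snps[j, , drop = FALSE],
             pedigree = cohort$pedigree,
             n_autosomes = cohort$n_autosomes)
}

#' Per-SNP frequency of the counted allele
#'
#' @param cohort a cohort.
#' @param rows optional subset of individuals to compute over.
#' @return Numeric vector, one frequency per SNP (`NaN` where untyped).
#' @export
allele_freq <- function(cohort, rows = NULL) {
  g <- if (is.null(rows)) cohort$calls else cohort$calls[rows, , drop = FALSE]
  colMeans(g, na.rm = TRUE) / 2
}

#' Per-SNP minor allele frequency
#' @inheritParams allele_freq
#' @return Numeric vector of MAFs.
#' @export
maf <- function(cohort, rows = NULL) {
  g <- if (is.null(rows)) cohort$calls else cohort$calls[rows, , drop = FALSE]
  # integer allele counts keep the result exactly symmetric in allele labels
  s <- colSums(g, na.rm = TRUE)
  tot <- 2 * colSums(!is.na(g))
  pmin(s, tot - s) / tot
}
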