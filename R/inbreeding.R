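#' ROH-based inbreeding coefficient
#'
#' Sum of ROH lengths at or above a minimum length threshold, as a fraction
#' of the autosomal length. The denominator defaults to the SNP-map span
#' (sum over chromosomes of last minus first SNP position); pass a fixed
#' constant (e.g. `2.44e9` for the ovine 50K panel coverage) to override.
#'
#' @param segments ROH table from [scan_roh()] (any individuals).
#' @param cohort the cohort (used for the animal list and map span).
#' @param min_length_mb minimum segment length to include (1, 5 or 10 Mb).
#' @param autosome_length_bp denominator in bp; `NULL` for map span.
#' @return Named numeric vector of F_ROH, one entry per cohort individual
#'   (zero where an animal has no qualifying segment).
#' @export
f_roh <- function(segments, cohort, min_length_mb = 1,
                  autosome_length_bp = NULL) {
  if (is.null(autosome_length_bp)) autosome_length_bp <- map_span_bp(cohort)
  stopifnot(autosome_length_bp > 0)
  out <- stats::setNames(numeric(nrow(cohort$individuals)),
                         cohort$individuals$id)
  seg <- segments[segments$length_mb >= min_length_mb, , drop = FALSE]
  if (nrow(seg)) {
    sums <- tapply((seg$end_bp - seg$start_bp + 1), seg$individual_id, sum)
    out[names(sums)] <- sums / autosome_length_bp
  }
  out
}

#' Autosomal span covered by the SNP map
#' @param cohort a cohort.
#' @return Total bp, summed over chromosomes as last minus first SNP.
#' @export
map_span_bp <- function(cohort) {
  sum(vapply(unique(cohort$snps$chrom), function(ch) {
    bp <- cohort$snps$bp[cohort$snps$chrom == ch]
    diff(range(bp))
  }, numeric(1)))
}

#' Pedigree inbreeding by the Meuwissen-Luo algorithm
#'
#' Computes each animal's inbreeding coefficient as the diagonal excess of
#' the numerator relationship matrix, accumulated per animal from its
#' generation coefficients L and the Mendelian-sampling variances D of its
#' ancestors (`A_ii = sum_j L_ij^2 D_j`), in topological order so ancestor
#' inbreeding is available when needed. Founders get F = 0.
#'
#' @param pedigree a `pedigree_table` from [read_pedigree()] /
#'   [as_pedigree()].
#' @return Named numeric vector of inbreeding coefficients.
#' @export
f_ped_meuwissen_luo <- function(pedigree) {
  ped <- as_pedigree(pedigree)      # validates, topologically orders
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  F <- numeric(n)
  D <- numeric(n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    D[i] <- if (is.na(s) && is.na(d)) 1 else
      if (is.na(s)) 0.75 - 0.25 * F[d] else
        if (is.na(d)) 0.75 - 0.25 * F[s] else
          0.5 - 0.25 * (F[s] + F[d])
    if (is.na(s) || is.na(d)) { F[i] <- 0; next }
    # accumulate L coefficients over the ancestor set of i
    L <- numeric(i)
    L[i] <- 1
    aii <- 0
    for (j in i:1) {
      if (L[j] == 0) next
      aii <- aii + L[j]^2 * D[j]
      if (!is.na(si[j])) L[si[j]] <- L[si[j]] + 0.5 * L[j]
      if (!is.na(di[j])) L[di[j]] <- L[di[j]] + 0.5 * L[j]
    }
    F[i] <- aii - 1
  }
  stats::setNames(F, ped$id)
}

#' Complete generation equivalents
#'
#' Pedigree-depth measure: the sum over all known ancestors of (1/2)^g,
#' where g is the generation distance (parents g = 1). Computed by the
#' recursion `CGE(i) = sum over known parents p of 0.5 * (1 + CGE(p))`.
#'
#' @inheritParams f_ped_meuwissen_luo
#' @return Named numeric vector of CGE values.
#' @export
complete_generation_equivalents <- function(pedigree) {
  ped <- as_pedigree(pedigree)
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  cge <- numeric(n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i]))
      if (!is.na(p)) cge[i] <- cge[i] + 0.5 * (1 + cge[p])
  }
  stats::setNames(cge, ped$id)
}

#' Genomic inbreeding from the GRM diagonal (VanRaden)
#'
#' `F(i) = sum_j (x_ij - 2 p_j)^2 / (2 sum_j p_j (1 - p_j)) - 1`, with
#' dosages x, counted-allele frequencies p estimated in the analysed set,
#' and both sums restricted per individual to its typed SNPs. SNPs fixed in
#' the analysed set are excluded (zero variance).
#'
#' @param cohort a cohort (subset to the analysis scope first, e.g. one
#'   breed, if within-breed frequencies are wanted).
#' @return Named numeric vector; may be negative for less-inbred-than-
#'   average individuals.
#' @export
f_grm_vanraden <- function(cohort) {
  p <- allele_freq(cohort)
  use <- !is.na(p) & p > 0 & p < 1
  g <- cohort$calls[, use, drop = FALSE]
  p <- p[use]
  dev2 <- sweep(g, 2, 2 * p)^2
  w <- 2 * p * (1 - p)
  typed <- !is.na(g)
  dev2[!typed] <- 0
  num <- rowSums(dev2)
  den <- typed %*% w
  stats::setNames(as.numeric(num / den - 1), cohort$individuals$id)
}

#' Inbreeding from excess homozygosity
#'
#' Wright-style fixation estimate per individual:
#' `F(i) = (O_i - E_i) / (m_i - E_i)` with observed homozygote count O,
#' expected homozygote count under HWE `E = sum_j (1 - 2 p_j (1 - p_j))`
#' over the individual's typed SNPs, and typed SNP count m.
#'
#' @inheritParams f_grm_vanraden
#' @return Named numeric vector; `NaN` (flagged) where every typed SNP is
#'   fixed (m = E).
#' @export
f_hom <- function(cohort) {
  p <- allele_freq(cohort)
  use <- !is.na(p)
  g <- cohort$calls[, use, drop = FALSE]
  p <- p[use]
  typed <- !is.na(g)
  O <- rowSums(g != 1, na.rm = TRUE)
  e_snp <- 1 - 2 * p * (1 - p)
  E <- as.numeric(typed %*% e_snp)
  m <- rowSums(typed)
  out <- (O - E) / (m - E)
  out[m == E] <- NaN
  stats::setNames(out, cohort$individuals$id)
}

#' Assemble per-individual inbreeding records
#'
#' @param cohort a cohort with pedigree attached (pedigree measures are
#'   `NA` otherwise).
#' @param segments ROH table from [scan_roh()].
#' @param autosome_length_bp denominator for F_ROH; `NULL` for map span.
#' @param freq_scope `"pooled"` to estimate allele frequencies across the
#'   whole cohort, `"breed"` to estimate them within each breed.
#' @return data.frame `individual_id, breed, f_roh_1mb, f_roh_5mb,
#'   f_roh_10mb, f_ped, cge, f_grm, f_hom`.
#' @export
inbreeding_records <- function(cohort, segments, autosome_length_bp = NULL,
                               freq_scope = c("pooled", "breed")) {
  freq_scope <- match.arg(freq_scope)
  ids <- cohort$individuals$id
  rec <- data.frame(individual_id = ids, breed = cohort$individuals$breed,
                    f_roh_1mb = f_roh(segments, cohort, 1, autosome_length_bp),
                    f_roh_5mb = f_roh(segments, cohort, 5, autosome_length_bp),
                    f_roh_10mb = f_roh(segments, cohort, 10, autosome_length_bp),
                    f_ped = NA_real_, cge = NA_real_,
                    f_grm = NA_real_, f_hom = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(cohort$pedigree)) {
    fp <- f_ped_meuwissen_luo(cohort$pedigree)
    cg <- complete_generation_equivalents(cohort$pedigree)
    rec$f_ped <- fp[match(ids, names(fp))]
    rec$cge <- cg[match(ids, names(cg))]
  }
  scopes <- if (freq_scope == "pooled") list(seq_along(ids)) else
    breed_index(cohort)
  for (rows in scopes) {
    sub <- subset_cohort(cohort, individuals = rows)
    rec$f_grm[rows] <- f_grm_vanraden(sub)
    rec$f_hom[rows] <- f_hom(sub)
  }
  rec
}

#' Correlation and regression report across inbreeding measures
#'
#' Pearson correlations (with two-sided p-values) between all pairs of
#' coefficients, within breed and pooled, restricted to animals whose
#' pedigree depth reaches `min_cge` complete generation equivalents; plus
#' ordinary-least-squares slope and intercept of each F_ROH measure on the
#' pedigree coefficient. Measures with zero variance in a scope are flagged
#' with `NA`.
#'
#' @param records output of [inbreeding_records()].
#' @param min_cge minimum pedigree depth for inclusion (6 by convention).
#' @param measures coefficient columns to correlate.
#' @return list with data.frames `correlations` (`scope, measure_x,
#'   measure_y, n, r, p`) and `regressions` (`scope, response, slope,
#'   intercept`).
#' @export
inbreeding_report <- function(records, min_cge = 6,
                              measures = c("f_roh_1mb", "f_roh_5mb",
                                           "f_roh_10mb", "f_ped",
                                           "f_grm", "f_hom")) {
  elig <- records[!is.na(records$cge) & records$cge >= min_cge, , drop = FALSE]
  if (nrow(elig) < 3) stop("fewer than 3 individuals reach the CGE threshold")
  scopes <- c(list(pooled = elig),
              split(elig, elig$breed))
  cors <- list(); regs <- list()
  for (sc in names(scopes)) {
    d <- scopes[[sc]]
    pairs <- utils::combn(measures, 2)
    for (k in seq_len(ncol(pairs))) {
      x <- d[[pairs[1, k]]]; y <- d[[pairs[2, k]]]
      ok <- stats::complete.cases(x, y) & is.finite(x) & is.finite(y)
      r <- p <- NA_real_
      if (sum(ok) >= 3 && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
        ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
        r <- unname(ct$estimate); p <- ct$p.value
      }
      cors[[length(cors) + 1L]] <- data.frame(
        scope = sc, measure_x = pairs[1, k], measure_y = pairs[2, k],
        n = sum(ok), r = r, p = p, stringsAsFactors = FALSE)
    }
    for (resp in intersect(c("f_roh_1mb", "f_roh_5mb", "f_roh_10mb"),
                           measures)) {
      ok <- stats::complete.cases(d[[resp]], d$f_ped)
      slope <- intercept <- NA_real_
      if (sum(ok) >= 3 && stats::sd(d$f_ped[ok]) > 0) {
        fit <- stats::lm(d[[resp]][ok] ~ d$f_ped[ok])
        intercept <- unname(stats::coef(fit)[1])
        slope <- unname(stats::coef(fit)[2])
      }
      regs[[length(regs) + 1L]] <- data.frame(
        scope = sc, response = resp, slope = slope, intercept = intercept,
        stringsAsFactors = FALSE)
    }
  }
  list(correlations = do.call(rbind, cors),
       regressions = do.call(rbind, regs))
}
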