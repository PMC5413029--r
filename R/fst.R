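#' Per-SNP Weir-Cockerham F_ST variance components
#'
#' Computes the 1984 moment estimator per SNP across the requested breeds:
#' among-population (a), among-individual-within-population (b) and
#' within-individual (c) variance components from sample sizes, counted-
#' allele frequencies and observed heterozygote fractions, with
#' `theta = a / (a + b + c)`. Breeds untyped at a SNP drop out of that SNP;
#' SNPs monomorphic across the included breeds (or typed in fewer than two
#' breeds) get `NA` theta and are excluded from ranking downstream.
#'
#' @param cohort a cohort.
#' @param breeds breed labels to contrast (default: all; at least 2).
#' @return data.frame `snp_id, chrom, bp, a, b, c, theta`.
#' @export
wc_theta <- function(cohort, breeds = NULL) {
  bi <- breed_index(cohort)
  if (!is.null(breeds)) bi <- bi[as.character(breeds)]
  if (length(bi) < 2) stop("Weir-Cockerham F_ST needs at least 2 breeds")
  m <- ncol(cohort$calls)
  r_pop <- length(bi)
  nmat <- pmat <- hmat <- matrix(0, r_pop, m)
  for (k in seq_len(r_pop)) {
    g <- cohort$calls[bi[[k]], , drop = FALSE]
    typed <- !is.na(g)
    nmat[k, ] <- colSums(typed)
    pmat[k, ] <- ifelse(nmat[k, ] > 0,
                        colSums(g, na.rm = TRUE) / (2 * pmax(nmat[k, ], 1)), 0)
    hmat[k, ] <- ifelse(nmat[k, ] > 0,
                        colSums(g == 1, na.rm = TRUE) / pmax(nmat[k, ], 1), 0)
  }
  present <- nmat > 0
  r <- colSums(present)
  ntot <- colSums(nmat)
  nbar <- ntot / pmax(r, 1)
  sum_n2 <- colSums(nmat^2)
  nc <- (ntot - sum_n2 / pmax(ntot, 1)) / pmax(r - 1, 1)
  pbar <- colSums(nmat * pmat) / pmax(ntot, 1)
  s2 <- colSums(nmat * sweep(pmat, 2, pbar)^2 * present) /
    (pmax(r - 1, 1) * pmax(nbar, 1e-300))
  hbar <- colSums(nmat * hmat) / pmax(ntot, 1)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2

  denom <- a + b + cc
  theta <- a / denom
  bad <- r < 2 | nbar <= 1 | nc <= 0 | !is.finite(denom) | denom == 0
  theta[bad] <- NA_real_
  a[bad] <- b[bad] <- cc[bad] <- NA_real_
  data.frame(snp_id = cohort$snps$snp_id, chrom = cohort$snps$chrom,
             bp = cohort$snps$bp, a = a, b = b, c = cc, theta = theta,
             stringsAsFactors = FALSE)
}

#' Sliding-window average of per-SNP F_ST
#'
#' Centered mean over `window_snps` consecutive SNPs on the same chromosome,
#' assigned to the middle SNP; the first and last `(window_snps-1)/2` SNPs
#' of each chromosome get no windowed value (windows never span chromosome
#' boundaries). Undefined per-SNP thetas are dropped from each window's
#' mean; negative thetas are retained unclamped.
#'
#' @param records output of [wc_theta()], sorted by chromosome and bp.
#' @param window_snps odd window size (5 by convention).
#' @return `records` with a `windowed_theta` column appended.
#' @export
window_average <- function(records, window_snps = 5L) {
  stopifnot(window_snps %% 2 == 1, window_snps >= 3)
  half <- (window_snps - 1L) %/% 2L
  wt <- rep(NA_real_, nrow(records))
  for (ch in unique(records$chrom)) {
    j <- which(records$chrom == ch)
    mc <- length(j)
    if (mc < window_snps) next
    th <- records$theta[j]
    def <- !is.na(th)
    th0 <- ifelse(def, th, 0)
    csum <- c(0, cumsum(th0)); cdef <- c(0, cumsum(def))
    centers <- (half + 1L):(mc - half)
    tot <- csum[centers + half + 1L] - csum[centers - half]
    cnt <- cdef[centers + half + 1L] - cdef[centers - half]
    wt[j[centers]] <- ifelse(cnt > 0, tot / cnt, NA)
  }
  records$windowed_theta <- wt
  records
}

# value of the k-th largest element, k = max(1, floor(n * frac))
top_threshold <- function(x, frac) {
  x <- x[!is.na(x)]
  k <- max(1L, floor(length(x) * frac))
  sort(x, decreasing = TRUE)[k]
}

#' Call selection-signature regions from windowed F_ST
#'
#' Seed SNPs are those whose windowed theta reaches the upper `top_call`
#' empirical threshold (top 0.1% by convention). From each seed the region
#' is extended SNP-by-SNP in both directions until two consecutive SNPs
#' rank outside the upper `top_extend` (top 5%) threshold: the first
#' sub-threshold SNP of the stopping pair is included, the second excluded.
#' Only SNPs with a defined windowed value participate. Overlapping or
#' touching regions from multiple seeds are merged.
#'
#' @param records output of [window_average()].
#' @param top_call seed tail fraction.
#' @param top_extend extension tail fraction.
#' @return data.frame `chrom, start_bp, end_bp, n_top_snps,
#'   max_windowed_theta, max_snp_id`.
#' @export
call_signatures <- function(records, top_call = 0.001, top_extend = 0.05) {
  wt <- records$windowed_theta
  if (all(is.na(wt))) stop("no windowed theta values; run window_average()")
  thr_call <- top_threshold(wt, top_call)
  thr_ext <- top_threshold(wt, top_extend)
  out <- list()
  for (ch in unique(records$chrom)) {
    j <- which(records$chrom == ch & !is.na(wt))
    if (!length(j)) next
    v <- wt[j]
    seeds <- which(v >= thr_call)
    if (!length(seeds)) next
    ivs <- matrix(0L, 0, 2)
    for (s in seeds) {
      lo <- hi <- s
      below <- 0L
      for (k in seq(s + 1L, length.out = max(0L, length(v) - s))) {
        if (v[k] >= thr_ext) { below <- 0L; hi <- k } else {
          below <- below + 1L
          if (below == 1L) hi <- k          # first outlier included
          if (below == 2L) { hi <- k - 1L; break }  # second excluded
        }
      }
      below <- 0L
      for (k in seq(s - 1L, length.out = max(0L, s - 1L), by = -1L)) {
        if (v[k] >= thr_ext) { below <- 0L; lo <- k } else {
          below <- below + 1L
          if (below == 1L) lo <- k
          if (below == 2L) { lo <- k + 1L; break }
        }
      }
      ivs <- rbind(ivs, c(lo, hi))
    }
    ivs <- ivs[order(ivs[, 1]), , drop = FALSE]
    merged <- ivs[1, , drop = FALSE]
    for (k in seq_len(nrow(ivs))[-1]) {
      last <- nrow(merged)
      if (ivs[k, 1] <= merged[last, 2] + 1L)
        merged[last, 2] <- max(merged[last, 2], ivs[k, 2])
      else merged <- rbind(merged, ivs[k, ])
    }
    for (k in seq_len(nrow(merged))) {
      rng <- j[merged[k, 1]:merged[k, 2]]
      imax <- rng[which.max(wt[rng])]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start_bp = records$bp[rng[1]],
        end_bp = records$bp[rng[length(rng)]],
        n_top_snps = sum(wt[rng] >= thr_call),
        max_windowed_theta = wt[imax],
        max_snp_id = records$snp_id[imax],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = integer(), start_bp = integer(),
                      end_bp = integer(), n_top_snps = integer(),
                      max_windowed_theta = numeric(),
                      max_snp_id = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mean genomic F_ST
#'
#' Unweighted mean of the per-SNP theta over SNPs where it is defined.
#'
#' @param records output of [wc_theta()].
#' @return A single number.
#' @export
mean_genomic_fst <- function(records) {
  th <- records$theta[!is.na(records$theta)]
  stopifnot(length(th) >= 1)
  mean(th)
}

#' Pairwise-breed F_ST over all breed pairs
#'
#' @param cohort a cohort with >= 2 breeds.
#' @return list with `mean_fst` (data.frame `breed_a, breed_b, mean_theta`)
#'   and `records` (named list of per-pair [wc_theta()] tables).
#' @export
pairwise_fst <- function(cohort) {
  breeds <- sort(unique(cohort$individuals$breed))
  stopifnot(length(breeds) >= 2)
  pairs <- utils::combn(breeds, 2)
  recs <- list(); means <- list()
  for (k in seq_len(ncol(pairs))) {
    rec <- wc_theta(cohort, breeds = pairs[, k])
    nm <- paste(pairs[1, k], pairs[2, k], sep = ":")
    recs[[nm]] <- rec
    means[[k]] <- data.frame(breed_a = pairs[1, k], breed_b = pairs[2, k],
                             mean_theta = mean_genomic_fst(rec),
                             stringsAsFactors = FALSE)
  }
  list(mean_fst = do.call(rbind, means), records = recs)
}

#' Correlate a per-SNP statistic with ROH incidence
#'
#' Pearson correlation (two-sided p) between per-SNP ROH incidence and a
#' per-SNP statistic such as global theta, over the shared SNP set.
#'
#' @param records a data.frame with `snp_id` and a statistic column.
#' @param incidence output of [snp_roh_incidence()].
#' @param stat name of the statistic column in `records`.
#' @return list `r`, `p`, `n`; `r` is `NA` (flagged) under zero variance.
#' @export
correlate_snp_stat_with_incidence <- function(records, incidence,
                                              stat = "theta") {
  hit <- match(incidence$snp_id, records$snp_id)
  x <- records[[stat]][hit]
  y <- incidence$incidence
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(list(r = NA_real_, p = NA_real_, n = sum(ok)))
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
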