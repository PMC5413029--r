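#' Quality-control parameters
#'
#' Defaults follow common SNP-array practice for livestock panels:
#' individuals and SNPs below 95% call rate dropped, MAF < 0.01 dropped,
#' within-breed Hardy-Weinberg exact-test p < 1e-7 dropped, and optional LD
#' pruning at r-squared > 0.1 inside sliding 50-SNP blocks.
#'
#' @param min_call_rate minimum fraction of non-missing calls, per
#'   individual and per SNP.
#' @param min_maf minimum minor allele frequency across all individuals.
#' @param hwe_p_threshold within-breed exact-test p below which a SNP is
#'   discarded.
#' @param prune_r2 r-squared above which the later SNP of a pair is pruned.
#' @param prune_window_snps size of the sliding pruning block (SNPs).
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(min_call_rate = 0.95, min_maf = 0.01,
                      hwe_p_threshold = 1e-7, prune_r2 = 0.1,
                      prune_window_snps = 50L) {
  stopifnot(min_call_rate > 0, min_call_rate <= 1,
            min_maf >= 0, min_maf < 0.5,
            hwe_p_threshold > 0, hwe_p_threshold <= 1,
            prune_r2 > 0, prune_window_snps >= 2)
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 hwe_p_threshold = hwe_p_threshold, prune_r2 = prune_r2,
                 prune_window_snps = as.integer(prune_window_snps)),
            class = "qc_params")
}

qc_report_row <- function(step, ind_removed, snp_removed, cohort) {
  data.frame(step = step,
             individuals_removed = ind_removed, snps_removed = snp_removed,
             individuals_retained = nrow(cohort$calls),
             snps_retained = ncol(cohort$calls),
             stringsAsFactors = FALSE)
}

#' Call-rate filter
#'
#' Individuals below the call-rate threshold are removed first; SNP call
#' rates are then computed on the retained individuals only.
#'
#' @param cohort a cohort.
#' @param params a [qc_params()] object.
#' @return `list(cohort, report)` where `report` is a per-step count table.
#' @export
filter_call_rate <- function(cohort, params = qc_params()) {
  stopifnot(nrow(cohort$calls) > 0)
  cr_ind <- rowMeans(!is.na(cohort$calls))
  keep_i <- cr_ind >= params$min_call_rate
  if (!any(keep_i)) stop("call-rate filter removed every individual")
  cohort <- subset_cohort(cohort, individuals = keep_i)
  cr_snp <- colMeans(!is.na(cohort$calls))
  keep_j <- cr_snp >= params$min_call_rate
  cohort2 <- subset_cohort(cohort, snps = keep_j)
  list(cohort = cohort2,
       report = qc_report_row("call_rate", sum(!keep_i), sum(!keep_j), cohort2))
}

#' Autosome and MAF filter
#'
#' Removes non-autosomal SNPs (chromosome label outside 1..n_autosomes),
#' then SNPs whose MAF across all retained individuals is strictly below
#' the threshold (a SNP at exactly the threshold is retained).
#'
#' @inheritParams filter_call_rate
#' @return `list(cohort, report)`.
#' @export
filter_maf_autosomal <- function(cohort, params = qc_params()) {
  auto <- cohort$snps$chrom >= 1 & cohort$snps$chrom <= cohort$n_autosomes
  cohort1 <- subset_cohort(cohort, snps = auto)
  mafs <- maf(cohort1)
  keep <- !is.na(mafs) & mafs >= params$min_maf
  cohort2 <- subset_cohort(cohort1, snps = keep)
  list(cohort = cohort2,
       report = qc_report_row("autosome_maf", 0L, sum(!auto) + sum(!keep),
                              cohort2))
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact conditional test: given the allele counts, heterozygote
#' counts are distributed as the (doubled) hypergeometric under the HWE
#' null; the p-value sums the probabilities of all heterozygote counts at
#' most as probable as the observed one. Probabilities are built by the
#' stable ratio recurrence rather than raw factorials.
#'
#' @param nAA,nAa,naa genotype counts.
#' @return The exact two-sided p-value.
#' @export
hwe_exact_test <- function(nAA, nAa, naa) {
  stopifnot(nAA >= 0, nAa >= 0, naa >= 0)
  n <- nAA + nAa + naa
  if (n == 0) stop("all genotype counts are zero")
  nA <- 2 * nAA + nAa
  nB <- 2 * naa + nAa
  rare <- min(nA, nB)
  if (rare == 0) return(1)                    # monomorphic: single outcome
  hs <- seq(rare %% 2, rare, by = 2)          # feasible heterozygote counts
  probs <- numeric(length(hs))
  probs[1] <- 1
  for (k in seq_along(hs)[-1]) {
    h <- hs[k - 1]
    n_rr <- (rare - h) / 2                    # rare-allele homozygotes at h
    n_cc <- n - n_rr - h                      # common-allele homozygotes
    probs[k] <- probs[k - 1] * 4 * n_rr * n_cc / ((h + 2) * (h + 1))
  }
  probs <- probs / sum(probs)
  obs <- probs[match(nAa, hs)]
  if (is.na(obs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(probs[probs <= obs * (1 + 1e-10)]))
}

genotype_counts <- function(g) {
  list(nAA = colSums(g == 2, na.rm = TRUE),
       nAa = colSums(g == 1, na.rm = TRUE),
       naa = colSums(g == 0, na.rm = TRUE))
}

#' Within-breed Hardy-Weinberg filter
#'
#' A SNP is discarded if its exact-test p-value falls below the threshold
#' in any single breed. Breeds with no typed genotypes at a SNP are skipped
#' for that SNP.
#'
#' @inheritParams filter_call_rate
#' @return `list(cohort, report)`.
#' @export
hwe_filter_within_breed <- function(cohort, params = qc_params()) {
  bi <- breed_index(cohort)
  stopifnot(length(bi) >= 1)
  m <- ncol(cohort$calls)
  fail <- rep(FALSE, m)
  for (rows in bi) {
    cnt <- genotype_counts(cohort$calls[rows, , drop = FALSE])
    typed <- cnt$nAA + cnt$nAa + cnt$naa > 0
    for (j in which(typed & !fail)) {
      p <- hwe_exact_test(cnt$nAA[j], cnt$nAa[j], cnt$naa[j])
      if (p < params$hwe_p_threshold) fail[j] <- TRUE
    }
  }
  cohort2 <- subset_cohort(cohort, snps = !fail)
  list(cohort = cohort2,
       report = qc_report_row("hwe_within_breed", 0L, sum(fail), cohort2))
}

# correlation between column pairs at a fixed index lag, pairwise-complete
lag_r2 <- function(g, lag) {
  m <- ncol(g)
  A <- g[, seq_len(m - lag), drop = FALSE]
  B <- g[, seq_len(m - lag) + lag, drop = FALSE]
  ok <- !is.na(A) & !is.na(B)
  A[!ok] <- 0; B[!ok] <- 0
  n <- colSums(ok)
  sa <- colSums(A); sb <- colSums(B)
  saa <- colSums(A^2); sbb <- colSums(B^2); sab <- colSums(A * B)
  cov <- sab - sa * sb / pmax(n, 1)
  va <- saa - sa^2 / pmax(n, 1)
  vb <- sbb - sb^2 / pmax(n, 1)
  r2 <- cov^2 / (va * vb)
  r2[n < 2 | va <= 0 | vb <= 0] <- NA
  r2
}

#' LD pruning
#'
#' Within every sliding block of `prune_window_snps` consecutive SNPs on a
#' chromosome, each pair with genotype-correlation r-squared above
#' `prune_r2` marks its later (higher-bp) member for removal; the earlier
#' SNP is kept. Passes repeat on the surviving set until no pair inside any
#' block of the output exceeds the threshold, so the result is stable and
#' deterministic given the input order. Missing genotypes are
#' pairwise-deleted.
#'
#' @inheritParams filter_call_rate
#' @return The pruned cohort.
#' @export
ld_prune <- function(cohort, params = qc_params()) {
  repeat {
    m <- ncol(cohort$calls)
    drop <- rep(FALSE, m)
    for (ch in unique(cohort$snps$chrom)) {
      idx <- which(cohort$snps$chrom == ch)
      mc <- length(idx)
      if (mc < 2) next
      g <- cohort$calls[, idx, drop = FALSE]
      storage.mode(g) <- "double"
      for (lag in seq_len(min(params$prune_window_snps - 1L, mc - 1L))) {
        r2 <- lag_r2(g, lag)
        hit <- which(!is.na(r2) & r2 > params$prune_r2)
        drop[idx[hit + lag]] <- TRUE
      }
    }
    if (!any(drop)) return(cohort)
    cohort <- subset_cohort(cohort, snps = !drop)
  }
}

#' Run the full QC chain
#'
#' Applies the filters in sequence: call rate, autosome/MAF, within-breed
#' HWE, and (optionally) LD pruning. Re-running the chain on its own output
#' is a no-op.
#'
#' @inheritParams filter_call_rate
#' @param prune whether to LD-prune after filtering (used for population
#'   structure analyses, not for ROH/F_ST stages).
#' @return `list(cohort, report)` with one report row per step.
#' @export
run_qc <- function(cohort, params = qc_params(), prune = FALSE) {
  s1 <- filter_call_rate(cohort, params)
  s2 <- filter_maf_autosomal(s1$cohort, params)
  s3 <- hwe_filter_within_breed(s2$cohort, params)
  out <- s3$cohort
  report <- rbind(s1$report, s2$report, s3$report)
  if (prune) {
    out <- ld_prune(out, params)
    report <- rbind(report,
                    qc_report_row("ld_prune", 0L,
                                  ncol(s3$cohort$calls) - ncol(out$calls), out))
  }
  list(cohort = out, report = report)
}
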