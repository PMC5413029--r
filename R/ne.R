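#' Parameters for LD-based effective population size
#'
#' @param min_maf within-breed MAF above which SNPs enter the analysis
#'   (strictly greater than, 0.05 by convention).
#' @param max_pair_distance_kb maximum physical distance between SNP pairs.
#' @param n_distance_bins number of equal-width recombination-fraction bins.
#' @param min_pairs_per_bin bins with fewer pairs are dropped.
#' @param mapping_function distance-to-recombination mapping:
#'   `"linear_1cM_per_Mb"` (c = bp x 1e-8, capped at 0.5), `"haldane"`
#'   (c = (1 - exp(-2m))/2 with m Morgans at 1 cM/Mb), or `"sved_feldman"`
#'   (c = m / (1 + 2m), this package's reading of the 1973 relation; the
#'   mapping is pluggable precisely because sources differ).
#' @param alpha_mutation mutation correction in the Ne equation: 2 when LD
#'   is shaped by both drift and mutation (default), 1 for drift only.
#' @param sample_size_adjustment `"unphased"` subtracts 1/n from r-squared
#'   (genotype correlations; the default for array data), `"phased"`
#'   subtracts 1/(2n).
#' @return A list of class `ne_params`.
#' @export
ne_params <- function(min_maf = 0.05, max_pair_distance_kb = 50000,
                      n_distance_bins = 30L, min_pairs_per_bin = 100L,
                      mapping_function = c("linear_1cM_per_Mb", "haldane",
                                           "sved_feldman"),
                      alpha_mutation = 2,
                      sample_size_adjustment = c("unphased", "phased")) {
  stopifnot(min_maf >= 0, min_maf < 0.5, n_distance_bins >= 2,
            alpha_mutation %in% c(1, 2))
  structure(list(min_maf = min_maf,
                 max_pair_distance_kb = max_pair_distance_kb,
                 n_distance_bins = as.integer(n_distance_bins),
                 min_pairs_per_bin = as.integer(min_pairs_per_bin),
                 mapping_function = match.arg(mapping_function),
                 alpha_mutation = alpha_mutation,
                 sample_size_adjustment = match.arg(sample_size_adjustment)),
            class = "ne_params")
}

#' All within-chromosome pairwise r-squared for one breed
#'
#' Squared Pearson correlation of genotype dosages over individuals typed
#' at both SNPs, for every same-chromosome pair within the distance cap,
#' after filtering SNPs to within-breed MAF strictly above `min_maf`.
#' Pairs with fewer than two shared typed individuals are skipped.
#'
#' @param cohort a cohort.
#' @param breed breed label (`NULL`: use all individuals).
#' @param params an [ne_params()] object.
#' @return data.frame `distance_bp, r2, n`.
#' @export
pairwise_r2 <- function(cohort, breed = NULL, params = ne_params()) {
  rows <- if (is.null(breed)) seq_len(nrow(cohort$calls)) else
    which(cohort$individuals$breed == breed)
  stopifnot(length(rows) >= 2)
  sub <- subset_cohort(cohort, individuals = rows)
  keep <- !is.na(maf(sub)) & maf(sub) > params$min_maf
  sub <- subset_cohort(sub, snps = keep)
  maxd <- params$max_pair_distance_kb * 1000
  out <- list()
  for (ch in unique(sub$snps$chrom)) {
    j <- which(sub$snps$chrom == ch)
    if (length(j) < 2) next
    g <- sub$calls[, j, drop = FALSE]
    storage.mode(g) <- "double"
    bp <- sub$snps$bp[j]
    cm <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))
    typed <- !is.na(g)
    npair <- crossprod(typed)
    pr <- which(upper.tri(cm), arr.ind = TRUE)
    d <- bp[pr[, 2]] - bp[pr[, 1]]
    ok <- d <= maxd & npair[pr] >= 2 & !is.na(cm[pr])
    out[[length(out) + 1L]] <- data.frame(distance_bp = d[ok],
                                          r2 = cm[pr][ok]^2,
                                          n = npair[pr][ok])
  }
  if (!length(out)) return(data.frame(distance_bp = numeric(),
                                      r2 = numeric(), n = numeric()))
  do.call(rbind, out)
}

#' Sample-size adjustment of r-squared
#'
#' Removes the expected sampling inflation of the squared correlation:
#' `r2 - 1/n` for unphased genotype correlations, `r2 - 1/(2n)` for phased
#' haplotype data. May be negative.
#'
#' @param r2 squared correlation(s).
#' @param n individuals the correlation was computed on.
#' @param mode `"unphased"` or `"phased"`.
#' @return Adjusted value(s).
#' @export
adjust_r2 <- function(r2, n, mode = c("unphased", "phased")) {
  mode <- match.arg(mode)
  stopifnot(all(n >= 2))
  r2 - 1 / (if (mode == "phased") 2 * n else n)
}

#' Physical distance to recombination fraction
#'
#' @param distance_bp physical distance(s) in bp.
#' @param mapping one of `"linear_1cM_per_Mb"`, `"haldane"`,
#'   `"sved_feldman"` (see [ne_params()]).
#' @return Recombination fraction(s) in (0, 0.5].
#' @export
distance_to_c <- function(distance_bp,
                          mapping = c("linear_1cM_per_Mb", "haldane",
                                      "sved_feldman")) {
  mapping <- match.arg(mapping)
  stopifnot(all(distance_bp > 0))
  m <- distance_bp * 1e-8          # Morgans at 1 cM/Mb
  switch(mapping,
         linear_1cM_per_Mb = pmin(m, 0.5),
         haldane = 0.5 * (1 - exp(-2 * m)),
         sved_feldman = m / (1 + 2 * m))
}

#' Effective population size from binned adjusted r-squared
#'
#' Applies `N_t = (4 c_t)^-1 (1 / E[r2_adj | c_t] - alpha)` per bin, with
#' the generation depth `t = (2 c_t)^-1`. Bins whose mean adjusted
#' r-squared is non-positive, or whose N comes out non-positive, are
#' flagged invalid.
#'
#' @param bins data.frame with columns `c_t` and `mean_r2_adj` (and
#'   optionally `n_pairs`).
#' @param params an [ne_params()] object (supplies alpha).
#' @return `bins` with columns `N_t`, `t` and logical `valid` appended.
#' @export
estimate_ne <- function(bins, params = ne_params()) {
  stopifnot(all(c("c_t", "mean_r2_adj") %in% names(bins)))
  a <- params$alpha_mutation
  ok <- bins$mean_r2_adj > 0
  N <- rep(NA_real_, nrow(bins))
  N[ok] <- (1 / (4 * bins$c_t[ok])) * (1 / bins$mean_r2_adj[ok] - a)
  bins$N_t <- N
  bins$t <- 1 / (2 * bins$c_t)
  bins$valid <- ok & !is.na(N) & N >= 0
  bins
}

#' Historical effective population size trajectory
#'
#' Full pipeline for one breed: within-breed MAF filter, all pairwise
#' genotype r-squared within the distance cap, sample-size adjustment,
#' mapping of physical distance to recombination fraction, equal-width
#' binning in c, and the closed-form Ne estimate per bin. Rows are sorted
#' by generation depth t ascending; a years column assumes the given
#' generation interval.
#'
#' @inheritParams pairwise_r2
#' @param generation_interval_years years per generation (4 for sheep).
#' @return data.frame `t, years, c_t, mean_r2_adj, n_pairs, N_t, valid`.
#' @export
ne_trajectory <- function(cohort, breed = NULL, params = ne_params(),
                          generation_interval_years = 4) {
  pr <- pairwise_r2(cohort, breed, params)
  if (!nrow(pr)) stop("no SNP pairs available for the Ne estimate")
  n_eff <- if (params$sample_size_adjustment == "phased") 2 * pr$n else pr$n
  r2a <- pr$r2 - 1 / n_eff
  cvec <- distance_to_c(pr$distance_bp, params$mapping_function)
  edges <- seq(min(cvec), max(cvec), length.out = params$n_distance_bins + 1L)
  bin <- findInterval(cvec, edges, rightmost.closed = TRUE, all.inside = TRUE)
  agg <- data.frame(
    c_t = tapply(cvec, bin, mean),
    mean_r2_adj = tapply(r2a, bin, mean),
    n_pairs = as.integer(tapply(r2a, bin, length)))
  agg <- agg[agg$n_pairs >= params$min_pairs_per_bin, , drop = FALSE]
  res <- estimate_ne(agg, params)
  res$years <- res$t * generation_interval_years
  res <- res[order(res$t), c("t", "years", "c_t", "mean_r2_adj",
                             "n_pairs", "N_t", "valid")]
  rownames(res) <- NULL
  res
}
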