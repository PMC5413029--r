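#' ROH scan parameters
#'
#' Window rules of the sliding-window genotype scan: 50-SNP windows, at most
#' one heterozygote and two missing calls per compliant window, a SNP
#' qualifies when at least 5% of the windows overlapping it are compliant.
#' Run-level constraints: a minimum SNP count (usually from
#' [lencz_min_snps()]), minimum physical length 1 Mb, average density of at
#' least one SNP per 100 kb, and a maximum 250-kb gap between consecutive
#' SNPs in a run.
#'
#' @param window_size SNPs per scanning window.
#' @param max_missing_per_window missing calls allowed in a compliant window.
#' @param max_het_per_window heterozygotes allowed in a compliant window.
#' @param window_hit_threshold minimum fraction of overlapping compliant
#'   windows for a SNP to qualify.
#' @param min_snps minimum SNPs per run; set from [lencz_min_snps()] to
#'   bound the expected number of chance runs.
#' @param min_length_mb minimum run length (Mb).
#' @param min_density_kb_per_snp maximum average spacing (kb per SNP).
#' @param max_gap_kb maximum gap between consecutive run SNPs (kb).
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(window_size = 50L, max_missing_per_window = 2L,
                       max_het_per_window = 1L, window_hit_threshold = 0.05,
                       min_snps = 50L, min_length_mb = 1,
                       min_density_kb_per_snp = 100, max_gap_kb = 250) {
  stopifnot(window_size >= 2, window_hit_threshold > 0, min_length_mb > 0,
            min_density_kb_per_snp > 0, max_gap_kb > 0, min_snps >= 1)
  structure(list(window_size = as.integer(window_size),
                 max_missing_per_window = as.integer(max_missing_per_window),
                 max_het_per_window = as.integer(max_het_per_window),
                 window_hit_threshold = window_hit_threshold,
                 min_snps = as.integer(min_snps),
                 min_length_mb = min_length_mb,
                 min_density_kb_per_snp = min_density_kb_per_snp,
                 max_gap_kb = max_gap_kb),
            class = "roh_params")
}

#' Minimum SNPs per ROH bounding chance runs
#'
#' Number of consecutive homozygous SNPs `l` needed so that the expected
#' count of length-l runs arising by chance across the whole dataset stays
#' below `alpha`:
#' `l = ceiling( ln(alpha / (n_snps * n_individuals)) / ln(1 - mean_het) )`.
#'
#' @param n_snps_per_individual SNPs genotyped per individual.
#' @param n_individuals individuals in the dataset.
#' @param alpha tolerated expected number of false-positive ROH (0.05 by
#'   convention).
#' @param mean_het mean per-SNP heterozygosity across all SNPs, in (0, 1).
#' @return Integer minimum SNP count.
#' @export
lencz_min_snps <- function(n_snps_per_individual, n_individuals,
                           alpha = 0.05, mean_het) {
  stopifnot(n_snps_per_individual >= 1, n_individuals >= 1, alpha > 0)
  if (!(mean_het > 0 && mean_het < 1))
    stop("mean_het must lie strictly between 0 and 1")
  as.integer(ceiling(log(alpha / (n_snps_per_individual * n_individuals)) /
                       log(1 - mean_het)))
}

#' Mean per-SNP heterozygosity of a cohort
#'
#' @param cohort a cohort.
#' @return Mean over SNPs of the observed heterozygote fraction.
#' @export
mean_snp_heterozygosity <- function(cohort) {
  mean(colMeans(cohort$calls == 1, na.rm = TRUE), na.rm = TRUE)
}

# scan one individual's genotypes on one chromosome; returns qualifying flag
scan_qualifying <- function(g, params) {
  m <- length(g)
  w <- min(params$window_size, m)
  if (w < params$window_size && w < 20L) return(NULL)   # chromosome too short
  het <- as.integer(!is.na(g) & g == 1)
  mis <- as.integer(is.na(g))
  nwin <- m - w + 1L
  roll <- function(x) {
    cs <- c(0, cumsum(x))
    cs[(w + 1):(m + 1)] - cs[1:nwin]
  }
  compliant <- as.integer(roll(het) <= params$max_het_per_window &
                            roll(mis) <= params$max_missing_per_window)
  # windows overlapping SNP j start in [j-w+1, j] clipped to [1, nwin]
  cs <- c(0, cumsum(compliant))
  j <- seq_len(m)
  lo <- pmax(j - w + 1L, 1L)
  hi <- pmin(j, nwin)
  nhit <- cs[hi + 1L] - cs[lo]
  nhit / (hi - lo + 1L) >= params$window_hit_threshold
}

run_bounds <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

#' Detect runs of homozygosity
#'
#' Per individual and chromosome: 50-SNP windows are classified compliant
#' (at most one heterozygote, at most two missing); a SNP qualifies when the
#' compliant fraction of windows overlapping it reaches the hit threshold;
#' maximal runs of qualifying SNPs are split at gaps above `max_gap_kb` and
#' must then pass the minimum SNP count, length and density constraints.
#' Chromosomes with fewer SNPs than a window are scanned with the available
#' size down to 20 SNPs, and skipped (with a warning) below that.
#'
#' @param cohort a QC'd cohort with SNPs sorted by chromosome and position.
#' @param params a [roh_params()] object.
#' @return data.frame with columns `individual_id, breed, chrom, start_bp,
#'   end_bp, n_snps, length_mb, genetic_length_cM` (cM is `NA` without a
#'   genetic map), sorted by individual, chromosome, start.
#' @export
scan_roh <- function(cohort, params = roh_params()) {
  snps <- cohort$snps
  out <- list()
  for (ch in unique(snps$chrom)) {
    idx <- which(snps$chrom == ch)
    if (length(idx) < 20L) {
      warning(sprintf("chromosome %s has <20 SNPs; skipped in ROH scan", ch))
      next
    }
    bp <- snps$bp[idx]
    cm <- snps$cM[idx]
    gap_ok <- c(TRUE, diff(bp) <= params$max_gap_kb * 1000)
    for (i in seq_len(nrow(cohort$calls))) {
      qual <- scan_qualifying(cohort$calls[i, idx], params)
      if (is.null(qual)) next
      runs <- run_bounds(qual)
      if (!nrow(runs)) next
      # split runs where the gap to the previous SNP is too large
      segs <- list()
      for (k in seq_len(nrow(runs))) {
        a <- runs[k, 1]; b <- runs[k, 2]
        cut <- which(!gap_ok[seq(a, b)])                  # positions after a gap
        starts <- c(a, a + cut - 1L)
        ends <- c(a + cut - 2L, b)
        for (s in seq_along(starts)) {
          if (starts[s] > ends[s]) next
          segs[[length(segs) + 1L]] <- c(starts[s], ends[s])
        }
      }
      for (sg in segs) {
        a <- sg[1]; b <- sg[2]
        ns <- b - a + 1L
        len_mb <- (bp[b] - bp[a] + 1) / 1e6
        if (ns < params$min_snps) next
        if (len_mb < params$min_length_mb) next
        if (len_mb * 1000 / ns > params$min_density_kb_per_snp) next
        out[[length(out) + 1L]] <- data.frame(
          individual_id = cohort$individuals$id[i],
          breed = cohort$individuals$breed[i],
          chrom = ch, start_bp = bp[a], end_bp = bp[b], n_snps = ns,
          length_mb = len_mb,
          genetic_length_cM = if (any(is.na(cm[c(a, b)]))) NA_real_ else
            cm[b] - cm[a],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(individual_id = character(), breed = character(),
                      chrom = integer(), start_bp = integer(),
                      end_bp = integer(), n_snps = integer(),
                      length_mb = numeric(), genetic_length_cM = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$individual_id, res$chrom, res$start_bp), ]
  rownames(res) <- NULL
  res
}

#' Physical length classes of ROH
#' @return Character vector of the five class labels.
#' @export
roh_length_classes <- function() {
  c("[1,5)", "[5,10)", "[10,15)", "[15,20)", ">=20")
}

classify_length <- function(length_mb) {
  cut(length_mb, breaks = c(1, 5, 10, 15, 20, Inf), right = FALSE,
      labels = roh_length_classes())
}

#' Mean ROH sum per animal by length class and breed
#'
#' Segments are binned into left-closed physical length classes
#' (1 to <5, 5 to <10, 10 to <15, 15 to <20, >=20 Mb); within each breed and
#' class the per-animal sums are averaged over all animals of the breed,
#' counting animals without ROH in a class as zero.
#'
#' @param segments output of [scan_roh()].
#' @param cohort the cohort the segments came from (supplies the full
#'   animal list per breed).
#' @return data.frame `breed, length_class, mean_sum_mb`.
#' @export
summarize_length_classes <- function(segments, cohort) {
  breeds <- sort(unique(cohort$individuals$breed))
  classes <- roh_length_classes()
  grid <- expand.grid(breed = breeds, length_class = classes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  nb <- table(cohort$individuals$breed)
  if (nrow(segments)) {
    segments$length_class <- as.character(classify_length(segments$length_mb))
    agg <- stats::aggregate(length_mb ~ breed + length_class, segments, sum)
  } else {
    agg <- data.frame(breed = character(), length_class = character(),
                      length_mb = numeric())
  }
  key <- paste(grid$breed, grid$length_class)
  hit <- match(key, paste(agg$breed, agg$length_class))
  grid$mean_sum_mb <- ifelse(is.na(hit), 0, agg$length_mb[hit]) /
    as.numeric(nb[grid$breed])
  grid
}

#' Per-SNP ROH incidence
#'
#' Fraction of in-scope individuals whose ROH set covers each SNP's physical
#' position.
#'
#' @param segments output of [scan_roh()].
#' @param cohort the cohort.
#' @param scope `"pooled"` for all individuals, or a breed label.
#' @return data.frame `snp_id, chrom, bp, incidence`.
#' @export
snp_roh_incidence <- function(segments, cohort, scope = "pooled") {
  if (identical(scope, "pooled")) {
    ids <- cohort$individuals$id
  } else {
    ids <- cohort$individuals$id[cohort$individuals$breed == scope]
    segments <- segments[segments$individual_id %in% ids, , drop = FALSE]
  }
  snps <- cohort$snps
  cover <- numeric(nrow(snps))
  if (nrow(segments)) {
    for (ch in unique(segments$chrom)) {
      j <- which(snps$chrom == ch)
      seg <- segments[segments$chrom == ch, , drop = FALSE]
      # count covering individuals per SNP via interval difference sums
      for (id in unique(seg$individual_id)) {
        si <- seg[seg$individual_id == id, , drop = FALSE]
        hit <- rep(FALSE, length(j))
        for (k in seq_len(nrow(si)))
          hit <- hit | (snps$bp[j] >= si$start_bp[k] &
                          snps$bp[j] <= si$end_bp[k])
        cover[j] <- cover[j] + hit
      }
    }
  }
  data.frame(snp_id = snps$snp_id, chrom = snps$chrom, bp = snps$bp,
             incidence = if (length(ids)) cover / length(ids) else 0,
             stringsAsFactors = FALSE)
}

#' Call ROH hotspots from incidence
#'
#' The top `top_fraction` of SNPs by incidence are selected (threshold = the
#' k-th largest value, k = floor(n x top_fraction), ties sharing the rank);
#' maximal runs of map-adjacent selected SNPs are merged into hotspot
#' regions (no bridging across non-selected SNPs).
#'
#' @param incidence output of [snp_roh_incidence()].
#' @param top_fraction upper tail fraction (default top 1%).
#' @param cohort optional cohort with genetic positions, used to attach a
#'   mean recombination rate (cM/Mb) per hotspot.
#' @return data.frame `chrom, start_bp, end_bp, n_snps, mean_incidence,
#'   recomb_cM_per_Mb`.
#' @export
call_hotspots <- function(incidence, top_fraction = 0.01, cohort = NULL) {
  thr <- top_threshold(incidence$incidence, top_fraction)
  sel <- incidence$incidence >= thr
  out <- list()
  for (ch in unique(incidence$chrom)) {
    j <- which(incidence$chrom == ch)
    runs <- run_bounds(sel[j])
    if (!nrow(runs)) next
    for (k in seq_len(nrow(runs))) {
      a <- j[runs[k, 1]]; b <- j[runs[k, 2]]
      rate <- NA_real_
      if (!is.null(cohort)) {
        cm <- cohort$snps$cM[c(a, b)]
        span_mb <- (incidence$bp[b] - incidence$bp[a]) / 1e6
        if (!any(is.na(cm)) && span_mb > 0) rate <- (cm[2] - cm[1]) / span_mb
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start_bp = incidence$bp[a], end_bp = incidence$bp[b],
        n_snps = runs[k, 2] - runs[k, 1] + 1L,
        mean_incidence = mean(incidence$incidence[a:b]),
        recomb_cM_per_Mb = rate)
    }
  }
  if (!length(out))
    return(data.frame(chrom = integer(), start_bp = integer(),
                      end_bp = integer(), n_snps = integer(),
                      mean_incidence = numeric(), recomb_cM_per_Mb = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fraction of each chromosome in ROH, by breed
#'
#' Chromosomal length is taken from the SNP coverage (last minus first SNP
#' position); the fraction is the breed's mean per-individual ROH sum on the
#' chromosome divided by that length.
#'
#' @param segments output of [scan_roh()].
#' @param cohort the cohort.
#' @return data.frame `breed, chrom, fraction`.
#' @export
chromosome_roh_fraction <- function(segments, cohort) {
  breeds <- sort(unique(cohort$individuals$breed))
  chroms <- unique(cohort$snps$chrom)
  nb <- table(cohort$individuals$breed)
  grid <- expand.grid(breed = breeds, chrom = chroms,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  span <- vapply(chroms, function(ch) {
    bp <- cohort$snps$bp[cohort$snps$chrom == ch]
    diff(range(bp))
  }, numeric(1))
  names(span) <- as.character(chroms)
  grid$fraction <- 0
  if (nrow(segments)) {
    seglen <- (segments$end_bp - segments$start_bp + 1)
    agg <- stats::aggregate(seglen,
                            by = list(breed = segments$breed,
                                      chrom = segments$chrom), FUN = sum)
    hit <- match(paste(grid$breed, grid$chrom), paste(agg$breed, agg$chrom))
    tot <- ifelse(is.na(hit), 0, agg$x[hit])
    grid$fraction <- tot / as.numeric(nb[grid$breed]) /
      span[as.character(grid$chrom)]
  }
  grid
}

#' TMRCA bins from genetic ROH length
#'
#' An identical-by-descent segment from a common ancestor `g` generations
#' back has expected map length `100/(2g)` cM, so genetic ROH length maps to
#' time depth: >= 10 cM within ~5 generations, 5 to <10 cM 5-10 generations,
#' 2.5 to <5 cM 10-20 generations, < 2.5 cM more than 20 generations
#' (bins left-closed on their lower cM edge). Reports the mean per-animal
#' ROH sum (cM) per breed per bin; segments without a genetic length are
#' excluded and counted.
#'
#' @param segments output of [scan_roh()] with `genetic_length_cM` filled.
#' @param cohort the cohort.
#' @return list with `table` (data.frame `breed, tmrca_bin, mean_sum_cM`)
#'   and `n_excluded` (segments lacking cM).
#' @export
tmrca_bins <- function(segments, cohort) {
  labels <- c("<=5 gen", "5-10 gen", "10-20 gen", ">20 gen")
  excl <- sum(is.na(segments$genetic_length_cM))
  seg <- segments[!is.na(segments$genetic_length_cM), , drop = FALSE]
  breeds <- sort(unique(cohort$individuals$breed))
  nb <- table(cohort$individuals$breed)
  grid <- expand.grid(breed = breeds, tmrca_bin = labels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$mean_sum_cM <- 0
  if (nrow(seg)) {
    # edges at 100/(2g) for g = 5, 10, 20
    bin <- cut(seg$genetic_length_cM, breaks = c(-Inf, 2.5, 5, 10, Inf),
               right = FALSE, labels = rev(labels))
    agg <- stats::aggregate(seg$genetic_length_cM,
                            by = list(breed = seg$breed,
                                      tmrca_bin = as.character(bin)),
                            FUN = sum)
    hit <- match(paste(grid$breed, grid$tmrca_bin),
                 paste(agg$breed, agg$tmrca_bin))
    grid$mean_sum_cM <- ifelse(is.na(hit), 0, agg$x[hit]) /
      as.numeric(nb[grid$breed])
  }
  list(table = grid, n_excluded = excl)
}

#' Recombination rate in fixed physical windows
#'
#' Tiles each chromosome with non-overlapping windows (500 kb by default)
#' and reports (cM at last SNP in tile - cM at first SNP) / (bp span in Mb);
#' tiles with fewer than two mapped SNPs get `NA`.
#'
#' @param cohort a cohort with genetic positions attached.
#' @param window_kb tile width in kb.
#' @return data.frame `chrom, start_bp, end_bp, n_snps, cM_per_Mb`.
#' @export
recombination_windows <- function(cohort, window_kb = 500) {
  snps <- cohort$snps
  out <- list()
  for (ch in unique(snps$chrom)) {
    j <- which(snps$chrom == ch & !is.na(snps$cM))
    if (length(j) < 2) next
    bp <- snps$bp[j]; cm <- snps$cM[j]
    tile <- (bp - 1) %/% (window_kb * 1000)
    for (tl in unique(tile)) {
      k <- which(tile == tl)
      start <- tl * window_kb * 1000 + 1
      rate <- NA_real_
      if (length(k) >= 2) {
        span_mb <- (bp[k[length(k)]] - bp[k[1]]) / 1e6
        rate <- if (span_mb > 0) (cm[k[length(k)]] - cm[k[1]]) / span_mb else NA
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start_bp = start, end_bp = start + window_kb * 1000 - 1,
        n_snps = length(k), cM_per_Mb = rate)
    }
  }
  if (!length(out))
    return(data.frame(chrom = integer(), start_bp = numeric(),
                      end_bp = numeric(), n_snps = integer(),
                      cM_per_Mb = numeric()))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start_bp), ]
  rownames(res) <- NULL
  res
}
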