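test_that("minimum-SNP formula evaluates, is monotone, and rejects het=0", {
  l <- lencz_min_snps(42182, 3191, 0.05, 0.35)
  expect_identical(l, 51L)
  # monotone: more heterozygosity means shorter required runs
  expect_lt(lencz_min_snps(42182, 3191, 0.05, 0.5), l)
  # looser alpha never lengthens the requirement
  expect_lte(lencz_min_snps(42182, 3191, 1, 0.35), l)
  expect_error(lencz_min_snps(100, 10, 0.05, 0), "mean_het")
})

test_that("a fully homozygous chromosome yields one spanning segment", {
  co <- planted_roh_cohort(n_snps = 60, spacing_bp = 50000)  # 3-Mb chromosome
  segs <- scan_roh(co, roh_params(min_snps = 20))
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$start_bp, co$snps$bp[1])
  expect_identical(segs$end_bp, co$snps$bp[60])
  expect_identical(segs$n_snps, 60L)
  expect_equal(segs$length_mb, (co$snps$bp[60] - co$snps$bp[1] + 1) / 1e6)
  expect_equal(segs$genetic_length_cM, co$snps$cM[60] - co$snps$cM[1])
})

test_that("regular heterozygosity defeats the window rule", {
  co <- planted_roh_cohort(n_snps = 60, spacing_bp = 50000, het_every = 10)
  segs <- scan_roh(co, roh_params(min_snps = 20))
  expect_identical(nrow(segs), 0L)
})

test_that("segments split at large gaps and respect run-level constraints", {
  co <- planted_roh_cohort(n_snps = 80, spacing_bp = 50000)
  co$snps$bp[41:80] <- co$snps$bp[41:80] + 500000L   # 550-kb gap after SNP 40
  segs <- scan_roh(co, roh_params(min_snps = 20))
  expect_identical(nrow(segs), 2L)
  expect_identical(segs$end_bp[1], co$snps$bp[40])
  expect_identical(segs$start_bp[2], co$snps$bp[41])
  # raising the length floor never adds segments
  for (lmb in c(1, 2, 3)) {
    n1 <- nrow(scan_roh(co, roh_params(min_snps = 20, min_length_mb = lmb)))
    n2 <- nrow(scan_roh(co, roh_params(min_snps = 20,
                                       min_length_mb = lmb + 1)))
    expect_lte(n2, n1)
  }
  # density rule: 60 SNPs stretched over 30 Mb is too sparse
  sparse <- planted_roh_cohort(n_snps = 60, spacing_bp = 500000)
  expect_identical(nrow(scan_roh(sparse, roh_params(min_snps = 20,
                                                    max_gap_kb = 600))), 0L)
})

test_that("length classes average over all animals of the breed", {
  co <- planted_roh_cohort(60, 50000)
  co$individuals <- data.frame(id = "x1", breed = "B",
                               stringsAsFactors = FALSE)
  two <- new_cohort(rbind(co$calls, co$calls),
                    data.frame(id = c("x1", "x2"), breed = "B"), co$snps)
  segs <- data.frame(individual_id = "x1", breed = "B", chrom = 1L,
                     start_bp = 1L, end_bp = 3000000L, n_snps = 60L,
                     length_mb = 3, genetic_length_cM = 3)
  tab <- summarize_length_classes(segs, two)
  expect_equal(tab$mean_sum_mb[tab$length_class == "[1,5)"], 1.5)
  expect_true(all(tab$mean_sum_mb[tab$length_class != "[1,5)"] == 0))
  # boundary: exactly 5 Mb falls in [5,10)
  segs$length_mb <- 5
  tab5 <- summarize_length_classes(segs, two)
  expect_equal(tab5$mean_sum_mb[tab5$length_class == "[5,10)"], 2.5)
  # empty input: all-zero table
  none <- summarize_length_classes(segs[0, ], two)
  expect_true(all(none$mean_sum_mb == 0))
})

test_that("incidence counts covering individuals and is order-invariant", {
  co <- planted_roh_cohort(10, 100000)
  calls <- matrix(0L, 10, 10)
  co10 <- new_cohort(calls,
                     data.frame(id = sprintf("x%d", 1:10), breed = "B"),
                     co$snps)
  segs <- data.frame(individual_id = sprintf("x%d", 1:3), breed = "B",
                     chrom = 1L, start_bp = co10$snps$bp[2],
                     end_bp = co10$snps$bp[5], n_snps = 4L,
                     length_mb = 0.4, genetic_length_cM = NA_real_)
  inc <- snp_roh_incidence(segs, co10)
  expect_equal(inc$incidence, c(0, .3, .3, .3, .3, 0, 0, 0, 0, 0))
  perm <- sample(10)
  co_perm <- subset_cohort(co10, individuals = perm)
  expect_equal(snp_roh_incidence(segs, co_perm)$incidence, inc$incidence)
})

test_that("hotspot calling merges adjacent top SNPs without bridging", {
  inc <- data.frame(snp_id = sprintf("s%d", 1:1000), chrom = 1L,
                    bp = as.integer(1:1000 * 1000),
                    incidence = rep(0.05, 1000))
  inc$incidence[301:310] <- 0.9
  hs <- call_hotspots(inc, top_fraction = 0.01)
  expect_identical(nrow(hs), 1L)
  expect_identical(hs$n_snps, 10L)
  expect_identical(hs$start_bp, 301000L)
  expect_identical(hs$end_bp, 310000L)
  # alternating top SNPs give singleton hotspots
  inc$incidence <- rep(0.05, 1000)
  inc$incidence[seq(101, 119, by = 2)] <- 0.9
  hs2 <- call_hotspots(inc, top_fraction = 0.01)
  expect_identical(nrow(hs2), 10L)
  expect_true(all(hs2$n_snps == 1L))
})

test_that("chromosome fractions reflect mean per-individual coverage", {
  co <- planted_roh_cohort(60, 50000)
  two <- new_cohort(rbind(co$calls, co$calls),
                    data.frame(id = c("x1", "x2"), breed = "B"), co$snps)
  span <- diff(range(co$snps$bp))
  full <- data.frame(individual_id = c("x1", "x2"), breed = "B", chrom = 1L,
                     start_bp = co$snps$bp[1], end_bp = co$snps$bp[60],
                     n_snps = 60L, length_mb = 3,
                     genetic_length_cM = NA_real_)
  f <- chromosome_roh_fraction(full, two)
  expect_equal(f$fraction, (span + 1) / span)     # whole chromosome covered
  half <- full[1, , drop = FALSE]
  expect_equal(chromosome_roh_fraction(half, two)$fraction,
               (span + 1) / span / 2)
  expect_equal(chromosome_roh_fraction(full[0, ], two)$fraction, 0)
})

test_that("TMRCA bins follow the 100/(2g) cM edges, left-closed", {
  co <- planted_roh_cohort(10, 100000)
  seg <- function(cm) data.frame(individual_id = "x1", breed = "B",
                                 chrom = 1L, start_bp = 1L, end_bp = 2L,
                                 n_snps = 2L, length_mb = 1,
                                 genetic_length_cM = cm)
  bin_of <- function(cm) {
    t <- tmrca_bins(seg(cm), co)$table
    t$tmrca_bin[t$mean_sum_cM > 0]
  }
  expect_identical(bin_of(12), "<=5 gen")
  expect_identical(bin_of(10), "<=5 gen")      # edge 100/(2*5)
  expect_identical(bin_of(4), "10-20 gen")
  expect_identical(bin_of(2.5), "10-20 gen")   # left-closed at 100/(2*20)
  expect_identical(bin_of(1), ">20 gen")
  # segments without genetic length are excluded but counted
  s <- seg(NA_real_)
  res <- tmrca_bins(s, co)
  expect_identical(res$n_excluded, 1L)
  expect_true(all(res$table$mean_sum_cM == 0))
})

test_that("recombination windows recover a uniform map rate", {
  co <- planted_roh_cohort(n_snps = 60, spacing_bp = 50000)  # 1 cM/Mb map
  rw <- recombination_windows(co, window_kb = 500)
  expect_true(all(abs(rw$cM_per_Mb - 1) < 1e-9, na.rm = TRUE))
  # a zero-recombination plateau reads 0
  co$snps$cM[21:40] <- co$snps$cM[21]
  rw2 <- recombination_windows(co, window_kb = 500)
  expect_true(any(rw2$cM_per_Mb == 0, na.rm = TRUE))
  # single-SNP tiles carry no rate
  co2 <- planted_roh_cohort(n_snps = 30, spacing_bp = 600000)
  rw3 <- recombination_windows(co2, window_kb = 500)
  expect_true(all(is.na(rw3$cM_per_Mb)))
})
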