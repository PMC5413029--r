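test_that("F_ROH is a length fraction with threshold monotonicity", {
  co <- planted_roh_cohort(10, 100000)
  segs <- data.frame(individual_id = "x1", breed = "B", chrom = 1L,
                     start_bp = 1L, end_bp = 244000000L, n_snps = 10L,
                     length_mb = 244, genetic_length_cM = NA_real_)
  expect_equal(unname(f_roh(segs, co, 1, autosome_length_bp = 2.44e9)), 0.1)
  expect_equal(unname(f_roh(segs[0, ], co, 1, 2.44e9)), 0)
  mixed <- rbind(segs, segs, segs)
  mixed$length_mb <- c(2, 6, 12)
  mixed$end_bp <- as.integer(mixed$length_mb * 1e6)
  f1 <- f_roh(mixed, co, 1, 2.44e9)
  f5 <- f_roh(mixed, co, 5, 2.44e9)
  f10 <- f_roh(mixed, co, 10, 2.44e9)
  expect_true(f10 <= f5 && f5 <= f1)
  expect_equal(unname(f1), (2 + 6 + 12) * 1e6 / 2.44e9, tolerance = 1e-6)
})

test_that("pedigree inbreeding reproduces textbook kinship values", {
  founders <- data.frame(id = c("A", "B"), sire = NA, dam = NA, breed = "x")
  expect_equal(unname(f_ped_meuwissen_luo(founders)), c(0, 0))
  # offspring of two unrelated founders
  trio <- rbind(founders, data.frame(id = "C", sire = "A", dam = "B",
                                     breed = "x"))
  expect_equal(f_ped_meuwissen_luo(trio)[["C"]], 0)
  # offspring of full sibs: F = 0.25
  fs <- rbind(trio, data.frame(id = c("D", "X"), sire = c("A", "C"),
                               dam = c("B", "D"), breed = "x"))
  expect_equal(f_ped_meuwissen_luo(fs)[["X"]], 0.25)
  # offspring of half sibs: F = 0.125
  hs <- data.frame(id = c("S", "D1", "D2", "H1", "H2", "Y"),
                   sire = c(NA, NA, NA, "S", "S", "H1"),
                   dam = c(NA, NA, NA, "D1", "D2", "H2"), breed = "x")
  expect_equal(f_ped_meuwissen_luo(hs)[["Y"]], 0.125)
})

test_that("Meuwissen-Luo agrees exactly with the tabular-method oracle", {
  set.seed(11)
  for (rep in 1:10) {
    ped <- random_pedigree(sample(10:40, 1))
    expect_equal(f_ped_meuwissen_luo(ped), tabular_f_oracle(ped),
                 tolerance = 1e-12)
  }
})

test_that("complete generation equivalents count discounted known ancestors", {
  ped <- data.frame(id = c("gp1", "gp2", "gp3", "gp4", "p1", "p2", "k",
                           "half"),
                    sire = c(NA, NA, NA, NA, "gp1", "gp3", "p1", "p1"),
                    dam = c(NA, NA, NA, NA, "gp2", "gp4", "p2", NA),
                    breed = "x")
  cge <- complete_generation_equivalents(ped)
  expect_equal(cge[["p1"]], 1)      # both parents known, nothing deeper
  expect_equal(cge[["k"]], 2)       # two complete generations
  expect_equal(cge[["half"]], 0.5 * (1 + 1))  # one known parent with depth 1
  expect_equal(complete_generation_equivalents(ped),
               cge_traversal_oracle(ped))
})

test_that("F_GRM and F_HOM center near zero in an outbred HWE population", {
  set.seed(12)
  n <- 400; m <- 2000
  p <- runif(m, 0.1, 0.9)
  calls <- sapply(p, function(pp) rbinom(n, 2, pp))
  co <- new_cohort(calls,
                   data.frame(id = sprintf("i%d", 1:n), breed = "B"),
                   data.frame(snp_id = sprintf("s%d", 1:m), chrom = 1L,
                              bp = as.integer(1:m * 1000), cM = NA_real_))
  fg <- f_grm_vanraden(co)
  fh <- f_hom(co)
  expect_lt(abs(mean(fg)), 3 * sd(fg) / sqrt(n))
  expect_lt(abs(mean(fh)), 3 * sd(fh) / sqrt(n))
  # a duplicated individual gets an identical coefficient
  ind2 <- rbind(co$individuals, data.frame(id = "dup", breed = "B"))
  co2 <- new_cohort(rbind(co$calls, co$calls[1, ]), ind2, co$snps)
  fg2 <- f_grm_vanraden(co2)
  expect_equal(unname(fg2[1]), unname(fg2[n + 1]))
})

test_that("extreme homozygosity pushes the genomic coefficients up", {
  set.seed(13)
  n <- 100; m <- 500
  p <- runif(m, 0.2, 0.8)
  calls <- sapply(p, function(pp) rbinom(n, 2, pp))
  # individual 1 homozygous for the rarer allele everywhere
  calls[1, ] <- ifelse(p < 0.5, 2L, 0L)
  co <- new_cohort(calls,
                   data.frame(id = sprintf("i%d", 1:n), breed = "B"),
                   data.frame(snp_id = sprintf("s%d", 1:m), chrom = 1L,
                              bp = as.integer(1:m * 1000), cM = NA_real_))
  expect_gt(f_grm_vanraden(co)[["i1"]], 0)
  expect_equal(f_hom(co)[["i1"]], 1)   # O = m exactly
})

test_that("the inbreeding report restricts by CGE and flags degeneracy", {
  set.seed(14)
  n <- 60
  rec <- data.frame(individual_id = sprintf("i%d", 1:n), breed = "B",
                    f_roh_1mb = runif(n, 0, 0.3))
  rec$f_roh_5mb <- rec$f_roh_1mb * 0.8
  rec$f_roh_10mb <- rec$f_roh_1mb * 0.5
  rec$f_ped <- rec$f_roh_1mb                  # duplicated column
  rec$f_grm <- rnorm(n, 0, 0.05)              # independent
  rec$f_hom <- rnorm(n, 0, 0.05)
  rec$cge <- c(rep(10, 40), rep(2, 20))       # 20 animals below threshold
  rep1 <- inbreeding_report(rec, min_cge = 6)
  row <- rep1$correlations[rep1$correlations$scope == "pooled" &
                             rep1$correlations$measure_x == "f_roh_1mb" &
                             rep1$correlations$measure_y == "f_ped", ]
  expect_equal(row$r, 1)
  expect_identical(row$n, 40L)
  reg <- rep1$regressions[rep1$regressions$scope == "pooled" &
                            rep1$regressions$response == "f_roh_1mb", ]
  expect_equal(reg$slope, 1)
  expect_equal(reg$intercept, 0, tolerance = 1e-12)
  # independent column correlates near zero
  row2 <- rep1$correlations[rep1$correlations$scope == "pooled" &
                              rep1$correlations$measure_x == "f_ped" &
                              rep1$correlations$measure_y == "f_grm", ]
  expect_lt(abs(row2$r), 0.4)
  # zero-variance measure flagged NA
  rec$f_hom <- 0
  rep2 <- inbreeding_report(rec, min_cge = 6)
  expect_true(all(is.na(
    rep2$correlations$r[rep2$correlations$measure_y == "f_hom"])))
  expect_error(inbreeding_report(rec, min_cge = 99), "CGE")
})
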