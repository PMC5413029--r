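make_fst_cohort <- function(pop_list, bp = NULL) {
  calls <- do.call(rbind, pop_list)
  m <- ncol(calls)
  if (is.null(bp)) bp <- as.integer(seq_len(m) * 1000)
  breeds <- rep(sprintf("P%d", seq_along(pop_list)),
                vapply(pop_list, nrow, 1L))
  new_cohort(calls,
             data.frame(id = sprintf("i%d", seq_len(nrow(calls))),
                        breed = breeds, stringsAsFactors = FALSE),
             data.frame(snp_id = sprintf("s%d", seq_len(m)), chrom = 1L,
                        bp = bp, cM = NA_real_, stringsAsFactors = FALSE))
}

test_that("fixed differences give theta = 1, shared columns never exceed 0", {
  co <- make_fst_cohort(list(matrix(0L, 10, 2), matrix(2L, 12, 2)))
  rec <- wc_theta(co)
  expect_equal(rec$theta, c(1, 1))
  set.seed(21)
  col <- rbinom(15, 2, 0.5)
  co2 <- make_fst_cohort(list(matrix(col, 15, 3), matrix(col, 15, 3)))
  rec2 <- wc_theta(co2)
  expect_true(all(rec2$theta <= 0))
  # monomorphic across included breeds: undefined, excluded from the mean
  co3 <- make_fst_cohort(list(cbind(matrix(0L, 8, 1), rbinom(8, 2, .5)),
                              cbind(matrix(0L, 8, 1), rbinom(8, 2, .5))))
  rec3 <- wc_theta(co3)
  expect_true(is.na(rec3$theta[1]))
  expect_equal(mean_genomic_fst(rec3), rec3$theta[2])
  expect_error(wc_theta(subset_cohort(co, 1:10)), "2 breeds")
})

test_that("theta matches the scalar oracle on random configurations", {
  set.seed(22)
  for (rep in 1:25) {
    npop <- sample(2:3, 1)
    pops <- lapply(seq_len(npop), function(i) {
      n <- sample(4:25, 1)
      p <- runif(1, 0.1, 0.9)
      g <- matrix(rbinom(n, 2, p), ncol = 1)
      if (runif(1) < 0.3) g[sample(n, 1)] <- NA
      g
    })
    co <- make_fst_cohort(pops)
    rec <- wc_theta(co)
    ora <- wc_oracle(lapply(pops, as.vector))
    if (is.na(rec$theta)) {
      expect_true(!is.finite(ora[["theta"]]) || is.na(ora[["theta"]]))
    } else {
      expect_equal(rec$a, unname(ora["a"]), tolerance = 1e-12)
      expect_equal(rec$b, unname(ora["b"]), tolerance = 1e-12)
      expect_equal(rec$c, unname(ora["c"]), tolerance = 1e-12)
      expect_equal(rec$theta, unname(ora["theta"]), tolerance = 1e-12)
    }
  }
})

test_that("theta is invariant to allele relabeling and individual order", {
  set.seed(23)
  pops <- list(matrix(rbinom(40, 2, 0.3), 20), matrix(rbinom(40, 2, 0.7), 20))
  co <- make_fst_cohort(pops)
  t1 <- wc_theta(co)$theta
  # relabel: dosage g -> 2 - g
  co_flip <- co; co_flip$calls <- 2L - co$calls
  expect_equal(wc_theta(co_flip)$theta, t1)
  perm <- sample(nrow(co$calls))
  expect_equal(wc_theta(subset_cohort(co, perm))$theta, t1)
})

test_that("window averaging centers full same-chromosome windows", {
  rec <- data.frame(snp_id = sprintf("s%d", 1:12),
                    chrom = rep(c(1L, 2L), c(8, 4)),
                    bp = as.integer(c(1:8, 1:4) * 1000),
                    theta = c(rep(0.2, 8), rep(0.3, 4)))
  w <- window_average(rec, 5)
  expect_equal(w$windowed_theta[3:6], rep(0.2, 4))
  expect_true(all(is.na(w$windowed_theta[c(1, 2, 7, 8)])))
  expect_true(all(is.na(w$windowed_theta[9:12])))   # 4-SNP chromosome
  # a single spike averages to spike/5 at the center
  rec$theta <- c(0, 0, 0, 0, 1, 0, 0, 0, rep(0, 4))
  w2 <- window_average(rec, 5)
  expect_equal(w2$windowed_theta[5], 0.2)
  expect_equal(w2$windowed_theta[3], 0.2)
  # undefined thetas drop out of the window mean
  rec$theta[4] <- NA
  w3 <- window_average(rec, 5)
  expect_equal(w3$windowed_theta[6], 1 / 4)
})

test_that("signature boundaries include the first outlier and stop at the second", {
  # ranks crafted around thresholds: seed at the top, flanks above/below the
  # extension threshold (10th largest value = 0.95, from a distant cluster)
  v <- c(0.90, 0.91, 0.80, 0.96, 0.97, 0.9995, 0.97, 0.94, 0.93,
         seq(0.01, 0.70, length.out = 85), rep(0.95, 6))
  n <- length(v)
  rec <- data.frame(snp_id = sprintf("s%d", 1:n), chrom = 1L,
                    bp = as.integer(1:n * 1000), theta = v,
                    windowed_theta = v)
  # thresholds: top 1% seed = 0.9995; top 10% extension
  sig <- call_signatures(rec, top_call = 0.01, top_extend = 0.10)
  thr_ext <- sort(v, decreasing = TRUE)[10]
  expect_equal(thr_ext, 0.95)
  expect_identical(nrow(sig), 1L)
  # right: 0.97, 0.94 (first below), 0.93 (second below, excluded)
  expect_false(0.94 >= thr_ext)
  expect_identical(sig$end_bp, 8000L)
  # left: 0.97, 0.96, 0.80 (first below), 0.91 (second below, excluded)
  expect_identical(sig$start_bp, 3000L)
  expect_equal(sig$max_windowed_theta, 0.9995)
  expect_identical(sig$max_snp_id, "s6")
})

test_that("nearby seeds merge into a single region deterministically", {
  v <- rep(0.1, 100)
  v[40] <- v[44] <- 1            # two seeds 3 SNPs apart
  v[41:43] <- 0.8                # in between, above extension threshold
  v[c(37:39, 45:47)] <- 0.01     # below: stop immediately on both sides
  rec <- data.frame(snp_id = sprintf("s%d", 1:100), chrom = 1L,
                    bp = as.integer(1:100 * 1000), theta = v,
                    windowed_theta = v)
  sig <- call_signatures(rec, top_call = 0.02, top_extend = 0.10)
  expect_identical(nrow(sig), 1L)
  expect_identical(sig$n_top_snps, 2L)
  # reversed SNP order (relabelled coordinates) calls the mirrored region
  rec_rev <- rec
  rec_rev$theta <- rev(v); rec_rev$windowed_theta <- rev(v)
  sig_rev <- call_signatures(rec_rev, top_call = 0.02, top_extend = 0.10)
  expect_identical(nrow(sig_rev), 1L)
  expect_identical(sig_rev$end_bp - sig_rev$start_bp,
                   sig$end_bp - sig$start_bp)
})

test_that("incidence correlation detects constructed dependence", {
  set.seed(24)
  n <- 200
  theta <- runif(n)
  rec <- data.frame(snp_id = sprintf("s%d", 1:n), theta = theta)
  inc <- data.frame(snp_id = sprintf("s%d", 1:n), chrom = 1L,
                    bp = as.integer(1:n), incidence = theta / 2)
  r1 <- correlate_snp_stat_with_incidence(rec, inc)
  expect_equal(r1$r, 1)
  inc$incidence <- 1 - theta / 2
  expect_lt(correlate_snp_stat_with_incidence(rec, inc)$r, 0)
  inc$incidence <- runif(n)
  expect_lt(abs(correlate_snp_stat_with_incidence(rec, inc)$r), 0.25)
  inc$incidence <- 0.5
  expect_true(is.na(correlate_snp_stat_with_incidence(rec, inc)$r))
})

test_that("pairwise F_ST iterates all breed pairs", {
  set.seed(25)
  pops <- lapply(1:4, function(i) matrix(rbinom(60, 2, runif(1, .2, .8)), 15))
  co <- make_fst_cohort(pops)
  pw <- pairwise_fst(co)
  expect_identical(nrow(pw$mean_fst), 6L)
  expect_identical(length(pw$records), 6L)
  expect_true(all(is.finite(pw$mean_fst$mean_theta)))
})
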