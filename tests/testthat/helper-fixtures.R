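# Small deterministic fixtures built in code at test time.

# 4-individual, 3-SNP cohort over two breeds with one missing call.
toy_cohort <- function() {
  calls <- rbind(c(0L, 1L, 2L),
                 c(1L, 1L, 2L),
                 c(2L, 0L, NA),
                 c(0L, 0L, 2L))
  divscan::new_cohort(
    calls,
    data.frame(id = c("i1", "i2", "i3", "i4"),
               breed = c("B1", "B1", "B2", "B2"),
               stringsAsFactors = FALSE),
    data.frame(snp_id = c("s1", "s2", "s3"), chrom = c(1L, 1L, 2L),
               bp = c(100L, 2000L, 500L), cM = NA_real_,
               stringsAsFactors = FALSE))
}

# Write a hand-rolled PED/MAP pair and return the two paths.
write_toy_pedmap <- function(dir = withr::local_tempdir(),
                             ped_lines = c(
                               "B1 i1 0 0 0 -9 A A A C G G",
                               "B1 i2 0 0 0 -9 A C 0 0 G G"),
                             map_lines = c("1\ts1\t0\t100",
                                           "1\ts2\t0\t2000",
                                           "2\ts3\t0\t500")) {
  ped <- file.path(dir, "toy.ped")
  map <- file.path(dir, "toy.map")
  writeLines(ped_lines, ped)
  writeLines(map_lines, map)
  list(ped = ped, map = map)
}

# Uniform-map single-chromosome cohort with planted genotypes, for ROH
# unit tests: `het_every` = 0 means fully homozygous.
planted_roh_cohort <- function(n_snps = 60, spacing_bp = 50000,
                               het_every = 0) {
  g <- rep(0L, n_snps)
  if (het_every > 0) g[seq(het_every, n_snps, by = het_every)] <- 1L
  bp <- as.integer(seq_len(n_snps) * spacing_bp)
  divscan::new_cohort(
    matrix(g, nrow = 1),
    data.frame(id = "x1", breed = "B", stringsAsFactors = FALSE),
    data.frame(snp_id = sprintf("s%d", seq_len(n_snps)), chrom = 1L,
               bp = bp, cM = bp / 1e6, stringsAsFactors = FALSE))
}
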