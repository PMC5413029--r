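#' Build a regular SNP map
#'
#' Evenly spaced SNPs with a uniform genetic map. The defaults mirror a
#' medium-density ovine array at one-tenth scale: 26 autosomes of 94 Mb
#' covered at one SNP per 500 kb (about 4,900 SNPs over ~2.44 Gb).
#'
#' @param n_chrom number of autosomes.
#' @param chrom_length_mb chromosome length (recycled across chromosomes).
#' @param spacing_kb distance between consecutive SNPs.
#' @param cM_per_Mb constant recombination rate of the genetic map.
#' @return SNP data.frame suitable for [new_cohort()] / [gene_drop()].
#' @export
make_genome_map <- function(n_chrom = 26L, chrom_length_mb = 94,
                            spacing_kb = 500, cM_per_Mb = 1) {
  chrom_length_mb <- rep_len(chrom_length_mb, n_chrom)
  out <- list()
  for (ch in seq_len(n_chrom)) {
    bp <- seq(spacing_kb * 1000 / 2, chrom_length_mb[ch] * 1e6,
              by = spacing_kb * 1000)
    out[[ch]] <- data.frame(
      snp_id = sprintf("snp%d_%d", ch, seq_along(bp)),
      chrom = ch, bp = as.integer(bp), cM = bp / 1e6 * cM_per_Mb,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

default_breed_design <- function() {
  # six breeds at one-tenth the cohort scale, shared drift parameter 0.1
  data.frame(breed = c("Belclare", "Beltex", "Charollais", "Suffolk",
                       "Texel", "Vendeen"),
             n = c(66L, 6L, 67L, 78L, 49L, 63L),
             drift_c = 0.1, stringsAsFactors = FALSE)
}

#' Simulate breed-divergent genotypes (Balding-Nichols model)
#'
#' Per SNP an ancestral frequency p is drawn once (uniform between 0.05
#' and 0.95); each breed's frequency is drawn from
#' `Beta(p (1-c)/c, (1-p)(1-c)/c)` with its drift parameter c, and
#' genotypes are Binomial(2, breed frequency). Under this model the
#' expected Weir-Cockerham theta approximates c, which makes the simulator
#' an oracle for F_ST recovery.
#'
#' @param breeds data.frame `breed, n, drift_c` (defaults to a six-breed
#'   design at one-tenth cohort scale).
#' @param map SNP map data.frame (default [make_genome_map()]).
#' @param ancestral_range range of the uniform ancestral frequency draw.
#' @param seed optional RNG seed for reproducibility.
#' @return A cohort; the truth is attached as attributes `ancestral_p`
#'   (per SNP) and `drift_c` (named per breed).
#' @export
simulate_balding_nichols <- function(breeds = default_breed_design(),
                                     map = make_genome_map(),
                                     ancestral_range = c(0.05, 0.95),
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nrow(breeds) >= 2)
  if (any(breeds$drift_c <= 0 | breeds$drift_c >= 1))
    stop("drift_c must lie in (0, 1)")
  m <- nrow(map)
  p <- stats::runif(m, ancestral_range[1], ancestral_range[2])
  calls <- list(); ind <- list()
  for (k in seq_len(nrow(breeds))) {
    c_k <- breeds$drift_c[k]
    shape <- (1 - c_k) / c_k
    pk <- stats::rbeta(m, p * shape, (1 - p) * shape)
    g <- matrix(stats::rbinom(breeds$n[k] * m, 2, rep(pk, each = breeds$n[k])),
                nrow = breeds$n[k])
    calls[[k]] <- g
    ind[[k]] <- data.frame(
      id = sprintf("%s_%d", breeds$breed[k], seq_len(breeds$n[k])),
      breed = breeds$breed[k], stringsAsFactors = FALSE)
  }
  cohort <- new_cohort(do.call(rbind, calls), do.call(rbind, ind), map)
  attr(cohort, "ancestral_p") <- p
  attr(cohort, "drift_c") <- stats::setNames(breeds$drift_c, breeds$breed)
  cohort
}

#' Simulate a pedigree with known expected inbreeding
#'
#' Three designs: `"random"` (each generation's offspring draw two distinct
#' parents at random from the previous generation), `"full_sib_loop"`
#' (repeated full-sib matings: the first loop's offspring have F = 0.25
#' exactly, later loops increase F), and `"half_sib_loop"` (a sire line
#' mated to fresh founder dams; half-sib offspring F = 0.125 at the first
#' loop).
#'
#' @param founders number of founder animals (>= 2).
#' @param generations generations (loops) to simulate.
#' @param mating mating rule.
#' @param offspring_per_generation offspring per generation for `"random"`.
#' @param breed breed label written on every animal.
#' @param seed optional RNG seed (only `"random"` uses randomness).
#' @return A `pedigree_table`.
#' @export
simulate_pedigree <- function(founders = 10L, generations = 3L,
                              mating = c("random", "full_sib_loop",
                                         "half_sib_loop"),
                              offspring_per_generation = founders,
                              breed = "sim", seed = NULL) {
  mating <- match.arg(mating)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(founders >= 2, generations >= 1)
  rows <- data.frame(id = sprintf("F0_%d", seq_len(founders)),
                     sire = NA_character_, dam = NA_character_,
                     breed = breed, stringsAsFactors = FALSE)
  if (mating == "random") {
    prev <- rows$id
    for (g in seq_len(generations)) {
      ids <- sprintf("G%d_%d", g, seq_len(offspring_per_generation))
      par <- t(vapply(ids, function(i) sample(prev, 2), character(2)))
      rows <- rbind(rows, data.frame(id = ids, sire = par[, 1],
                                     dam = par[, 2], breed = breed,
                                     stringsAsFactors = FALSE))
      prev <- ids
    }
  } else if (mating == "full_sib_loop") {
    pair <- rows$id[1:2]
    for (g in seq_len(generations)) {
      ids <- sprintf("G%d_%d", g, 1:2)
      rows <- rbind(rows, data.frame(id = ids, sire = pair[1], dam = pair[2],
                                     breed = breed, stringsAsFactors = FALSE))
      pair <- ids
    }
  } else {
    sire <- rows$id[1]
    dam_pool <- rows$id[-1]
    for (g in seq_len(generations)) {
      dams <- sprintf("D%d_%d", g, 1:2)
      rows <- rbind(rows, data.frame(id = dams, sire = NA_character_,
                                     dam = NA_character_, breed = breed,
                                     stringsAsFactors = FALSE))
      halfs <- sprintf("H%d_%d", g, 1:2)
      rows <- rbind(rows, data.frame(id = halfs, sire = sire, dam = dams,
                                     breed = breed, stringsAsFactors = FALSE))
      ids <- sprintf("G%d_1", g)
      rows <- rbind(rows, data.frame(id = ids, sire = halfs[1],
                                     dam = halfs[2], breed = breed,
                                     stringsAsFactors = FALSE))
      sire <- ids
    }
  }
  as_pedigree(rows)
}

# one meiosis on one chromosome: recombine the parent's two per-SNP vectors
meiosis <- function(h1, h2, cm_pos, len_cm) {
  k <- stats::rpois(1, len_cm / 100)
  phase <- stats::rbinom(1, 1, 0.5)
  if (k == 0) return(if (phase) h2 else h1)
  xo <- sort(stats::runif(k, 0, len_cm))
  idx <- (phase + findInterval(cm_pos, xo)) %% 2
  ifelse(idx == 0, h1, h2)
}

#' Gene-drop simulation with identity-by-descent ground truth
#'
#' Founders receive two haplotypes labelled by founder-allele origin;
#' every meiosis recombines with a Poisson(map length in Morgans)
#' crossover count at uniform map positions (no interference). Descendant
#' genotypes are emitted at the SNP positions, and autozygous segments --
#' maximal marker runs where both haplotypes carry the same founder label
#' -- are recorded per individual as truth for ROH validation. Mutation is
#' deliberately omitted so labels define IBD exactly.
#'
#' @param pedigree a `pedigree_table`.
#' @param map SNP map data.frame with `snp_id, chrom, bp, cM`.
#' @param founder_freqs per-SNP counted-allele frequency for founder
#'   haplotypes (single value recycled, or vector of length `nrow(map)`).
#' @param seed optional RNG seed.
#' @return list with `cohort` (pedigree attached) and `true_ibd`
#'   (data.frame `individual_id, chrom, start_bp, end_bp, n_snps,
#'   autozygous`), plus `true_f` (named per-individual autozygous marker
#'   fraction).
#' @export
gene_drop <- function(pedigree, map, founder_freqs = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ped <- as_pedigree(pedigree)
  stopifnot(all(!is.na(map$cM)))
  m <- nrow(map)
  freqs <- rep_len(founder_freqs, m)
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  founder <- is.na(si) & is.na(di)
  # per-SNP founder-haplotype labels, per individual x {1,2}
  labA <- labB <- matrix(NA_integer_, n, m)
  nfh <- 0L
  chroms <- unique(map$chrom)
  chrom_idx <- lapply(chroms, function(ch) which(map$chrom == ch))
  cm_list <- lapply(chrom_idx, function(j) map$cM[j])
  len_list <- vapply(cm_list, function(x) diff(range(x)), numeric(1))
  for (i in seq_len(n)) {
    if (founder[i]) {
      labA[i, ] <- nfh + 1L
      labB[i, ] <- nfh + 2L
      nfh <- nfh + 2L
    } else {
      for (kk in seq_along(chroms)) {
        j <- chrom_idx[[kk]]
        cmp <- cm_list[[kk]] - min(cm_list[[kk]])
        s <- si[i]; d <- di[i]
        labA[i, j] <- if (is.na(s)) { nfh <- nfh + 1L; nfh } else
          meiosis(labA[s, j], labB[s, j], cmp, len_list[kk])
        labB[i, j] <- if (is.na(d)) { nfh <- nfh + 1L; nfh } else
          meiosis(labA[d, j], labB[d, j], cmp, len_list[kk])
      }
    }
  }
  # unknown single parents above may have allocated one label per chromosome;
  # founder haplotype alleles are drawn per label on demand
  labels <- sort(unique(c(labA, labB)))
  hap_alleles <- matrix(NA_integer_, max(labels), m)
  for (lb in labels)
    hap_alleles[lb, ] <- stats::rbinom(m, 1, freqs)
  calls <- matrix(NA_integer_, n, m)
  for (i in seq_len(n))
    calls[i, ] <- hap_alleles[cbind(labA[i, ], seq_len(m))] +
      hap_alleles[cbind(labB[i, ], seq_len(m))]
  individuals <- data.frame(id = ped$id, breed = ped$breed,
                            stringsAsFactors = FALSE)
  cohort <- new_cohort(calls, individuals, map, pedigree = ped)

  truth <- list()
  for (i in seq_len(n)) {
    auto <- labA[i, ] == labB[i, ]
    for (kk in seq_along(chroms)) {
      j <- chrom_idx[[kk]]
      r <- rle(auto[j])
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      truth[[length(truth) + 1L]] <- data.frame(
        individual_id = ped$id[i], chrom = chroms[kk],
        start_bp = map$bp[j][starts], end_bp = map$bp[j][ends],
        n_snps = r$lengths, autozygous = r$values,
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  true_f <- stats::setNames(rowMeans(labA == labB), ped$id)
  list(cohort = cohort, true_ibd = truth, true_f = true_f)
}

#' Forward Wright-Fisher simulation
#'
#' Simulates 2N haplotypes on one linear chromosome for a fixed number of
#' discrete generations (Poisson recombination, optional symmetric
#' mutation; compiled core), then samples individuals from the final
#' generation. The constant N is the ground truth for
#' [ne_trajectory()] recovery.
#'
#' @param N constant diploid population size (>= 20).
#' @param generations generations to simulate.
#' @param n_snps SNPs on the chromosome.
#' @param chromosome_morgans genetic map length of the chromosome.
#' @param chromosome_length_bp physical length; defaults to 1 cM/Mb
#'   (1 Morgan spans 100 Mb) but can be set independently, e.g. to give a
#'   zero-recombination chromosome real physical coordinates.
#' @param mutation_rate per-site per-generation symmetric flip rate.
#' @param n_sample diploid individuals sampled from the final generation
#'   (default: all N).
#' @param breed breed label on the sampled cohort.
#' @param seed optional RNG seed.
#' @return A cohort with attribute `true_N`.
#' @export
simulate_wright_fisher <- function(N, generations, n_snps = 2000L,
                                   chromosome_morgans = 1,
                                   chromosome_length_bp = NULL,
                                   mutation_rate = 0, n_sample = NULL,
                                   breed = "WF", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(N >= 20)
  if (is.null(chromosome_length_bp))
    chromosome_length_bp <- round(chromosome_morgans * 1e8)
  stopifnot(chromosome_length_bp >= 2 * n_snps)
  haps <- wf_sim_cpp(as.integer(N), as.integer(generations),
                     as.integer(n_snps), chromosome_morgans, mutation_rate)
  if (is.null(n_sample)) n_sample <- N
  pick <- sort(sample.int(N, n_sample))
  calls <- haps[2 * pick - 1L, , drop = FALSE] + haps[2 * pick, , drop = FALSE]
  frac <- (seq_len(n_snps) - 0.5) / n_snps
  bp <- as.integer(round(chromosome_length_bp * frac))
  map <- data.frame(snp_id = sprintf("wf_%d", seq_len(n_snps)), chrom = 1L,
                    bp = bp, cM = chromosome_morgans * 100 * frac,
                    stringsAsFactors = FALSE)
  cohort <- new_cohort(calls,
                       data.frame(id = sprintf("%s_%d", breed, pick),
                                  breed = breed, stringsAsFactors = FALSE),
                       map)
  attr(cohort, "true_N") <- N
  cohort
}

#' Inject a selective-sweep signal
#'
#' In the target breeds, genotypes at SNPs inside the region are resampled
#' as Binomial(2, `final_freq`) for the counted allele, driving the region
#' toward fixation there while leaving other breeds untouched. A positive
#' control for F_ST signature calling and ROH hotspot detection.
#'
#' @param cohort a cohort.
#' @param chrom,start_bp,end_bp sweep region (closed interval).
#' @param target_breeds breed labels carrying the sweep.
#' @param final_freq near-fixed counted-allele frequency.
#' @param seed optional RNG seed.
#' @return The modified cohort.
#' @export
inject_sweep <- function(cohort, chrom, start_bp, end_bp, target_breeds,
                         final_freq = 0.98, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  j <- which(cohort$snps$chrom == chrom & cohort$snps$bp >= start_bp &
               cohort$snps$bp <= end_bp)
  if (length(j) < 1) stop("sweep region contains no SNPs")
  rows <- which(cohort$individuals$breed %in% target_breeds)
  g <- matrix(stats::rbinom(length(rows) * length(j), 2, final_freq),
              nrow = length(rows))
  cohort$calls[rows, j] <- g
  cohort
}
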