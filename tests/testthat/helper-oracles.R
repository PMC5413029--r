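# Independent oracles used to cross-check the package implementations.
# Each deliberately takes a different computational route from the code
# under test.

# HWE exact test by direct enumeration: probability of every feasible
# heterozygote count from log-factorials, no recurrence.
hwe_enum_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  hs <- seq(min(nA, 2 * n - nA) %% 2, min(nA, 2 * n - nA), by = 2)
  logp <- vapply(hs, function(h) {
    nrr <- (nA - h) / 2
    if (nA > 2 * n - nA) nrr <- (2 * n - nA - h) / 2
    ncc <- n - nrr - h
    lgamma(n + 1) - lgamma(nrr + 1) - lgamma(h + 1) - lgamma(ncc + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(2 * n - nA + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp)
  obs <- p[match(nAa, hs)]
  min(1, sum(p[p <= obs * (1 + 1e-10)]))
}

# Weir & Cockerham (1984) variance components, scalar per-population
# arithmetic on a list of genotype vectors for a single SNP.
wc_oracle <- function(pops) {
  pops <- lapply(pops, function(g) g[!is.na(g)])
  pops <- pops[vapply(pops, length, 1L) > 0]
  r <- length(pops)
  n <- vapply(pops, length, numeric(1))
  p <- vapply(pops, function(g) sum(g) / (2 * length(g)), numeric(1))
  h <- vapply(pops, function(g) mean(g == 1), numeric(1))
  nbar <- sum(n) / r
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# Pedigree inbreeding via the tabular relationship-matrix recursion
# (builds the full A matrix; F = diag(A) - 1). Independent of the
# per-animal L/D accumulation used by the package.
tabular_f_oracle <- function(ped) {
  ped <- divscan::as_pedigree(ped)
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    for (j in seq_len(i - 1)) {
      A[i, j] <- A[j, i] <-
        0.5 * ((if (is.na(s)) 0 else A[j, s]) +
                 (if (is.na(d)) 0 else A[j, d]))
    }
    A[i, i] <- 1 + (if (is.na(s) || is.na(d)) 0 else 0.5 * A[s, d])
  }
  stats::setNames(diag(A) - 1, ped$id)
}

# CGE by explicit breadth-first ancestor traversal.
cge_traversal_oracle <- function(ped) {
  ped <- divscan::as_pedigree(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  one <- function(i) {
    total <- 0
    frontier <- c(si[i], di[i])
    g <- 1
    while (length(frontier <- frontier[!is.na(frontier)])) {
      total <- total + length(frontier) * 0.5^g
      frontier <- c(si[frontier], di[frontier])
      g <- g + 1
    }
    total
  }
  stats::setNames(vapply(seq_len(nrow(ped)), one, numeric(1)), ped$id)
}

# Random acyclic pedigree: each animal draws each parent (possibly
# unknown) from the earlier animals.
random_pedigree <- function(n, p_known = 0.7) {
  id <- sprintf("a%d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i >= 3) {
      if (stats::runif(1) < p_known) sire[i] <- id[sample.int(i - 1, 1)]
      if (stats::runif(1) < p_known) dam[i] <- id[sample.int(i - 1, 1)]
    }
  }
  data.frame(id = id, sire = sire, dam = dam, breed = "sim",
             stringsAsFactors = FALSE)
}
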