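#' Read a PED/MAP text fileset
#'
#' Reads PLINK-1.9-dialect text genotypes. Alleles are recoded to dosages of
#' the cohort-wide minor allele (counted allele), frozen thereafter: F_ST and
#' r-squared are invariant to allele labelling, and freezing the counted
#' allele at read time prevents per-breed relabelling inconsistencies.
#' `0 0` allele pairs become missing. A MAP cM column that is zero everywhere
#' is treated as "no genetic map" and left absent.
#'
#' @param ped_path path to the PED file (6 metadata columns, then two allele
#'   columns per SNP). Column 1 (family ID) is used as the breed label.
#' @param map_path path to the 4-column MAP file (chrom, snp_id, cM, bp).
#' @param n_autosomes autosome count of the karyotype (26 for sheep).
#' @return A [new_cohort()] object. The SNP table carries `allele_counted`
#'   and `allele_other` columns so writers can round-trip allele symbols.
#' @export
read_plink_text <- function(ped_path, map_path, n_autosomes = 26L) {
  stopifnot(file.exists(ped_path), file.exists(map_path))
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  if (ncol(map) != 4) stop("MAP file must have 4 columns")
  names(map) <- c("chrom", "snp_id", "cM", "bp")
  m <- nrow(map)

  ped <- utils::read.table(ped_path, header = FALSE, colClasses = "character")
  if (nrow(ped) > 0 && ncol(ped) != 6 + 2 * m)
    stop(sprintf("PED row length %d does not match 6 + 2 x %d MAP SNPs",
                 ncol(ped), m))
  n <- nrow(ped)
  individuals <- data.frame(
    id = if (n) ped[[2]] else character(),
    breed = if (n) ped[[1]] else character(),
    stringsAsFactors = FALSE)

  calls <- matrix(NA_integer_, n, m)
  counted <- other <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    a1 <- ped[[6 + 2 * j - 1]]
    a2 <- ped[[6 + 2 * j]]
    miss <- a1 == "0" | a2 == "0"
    obs <- c(a1[!miss], a2[!miss])
    alleles <- sort(unique(obs))
    if (length(alleles) > 2)
      stop(sprintf("SNP %s is not biallelic (%d alleles observed)",
                   map$snp_id[j], length(alleles)))
    if (length(alleles) == 0) next            # all missing: dosage stays NA
    if (length(alleles) == 1) {
      other[j] <- alleles[1]                  # minor allele unobserved
      calls[!miss, j] <- 0L
    } else {
      cnt <- c(sum(obs == alleles[1]), sum(obs == alleles[2]))
      # counted allele = minor; on a tie the lexicographically smaller one
      k <- if (cnt[1] <= cnt[2]) 1L else 2L
      counted[j] <- alleles[k]
      other[j] <- alleles[3L - k]
      calls[, j] <- (a1 == counted[j]) + (a2 == counted[j])
      calls[miss, j] <- NA_integer_
    }
  }
  snps <- data.frame(snp_id = map$snp_id, chrom = suppressWarnings(as.integer(map$chrom)),
                     bp = map$bp,
                     cM = if (all(map$cM == 0)) NA_real_ else map$cM,
                     allele_counted = counted, allele_other = other,
                     stringsAsFactors = FALSE)
  snps$chrom[is.na(snps$chrom)] <- 0L         # non-numeric labels -> non-autosomal
  new_cohort(calls, individuals, snps, n_autosomes = n_autosomes)
}

allele_symbols <- function(cohort) {
  a1 <- cohort$snps$allele_counted
  a2 <- cohort$snps$allele_other
  if (is.null(a1)) a1 <- rep(NA_character_, ncol(cohort$calls))
  if (is.null(a2)) a2 <- rep(NA_character_, ncol(cohort$calls))
  a1[is.na(a1)] <- "A"
  a2[is.na(a2)] <- "B"
  list(a1 = a1, a2 = a2)
}

#' Write a cohort as PED/MAP text
#'
#' Mirrors [read_plink_text()] bit-exactly for the fields the cohort model
#' carries (breed as family ID, dosages, map positions). Sex and phenotype
#' columns are written as 0/-9 placeholders.
#'
#' @param cohort a cohort.
#' @param ped_path,map_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_plink_text <- function(cohort, ped_path, map_path) {
  s <- cohort$snps
  cm <- ifelse(is.na(s$cM), 0, s$cM)
  utils::write.table(
    data.frame(s$chrom, s$snp_id, cm, s$bp),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  al <- allele_symbols(cohort)
  n <- nrow(cohort$calls)
  lines <- character(n)
  for (i in seq_len(n)) {
    g <- cohort$calls[i, ]
    a <- ifelse(is.na(g), "0", ifelse(g >= 1, al$a1, al$a2))
    b <- ifelse(is.na(g), "0", ifelse(g == 2, al$a1, al$a2))
    lines[i] <- paste(c(cohort$individuals$breed[i], cohort$individuals$id[i],
                        "0", "0", "0", "-9", rbind(a, b)), collapse = " ")
  }
  writeLines(lines, ped_path)
  invisible(c(ped_path, map_path))
}

#' Read PLINK binary BED/BIM/FAM genotypes
#'
#' SNP-major 2-bit codec. The BIM A1 allele is taken as the counted allele,
#' so a binary file written by [write_plink_binary()] reads back to an
#' identical calls matrix.
#'
#' @param bed_path,bim_path,fam_path the three file paths.
#' @param n_autosomes autosome count of the karyotype.
#' @return A [new_cohort()] object.
#' @export
read_plink_binary <- function(bed_path, bim_path, fam_path, n_autosomes = 26L) {
  stopifnot(file.exists(bed_path), file.exists(bim_path), file.exists(fam_path))
  bim <- utils::read.table(bim_path, header = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  names(bim) <- c("chrom", "snp_id", "cM", "bp", "a1", "a2")
  fam <- tryCatch(utils::read.table(fam_path, header = FALSE,
                                    colClasses = "character"),
                  error = function(e) data.frame())
  n <- nrow(fam); m <- nrow(bim)

  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK BED file (bad magic bytes)")
  if (raw[3] != as.raw(0x01))
    stop("BED file is not in SNP-major mode")
  bytes_per_snp <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bytes_per_snp * m)
    stop("BED payload size does not match BIM/FAM dimensions")

  # 2-bit codes per individual: 00 -> 2 copies of A1, 10 -> 1, 11 -> 0, 01 -> NA
  lut <- c(2L, NA_integer_, 1L, 0L)
  calls <- matrix(NA_integer_, n, m)
  if (n > 0 && m > 0) {
    ints <- as.integer(body)
    dim(ints) <- c(bytes_per_snp, m)
    for (shift in 0:3) {
      codes <- (ints %/% 4L^shift) %% 4L
      idx <- shift + 1L + 4L * (seq_len(bytes_per_snp) - 1L)
      keep <- idx <= n
      if (any(keep)) calls[idx[keep], ] <- lut[codes[keep, , drop = FALSE] + 1L]
    }
  }
  individuals <- data.frame(id = if (n) fam[[2]] else character(),
                            breed = if (n) fam[[1]] else character(),
                            stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = bim$snp_id,
                     chrom = suppressWarnings(as.integer(bim$chrom)),
                     bp = bim$bp,
                     cM = if (m == 0 || all(bim$cM == 0)) NA_real_ else bim$cM,
                     allele_counted = ifelse(bim$a1 == "0", NA, bim$a1),
                     allele_other = ifelse(bim$a2 == "0", NA, bim$a2),
                     stringsAsFactors = FALSE)
  snps$chrom[is.na(snps$chrom)] <- 0L
  new_cohort(calls, individuals, snps, n_autosomes = n_autosomes)
}

#' Write a cohort as PLINK binary BED/BIM/FAM
#'
#' @param cohort a cohort.
#' @param bed_path,bim_path,fam_path output paths.
#' @return Invisibly, the three paths.
#' @export
write_plink_binary <- function(cohort, bed_path, bim_path, fam_path) {
  s <- cohort$snps
  al <- allele_symbols(cohort)
  cm <- ifelse(is.na(s$cM), 0, s$cM)
  utils::write.table(data.frame(s$chrom, s$snp_id, cm, s$bp, al$a1, al$a2),
                     bim_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ind <- cohort$individuals
  z <- rep(0L, nrow(ind))
  utils::write.table(data.frame(ind$breed, ind$id, z, z, z, z - 9L),
                     fam_path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  n <- nrow(cohort$calls); m <- ncol(cohort$calls)
  bytes_per_snp <- ceiling(n / 4)
  code <- matrix(1L, 4 * bytes_per_snp, max(m, 0))   # pad bits use the NA code
  if (n > 0 && m > 0) {
    enc <- c(3L, 2L, 0L)[cohort$calls + 1L]          # dosage 0/1/2 -> code
    enc[is.na(enc)] <- 1L
    code[seq_len(n), ] <- enc
  }
  if (m > 0 && bytes_per_snp > 0) {
    w <- 4L^(0:3)
    dim(code) <- c(4, bytes_per_snp * m)
    bytes <- as.raw(colSums(code * w))
  } else bytes <- raw(0)
  con <- file(bed_path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(bytes, con)
  invisible(c(bed_path, bim_path, fam_path))
}

#' Attach genetic positions from a linkage map
#'
#' SNPs present in the map get their exact cM; SNPs between mapped anchors
#' get cM by linear interpolation on physical position; SNPs outside the
#' mapped span get the terminal anchor cM (constant extrapolation).
#' Chromosomes with fewer than two mapped SNPs are left without genetic
#' positions, with a warning.
#'
#' @param cohort a cohort.
#' @param linkage_map data.frame with columns `snp_id`, `chrom`, `cM`.
#' @return The cohort with its `snps$cM` column filled in.
#' @export
attach_linkage_map <- function(cohort, linkage_map) {
  lm <- as.data.frame(linkage_map, stringsAsFactors = FALSE)
  stopifnot(all(c("snp_id", "chrom", "cM") %in% names(lm)))
  snps <- cohort$snps
  cM <- rep(NA_real_, nrow(snps))
  for (ch in unique(snps$chrom)) {
    idx <- which(snps$chrom == ch)
    hit <- match(snps$snp_id[idx], lm$snp_id)
    anchored <- !is.na(hit)
    if (sum(anchored) < 2) {
      warning(sprintf("chromosome %s has <2 mapped SNPs; cM left absent", ch))
      next
    }
    ax <- snps$bp[idx][anchored]
    ay <- lm$cM[hit[anchored]]
    cM[idx] <- stats::approx(ax, ay, xout = snps$bp[idx], rule = 2,
                             ties = "ordered")$y
    cM[idx][anchored] <- ay                      # exact where mapped
  }
  cohort$snps$cM <- cM
  cohort
}

#' Read and validate a pedigree table
#'
#' Expects delimited text (comma or whitespace) with a header naming columns
#' `id`, `sire`, `dam`, `breed`. Unknown parents (`0`, `NA`, `.`, empty) are
#' normalised to `NA`. The returned table is topologically ordered (parents
#' before offspring); a parentage cycle is an error.
#'
#' @param path file path.
#' @return data.frame of class `pedigree_table` with columns
#'   `id, sire, dam, breed`.
#' @export
read_pedigree <- function(path) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character",
                          stringsAsFactors = FALSE, strip.white = TRUE)
  names(df) <- tolower(names(df))
  stopifnot(all(c("id", "sire", "dam") %in% names(df)))
  if (is.null(df$breed)) df$breed <- "unknown"
  as_pedigree(df[, c("id", "sire", "dam", "breed")])
}

#' Validate and topologically order a pedigree data.frame
#'
#' @param df data.frame with columns `id`, `sire`, `dam` and optionally
#'   `breed`.
#' @return data.frame of class `pedigree_table`, parents before offspring.
#' @export
as_pedigree <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(df$breed)) df$breed <- "unknown"
  for (col in c("id", "sire", "dam")) {
    v <- as.character(df[[col]])
    v[v %in% c("0", "", ".", "NA")] <- NA
    df[[col]] <- v
  }
  if (anyDuplicated(df$id)) stop("duplicate individual ids in pedigree")
  # parents that never appear as rows are treated as founders of unknown origin
  for (col in c("sire", "dam"))
    df[[col]][!is.na(df[[col]]) & !(df[[col]] %in% df$id)] <- NA

  n <- nrow(df)
  idx <- function(v) match(v, df$id)
  si <- idx(df$sire); di <- idx(df$dam)
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) for (p in c(si[i], di[i])) if (!is.na(p)) {
    indeg[i] <- indeg[i] + 1L
    children[[p]] <- c(children[[p]], i)
  }
  order <- integer(0)
  queue <- which(indeg == 0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    left <- setdiff(seq_len(n), order)
    # walk parent links inside the leftover set until a repeat: that's a cycle
    cur <- left[1]; seen <- integer(0)
    while (!(cur %in% seen)) {
      seen <- c(seen, cur)
      nxt <- c(si[cur], di[cur])
      cur <- nxt[!is.na(nxt) & nxt %in% left][1]
    }
    cyc <- df$id[seen[which(seen == cur):length(seen)]]
    stop(sprintf("pedigree contains a cycle: %s",
                 paste(c(cyc, cyc[1]), collapse = " -> ")))
  }
  out <- df[order, c("id", "sire", "dam", "breed")]
  rownames(out) <- NULL
  class(out) <- c("pedigree_table", "data.frame")
  out
}
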