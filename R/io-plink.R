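#' Read genotypes from PLINK bed/bim/fam
#'
#' Reads the binary PLINK 1 format (SNP-major, magic bytes 0x6c 0x1b 0x01).
#' The counted allele (`allele_b`) is the bim A2 allele, so a hom-A2 call is
#' dosage 2 and the 01 bit pattern maps to `NA`.
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim`, `.fam` must exist.
#' @return A [genotype_matrix()]. Population is taken from the fam family id
#'   column.
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (p in paths) if (!file.exists(p)) stop("missing file: ", p)
  if (file.size(paths[2]) > 0) {
    bim <- utils::read.table(paths[2], header = FALSE, sep = "\t",
                             colClasses = c("character", "character", "numeric",
                                            "integer", "character", "character"))
  } else {
    bim <- data.frame(V1 = character(), V2 = character(), V3 = numeric(),
                      V4 = integer(), V5 = character(), V6 = character())
  }
  names(bim) <- c("chrom", "snp_id", "cm", "pos", "a1", "a2")
  if (file.size(paths[3]) > 0) {
    fam <- utils::read.table(paths[3], header = FALSE, sep = "\t",
                             colClasses = "character")
  } else {
    fam <- data.frame(V1 = character(), V2 = character(), V3 = character(),
                      V4 = character(), V5 = character(), V6 = character())
  }
  names(fam) <- c("fid", "iid", "pat", "mat", "sex", "pheno")[seq_len(ncol(fam))]
  n <- nrow(fam)
  m <- nrow(bim)
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(paths[1], "raw", n = 3 + m * bytes_per_snp)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK bed file (bad magic bytes): ", paths[1])
  }
  if (raw[3] != as.raw(0x01)) {
    stop("only SNP-major bed files are supported: ", paths[1])
  }
  body <- raw[-(1:3)]
  if (length(body) != m * bytes_per_snp) {
    stop("bed file size inconsistent with bim/fam dimensions: ", paths[1])
  }
  # unpack 2-bit codes: per byte, samples are in the low bits first
  codes <- matrix(0L, nrow = 4 * bytes_per_snp, ncol = max(m, 1))
  if (m > 0 && n > 0) {
    bmat <- matrix(as.integer(body), nrow = bytes_per_snp, ncol = m)
    for (k in 0:3) {
      codes[seq_len(bytes_per_snp) * 4 - 3 + k, ] <- bmat %/% (4L^k) %% 4L
    }
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  # 00 = hom A1 -> dosage 0; 10 (=2) het -> 1; 11 (=3) hom A2 -> 2;
  # 01 (=1) missing
  map <- c(0L, NA_integer_, 1L, 2L)
  calls <- matrix(map[codes + 1L], nrow = n, ncol = m)
  snps <- data.frame(snp_id = bim$snp_id, chrom = bim$chrom, pos = bim$pos,
                     allele_a = bim$a1, allele_b = bim$a2,
                     stringsAsFactors = FALSE)
  sex <- if (!is.null(fam$sex)) fam$sex else NA_character_
  samples <- data.frame(sample_id = fam$iid, population = fam$fid,
                        sex = sex, stringsAsFactors = FALSE)
  genotype_matrix(calls, snps, samples)
}

#' Write genotypes to PLINK bed/bim/fam
#'
#' @param g a [genotype_matrix()].
#' @param prefix output path prefix.
#' @return Invisibly, the three file paths written.
#' @export
write_plink <- function(g, prefix) {
  n <- n_samples(g)
  m <- n_snps(g)
  bim <- data.frame(g$snps$chrom, g$snps$snp_id, 0, g$snps$pos,
                    g$snps$allele_a, g$snps$allele_b)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  pop <- g$samples$population
  pop[is.na(pop)] <- "0"
  sex <- g$samples$sex
  sex[is.na(sex)] <- "0"
  fam <- data.frame(pop, g$samples$sample_id, rep(0, n), rep(0, n), sex,
                    rep(-9, n))
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bytes_per_snp <- ceiling(n / 4)
  # dosage -> 2-bit code (00 hom A1, 10 het, 11 hom A2, 01 missing)
  code <- matrix(1L, nrow = 4 * bytes_per_snp, ncol = max(m, 1))
  if (n > 0 && m > 0) {
    cmap <- c(0L, 2L, 3L)
    cc <- g$calls
    v <- cmap[cc + 1L]
    v[is.na(cc)] <- 1L
    code[seq_len(n), ] <- v
    code[seq_len(4 * bytes_per_snp) > n, ] <- 0L  # pad bits are zero
  } else {
    code[] <- 0L
  }
  body <- raw(0)
  if (m > 0) {
    idx <- seq_len(bytes_per_snp) * 4
    bmat <- code[idx - 3, , drop = FALSE] +
      4L * code[idx - 2, , drop = FALSE] +
      16L * code[idx - 1, , drop = FALSE] +
      64L * code[idx, , drop = FALSE]
    body <- as.raw(bmat)
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  if (length(body)) writeBin(body, con)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}
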