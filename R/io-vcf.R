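#' Read genotypes from a VCF file
#'
#' Parses a VCF (4.x) with GT fields via \pkg{vcfR}. Only biallelic SNP
#' records are accepted; multiallelic records raise an error naming the
#' offending site. The counted allele (`allele_b`) is the ALT allele, so the
#' dosage is the ALT allele count. Phase separators are ignored.
#'
#' @param path path to a `.vcf` (optionally bgzipped) file.
#' @return A [genotype_matrix()]; sample metadata holds ids only.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) fixm <- t(fixm)   # single-record VCF
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no variant records: ", path)
  multi <- grepl(",", fix$ALT) | nchar(fix$REF) != 1 | nchar(fix$ALT) != 1
  if (any(multi)) {
    stop("multiallelic or non-SNP record at ",
         fix$CHROM[which(multi)[1]], ":", fix$POS[which(multi)[1]])
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  al1 <- substr(gt, 1, 1)
  al3 <- substr(gt, 3, 3)
  dose <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  known <- al1 %in% c("0", "1") & al3 %in% c("0", "1")
  odd <- !known & !(al1 == "." | is.na(gt))
  if (any(odd)) stop("unknown genotype code '", gt[which(odd)[1]], "' in ", path)
  dose[known] <- (al1 == "1")[known] + (al3 == "1")[known]
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  snps <- data.frame(snp_id = ids, chrom = fix$CHROM,
                     pos = as.integer(fix$POS),
                     allele_a = fix$REF, allele_b = fix$ALT,
                     stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = colnames(gt), stringsAsFactors = FALSE)
  genotype_matrix(t(dose), snps, samples)
}

#' Write genotypes to a VCF file
#'
#' Emits a minimal VCF 4.2 with a single GT FORMAT field; REF is `allele_a`,
#' ALT is `allele_b`, and genotypes are unphased.
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(g, path) {
  n <- n_samples(g)
  m <- n_snps(g)
  gt_code <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples$sample_id), collapse = "\t")
  )
  lines <- character(m)
  if (m > 0) {
    gmat <- matrix("./.", nrow = n, ncol = m)
    ok <- !is.na(g$calls)
    gmat[ok] <- gt_code[g$calls[ok] + 1L]
    body <- if (n > 0) apply(gmat, 2, paste, collapse = "\t") else rep("", m)
    lines <- paste(g$snps$chrom, g$snps$pos, g$snps$snp_id,
                   g$snps$allele_a, g$snps$allele_b, ".", ".", ".", "GT",
                   body, sep = "\t")
    if (n == 0) lines <- sub("\tGT\t$", "\tGT", lines)
  }
  writeLines(c(header, lines), path)
  invisible(path)
}
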