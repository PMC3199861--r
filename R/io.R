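#' Load or save cohort genotypes in a standard format
#'
#' Thin dispatchers over [read_plink()]/[write_plink()] and
#' [read_vcf()]/[write_vcf()]. `path` is a bed/bim/fam prefix for
#' `format = "plink-bed"` and a file path for `format = "vcf"`.
#'
#' @param path file path or PLINK prefix.
#' @param format `"plink-bed"` or `"vcf"`.
#' @return `load_genotypes()` returns a [genotype_matrix()];
#'   `save_genotypes()` returns the written path(s) invisibly.
#' @export
load_genotypes <- function(path, format = c("plink-bed", "vcf")) {
  format <- match.arg(format)
  switch(format, "plink-bed" = read_plink(path), "vcf" = read_vcf(path))
}

#' @rdname load_genotypes
#' @param g a [genotype_matrix()].
#' @export
save_genotypes <- function(g, path, format = c("plink-bed", "vcf")) {
  format <- match.arg(format)
  switch(format, "plink-bed" = write_plink(g, path), "vcf" = write_vcf(g, path))
}
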