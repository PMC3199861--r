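#!/usr/bin/env Rscript
# Stage 2: SNP quality control — combined call rate, stratified HWE,
# between-platform allele-frequency test; the union of failures is removed.

source("analysis/00_config.R")

g <- read_plink(DATA_PREFIX)
meta <- read.delim(file.path(RESULTS, "data", "samples.tsv"))
g$samples$platform <- meta$platform[match(g$samples$sample_id,
                                          meta$sample_id)]
out <- apply_qc(g, qc_thresholds(), platform_within = "isolate")
rep_ <- out$report

message(sprintf(paste0("QC: %d SNPs in; failures: call rate %d, ",
                       "stratified HWE %d, platform frequency %d; ",
                       "union removed %d; %d retained"),
                rep_$n_input, length(rep_$removed_call_rate),
                length(rep_$removed_hwe), length(rep_$removed_platform),
                rep_$n_removed_union, rep_$n_retained))

# how many of the planted platform artifacts were caught
art <- tryCatch(read.delim(file.path(RESULTS, "truth_artifact_snps.tsv")),
                error = function(e) NULL)
if (!is.null(art) && nrow(art)) {
  message("  platform test removed ",
          sum(art$snp_id %in% rep_$removed_platform), " of ",
          nrow(art), " planted artifact SNPs")
}

write_tsv(data.frame(
  criterion = c("input", "call_rate", "stratified_hwe", "platform", "union",
                "retained"),
  n = c(rep_$n_input, length(rep_$removed_call_rate),
        length(rep_$removed_hwe), length(rep_$removed_platform),
        rep_$n_removed_union, rep_$n_retained)), "qc_report.tsv")
write_plink(out$genotypes, paste0(DATA_PREFIX, "_qc"))
message("  wrote ", DATA_PREFIX, "_qc.bed/.bim/.fam")
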