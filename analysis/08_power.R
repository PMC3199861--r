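#!/usr/bin/env Rscript
# Stage 8: power of proxy-SNP association testing. Every chromosome-1 SNP
# is treated as causal in turn, tested through its best proxy (max |r|
# within 2 Mb): analytic power under independent phenotypes, simulated
# power under the relatedness mixed model at full heritability, and the
# variance-inflation diagnostic for the family-structured isolate.

source("analysis/00_config.R")

g <- read_plink(paste0(DATA_PREFIX, "_qc"))
subsets <- read.delim(file.path(RESULTS, "subsets.tsv"))
get_set <- function(nm) subsets$sample_id[subsets$set == nm]

on1 <- which(g$snps$chrom == "1")
g_pw <- subset_genotypes(g, snps = on1[seq_len(min(400, length(on1)))])

rows <- list()
for (v_s in c(0.02, 0.05)) {
  sp <- power_spec(v_s = v_s, alpha_grid = c(1e-5, 1e-7))
  for (nm in unique(subsets$set)) {
    ids <- match(get_set(nm), g_pw$samples$sample_id)
    q <- power_distribution(g_pw, "1", sp, mode = "analytic",
                            samples = ids)$quartiles
    rows[[length(rows) + 1]] <- cbind(explained_variance = v_s,
                                      subset = nm, mode = "analytic", q)
  }
}
# mixed model at h2 = 1 for the family-structured full isolate cohort
R <- estimate_relatedness(g)
iso_ids <- match(get_set("iso_full"), g_pw$samples$sample_id)
for (v_s in c(0.02, 0.05)) {
  spm <- power_spec(v_s = v_s, h2 = 1, alpha_grid = c(1e-5, 1e-7),
                    n_reps = 400)
  qm <- power_distribution(g_pw, "1", spm, mode = "mixed",
                           G = R, samples = iso_ids,
                           seed = SEED + round(100 * v_s))$quartiles
  rows[[length(rows) + 1]] <- cbind(explained_variance = v_s,
                                    subset = "iso_full", mode = "mixed_h2_1",
                                    qm)
}
tab <- do.call(rbind, rows)
tab[, c("q1", "median", "q3")] <- round(tab[, c("q1", "median", "q3")], 2)
print(tab, row.names = FALSE)
write_tsv(tab, "power_quartiles.tsv")

# variance inflation for a mid-frequency causal SNP in the isolate
p1 <- allele_freq(g_pw, iso_ids)
snp <- which.min(abs(p1 - 0.3))
s1 <- g_pw$calls[iso_ids, snp]
vi <- variance_inflation(s1, s1, R[iso_ids, iso_ids],
                         power_spec(v_s = 0.02, h2 = 1, n_reps = 1000),
                         seed = SEED)
message(sprintf(paste0("variance inflation of the naive beta estimator in ",
                       "the full isolate cohort at h2 = 1: %.3f +- %.3f"),
                vi$ratio, vi$mc_se))
write_tsv(data.frame(quantity = "variance_inflation_iso_full_h2_1",
                     value = vi$ratio, mc_se = vi$mc_se),
          "variance_inflation.tsv")
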