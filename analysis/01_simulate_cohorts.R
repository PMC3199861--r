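#!/usr/bin/env Rscript
# Stage 1: generate the two study cohorts with recorded ground truth and
# store them in PLINK format for the downstream stages.

source("analysis/00_config.R")

cfg <- study_sim_config()
message("simulating ", cfg$n_pop1, " + ", cfg$n_pop2, " individuals at ",
        cfg$n_snps, " SNPs (seed ", cfg$seed, ") ...")
sim <- simulate_cohorts(cfg)
g <- sim$genotypes
print(g)

dir.create(dirname(DATA_PREFIX), recursive = TRUE, showWarnings = FALSE)
write_plink(g, DATA_PREFIX)
message("  wrote ", DATA_PREFIX, ".bed/.bim/.fam")
# fam files carry no platform column; keep the full sample table alongside
write_tsv(g$samples, "data/samples.tsv")

# ground-truth sidecars: pedigree, true relatedness of planted pairs,
# artifact SNPs
truth <- sim$truth
ped <- truth$pedigree
write_tsv(ped[!is.na(ped$father), ], "truth_offspring.tsv")
K <- truth$true_kinship
rel_pairs <- which(K > 0 & upper.tri(K), arr.ind = TRUE)
write_tsv(data.frame(id1 = rownames(K)[rel_pairs[, 1]],
                     id2 = colnames(K)[rel_pairs[, 2]],
                     relatedness = K[rel_pairs]),
          "truth_related_pairs.tsv")
write_tsv(data.frame(snp_id = truth$artifact_snps), "truth_artifact_snps.tsv")

n_inbred <- sum(abs(diag(K) - (1 + 1 / 16)) < 1e-9)
message("planted: ", nrow(ped[!is.na(ped$father), ]), " pedigree offspring, ",
        n_inbred, " of them from first-cousin matings; ",
        length(truth$artifact_snps), " platform-shifted SNPs")
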