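#!/usr/bin/env Rscript
# Stage 6: runs of homozygosity per individual; per-population summaries —
# the proportion of individuals with a run per length class and the mean
# total run length as a function of the minimum run length.

source("analysis/00_config.R")

g <- read_plink(paste0(DATA_PREFIX, "_qc"))
runs <- detect_roh(g)
write_tsv(runs, "roh_runs.tsv")
message(nrow(runs), " runs detected across ", n_samples(g), " individuals")

iso <- g$samples$sample_id[g$samples$population == "isolate"]
out <- g$samples$sample_id[g$samples$population == "outbred"]
cls <- rbind(
  cbind(population = "isolate",
        roh_length_class_summary(runs[runs$sample_id %in% iso, ], iso)),
  cbind(population = "outbred",
        roh_length_class_summary(runs[runs$sample_id %in% out, ], out)))
print(cls, row.names = FALSE)
write_tsv(cls, "roh_length_classes.tsv")

mt <- rbind(
  cbind(population = "isolate",
        mean_total_roh_length(runs[runs$sample_id %in% iso, ], iso)),
  cbind(population = "outbred",
        mean_total_roh_length(runs[runs$sample_id %in% out, ], out)))
write_tsv(mt, "roh_mean_total_length.tsv")

p_i <- cls$proportion[cls$population == "isolate" & cls$bin == "[2.5,5)"]
p_o <- cls$proportion[cls$population == "outbred" & cls$bin == "[2.5,5)"]
message(sprintf(paste0("individuals with a 2.5-5 Mb run: %.1f%% isolate vs ",
                       "%.1f%% outbred (consanguinity signature)"),
                100 * p_i, 100 * p_o))
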