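#!/usr/bin/env Rscript
# Stage 5: Weir-Cockerham F_IS per cohort and pairwise F_ST, with
# delete-one-individual jackknife standard errors, for the full and the
# unrelated matched subsets.

source("analysis/00_config.R")

g <- read_plink(paste0(DATA_PREFIX, "_qc"))
subsets <- read.delim(file.path(RESULTS, "subsets.tsv"))
get_set <- function(nm) subsets$sample_id[subsets$set == nm]

rows <- list()
for (pair in list(c("iso_full", "out_full"), c("iso_unrel", "out_unrel"))) {
  ids <- c(get_set(pair[1]), get_set(pair[2]))
  gg <- subset_genotypes(g, samples = match(ids, g$samples$sample_id))
  f_iso <- fis(gg, "isolate")
  f_out <- fis(gg, "outbred")
  f_st <- fst(gg, "isolate", "outbred")
  for (r in list(c("isolate", "F_IS", f_iso$estimate, f_iso$se),
                 c("outbred", "F_IS", f_out$estimate, f_out$se),
                 c("both", "F_ST", f_st$estimate, f_st$se))) {
    rows[[length(rows) + 1]] <- data.frame(
      subset = paste(pair, collapse = "/"), population = r[1],
      statistic = r[2], estimate = signif(as.numeric(r[3]), 3),
      se = signif(as.numeric(r[4]), 3))
  }
}
tab <- do.call(rbind, rows)
print(tab, row.names = FALSE)
write_tsv(tab, "fstatistics.tsv")

fst_full <- tab$estimate[tab$statistic == "F_ST"][1]
message(sprintf("between-cohort F_ST (full subsets) = %.4g, on the scale of the configured divergence (0.003)",
                fst_full))
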