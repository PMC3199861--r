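#!/usr/bin/env Rscript
# Stage 3: pairwise relatedness, the related-pair distribution with odds
# ratios (isolate vs outbred), greedy unrelated subsets, and the matched
# study subsets used by every later stage.

source("analysis/00_config.R")

g <- read_plink(paste0(DATA_PREFIX, "_qc"))
R <- estimate_relatedness(g)
iso <- g$samples$sample_id[g$samples$population == "isolate"]
out <- g$samples$sample_id[g$samples$population == "outbred"]

pd_iso <- pair_distribution(R[iso, iso])
pd_out <- pair_distribution(R[out, out])
tab <- data.frame(lower_bound = pd_iso$lower_bound,
                  n_pairs_isolate = pd_iso$n_pairs,
                  n_pairs_outbred = pd_out$n_pairs)
tab$odds_ratio <- NA
tab$ci <- NA
for (i in seq_len(nrow(tab))) {
  o <- related_pair_odds_ratio(tab$n_pairs_isolate[i], pd_iso$total_pairs[i],
                               tab$n_pairs_outbred[i], pd_out$total_pairs[i])
  tab$odds_ratio[i] <- round(o$or, 1)
  tab$ci[i] <- sprintf("[%.0f;%.0f]", o$ci[1], o$ci[2])
}
message("related-pair distribution (odds ratio: outbred = reference):")
print(tab, row.names = FALSE)
write_tsv(tab, "relatedness_pair_distribution.tsv")

unrel_iso <- select_unrelated(R[iso, iso], 0.2)
unrel_out <- select_unrelated(R[out, out], 0.2)
message("unrelated at cutoff 0.2: ", length(unrel_iso), " of ",
        length(iso), " isolate; ", length(unrel_out), " of ", length(out),
        " outbred individuals")

# matched subsets: full isolate vs equal-size unrelated outbred draw, and
# unrelated isolate vs an equal-size sub-draw
set.seed(SEED)
n_full <- min(length(iso), length(unrel_out))
out_full <- sort(sample(unrel_out, n_full))
n_sub <- min(length(unrel_iso), n_full)
subsets <- rbind(
  data.frame(set = "iso_full", sample_id = iso),
  data.frame(set = "out_full", sample_id = out_full),
  data.frame(set = "iso_unrel", sample_id = sort(sample(unrel_iso, n_sub))),
  data.frame(set = "out_unrel", sample_id = sort(sample(out_full, n_sub))))
write_tsv(subsets, "subsets.tsv")
message("matched subsets: full ", n_full, " vs ", n_full,
        "; unrelated ", n_sub, " vs ", n_sub)
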