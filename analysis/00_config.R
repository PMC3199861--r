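# Shared settings for the analysis workflow. Each numbered script is a thin
# driver over the isopop package; run them in order from the repository
# root:  Rscript analysis/01_simulate_cohorts.R  etc.
# Outputs accumulate under results/.

library(isopop)

RESULTS <- "results"
DATA_PREFIX <- file.path(RESULTS, "data", "cohorts")
SEED <- 2011L

# The study conditions: an isolate-like cohort (families oversampled, a
# consanguineous fraction, two genotyping platforms) against an outbred
# reference, diverged at F_ST 0.003 with LD decaying on a 25-kb scale.
study_sim_config <- function() {
  sim_config(seed = SEED, n_pop1 = 300, n_pop2 = 300, n_snps = 20000,
             n_chromosomes = 2, divergence_fst = 0.003,
             ld_decay_bp = 25000, snp_spacing_bp = 5000,
             recomb_rate_per_bp = 2.5e-8,
             family_spec = list(list(type = "trio", count = 15),
                                list(type = "sib_pair", count = 10)),
             inbred_fraction = 0.1,
             missing_rate_by_platform = c(chipA = 0.002, chipB = 0.002),
             platform_shift_snps = list(count = 50, shift = 0.25))
}

write_tsv <- function(df, name) {
  path <- file.path(RESULTS, name)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("  wrote ", path)
}
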