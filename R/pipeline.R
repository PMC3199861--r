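#' Study configuration
#'
#' @param input either a [sim_config()] (cohorts are simulated) or a list
#'   `list(path =, format =)` for [load_genotypes()].
#' @param thresholds a [qc_thresholds()].
#' @param relatedness_cutoff primary unrelatedness cutoff (default 0.2; the
#'   sensitivity analyses use 0.1).
#' @param analyses character vector of stages to run, any of
#'   `"relatedness"`, `"rare"`, `"fstats"`, `"roh"`, `"ld"`, `"power"`.
#' @param seed seed controlling every random choice of the study.
#' @param ld_chromosome chromosome used for the LD and power stages
#'   (default `"1"`).
#' @param ld_max_snps cap on the number of SNPs (from the start of the
#'   chromosome) entering the all-pairs LD profile (default 300; pairwise
#'   EM cost grows quadratically).
#' @param power_specs list of [power_spec()]s for the power stage.
#' @param roh_params_ a [roh_params()].
#' @return list of class `study_config`.
#' @export
study_config <- function(input = sim_config(),
                         thresholds = qc_thresholds(),
                         relatedness_cutoff = 0.2,
                         analyses = c("relatedness", "rare", "fstats",
                                      "roh", "ld", "power"),
                         seed = 1L,
                         ld_chromosome = "1",
                         ld_max_snps = 300L,
                         power_specs = list(power_spec(v_s = 0.02),
                                            power_spec(v_s = 0.05)),
                         roh_params_ = roh_params()) {
  structure(list(input = input, thresholds = thresholds,
                 relatedness_cutoff = relatedness_cutoff,
                 analyses = analyses, seed = as.integer(seed),
                 ld_chromosome = ld_chromosome,
                 ld_max_snps = as.integer(ld_max_snps),
                 power_specs = power_specs,
                 roh_params = roh_params_), class = "study_config")
}

#' Run the full two-cohort comparison study
#'
#' Executes the analysis sequence on the configured input: QC, relatedness
#' (pair distribution, odds ratios, greedy unrelated subsets and the
#' matched subsets: the full isolate cohort versus a size-matched random
#' unrelated outbred subset, and the unrelated isolate subset versus a
#' size-matched outbred subset), rare SNPs, F-statistics, ROH summaries, LD
#' profiles, and proxy-SNP power. All randomness derives from `cfg$seed`,
#' so a repeated run reproduces the report exactly.
#'
#' @param cfg a [study_config()].
#' @return list of class `study_report` with one element per stage plus
#'   `config` and `subsets`.
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  report <- list(config = cfg)
  if (inherits(cfg$input, "sim_config")) {
    sim <- simulate_cohorts(cfg$input)
    g <- sim$genotypes
    report$truth <- sim$truth["artifact_snps"]
  } else {
    g <- load_genotypes(cfg$input$path, cfg$input$format)
  }
  set.seed(cfg$seed)
  pops <- unique(g$samples$population)
  if (length(pops) < 2) stop("study needs two populations")
  pop_iso <- pops[1]
  pop_out <- pops[2]
  # QC: platform test within the cohort typed on two platforms
  two_plat <- vapply(pops, function(pp) {
    length(unique(g$samples$platform[g$samples$population == pp])) > 1
  }, TRUE)
  platform_within <- if (any(two_plat)) pops[which(two_plat)[1]] else NULL
  qc <- apply_qc(g, cfg$thresholds, platform_within = platform_within)
  report$qc <- qc$report
  g <- qc$genotypes
  # relatedness drives the subset construction even when its report is off
  R <- estimate_relatedness(g)
  iso_ids <- g$samples$sample_id[g$samples$population == pop_iso]
  out_ids <- g$samples$sample_id[g$samples$population == pop_out]
  unrel_iso <- select_unrelated(R[iso_ids, iso_ids], cfg$relatedness_cutoff)
  unrel_out <- select_unrelated(R[out_ids, out_ids], cfg$relatedness_cutoff)
  # matched subsets: full isolate vs equal-size random unrelated outbred;
  # unrelated isolate vs equal-size random subset of the former
  n_full <- length(iso_ids)
  if (length(unrel_out) < n_full) {
    warning("fewer unrelated outbred individuals than isolate cohort size; ",
            "matching at ", length(unrel_out))
    n_full <- length(unrel_out)
  }
  out_full <- sort(sample(unrel_out, n_full))
  n_sub <- min(length(unrel_iso), length(out_full))
  out_sub <- sort(sample(out_full, n_sub))
  iso_sub <- sort(sample(unrel_iso, n_sub))
  subsets <- list(iso_full = iso_ids, out_full = out_full,
                  iso_unrel = iso_sub, out_unrel = out_sub)
  report$subsets <- subsets
  if ("relatedness" %in% cfg$analyses) {
    pd_iso <- pair_distribution(R[iso_ids, iso_ids])
    pd_out <- pair_distribution(R[out_ids, out_ids])
    ors <- lapply(seq_len(nrow(pd_iso)), function(i) {
      related_pair_odds_ratio(pd_iso$n_pairs[i], pd_iso$total_pairs[i],
                              pd_out$n_pairs[i], pd_out$total_pairs[i])
    })
    report$relatedness <- list(
      pair_distribution = data.frame(
        lower_bound = pd_iso$lower_bound,
        n_pairs_isolate = pd_iso$n_pairs,
        n_pairs_outbred = pd_out$n_pairs,
        odds_ratio = vapply(ors, function(o) o$or, 0),
        ci_low = vapply(ors, function(o) o$ci[1], 0),
        ci_high = vapply(ors, function(o) o$ci[2], 0)),
      n_unrelated_isolate = length(unrel_iso),
      n_unrelated_outbred = length(unrel_out))
  }
  pair_sets <- list(full = list(a = subsets$iso_full, b = subsets$out_full),
                    unrel = list(a = subsets$iso_unrel, b = subsets$out_unrel))
  if ("rare" %in% cfg$analyses) {
    report$rare <- lapply(pair_sets, function(ps) {
      ra <- classify_rare(g, samples = match(ps$a, g$samples$sample_id))
      rb <- classify_rare(g, samples = match(ps$b, g$samples$sample_id))
      cmp <- compare_rare_odds(sum(ra$rare), n_snps(g), sum(rb$rare))
      list(n_rare_isolate = sum(ra$rare), n_rare_outbred = sum(rb$rare),
           n_snps = n_snps(g), or = cmp$or, p = cmp$p)
    })
  }
  if ("fstats" %in% cfg$analyses) {
    report$fstats <- lapply(pair_sets, function(ps) {
      gg <- subset_genotypes(g, samples = match(c(ps$a, ps$b),
                                                g$samples$sample_id))
      list(fis_isolate = fis(gg, pop_iso), fis_outbred = fis(gg, pop_out),
           fst = fst(gg, pop_iso, pop_out))
    })
  }
  if ("roh" %in% cfg$analyses) {
    rr <- detect_roh(g, params = cfg$roh_params)
    report$roh <- list(
      runs = rr,
      length_class = list(
        isolate = roh_length_class_summary(
          rr[rr$sample_id %in% iso_ids, ], iso_ids),
        outbred = roh_length_class_summary(
          rr[rr$sample_id %in% out_ids, ], out_ids)),
      mean_total = list(
        isolate = mean_total_roh_length(rr[rr$sample_id %in% iso_ids, ],
                                        iso_ids),
        outbred = mean_total_roh_length(rr[rr$sample_id %in% out_ids, ],
                                        out_ids)))
  }
  if ("ld" %in% cfg$analyses) {
    on_chr <- which(g$snps$chrom == cfg$ld_chromosome)
    keep_snps <- sort(union(on_chr[seq_len(min(length(on_chr),
                                               cfg$ld_max_snps))],
                            which(g$snps$chrom != cfg$ld_chromosome)))
    g_ld <- subset_genotypes(g, snps = keep_snps)
    report$ld <- lapply(pair_sets, function(ps) {
      list(isolate = ld_decay_profile(g_ld, cfg$ld_chromosome,
                                      measure = "abs_eta1",
                                      samples = match(ps$a, g_ld$samples$sample_id)),
           outbred = ld_decay_profile(g_ld, cfg$ld_chromosome,
                                      measure = "abs_eta1",
                                      samples = match(ps$b, g_ld$samples$sample_id)))
    })
  }
  if ("power" %in% cfg$analyses) {
    report$power <- lapply(cfg$power_specs, function(sp) {
      lapply(pair_sets, function(ps) {
        list(isolate = power_distribution(
               g, cfg$ld_chromosome, sp, mode = "analytic",
               samples = match(ps$a, g$samples$sample_id))$quartiles,
             outbred = power_distribution(
               g, cfg$ld_chromosome, sp, mode = "analytic",
               samples = match(ps$b, g$samples$sample_id))$quartiles)
      })
    })
  }
  class(report) <- "study_report"
  report
}
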