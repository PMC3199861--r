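#' Configuration for the two-cohort simulator
#'
#' Defines the statistical structure of a synthetic pair of cohorts: an
#' isolate-like population and an outbred reference diverged at a given
#' Weir-Cockerham F_ST, with linkage disequilibrium decaying along
#' chromosomes, optional oversampled families, consanguineous matings, and
#' platform artifacts.
#'
#' Divergence uses the Balding-Nichols model: population allele frequencies
#' are Beta-distributed around the ancestral frequency with variance
#' parameter `divergence_fst`. Haplotypes are built by a first-order latent
#' copying process whose pairwise allele correlation decays as
#' `exp(-distance / ld_decay_bp)`.
#'
#' @param seed integer RNG seed; the whole run is a single stream seeded here.
#' @param n_pop1,n_pop2 cohort sizes (population 1 is the isolate-like one).
#' @param n_snps total SNP count, split evenly across chromosomes.
#' @param n_chromosomes number of autosomes to simulate.
#' @param divergence_fst Balding-Nichols divergence parameter, in [0, 0.5):
#'   the expected pairwise Weir-Cockerham F_ST between the two cohorts.
#' @param isolate_drift_share share of the total drift carried by
#'   population 1 (default 0.75: the isolate has drifted further from the
#'   shared ancestral pool, the founder-effect signature that also yields
#'   its rare-variant excess; 0.5 makes drift symmetric). Population i
#'   drifts with its own Balding-Nichols parameter
#'   `2 * share_i * divergence_fst`, so the pairwise divergence stays at
#'   `divergence_fst`.
#' @param maf_range interval from which ancestral allele-b frequencies are
#'   drawn uniformly.
#' @param ld_decay_bp length scale (bp) of LD decay.
#' @param snp_spacing_bp mean inter-SNP spacing (bp); gaps are exponential.
#' @param family_spec list of `list(type =, count =)` entries with type one
#'   of `"trio"`, `"sib_pair"`, `"cousin_pair"`, `"cousin_mating"`; families
#'   are planted in population 1.
#' @param missing_rate_by_platform named numeric vector, per-platform missing
#'   call rate.
#' @param platform_shift_snps `list(count =, shift =)`: number of SNPs whose
#'   allele frequency is perturbed by `shift` on the first platform.
#' @param inbred_fraction fraction of population 1 replaced by offspring of
#'   first-cousin matings (drives ROH enrichment).
#' @param recomb_rate_per_bp crossover rate per bp per meiosis (default
#'   1e-8, i.e. 1 cM/Mb).
#' @param pop_names labels of the two populations.
#' @param platforms two platform labels; population 1 is split between both,
#'   population 2 is typed on the first only.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_pop1 = 300L, n_pop2 = 300L,
                       n_snps = 10000L, n_chromosomes = 2L,
                       divergence_fst = 0.003,
                       isolate_drift_share = 0.75,
                       maf_range = c(0.01, 0.5),
                       ld_decay_bp = 25000,
                       snp_spacing_bp = 5000,
                       family_spec = list(),
                       missing_rate_by_platform = c(chipA = 0, chipB = 0),
                       platform_shift_snps = list(count = 0L, shift = 0),
                       inbred_fraction = 0,
                       recomb_rate_per_bp = 1e-8,
                       pop_names = c("isolate", "outbred"),
                       platforms = c("chipA", "chipB")) {
  stopifnot(divergence_fst >= 0, divergence_fst < 0.5,
            isolate_drift_share >= 0, isolate_drift_share <= 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            ld_decay_bp > 0, snp_spacing_bp >= 1,
            inbred_fraction >= 0, inbred_fraction <= 1,
            n_pop1 >= 1, n_pop2 >= 1, n_snps >= 1, n_chromosomes >= 1)
  rates <- missing_rate_by_platform
  if (any(rates < 0 | rates > 1)) stop("missing rates must be in [0,1]")
  structure(list(seed = as.integer(seed), n_pop1 = as.integer(n_pop1),
                 n_pop2 = as.integer(n_pop2), n_snps = as.integer(n_snps),
                 n_chromosomes = as.integer(n_chromosomes),
                 divergence_fst = divergence_fst,
                 isolate_drift_share = isolate_drift_share,
                 maf_range = maf_range,
                 ld_decay_bp = ld_decay_bp, snp_spacing_bp = snp_spacing_bp,
                 family_spec = family_spec,
                 missing_rate_by_platform = rates,
                 platform_shift_snps = platform_shift_snps,
                 inbred_fraction = inbred_fraction,
                 recomb_rate_per_bp = recomb_rate_per_bp,
                 pop_names = pop_names, platforms = platforms),
            class = "sim_config")
}

# one haplotype pool: latent uniform is copied from the previous SNP with
# probability exp(-gap/L), else redrawn; allele_j = 1{u < p_j}. For equal
# frequencies the allele correlation across distance d is exactly exp(-d/L).
sim_haplotypes <- function(n_hap, freqs, pos, ld_decay_bp) {
  m <- length(freqs)
  H <- matrix(FALSE, n_hap, m)
  u <- stats::runif(n_hap)
  H[, 1] <- u < freqs[1]
  if (m > 1) {
    cprob <- exp(-diff(pos) / ld_decay_bp)
    for (j in 2:m) {
      redraw <- stats::runif(n_hap) >= cprob[j - 1]
      if (any(redraw)) u[redraw] <- stats::runif(sum(redraw))
      H[, j] <- u < freqs[j]
    }
  }
  H
}

#' Simulate two diverged cohorts with LD
#'
#' Draws ancestral allele frequencies uniformly on `maf_range`, population
#' frequencies from the Balding-Nichols distribution with parameter
#' `divergence_fst`, builds per-population haplotype pools with exponentially
#' decaying LD, and sums haplotype pairs into genotypes. Ground truth
#' (frequencies, haplotypes, pedigree, kinship) is recorded alongside.
#'
#' @param cfg a [sim_config()].
#' @return `list(genotypes = genotype_matrix, truth = list(...))`. The truth
#'   record holds `ancestral_freqs`, `pop_freqs` (matrix, one column per
#'   population), `pedigree` (id/father/mother), `true_kinship` (relatedness
#'   scale: expectation 0.5 for parent-offspring, diagonal 1 + F), the
#'   phased `haplotypes` matrix (two rows per sample, used only inside the
#'   simulator), and `artifact_snps`.
#' @export
simulate_two_populations <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  m <- cfg$n_snps
  per_chr <- rep(m %/% cfg$n_chromosomes, cfg$n_chromosomes)
  extra <- m %% cfg$n_chromosomes
  if (extra > 0) per_chr[seq_len(extra)] <- per_chr[seq_len(extra)] + 1L
  chrom <- rep(as.character(seq_len(cfg$n_chromosomes)), per_chr)
  pos <- unlist(lapply(per_chr, function(k) {
    cumsum(pmax(1L, as.integer(round(stats::rexp(k, 1 / cfg$snp_spacing_bp)))))
  }), use.names = FALSE)
  p_anc <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  shares <- c(cfg$isolate_drift_share, 1 - cfg$isolate_drift_share)
  draw_pop_freq <- function(share) {
    f <- 2 * share * cfg$divergence_fst
    if (f == 0) return(p_anc)
    q <- stats::rbeta(m, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
    pmin(pmax(q, 1e-6), 1 - 1e-6)
  }
  pop_freqs <- cbind(draw_pop_freq(shares[1]), draw_pop_freq(shares[2]))
  colnames(pop_freqs) <- cfg$pop_names
  n_tot <- cfg$n_pop1 + cfg$n_pop2
  H <- matrix(FALSE, 2L * n_tot, m)
  offs <- c(0L, cumsum(per_chr))
  hap_rows <- list(seq_len(2L * cfg$n_pop1),
                   2L * cfg$n_pop1 + seq_len(2L * cfg$n_pop2))
  for (k in seq_len(cfg$n_chromosomes)) {
    idx <- (offs[k] + 1L):offs[k + 1L]
    for (pp in 1:2) {
      H[hap_rows[[pp]], idx] <- sim_haplotypes(length(hap_rows[[pp]]),
                                               pop_freqs[idx, pp], pos[idx],
                                               cfg$ld_decay_bp)
    }
  }
  odd <- seq_len(n_tot) * 2L - 1L
  calls <- H[odd, , drop = FALSE] + H[odd + 1L, , drop = FALSE]
  storage.mode(calls) <- "integer"
  ids <- c(sprintf("%s_%04d", cfg$pop_names[1], seq_len(cfg$n_pop1)),
           sprintf("%s_%04d", cfg$pop_names[2], seq_len(cfg$n_pop2)))
  population <- rep(cfg$pop_names, c(cfg$n_pop1, cfg$n_pop2))
  platform <- c(cfg$platforms[1 + (seq_len(cfg$n_pop1) %% 2)],
                rep(cfg$platforms[1], cfg$n_pop2))
  samples <- data.frame(sample_id = ids, population = population,
                        platform = platform, stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = sprintf("snp_%06d", seq_len(m)),
                     chrom = chrom, pos = pos,
                     allele_a = "A", allele_b = "G", stringsAsFactors = FALSE)
  g <- genotype_matrix(calls, snps, samples)
  K <- diag(1, n_tot)
  dimnames(K) <- list(ids, ids)
  truth <- list(
    ancestral_freqs = p_anc,
    pop_freqs = pop_freqs,
    pedigree = data.frame(id = ids, father = NA_character_,
                          mother = NA_character_, stringsAsFactors = FALSE),
    true_kinship = K,
    haplotypes = H,
    artifact_snps = character(0)
  )
  list(genotypes = g, truth = truth)
}

# gamete from a parent's two haplotype rows, with crossovers at exponential
# inter-crossover distances (Poisson count per chromosome)
meiosis <- function(hap_pair, snps, rate) {
  gam <- logical(ncol(hap_pair))
  for (ch in unique(snps$chrom)) {
    idx <- which(snps$chrom == ch)
    p <- snps$pos[idx]
    len <- max(p) - min(p) + 1
    ncross <- stats::rpois(1, len * rate)
    xpos <- sort(stats::runif(ncross, min(p), max(p)))
    seg <- findInterval(p, xpos)
    strand <- (sample.int(2L, 1L) + seg) %% 2L + 1L
    gam[idx] <- hap_pair[cbind(strand, idx)]
  }
  gam
}

#' Plant families into a simulated cohort
#'
#' Replaces members of population 1 by pedigree-generated relatives:
#' offspring genotypes are produced by Mendelian transmission of parental
#' haplotypes with recombination. Supported family types: `"trio"`
#' (parent-offspring trio), `"sib_pair"`, `"cousin_pair"` (first cousins,
#' expected relatedness 0.125), `"cousin_mating"` (offspring of a
#' first-cousin mating, inbreeding coefficient 1/16). The true kinship
#' matrix is recomputed from the pedigree on the relatedness scale
#' (parent-offspring 0.5, full sibs expected 0.5, first cousins 0.125).
#'
#' @param g a [genotype_matrix()] from [simulate_two_populations()].
#' @param truth the matching truth record (needs its `haplotypes`).
#' @param family_spec list of `list(type =, count =)` entries.
#' @param cfg the [sim_config()] used (recombination rate, population name).
#' @return `list(genotypes =, truth =)` with updated calls, haplotypes,
#'   pedigree and `true_kinship`.
#' @export
overlay_families <- function(g, truth, family_spec, cfg) {
  if (length(family_spec) == 0) return(list(genotypes = g, truth = truth))
  pop1 <- which(g$samples$population == cfg$pop_names[1])
  free <- pop1                        # cohort slots not yet used by a family
  n_founders_needed <- 0L
  need <- list(trio = c(2L, 1L), sib_pair = c(2L, 2L),
               cousin_pair = c(4L, 2L), cousin_mating = c(4L, 1L))
  for (fs in family_spec) {
    if (!fs$type %in% names(need)) stop("unknown family type: ", fs$type)
    n_founders_needed <- n_founders_needed + sum(need[[fs$type]]) * fs$count
  }
  if (n_founders_needed > length(free)) {
    stop("family_spec needs ", n_founders_needed, " members of population 1 ",
         "but only ", length(free), " are available")
  }
  H <- truth$haplotypes
  ped_id <- g$samples$sample_id
  ped_father <- rep(NA_character_, length(ped_id))
  ped_mother <- rep(NA_character_, length(ped_id))
  extra <- list()  # internal (non-cohort) individuals: id, father, mother
  extra_hap <- list()
  fam_k <- 0L
  take <- function(k) {
    got <- free[seq_len(k)]
    free <<- free[-seq_len(k)]
    got
  }
  child_of <- function(fa_hap, mo_hap, rate) {
    rbind(meiosis(fa_hap, g$snps, rate), meiosis(mo_hap, g$snps, rate))
  }
  hap_of <- function(i) H[c(2L * i - 1L, 2L * i), , drop = FALSE]
  place <- function(slot, hap, father, mother) {
    H[c(2L * slot - 1L, 2L * slot), ] <<- hap
    ped_father[slot] <<- father
    ped_mother[slot] <<- mother
  }
  rate <- cfg$recomb_rate_per_bp
  for (fs in family_spec) {
    for (rep_i in seq_len(fs$count)) {
      fam_k <- fam_k + 1L
      if (fs$type == "trio") {
        par <- take(2L)
        kid <- take(1L)
        place(kid, child_of(hap_of(par[1]), hap_of(par[2]), rate),
              ped_id[par[1]], ped_id[par[2]])
      } else if (fs$type == "sib_pair") {
        par <- take(2L)
        kids <- take(2L)
        for (kd in kids) {
          place(kd, child_of(hap_of(par[1]), hap_of(par[2]), rate),
                ped_id[par[1]], ped_id[par[2]])
        }
      } else if (fs$type %in% c("cousin_pair", "cousin_mating")) {
        gp <- take(2L)       # shared grandparents
        sp <- take(2L)       # unrelated spouses
        # internal sibling parents
        c_id <- sprintf("fam%03d_p1", fam_k)
        d_id <- sprintf("fam%03d_p2", fam_k)
        c_hap <- child_of(hap_of(gp[1]), hap_of(gp[2]), rate)
        d_hap <- child_of(hap_of(gp[1]), hap_of(gp[2]), rate)
        extra[[length(extra) + 1L]] <- c(c_id, ped_id[gp[1]], ped_id[gp[2]])
        extra_hap[[c_id]] <- c_hap
        extra[[length(extra) + 1L]] <- c(d_id, ped_id[gp[1]], ped_id[gp[2]])
        extra_hap[[d_id]] <- d_hap
        if (fs$type == "cousin_pair") {
          kids <- take(2L)
          place(kids[1], child_of(c_hap, hap_of(sp[1]), rate),
                c_id, ped_id[sp[1]])
          place(kids[2], child_of(d_hap, hap_of(sp[2]), rate),
                d_id, ped_id[sp[2]])
        } else {
          # the cousins themselves stay internal; their child joins the cohort
          g_id <- sprintf("fam%03d_c1", fam_k)
          h_id <- sprintf("fam%03d_c2", fam_k)
          g_hap <- child_of(c_hap, hap_of(sp[1]), rate)
          h_hap <- child_of(d_hap, hap_of(sp[2]), rate)
          extra[[length(extra) + 1L]] <- c(g_id, c_id, ped_id[sp[1]])
          extra_hap[[g_id]] <- g_hap
          extra[[length(extra) + 1L]] <- c(h_id, d_id, ped_id[sp[2]])
          extra_hap[[h_id]] <- h_hap
          kid <- take(1L)
          place(kid, child_of(g_hap, h_hap, rate), g_id, h_id)
        }
      }
    }
  }
  odd <- seq_len(n_samples(g)) * 2L - 1L
  calls <- H[odd, , drop = FALSE] + H[odd + 1L, , drop = FALSE]
  storage.mode(calls) <- "integer"
  g2 <- genotype_matrix(calls, g$snps, g$samples)
  # full pedigree, parents before children: pure founders, internals in
  # creation order, then replaced cohort offspring in creation order
  extra_df <- if (length(extra)) {
    do.call(rbind, lapply(extra, function(e) {
      data.frame(id = e[1], father = e[2], mother = e[3],
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(id = character(), father = character(), mother = character())
  }
  cohort_df <- data.frame(id = ped_id, father = ped_father,
                          mother = ped_mother, stringsAsFactors = FALSE)
  founders <- cohort_df[is.na(cohort_df$father), , drop = FALSE]
  offspring <- cohort_df[!is.na(cohort_df$father), , drop = FALSE]
  ped <- rbind(founders, extra_df, offspring)
  K_all <- kinship_from_pedigree(ped)
  K <- K_all[ped_id, ped_id]
  truth$haplotypes <- H
  truth$pedigree <- cohort_df
  truth$true_kinship <- K
  list(genotypes = g2, truth = truth)
}

#' Relatedness matrix implied by a pedigree
#'
#' Tabular-method kinship over a pedigree whose parents precede their
#' children, reported on the relatedness scale (twice the kinship
#' coefficient: parent-offspring 0.5, first cousins 0.125; diagonal 1 + F).
#'
#' @param ped data.frame with columns `id`, `father`, `mother` (NA for
#'   founders); every parent id must appear earlier in the frame.
#' @return Symmetric named matrix.
#' @export
kinship_from_pedigree <- function(ped) {
  n <- nrow(ped)
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  if (any(!is.na(ped$father) & (is.na(fa) | fa >= seq_len(n)))) {
    stop("pedigree parents must precede children")
  }
  for (j in seq_len(n)) {
    if (is.na(fa[j])) {
      phi[j, j] <- 0.5
    } else {
      if (j > 1) {
        prev <- seq_len(j - 1L)
        phi[j, prev] <- 0.5 * (phi[fa[j], prev] + phi[mo[j], prev])
        phi[prev, j] <- phi[j, prev]
      }
      phi[j, j] <- 0.5 * (1 + phi[fa[j], mo[j]])
    }
  }
  2 * phi
}

#' Add platform artifacts to a simulated cohort
#'
#' Adds missing calls per platform at the configured rates, and perturbs the
#' allele frequency of `platform_shift_snps$count` randomly chosen SNPs by
#' `shift` on the first platform (genotypes of first-platform samples at
#' those SNPs are redrawn from the shifted frequency; shifts beyond the
#' feasible range are clipped with a warning). Artifact SNP ids are recorded
#' in the truth record.
#'
#' @param g a [genotype_matrix()].
#' @param truth matching truth record.
#' @param cfg a [sim_config()].
#' @return `list(genotypes =, truth =)`.
#' @export
inject_artifacts <- function(g, truth, cfg) {
  calls <- g$calls
  shift_spec <- cfg$platform_shift_snps
  if (!is.null(shift_spec$count) && shift_spec$count > 0) {
    pf1 <- which(g$samples$platform == cfg$platforms[1] &
                   g$samples$population == cfg$pop_names[1])
    if (length(pf1) == 0) stop("no samples on platform ", cfg$platforms[1])
    shift_idx <- sort(sample.int(n_snps(g), shift_spec$count))
    p0 <- colMeans(calls[, shift_idx, drop = FALSE], na.rm = TRUE) / 2
    p1 <- p0 + shift_spec$shift
    if (any(p1 < 0.01 | p1 > 0.99)) {
      warning("platform shift clipped to [0.01, 0.99] for some SNPs")
      p1 <- pmin(pmax(p1, 0.01), 0.99)
    }
    for (k in seq_along(shift_idx)) {
      calls[pf1, shift_idx[k]] <-
        stats::rbinom(length(pf1), 2L, p1[k])
    }
    truth$artifact_snps <- g$snps$snp_id[shift_idx]
  }
  rates <- cfg$missing_rate_by_platform
  for (pl in names(rates)) {
    if (rates[[pl]] <= 0) next
    rows <- which(g$samples$platform == pl)
    if (length(rows) == 0) next
    sub <- calls[rows, , drop = FALSE]
    sub[stats::runif(length(sub)) < rates[[pl]]] <- NA_integer_
    calls[rows, ] <- sub
  }
  list(genotypes = genotype_matrix(calls, g$snps, g$samples), truth = truth)
}

#' Run the full simulator
#'
#' Convenience wrapper: [simulate_two_populations()], then
#' [overlay_families()] (the configured `family_spec` plus
#' `inbred_fraction`-many cousin matings), then [inject_artifacts()], all on
#' one RNG stream seeded from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return `list(genotypes =, truth =)`.
#' @export
simulate_cohorts <- function(cfg) {
  sim <- simulate_two_populations(cfg)
  spec <- cfg$family_spec
  n_inbred <- floor(cfg$inbred_fraction * cfg$n_pop1)
  if (n_inbred > 0) {
    spec <- c(spec, list(list(type = "cousin_mating", count = n_inbred)))
  }
  if (length(spec) > 0) {
    sim <- overlay_families(sim$genotypes, sim$truth, spec, cfg)
  }
  inject_artifacts(sim$genotypes, sim$truth, cfg)
}
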