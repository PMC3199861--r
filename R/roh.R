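#' Parameters for runs-of-homozygosity detection
#'
#' Defaults follow the sliding-window homozygosity caller configuration used
#' for SNP-array isolate studies: 5000-kb windows of at least 50 SNPs,
#' allowing one heterozygote and five missing calls per window; a SNP is in
#' a homozygous segment when at least 5% of the windows spanning it are
#' homozygous; reported runs span at least 500 kb and 100 SNPs at a density
#' of one SNP per 50 kb or better, and candidate segments are split where
#' two consecutive SNPs lie at least 100 kb apart.
#'
#' @param window_kb window length in kb (default 5000).
#' @param window_min_snps minimum SNPs for a window to be assessed (50).
#' @param window_max_het heterozygotes allowed per window (1).
#' @param window_max_missing missing calls allowed per window (5).
#' @param hit_proportion minimum fraction of homozygous spanning windows
#'   (0.05).
#' @param min_run_kb minimum reported run length in kb (500).
#' @param min_run_snps minimum SNPs per reported run (100).
#' @param min_density_kb_per_snp maximum kb per SNP within a run (50).
#' @param gap_split_kb split a candidate segment at inter-SNP gaps of at
#'   least this many kb (100).
#' @return list of class `roh_params`.
#' @export
roh_params <- function(window_kb = 5000, window_min_snps = 50,
                       window_max_het = 1, window_max_missing = 5,
                       hit_proportion = 0.05, min_run_kb = 500,
                       min_run_snps = 100, min_density_kb_per_snp = 50,
                       gap_split_kb = 100) {
  stopifnot(window_kb > 0, window_min_snps > 0, hit_proportion > 0,
            min_run_kb > 0, min_run_snps > 0, min_density_kb_per_snp > 0,
            gap_split_kb > 0, min_run_kb <= window_kb)
  structure(list(window_kb = window_kb, window_min_snps = window_min_snps,
                 window_max_het = window_max_het,
                 window_max_missing = window_max_missing,
                 hit_proportion = hit_proportion, min_run_kb = min_run_kb,
                 min_run_snps = min_run_snps,
                 min_density_kb_per_snp = min_density_kb_per_snp,
                 gap_split_kb = gap_split_kb),
            class = "roh_params")
}

# one chromosome for one individual: x is the dosage vector, pos sorted bp
roh_chromosome <- function(x, pos, params) {
  m <- length(x)
  if (m < params$window_min_snps) return(NULL)
  if (any(diff(pos) <= 0)) stop("positions not sorted")
  w_bp <- params$window_kb * 1000
  het <- !is.na(x) & x == 1L
  mis <- is.na(x)
  cum_het <- c(0L, cumsum(het))
  cum_mis <- c(0L, cumsum(mis))
  # window anchored at SNP k spans [pos_k, pos_k + w_bp]; last SNP index
  # inside is found by a two-pointer sweep; truncated end-of-chromosome
  # windows count only while they still hold window_min_snps SNPs
  last <- findInterval(pos + w_bp, pos)
  w_n <- last - seq_len(m) + 1L
  valid <- w_n >= params$window_min_snps
  homozygous <- valid &
    (cum_het[last + 1L] - cum_het[seq_len(m)]) <= params$window_max_het &
    (cum_mis[last + 1L] - cum_mis[seq_len(m)]) <= params$window_max_missing
  # per SNP: spanning windows are anchors k with k <= j <= last[k];
  # count valid and homozygous ones with difference arrays over j
  span_valid <- numeric(m + 1L)
  span_hom <- numeric(m + 1L)
  add_v <- which(valid)
  if (length(add_v)) {
    sv <- tabulate(add_v, nbins = m + 1L) -
      tabulate(pmin(last[add_v] + 1L, m + 1L), nbins = m + 1L)
    span_valid <- cumsum(sv)[seq_len(m)]
  } else {
    span_valid <- numeric(m)
  }
  add_h <- which(homozygous)
  if (length(add_h)) {
    sh <- tabulate(add_h, nbins = m + 1L) -
      tabulate(pmin(last[add_h] + 1L, m + 1L), nbins = m + 1L)
    span_hom <- cumsum(sh)[seq_len(m)]
  } else {
    span_hom <- numeric(m)
  }
  inrun <- span_valid > 0 & span_hom / pmax(span_valid, 1) >= params$hit_proportion
  if (!any(inrun)) return(NULL)
  # maximal stretches of in-run SNPs, split at large gaps
  r <- rle(inrun)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- cbind(starts[r$values], ends[r$values])
  out <- list()
  for (i in seq_len(nrow(segs))) {
    idx <- segs[i, 1]:segs[i, 2]
    gaps <- which(diff(pos[idx]) >= params$gap_split_kb * 1000)
    bounds <- c(0L, gaps, length(idx))
    for (b in seq_len(length(bounds) - 1L)) {
      sub <- idx[(bounds[b] + 1L):bounds[b + 1L]]
      len_bp <- pos[sub[length(sub)]] - pos[sub[1]]
      nsnp <- length(sub)
      if (len_bp >= params$min_run_kb * 1000 &&
          nsnp >= params$min_run_snps &&
          len_bp / nsnp <= params$min_density_kb_per_snp * 1000) {
        out[[length(out) + 1L]] <- c(pos[sub[1]], pos[sub[length(sub)]], nsnp)
      }
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Detect runs of homozygosity
#'
#' Sliding-window ROH caller: (1) a window of `window_kb` anchored at every
#' SNP is homozygous if it holds at most `window_max_het` heterozygotes and
#' `window_max_missing` missing calls (windows with fewer than
#' `window_min_snps` SNPs are not assessed); (2) a SNP is part of a
#' homozygous segment if at least `hit_proportion` of the assessed windows
#' spanning it are homozygous; (3) maximal stretches of such SNPs are split
#' where consecutive SNPs are `gap_split_kb` or more apart; (4) segments
#' passing the length, SNP-count and density filters are reported. Run
#' length is last SNP position minus first SNP position. A heterozygote
#' inside a reported run is possible when window voting admits it.
#'
#' @param g a [genotype_matrix()] (positions sorted within chromosome).
#' @param individuals sample ids or indices (default: all).
#' @param params a [roh_params()].
#' @return data.frame with `sample_id`, `chrom`, `start_bp`, `end_bp`,
#'   `n_snps`, `length_kb`.
#' @export
detect_roh <- function(g, individuals = NULL, params = roh_params()) {
  ids <- g$samples$sample_id
  si <- if (is.null(individuals)) seq_along(ids) else individuals
  if (is.character(si)) si <- match(si, ids)
  chroms <- unique(g$snps$chrom)
  res <- list()
  for (ch in chroms) {
    idx <- which(g$snps$chrom == ch)
    pos <- g$snps$pos[idx]
    if (length(idx) < params$window_min_snps) next  # chromosome too sparse
    for (i in si) {
      runs <- roh_chromosome(g$calls[i, idx], pos, params)
      if (!is.null(runs)) {
        res[[length(res) + 1L]] <- data.frame(
          sample_id = ids[i], chrom = ch, start_bp = runs[, 1],
          end_bp = runs[, 2], n_snps = as.integer(runs[, 3]),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else {
    data.frame(sample_id = character(), chrom = character(),
               start_bp = integer(), end_bp = integer(), n_snps = integer())
  }
  out$length_kb <- (out$end_bp - out$start_bp) / 1000
  rownames(out) <- NULL
  out
}

#' Proportion of individuals with a run in each length class
#'
#' For each length bin, the fraction of individuals having at least one run
#' whose length (bp) falls in the half-open interval.
#'
#' @param rohs data.frame from [detect_roh()].
#' @param sample_ids all individuals of the population (including those with
#'   no runs).
#' @param breaks_mb bin edges in Mb, e.g. `c(0.5, 1, 2.5, 5, Inf)`.
#' @return data.frame with `bin`, `proportion`.
#' @export
roh_length_class_summary <- function(rohs, sample_ids,
                                     breaks_mb = c(0.5, 1, 1.5, 2.5, 5, 10, Inf)) {
  len_mb <- (rohs$end_bp - rohs$start_bp) / 1e6
  bins <- cut(len_mb, breaks = breaks_mb, right = FALSE)
  prop <- vapply(levels(bins), function(bn) {
    length(unique(rohs$sample_id[!is.na(bins) & bins == bn])) / length(sample_ids)
  }, 0)
  data.frame(bin = levels(bins), proportion = unname(prop),
             stringsAsFactors = FALSE)
}

#' Mean total run length versus minimum run length
#'
#' For each grid value L, the mean over individuals of the summed length of
#' their runs of length at least L. Non-increasing in L by construction.
#'
#' @param rohs data.frame from [detect_roh()].
#' @param sample_ids all individuals of the population.
#' @param min_length_grid_mb minimum single-run lengths (Mb).
#' @return data.frame with `min_length_mb`, `mean_total_mb`.
#' @export
mean_total_roh_length <- function(rohs, sample_ids,
                                  min_length_grid_mb = seq(0.5, 5, by = 0.5)) {
  len_mb <- (rohs$end_bp - rohs$start_bp) / 1e6
  mt <- vapply(min_length_grid_mb, function(L) {
    keep <- len_mb >= L
    sum(len_mb[keep]) / length(sample_ids)
  }, 0)
  data.frame(min_length_mb = min_length_grid_mb, mean_total_mb = mt)
}
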