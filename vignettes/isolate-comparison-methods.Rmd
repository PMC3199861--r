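---
title: "Comparing a genetic isolate with an outbred cohort: models and methods"
author: "isopop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing a genetic isolate with an outbred cohort: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`isopop` quantifies how a putative genetic isolate differs from an outbred
reference population, and how much of any apparent difference is an
artifact of over-sampled families rather than isolation itself. This
vignette records the models, the defaults and why they were chosen, the
numerical decisions, and what the synthetic-data tests do and do not
establish about real data.

## The synthetic two-cohort generator

No real cohort ships with the package; every analysis is exercised on
simulated cohorts whose ground truth is recorded. The generator is a
stand-in: nothing is known about the true demographic history of any
particular isolate, so the aim is to reproduce the *statistical structure*
the analyses consume, not a demography.

**Divergence.** Population allele frequencies follow the Balding–Nichols
model: given an ancestral frequency $p$ drawn uniformly on `maf_range`
(default 0.01–0.5), population $i$ draws its frequency from
$\mathrm{Beta}\!\left(p\frac{1-f_i}{f_i},\,(1-p)\frac{1-f_i}{f_i}\right)$,
which has mean $p$ and variance $f_i\,p(1-p)$. This is the natural
generative counterpart of the Weir–Cockerham $F_{ST}$ being estimated. The
two cohorts need not drift equally: `isolate_drift_share` (default 0.75)
sets the fraction of the total drift carried by the isolate,
$f_1 = 2s f,\ f_2 = 2(1-s)f$, so the pairwise divergence stays at the
configured `divergence_fst` while the isolate, having the smaller founder
pool, accumulates more frequency variance — which is what produces its
rare-variant excess. With $s = 0.5$ drift is symmetric and the excess
disappears; recovery of the *pairwise* $F_{ST}$ is unaffected by $s$
(verified in the test suite).

**LD.** Haplotypes come from a first-order latent-copying process: a latent
uniform variate is carried from one SNP to the next with probability
$e^{-d/L}$ ($d$ the inter-SNP distance, $L$ = `ld_decay_bp`, default
25 kb) and redrawn otherwise; the allele is the indicator that the latent
variate falls below the SNP's frequency. For equal frequencies the allele
correlation at distance $d$ is exactly $e^{-d/L}$, so the decay scale is a
direct dial. This is *not* a coalescent: it produces a single smooth decay
with no block structure, no hotspots and no allele-frequency–dependent LD.
It is sufficient to exercise distance binning, proxy search and the ROH
caller; conclusions about real LD landscapes do not follow from it.

**Families.** Pedigree units (parent–offspring trios, sib pairs, first
cousins, first-cousin matings) are planted into the isolate by Mendelian
transmission of the simulator's phased haplotypes with crossovers at
exponential spacing (`recomb_rate_per_bp`, default $10^{-8}$, i.e.
1 cM/Mb). True kinship is computed from the pedigree by the tabular method
and reported on the relatedness scale (parent–offspring 0.5, first cousins
0.125, diagonal $1+F$). A cousin-mating offspring has $F = 1/16$ and is the
generator's source of autozygous segments; `inbred_fraction` sets how many
such individuals the isolate contains. ROH enrichment is therefore produced
by explicit consanguinity, not by tuning an effective population size —
directly testable, at the price of realism of the segment-length spectrum.

**Artifacts.** Per-platform missingness and frequency shifts on one
platform emulate the multi-chip genotyping of real isolate samples; the
affected SNP ids are recorded so QC sensitivity and specificity are
measurable.

One RNG stream per run, seeded from `seed`; stage order is fixed, so a
given configuration is bit-reproducible.

## Quality control

Three per-SNP filters, removed as a union (a SNP failing twice is removed
once): combined-cohort call rate strictly below 0.95; the stratified HWE
test at $p < 10^{-6}$; the between-platform allele-frequency test at
$p < 10^{-7}$.

The stratified HWE statistic sums, over strata $s$, the signed heterozygote
deficits $d_s = O_s - E_s$ with $E_s$ and $\mathrm{Var}_s$ the exact
finite-sample (Levene) moments of the heterozygote count given the stratum
allele count, and refers $Z = \sum_s d_s / \sqrt{\sum_s \mathrm{Var}_s}$ to
a standard normal. Two properties pin this construction: with one stratum
it *is* the classic score test (asserted to $10^{-12}$ in the tests), and
strata in HWE at different frequencies produce no Wahlund rejection. The
normal reference is slightly anticonservative for very small strata; the
type-I test at $10^{-6}$ over $6\times10^4$ null SNPs bounds the damage.

The platform test works on allele counts (matching the frequency framing of
the problem), chi-square without continuity correction when all expected
cells reach 5, otherwise an exact hypergeometric two-sided p computed by
direct summation — the same routine handles genome-scale tables
(`stats::fisher.test` refuses them) and is asserted against `fisher.test`
on small ones.

## Relatedness

The estimator standardises genotypes by in-sample allele frequency and
averages $(x_i-2\hat p)(x_j-2\hat p)/(2\hat p(1-\hat p))$ over SNPs with
MAF ≥ 0.01, using per-pair complete cases. Its calibration anchor is the
first-degree expectation of 0.5. Frequencies are computed within each
population by default, so stratification does not leak into r̂. Two
finite-sample effects are worth knowing: in-sample frequencies bias r̂
downwards by $O(1/n)$ (noticeable below ~50 individuals, and in cohorts
dominated by large families), and low-MAF SNPs make it heavy-tailed.

Unrelated subsets are built greedily: repeatedly remove the individual with
the most partners above the cutoff (default 0.2, strict), ties broken by
the larger maximum r̂ and then by sample id — the tie-break is a package
decision, fixed so runs are reproducible. Greedy removal is not guaranteed
maximal; a property test bounds the gap to the exhaustive optimum on small
problems. Related-pair odds ratios are reported both as sample ORs with
Woolf intervals and as conditional-MLE ORs; on published contingency counts
the two differ in rounding, and the conditional MLE is the one that
reproduces the printed values at every threshold.

## Rare SNPs

"Rare" is an inferential statement: the Clopper–Pearson 95% interval for
the MAF must lie below 1%. The threshold function inverts the interval once
per realized chromosome count (so missingness lowers the bar SNP by SNP;
whether the original analyses used nominal or realized counts is not
documented, and realized counts are the reading consistent with an interval
about *observed* alleles). Below ~370 chromosomes even zero copies fail the
criterion, since the $k=0$ upper bound $1-0.025^{1/n}$ exceeds 1%.

## F-statistics

Weir–Cockerham variance components are computed per SNP from complete-case
sample sizes, allele and heterozygote frequencies, and combined as ratios
of sums — never means of ratios, which would weight SNPs by their own noise
(the test suite asserts the distinction against an independently coded
oracle). $F_{IS} = 1 - \sum c / \sum(b+c)$ from the within-population
components; $F_{ST} = \sum a / \sum(a+b+c)$. Standard errors are
delete-one-individual jackknives, recomputed incrementally from cached
per-SNP sufficient statistics so the total cost stays $O(nm)$. The
jackknife is validated against the exact closed form for the sample mean
and against the true replicate sampling SD for $F_{ST}$; the naive
with-replacement bootstrap is *not* a usable yardstick at small $n$ (it
inflates the variance severalfold by duplicating individuals).

## Runs of homozygosity

The caller reproduces the windowed mechanism: kb-length windows anchored at
every SNP (truncated end-of-chromosome windows count only while they hold
`window_min_snps`), a homozygosity vote per SNP, gap splitting, then
length / SNP-count / density filters. Run length is last-SNP minus
first-SNP position — flanking half-intervals are not added (the choice is
ambiguous in the tools of record; this one is fixed and documented). A
heterozygote can sit inside a reported run if the vote admits it; the
mechanism is reproduced faithfully rather than idealised. Equivalence with
a brute-force enumeration oracle is asserted on random fixtures, which is
the strongest statement the package makes about the caller.

Note an interaction that matters in practice: with dense panels a 5000-kb
window holds on the order of a thousand SNPs, so the default allowance of
five missing calls per window tolerates only ~0.5% missingness. The
synthetic studies therefore use post-QC array-scale missing rates (0.2%).

## Linkage disequilibrium

Haplotype frequencies for a SNP pair come from the standard two-locus EM on
unphased complete-case genotypes (the double heterozygote is the only
ambiguous class). From the fitted table: $D$, $r$, $|D'|$, the odds ratio
$\lambda$, and $\eta_1$.

$\eta_1$ is defined operationally: $|\eta_1|$ is the probability that a
haplotype-frequency vector drawn uniformly on the 3-simplex shows a smaller
$|\log\lambda|$ than observed, signed by $\log\lambda$. The defining
closed form is not reproduced here; the percentile semantics is
implemented directly via a cached Monte-Carlo quantile table
($10^6$ Dirichlet(1,1,1,1) draws, fixed seed, 4096-point grid with linear
interpolation), and a fresh independently-seeded Monte-Carlo estimate is
the authority the table is tested against. Whether "less extreme LD" should
be read on $|\log\lambda|$ or another monotone scale is ambiguous; the
$|\log\lambda|$ reading is implemented, and since any monotone transform of
$|\log\lambda|$ yields the same percentile, the choice matters only if
extremeness were defined on a non-equivalent ordering. Oddness
($\eta_1(1/\lambda) = -\eta_1(\lambda)$) holds by construction; strict
monotonicity is asserted on the grid.

Profiles average a measure in half-open 5-kb distance bins and smooth bin
means over midpoints by LOWESS with span 0.3 and one robustness iteration
(there is no canonical span for decay figures; 0.3 is smooth enough to
read a decay without erasing it, and it is configurable). Pairwise EM cost
grows quadratically, so the pipeline caps the number of profile SNPs
(`ld_max_snps`, default 300).

## PCA

Balanced subsamples (default 50 per group) are drawn greedily to minimise
within-selection relationships, because eigenvector geometry distorts under
unequal group sizes. Genotypes are centred and scaled by
$\sqrt{p(1-p)}$; each SNP is residualised on its `ld_regress_snps` (default
2) predecessors on the same chromosome; individuals beyond 6 SDs on any of
the top 10 components are removed and the decomposition recomputed, up to 5
iterations. The outlier rule (6 SD, top 10, per component) follows the
convention of the standard software since only the iteration count is
documented; all three values are configurable. Components are oriented so
the largest-magnitude score is positive. On LD-free data the LD correction
is only *statistically* null — finite-sample regression coefficients are
$O(1/\sqrt n)$ — so the tests assert stability of the structured axis, not
bitwise invariance.

## Power under proxy testing

With $\beta_1 = 1$ and $s_1$ explaining $v_s$ of the phenotype variance,
the residual variance is $\sigma^2 = \mathrm{Var}(s_1)(1-v_s)/v_s$ and the
OLS slope on the proxy $s_2$ is, conditional on genotypes, normal with mean
$\sum(s_{2i}-\bar s_2)s_{1i}/\sum(s_{2i}-\bar s_2)^2$ and variance
$\sigma^2/\sum(s_{2i}-\bar s_2)^2$. Two-sided power at level $\alpha$ is
$\Phi(-z_{1-\alpha/2}+|\mathrm{ncp}|)+\Phi(-z_{1-\alpha/2}-|\mathrm{ncp}|)$.
This formula was re-derived and is validated against a Monte-Carlo OLS
oracle; the Monte-Carlo test estimates $\sigma$ from residuals as a real
analysis would, so the agreement also covers the $t$-versus-normal gap at
the cohort sizes used (hundreds of individuals).

Under correlated phenotypes, draws follow
$y = s_1 + g + \varepsilon,\ g \sim N(0, \sigma_g^2 G)$. The variance
components come from $(v_s, h^2)$ by normalising the total variance to
$\mathrm{Var}(s_1)/v_s$ and scaling the polygenic share by the mean
diagonal of $G$ — the normalisation is stated explicitly because it is the
one free choice in mapping heritability to components; it makes
$h^2 = v_s$ collapse exactly onto the analytic model, which is the
reduction the tests assert. $G$ is clipped to positive semidefinite when
estimated relatedness has small negative eigenvalues (logged). The naive
analysis estimates its residual variance from residuals — precisely what
produces mis-calibration under relatedness. Variance inflation is the
empirical variance of the slope over draws divided by the nominal
uncorrelated variance; the closed-form sandwich
$s_2^{c\top}(\sigma_g^2 G + \sigma_e^2 I)s_2^c / (s_2^{c\top}s_2^c)^2$ is
the oracle it is tested against. Inflation requires relatives to share
*both* phenotype correlation (through $G$) and genotype at the tested
locus; the test fixture therefore gives sib pairs identical proxy
genotypes, the configuration in which the sandwich predicts a 1.5-fold
inflation at $h^2 = 1$.

The direction of the power shift follows from widening the estimator
distribution around its mean: power is lost where the critical value sits
below the noncentrality (liberal thresholds, high power) and gained where
it sits above (stringent thresholds, low power). Both directions are
asserted on the sib-block fixture with the noncentrality placed between
$z_{0.975}$ and $z_{1-10^{-7}/2}$.

## Problem sizes and seeds

The test suite runs cohorts of 40–600 individuals and panels of 100–20 000
SNPs; the acceptance script uses one 500+500 × 50 000 cohort for
genome-scale $F_{ST}$ recovery and 20 replicates of 200+200 × 4 000 per
divergence level — sizes at which every asserted tolerance (10% relative on
$F_{ST}$ recovery, 3 Monte-Carlo SEs on $\eta_1$ and power) has comfortable
margin by the SE arithmetic shown above. All stochastic tests fix their
seeds; the acceptance script derives every stream from its `--seed`
argument.

## Known limitations

- The generator's LD has no block structure and its site-frequency spectrum
  is uniform-ancestral, not neutral-coalescent; passing tests certify the
  estimators, not demographic realism.
- The relatedness estimator inherits the $O(1/n)$ in-sample-frequency bias
  and is noisy on low-MAF SNPs; pedigree recovery tests use cohorts of 100+.
- The stratified HWE construction and the relatedness estimator are this
  package's concrete realisations of methods that exist in several variants
  in the literature; both are pinned by their documented reductions (the
  single-stratum score test; the first-degree expectation of 0.5) rather
  than by any one published formula.
- X chromosomes, multiallelic sites and BGEN/Oxford formats are out of
  scope; VCF support is biallelic GT-only.
- The greedy unrelated-subset algorithm is deterministic but not maximal.
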