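---
title: "Methods and design of poolpig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of poolpig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

poolpig implements replicated pooled extreme-phenotype association
mapping (Pool-GWAS) and the companion analyses used to dissect the
genetic basis of *Drosophila* trident pigmentation. This vignette is the
package's account of the underlying models, the parameters that matter,
the numerical conventions, and what its synthetic-data experiments do and
do not demonstrate.

## 1. Data model

A pooled experiment sequences, per replicate, one pool of extremely light
and one pool of extremely dark individuals. The unit of data is the
**sync** site: chromosome, 1-based position, reference base, and one
vector of six counts (A, T, C, G, N, deletion — the popoolation2 column
order, fixed by `SYNC_CATEGORIES`) per pool. All coordinates in the
package are 1-based and fully closed; BED input (0-based, half-open) is
converted at the boundary by `read_bed()`.

`call_biallelic()` reduces each site to its two most frequent bases
summed across all pools (N and deletions never qualify as alleles), with
ties broken by the fixed order A < C < G < T so that calling is
deterministic and invariant to pool order. Depth in the remaining
categories is kept per pool (`other`) so that filters can reject sites
with substantial third-allele depth rather than silently absorbing it;
the 2×2×K association design requires genuinely biallelic strata.
**Coverage** of a site in a pool is the sum over all six categories —
read depth at the site includes N and deletion calls; a base-only
definition is available via the `coverage_categories` field of
`filter_config()` for users who prefer it.

## 2. Site-inclusion filters

`apply_filters()` evaluates, in a fixed order chosen for reproducible
failure attribution (coverage → minor allele count → high coverage →
placement/strand → interval mask):

* **Coverage**: every pool ≥ `min_coverage_per_sample` (default 15
  reads), bound inclusive.
* **Minor allele count (MAC)**: the site's dataset-wide minor allele must
  appear ≥ `min_minor_count_per_population` times (default 8) in each
  population, summed over all of that population's pools. Counting the
  minor allele per pool instead would conflate replicate-level sampling
  noise with the population-level floor this filter is meant to impose.
* **High coverage**: per pool, the empirical `high_coverage_quantile`
  (default 0.98) of coverage over the whole dataset is the cutoff;
  a site is excluded when any pool strictly exceeds its cutoff, removing
  the ~2% most highly covered sites, which are enriched for collapsed
  repeats and copy-number artefacts. The quantile is the inverse-ECDF
  (type-1) quantile, so with coverages 1..100 the cutoff is exactly 98.
  It is computed per pool over the whole dataset, not per chromosome arm
  (coverage profiles are pool properties; a per-arm variant would make
  cutoffs depend on arm length).
* **Read placement**: the mean distance of an allele's supporting base
  calls from the nearer read end must be strictly greater than
  `min_mean_end_distance` (default 8 bases) for both alleles — alignment
  artefacts concentrate near read ends; a value of exactly 8.0 fails.
* **Strand balance**: evaluated on the minor (variant-supporting)
  allele's forward/reverse counts. The published form of this rule,
  `max(fwd/rev, rev/fwd) > 0.1`, is satisfied by every table with any
  nonzero count (the maximum of a ratio and its reciprocal is at least
  1), i.e. it never filters anything. The default therefore uses the
  `min` aggregator — neither strand may be in worse than a 10:1 deficit
  at the default threshold 0.1 — which preserves a functioning filter;
  `strand_ratio_aggregator = "max"` reproduces the literal published
  behaviour. When the ratio condition fails, a two-sided Fisher exact
  test on the {major, minor} × {forward, reverse} table arbitrates: the
  site still passes if p > `strand_fisher_p_threshold` (default 0.01),
  so that low-count fluctuation does not kill sites. Ratio conventions:
  0/x = 0 and x/0 = ∞ for x > 0. Sites without metadata are marked
  untestable, never silently passed.
* **Interval masks**: sites within `indel_mask_radius` (default 5 bases)
  of an indel's reference footprint — the masked range is
  `[pos − radius, pos + length + radius]`, inclusive — or inside any
  repeat interval are removed.

Because all rules are per-site predicates, the surviving set is the
intersection of the individual rules and is independent of evaluation
order; only the attribution of a failure to its first failing rule
depends on the order. Both properties are asserted in the test suite, as
is monotonicity: raising any threshold never enlarges the surviving set.

## 3. Replicated association testing

For each site, `cmh_pipeline()` builds one 2×2 table per replicate (rows
light/dark pool, columns major/minor allele) and computes:

* the **CMH statistic**
  `(|Σ_k (a_k − E a_k)| − c)² / Σ_k Var(a_k)` with conditional
  hypergeometric moments given the stratum margins, referred to a 1-df
  chi-square. The continuity correction `c = 0.5` is **on by default**,
  matching the default of the standard implementations this field uses
  (e.g. `stats::mantelhaen.test`); it is exposed as a flag because the
  corrected test is conservative (see §7). Strata with an empty margin
  contribute nothing; a site with no informative stratum is untestable.
* the **Mantel–Haenszel odds ratio**
  `OR_MH = Σ_k (a_k d_k/n_k) / Σ_k (b_k c_k/n_k)` and its 95% interval
  from the Robins–Breslow–Greenland variance of `log OR_MH` — the
  standard asymptotic interval for stratified 2×2 tables. No continuity
  constant is added to zero cells: the MH estimator tolerates zeros
  unless an entire denominator vanishes, in which case the OR is
  reported as infinite and the interval as unbounded (`NA`), explicitly
  rather than clamped.
* `log(OR_MH)` as the effect-size proxy.

**Autosomal downsampling.** In males the X chromosome is sequenced at
half the autosomal depth, and CMH p-values scale with counts. For
cross-chromosome comparability the p-value pathway downsamples autosomal
counts to `downsample_fraction` (default 0.5) by a multivariate
hypergeometric draw (sampling reads without replacement), which preserves
expected allele frequencies and conserves the reduced total exactly
(`floor(total × fraction)`). Odds ratios and allele frequencies always
use full counts. One draw is made per site (reproducible under the
session seed); a site whose downsampled total drops below one read in
some pool is excluded from the p-value pathway. Averaging several draws
would shrink the Monte-Carlo noise of individual p-values but break the
simple "one experiment, one scan" semantics; users wanting a median over
draws can rerun the pipeline.

**Empirical FDR.** Genome scans of strongly structured genomes (here: a
common cosmopolitan inversion) violate the assumptions of
theoretical-null FDR procedures, so significance is controlled against
an empirical null: a set of p-values from a contrast expected to carry
no phenotype signal. At each candidate threshold t (the sorted observed
p-values), `empirical_fdr()` estimates
`FDR(t) = (#{null ≤ t} · N_obs/N_null) / max(1, #{obs ≤ t})` and reports
the largest t with estimated FDR ≤ q (default 0.05). Two null
constructions are provided, and the choice is the user's (the cited
literature does not fix one): `null_contrast_same_pool()` contrasts pools
of the same phenotype class across replicates, and
`null_within_pool_split()` randomly splits each pool's reads in half and
contrasts the halves. A single null draw is noisy in the extreme tail
(with N_null ≈ N_obs, the race between the observed and null minima can
certify a handful of spurious sites at FDR 0); concatenating several
split draws, as in the README example, stabilises the tail.

## 4. Inversion frequencies and the arcsine-sqrt model

An inversion's frequency in a pool is estimated as the **median** of the
per-marker frequencies of its diagnostic alleles (marker count over the
site's A+C+G+T depth) over the markers covered in that pool; the median
is robust to individual misbehaving markers, and markers with zero
coverage are skipped, never imputed. The same estimator serves
species-diagnostic contamination markers.

Association with the light/dark contrast is tested by ordinary least
squares on the arcsine-square-root transformed frequencies
(`asin(sqrt(f))`, the classical variance-stabilising transform for
binomial proportions) with categorical population and pool predictors —
one row per pool, since replicate pools are independent estimates and
averaging them first would discard the between-replicate variance the
t-test needs. Treatment coding with light as reference is used; for a
binary factor the pool coefficient's two-sided p-value is
coding-invariant. The p-value is Bonferroni-corrected over `family_size`
(default 7, the cosmopolitan inversions typically screened together with
this marker framework; configurable).

## 5. Read-pair haplotypes and LD

Fragments (read pairs) spanning several focal SNPs observe a haplotype
directly. `count_haplotypes()` tallies allele strings over fragments
covering **all** requested loci; fragments whose two reads disagree at a
locus are discarded entirely (a disagreement signals a sequencing error
with no way to arbitrate), and consistent duplicate calls count once.
Only direct evidence is used — no EM over partially covering fragments —
because directly counted configurations are auditable and the focal SNPs
here are close enough for a single insert to span them; an EM extension
is out of scope. No base-quality threshold is applied by default (the
fragment table is assumed pre-filtered); this is a documented assumption.
Two-locus `D` and `r² = D²/(p_A(1−p_A)p_B(1−p_B))` are computed from the
counted haplotype frequencies; a locus monomorphic among counted
haplotypes yields an explicitly flagged undefined result, not 0.

## 6. In-silico Pool-GWAS

`run_experiment()` simulates the mapping experiment from a haplotype
model: each individual carries **one** haplotype (the focal enhancer SNPs
are X-linked and the phenotyped individuals are males, hence hemizygous;
a diploid mode exists but is off by default), receives a phenotype equal
to the haplotype's base pigmentation score plus Gaussian noise with

    sd = sqrt( V_G (1 − h²) / h² ),

where V_G is the frequency-weighted variance of the base scores — this
makes h² the realised narrow-sense heritability of the simulated
phenotype. Defaults: 5 replicates × 1500 individuals, pools of the 100
lightest and 75 darkest, h² = 0.2 (the three focal SNPs plausibly explain
only a fraction of phenotypic variance). Lower phenotype value = lighter,
matching the 255-minus-pixel intensity scale (§8). Selection ties at a
pool boundary are broken by a seeded random permutation; pools are
disjoint by construction. Per SNP, D/L allele counts of the pools are
CMH-tested with K = replicates; strata are oriented so a positive
`log OR` means the D allele is enriched in the dark pool.

`coupled_snp_model()` ships an **illustrative** three-SNP model with the
qualitative haplotype structure of interest: SNP1 and SNP2 fully coupled
(alleles occur only in the LL and DD combinations, i.e. four haplotypes
DDD, DDL, LLD, LLL), SNP2's isolated effect lightening and opposed to
the coupled pair's net darkening effect. Under full coupling over three
SNPs only four haplotype strings exist; studies reporting a fifth
occurring haplotype necessarily observed a rare coupling-breaking
configuration, whose identity and frequency must come from the user's
own data. The shipped frequencies and scores are simulation defaults,
not estimates from any population; replication work supplies its model
via `haplotype_model()`/`read_haplotype_model()`. With this structure
the apparent direction of SNP2's effect in the pooled contrast is the
*opposite* of its isolated effect — the coupled pair segregates as a
unit and the pair's net effect wins — which the test suite verifies
against a zero-noise deterministic ranking oracle.

## 7. Synthetic pooled experiments and calibration

`generate_pool_experiment()` emulates the structure of a two-population
replicated experiment: Vienna-like (2 replicates, 120/120 light/dark
individuals) and Bolzano-like (3 replicates, 100/50 — dark individuals
are scarce), per-pool read depths drawn uniformly from a coverage range
(default 54–112×), neutral allele frequencies from a truncated
Beta(0.2, 0.2) U-shaped spectrum, and optional planted causal sites
whose pool frequencies arise from the §6 machinery (phenotype the
replicate, select extremes, count alleles). Reads are binomial draws
from the pool allele frequency; an optional beta-binomial
`overdispersion` parameter is available because real Pool-seq is
overdispersed, but the default is pure binomial.

Two modelling points matter for calibration:

* **Neutral sites draw reads from one shared frequency in both pools.**
  Resampling pool-level frequencies (individuals) per pool at neutral
  sites would add between-pool variance that the read-level CMH null
  does not model, and the scan would be anti-conservative by
  construction — a real phenomenon in Pool-seq, but one that belongs to
  the overdispersion knob, not to the null calibration experiment.
  Causal sites do model individual sampling, through extreme-pool
  selection.
* **The calibration scenario uses depths 54–66× (nominal 60×) and the
  uncorrected statistic.** Replicate depths in such experiments are
  never exactly equal, and with exactly equal light/dark depths the
  conditional expectations are half-integers, lattice-ing the statistic.
  The 0.5 continuity correction maps every stratum-sum deviation below
  0.5 to p = 1, an atom of ~4% of null sites, so corrected p-values are
  by design not uniform: across the calibration experiment the corrected
  test rejects ~3.9% at the 0.05 level (conservative), the uncorrected
  test ~5.0%. Uniformity (Kolmogorov–Smirnov) is therefore asserted for
  the uncorrected p-values; the corrected level is documented here, and
  the correction remains the default for analysis because it is what the
  field's standard implementation applies.

The generator returns ground truth (shared or realised pool frequencies,
causal flags and directions, planted filter violations) sufficient to
score any downstream result without re-simulation.
`generate_filter_fixture()` builds a deterministic 200-site dataset in
which every non-planted site passes every filter by construction
(constant depth 60, mid-range frequencies with clamped per-pool minor
counts, balanced strands, end distances of 25) and one or more sites
violate exactly one rule each; the test suite asserts that the cascade
removes exactly the planted set and attributes each removal to its rule.

**What passing these tests shows — and does not.** The generators
reproduce the sampling structure (replication, pool sizes, depths,
frequency spectrum, selection from phenotype tails) but not mapping
error, base-calling error, indel misalignment, linkage between neutral
sites, or Pool-seq overdispersion (unless enabled). Calibration and
power results on synthetic data therefore validate the statistical
machinery, not the upstream bioinformatics of any particular dataset.

## 8. Trident intensity and the factorial ANOVA

Trident pigmentation is quantified from the mean pixel value inside a
delimited trident polygon as `255 − mean(pixels)`, mapping 0 to white and
255 to black (image segmentation itself is out of scope; pixels or
intensities are inputs). The 2×2×2 transgenic assay (three enhancer
SNPs, alleles D/L, default 10 males per genotype) is analysed with the
full-factorial three-way ANOVA under zero-sum contrasts and **type-III
sums of squares**, computed by model comparison (`car::Anova`); for the
balanced design this equals both the sequential decomposition and the
direct orthogonal projection onto each term's contrast column, and the
implementation asserts that equality on every balanced fit. Saturated or
noise-free balanced fits (zero residual df or zero residual variance,
where model-comparison machinery breaks down) use the projection
decomposition directly and refuse F tests. Unbalanced data (real assays
lose flies) are accepted; the type-III path is then authoritative and
the orthogonality check is skipped. Effect sizes are
`η² = SS_term / SS_total` with SS_total the total sum of squares about
the grand mean — no covariates enter the model, so no other total is in
play; η² rows (residuals included) sum to 1 on balanced data. P-values
are kept at full precision; "<0.001"-style formatting is presentation
only.

`generate_transgenic()` inverts this analysis: given target η² shares
per term it builds cell means from zero-sum contrast coefficients
(`coef_t = sqrt(share_t) · total_sd`) plus Gaussian residual noise
making up the remainder, so the population variance decomposition equals
the plan. Defaults `grand_mean = 140`, `total_sd = 20` intensity units
keep simulated intensities comfortably inside [0, 255] for realistic
plans. At n = 10 per cell the recovered per-term η² is nearly unbiased
(each 1-df term inherits ~σ²_res/SS_total ≈ 0.3% upward bias); the test
suite verifies mean recovery within ±0.05 over repeated simulation.

## 9. Problem sizes and determinism

The test suite and the acceptance script run entirely on synthetic data
generated in-process. Sizes were chosen to make the stochastic
assertions statistically comfortable while keeping a full run in the
order of a minute: 500 factorial datasets for η² recovery, 1000 random
tables for the CMH oracle comparison, 30000 sites (~19000 after
filtering) for null calibration, 200 in-silico experiments for the
sign-reversal property, 1000 simulated inversion experiments for the
model sign rate, and 10⁴ draws for downsampling unbiasedness. All
stochastic tests fix their seeds; `run_experiment()` and the generators
are reproducible given the session RNG state, and identical seeds yield
identical outputs.

## 10. Known limitations

* The CMH test models read sampling only; pool-construction
  (individual-level) variance at non-causal sites is not part of the
  null. On real data this makes the scan anti-conservative when pools
  are small — the replicated design and empirical-null FDR are the
  mitigations, not a fix.
* Fragment-based haplotype counting ignores partially covering
  fragments; with short inserts and distant SNPs the qualifying-fragment
  count can be small, and frequencies are then noisy.
* The inversion model treats pool frequencies as independent
  observations on the transformed scale; it does not model read-depth
  heterogeneity between pools.
* Marker-based inversion frequencies assume the marker panel is
  diagnostic in the studied populations; panel validation is the user's
  responsibility.
* The factorial machinery is specialised to the 2×2×2 design of the
  transgenic assay; larger factorial layouts are out of scope.
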