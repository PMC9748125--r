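---
title: "Composite selection signals: model, assumptions and design choices"
author: "compsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite selection signals: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compsel)
```

## The problem

Strong artificial selection — for example, breeding horses for racing —
leaves footprints in the genome: alleles that rose quickly in frequency
drag long, unusually homogeneous haplotypes with them, and the selected
population differentiates from related, unselected populations around
the favoured loci. No single statistic captures all facets of this
footprint, so composite approaches combine several. `compsel`
implements such a composite scan and the downstream stages that turn it
into testable biology: integration with differentially expressed gene
(DEG) sets, prioritisation of protein-coding candidate variants, and
case-control validation of candidate SNPs in independent cohorts.

## The composite selection signal (CSS)

Three constituent statistics are computed per SNP, contrasting a
*selected* cohort against a *non-selected* reference:

* **F~ST~** — allele-frequency differentiation, Hudson's estimator with
  sample-size correction: numerator
  $(p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1}$,
  denominator $p_1(1-p_2) + p_2(1-p_1)$. Hudson's form is the standard
  two-cohort scan estimator (it is not downwardly biased by unequal
  sample sizes); Weir–Cockerham is available behind
  `fst_per_snp(estimator = "wc")`.
* **ΔSAF** — the signed change in alternate-allele frequency,
  $p_{sel} - p_{ns}$. Whether published scans rank the signed or
  the absolute difference varies by study; the signed form is the
  default (frequency gain in the selected cohort ranks high), the
  absolute form sits behind `absolute = TRUE`.
* **XP-EHH** — for each core SNP, each population's extended haplotype
  homozygosity (EHH) curve is integrated over physical distance in both
  directions until EHH falls below a cutoff (default 0.05) or the
  chromosome end; XP-EHH is the log-ratio of the selected to the
  reference integral. EHH at extension $k$ groups haplotypes by
  identity over the extended interval and computes
  $\sum_g \binom{n_g}{2} / \binom{n}{2}$ over all haplotypes of the
  population (no conditioning on a core allele), which is the form the
  cross-population statistic requires. Integration is over base pairs
  because SNP-array data rarely has a reliable genetic map. Values are
  left unstandardised: the composite score uses ranks, which are
  invariant to monotone standardisation.

Each constituent is ranked genome-wide across all $n$ SNPs (ascending,
ties averaged), converted to fractional ranks $r' = i/(n+1) \in (0,1)$,
then to z-values $z = \Phi^{-1}(r')$. The mean $\bar z$ over the $m$
available constituents at a SNP is referred to its null sampling
distribution $N(0, 1/m)$, giving the one-sided upper-tail
$P = 1 - \Phi(\bar z \sqrt m)$, and $\mathrm{CSS} = -\log_{10} P$. Two
consequences worth knowing:

* a SNP at the median rank of every test has CSS $= -\log_{10}(0.5)
  \approx 0.301$ regardless of $m$;
* with $m = 1$ the whole construction collapses to
  $\mathrm{CSS} = -\log_{10}(1 - r')$.

The upper tail is used because selection inflates the target
population's statistics; published descriptions of the statistic leave
sidedness implicit, so this is a documented package choice. SNPs missing some
constituents use the mean over the available tests with variance
$1/m_{avail}$ (a strict drop mode is available).

CSS is then smoothed: each SNP receives the mean CSS of all SNPs within
half a window of it (SNP-centred, boundaries inclusive). Published
applications describe both 1 Mb and 100 kb windows; both are
supported and 1 Mb is the default. Selection signals are
*clusters of more than five SNPs among the top 1%* of smoothed CSS,
where the threshold is the empirical 99th percentile and top SNPs are
merged while consecutive ones are no further apart than the merge gap
(default: the smoothing window; published applications report region
extents but no merge rule). Clusters are ranked by peak smoothed CSS,
with the mean reported alongside, since published cluster tables do
not state which of the two their score column reports.

## Integration with expression data

Given a DEG set with coordinates, the target SNP set is the
deduplicated union of scan SNPs within $\pm W$ of any DEG (gene body
inclusive, boundaries inclusive). Nominal CSS P values of a set are
converted to local false discovery rates, and the observed count of
SNPs with $q$ below a threshold (0.05 / 0.10 conventions retained) is
referred to a null distribution of `n_null` (default 1000) SNP sets of
exactly the target's size, resampled **with replacement from the whole
scan** (the search space). The permutation P uses the add-one
estimator $(1 + \#\{\text{null} \ge \text{obs}\})/(B+1)$: never zero
at finite $B$, and exactly reproducible given a seed. The width sweep
(default $W$ = 10–100 kb in 10 kb steps) selects the width maximising
the significant count, breaking ties by smaller permutation P and then
smaller width; the same seed is used at every width so that widths
with identical target sets give identical results and the tie-break is
well defined.

### The local FDR estimator

Rather than delegating this step to an external package, the
estimator is part of the package. P values
are mapped to $z = \Phi^{-1}(1-P)$ (null P values are uniform, so null
z-values are standard normal). The null component $N(\mu_0, s_0^2)$ is
fitted by central matching: $\mu_0$ is the median, $s_0$ comes from the
lower-quartile spread ($(\mu_0 - q_{0.25})/0.6745$) because one-sided
signals contaminate only the upper flank, and the null fraction
$\eta_0$ is the central mass below $\mu_0 + s_0$ relative to the fitted
null. The marginal density is a kernel density estimate, and
$q(z) = \eta_0 f_0(z)/f(z)$, clipped to $[0,1]$, set to 1 at and below
the null centre, and monotonised by pool-adjacent-violators so that $q$
never increases as P decreases. PAVA (rather than a running minimum)
matters: a running minimum propagates downward noise wiggles of the
kernel density into the tail and spuriously flags the most extreme
members of perfectly null sets. Agreement with other local-FDR
implementations is claimed only at the level of recovery
properties: on a 95% null / 5% strong-signal mixture of n = 5000 the
estimator recovers $\eta_0$ within a few percent and flags the planted
signals with high sensitivity (this is exactly what the test suite
measures).

### Within-set versus global q-values

The per-set conversion (target set
and every null set converted separately) is the default
(`q_scope = "within_set"`). It has a structural consequence users
should know: a target set *saturated* with true signals fits its
empirical null to the signals themselves and flags almost nothing —
the comparison can even invert. Detection therefore requires the
candidate region to be a small fraction of the scan and the target set
to mix signal and background windows. `q_scope = "global"` estimates q
once on the whole scan and is markedly more powerful in
signal-saturated settings; `match_split = TRUE` additionally matches
each null set's split of globally significant/non-significant SNPs,
for the alternative reading of the matched-null description.

## Variant prioritisation

Within candidate regions, variants pass a pure conjunction of rules:
VEP-style consequence class among `high`
(splice-acceptor — including the combined
`splice_acceptor_variant&intron_variant` annotation — frameshift,
stop-gained) or `moderate` (missense, in-frame deletion), with
multi-term annotations classed by their most severe term and
unrecognised terms demoted to `other` with a notice; minor allele
frequency ≥ 0.1 (published screens state the boundary both exclusively and
inclusively; inclusive is adopted and configurable); quality ≥ 999 by
default (the typical cap — configurable downward since not every
retained variant met it); membership in a known gene (the default;
whether "known genes" meant protein-coding only is unstated, so the
requirement is a flag); and indel length strictly under 50 bp. Because
the filter is a conjunction, the survivor set is independent of rule
order — a property the tests exercise directly.

## Association validation

Genotype QC runs in a fixed order — samples by call rate, SNPs by call
rate, then MAF on the survivors — with two presets: *scan* (SNP
missingness ≤ 10%, MAF ≥ 0.01) and *validation* (SNP call rate ≥ 80%,
sample call rate ≥ 90%). The allelic test is the 1-df Pearson
chi-square on the 2×2 allele-count table without continuity correction
(the convention of the standard association tools, and the one that
reproduces published tables), with OR $= ad/bc$ oriented so allele 1 is
the exposure; the Haldane–Anscombe +0.5 is applied to all cells only
when a cell is empty, and flagged. The quantitative trait uses OLS with
a sex covariate and the Wald statistic $(\hat\beta/SE)^2$ against
$\chi^2_1$; a single-sex cohort drops the covariate with a warning.
Bonferroni thresholds are $\alpha/n$, reported at full precision and at
3 significant figures (0.05/14 = 3.57 × 10⁻³).

Published association tables print allele frequencies rounded to four
decimals and computed on non-missing genotypes, so rebuilding a 2×2
table as `round(freq × 2n)` with the full cohort size occasionally
misses the printed OR. `infer_allele_counts()` recovers the largest
effective allele count (≤ the stated cohort size, stepping by whole
genotypes) whose implied rounded frequency reproduces the printed one;
the rebuilt tables then match published odds ratios and chi-squares to
rounding error. This is how the package recomputes such tables in its
acceptance script.

## The synthetic-data generator

The generator emulates exactly the statistical structure the scan
assumes, at desk scale:

* **Divergence**: ancestral allele frequencies uniform on
  [0.05, 0.95]; population frequencies Balding–Nichols
  $\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$, so the expected Hudson
  F~ST~ is approximately $F$. Default $F = 0.05$, the order of
  differentiation seen between related domestic breeds.
* **LD**: haplotypes are generated sequentially; each new haplotype is
  a mosaic of the previously generated one and fresh Bernoulli draws,
  with the copy/fresh mode persisting along the chromosome with
  probability `ld_copy_prob` per step (first-order Markov). Copying in
  *segments* is what creates genuine empirical LD and haplotype
  sharing; deciding site-by-site independently would leave columns
  independent. One knob therefore controls both haplotype relatedness
  and LD decay. Default 0.3, giving the short-range LD typical of
  array-density data. A side effect worth knowing: copying correlates
  haplotypes, so finite-sample F~ST~ acquires a small upward bias of
  roughly $2c/((1-c)\,n_{hap})$ (≈ 0.009 at the defaults) relative to
  the binomial sampling the Hudson correction assumes; the no-sweep
  calibration tests therefore use `ld_copy_prob = 0`.
* **Sweep**: a "star-like" hard sweep — one founder haplotype
  overwrites a fraction (default 0.9) of selected-population
  haplotypes within ± half-width of the core. This creates the joint
  F~ST~ / ΔSAF / XP-EHH signal without forward simulation; selection
  coefficients, partial soft sweeps and recombination-map realism are
  out of scope. Because the founder's allele at a site may be either
  variant, the *signed* ΔSAF of sweep SNPs points in a random
  direction site by site, which dilutes roughly half the sweep's
  per-SNP composite scores — a realistic feature, since real sweeps
  also drag both alleles.
* **Diploidy**: two consecutive haplotypes form one phased diploid
  sample; panels round-trip through VCF with `|` separators.
* **Seeds are mandatory**; there is no implicit global RNG state, and
  every output is byte-identical given a seed.

Case-control panels are drawn per SNP under Hardy–Weinberg at stated
case/control frequencies (`stochastic`), or constructed to match
`round(freq × 2n)` allele counts (`exact`) for rebuilding published
tables. DEG tables draw adjusted P values log-uniformly inside a
stated range (so an upper bound of 10⁻⁴ reproduces a "P~adj~ < 10⁻⁴"
filter by construction) and can force a chosen number of DEGs to
overlap a given interval to plant true enrichment.

What passing tests on these panels do **not** show: robustness to
demographic confounding (bottlenecks, admixture), to genotyping error,
to unphased or sparsely imputed data, or to soft sweeps — none of
which the generator produces.

## Problem sizes and numerical choices

The simulation-based checks use panel sizes chosen to make the
relevant effects measurable with stable Monte-Carlo error: sweep
recovery uses twenty 2 × 100-haplotype, 2,000-SNP panels on a 10 Mb
chromosome with a ±0.5 Mb sweep at the centre; the planted-enrichment
study uses 2 × 50 haplotypes and 6,000 SNPs on a 40 Mb chromosome with
a ±0.2 Mb sweep at background divergence $F = 0.02$ and sweep fraction
0.95, with four DEG windows tiling the sweep plus eight background
DEGs — a regime where the sweep occupies well under 1% of the scan, as
in real genome-wide data. The detection study runs with
`q_scope = "global"`: on a single simulated chromosome the null sets
resampled from the search space themselves carry the sweep, and the
within-set conversion's saturation behaviour then caps detection near
85% at its empirical optimum across the sweep strength/extent
configurations we profiled (collapsing entirely once targets
saturate), whereas the global conversion detects the same planted
signal in essentially every replicate; the reproduction script reports
both rates. Calibration studies (type-I error of the
allelic and Wald tests, permutation-P exchangeability, pure-null
enrichment) use closed-form or resampling oracles at sizes where the
binomial standard error is a few times smaller than the tolerance
asserted.

Other numerical details: the EHH loop stops at the first point below
the cutoff (which is included in the integral) or at a chromosome end
(flagged `truncated`); zero reference integrals make XP-EHH `NA`
(flagged, logged); top-percentile thresholds use the default empirical
quantile (type 7); fractional ranks of tied values are averaged, which
keeps $r'$ strictly inside (0, 1); degenerate local-FDR inputs (all P
identical) return $q = 1$ with a warning rather than an error.

## Known limitations

* The within-set q conversion's saturation behaviour (above) is
  inherent to the per-set conversion; use `q_scope = "global"` when
  target sets may be signal-dominated.
* XP-EHH needs phased haplotypes; the reader rejects unphased records
  rather than imputing phase.
* The scan assumes a single chromosome per panel; multi-chromosome
  data are handled at the table level (ranking and smoothing are
  genome-wide and per-chromosome respectively) but panels are
  per-chromosome.
* Cluster bounds are member-SNP extents; they do not extend into
  flanking SNP-free sequence.
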