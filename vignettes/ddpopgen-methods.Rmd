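---
title: "Population-genetic and social-evolution methods in ddpopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-genetic and social-evolution methods in ddpopgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddpopgen)
```

`ddpopgen` analyses multi-fragment re-sequencing panels of haploid strains
— the kind of data produced by surveying wild *Dictyostelium discoideum*
isolates at ~137 gene fragments (400–600 bp each, one chromosome sampled
densely) — and the chimeric fruiting-body mixing experiments used to
quantify kin discrimination in that system. This vignette explains the
models behind each module, the tunable parameters, and the choices made
where the design was genuinely open.

## Diversity statistics

For `S` biallelic segregating sites among `n` strains over `L` surveyed
bp, the package reports Watterson's estimator
$\theta_W = S / (a_n L)$ with $a_n = \sum_{i=1}^{n-1} 1/i$, the
nucleotide diversity $\pi$ (mean pairwise difference per site), and
Tajima's D with the 1989 constants.

Missing data (gaps and `N`s are both "missing") are handled by pairwise
deletion: each strain pair's raw mismatch count over its jointly-callable
sites is rescaled by `S / callable` before averaging, so a pair that
happens to miss a few SNP calls is compared on the same footing as a
complete pair. For $\theta_W$, `S` counts sites that are biallelic among
non-missing calls and `L` is the total surveyed length. Tajima's D uses
constants computed from the panel `n`, not a per-site `n`; at the
sporadic missingness these panels show (a few percent) the deviation is
negligible, and the simplification keeps D well-defined per fragment.
Sites with more than two observed alleles are excluded (and counted);
invariant fragments have no D, matching the convention that only
variable fragments enter D histograms. Hudson's
$F_{st} = 1 - H_w/H_b$ uses the mean within-group pairwise diversity
(two group means averaged) against the mean between-group diversity.

Both a pooled $\theta_W$ (total S over total L) and the mean of
per-fragment values are reported, because for a multi-fragment panel
either bookkeeping is defensible and published tables rarely say which
was used.

## Linkage disequilibrium

LD between two sites is $r^2 = D^2/(p_1(1-p_1)q_1(1-q_1))$ with
$D = p_{11} - p_1 q_1$ computed from complete-case haplotype counts
(haplotypes are observed directly — the organism is haploid). Sites
below 10% minor-allele frequency are removed once, globally, before any
pair is formed; rare alleles make $r^2$ extremely noisy. Pairs with a
monomorphic complete-case margin are dropped and counted.

The decay profile bins same-chromosome pairs into the study's distance
classes (<0.1 kb, 0.1–0.5 kb, 0.5–10 kb, 10–25 kb, 25–50 kb, 50–100 kb,
100 kb steps to 1 Mb, then 1 Mb windows; left-closed, right-open). The
baseline is estimated from cross-chromosome pairs: their mean $r^2$ and
80th percentile. A bin counts as "elevated" only when it holds more than
10 pairs *and* its mean exceeds that 80th percentile — with no unlinked
pairs the flags are withheld rather than guessed.

The decay test permutes distances against $r^2$ values (1000
permutations by default) and reports a one-sided add-one p-value for
negative association. The correlation statistic is Spearman by default —
the $r^2$ distribution is strongly skewed, with an atom near 1 from
within-fragment pairs — with Pearson behind a flag.

## Recombination

Three complementary views:

1. **Four-gamete / Hudson–Kaplan.** Two biallelic sites showing all four
   haplotypes among complete-case strains imply a crossover (or
   recurrent mutation). `minimum_recombination_events()` collects
   incompatible pairs as intervals, discards intervals containing
   another, and greedily selects disjoint intervals by right endpoint;
   Rm is the count. Breakpoints fall strictly between sites, so disjoint
   intervals may share an endpoint site.

2. **Moment estimator.** `wakeley_rho()` equates the observed sample
   variance of pairwise difference counts to its coalescent expectation
   $\bar K + \sum_s \theta_s^2 + \sum_{s\neq s'} \theta_s\theta_{s'}
   C(\rho d_{ss'}/\mathrm{span})$, where
   $C(\rho) = (\rho+18)/(\rho^2+13\rho+18)$ is the standard two-locus
   coalescence-time covariance for a pair of sequences and the per-site
   rates $\theta_s = \bar K/S$ sit on the observed SNP positions (the
   distance-weighted summation). The equation is solved by bisection
   (tolerance 1e-3 on $\rho$, upper bracket $10^4$); estimates that hit
   a boundary are flagged, including a `no_recombination_signal` flag
   when the observed variance already exceeds the $\rho = 0$
   expectation. One approximation is deliberate: the model matches the
   *marginal* variance of a pair's difference count, ignoring the
   covariance between strain pairs that share a sequence. That inflates
   the estimate somewhat relative to the composite-likelihood one — the
   same ordering the moment-vs-likelihood comparison shows on real
   panels — and is why the likelihood estimate is the headline number.

3. **Composite likelihood.** Following the Hudson/McVean pairwise
   approach, each SNP pair contributes the log-probability of its folded
   two-locus haplotype configuration at per-pair rate
   $\rho_T\, d_{ij}/\mathrm{span}$ (crossover probability linear in bp;
   gene conversion is not modelled), and $\hat\rho_T$ maximizes the
   summed curve over a grid. The per-configuration probabilities come
   from a Monte-Carlo lookup table (`build_two_locus_table()`): for each
   grid $\rho$, two-locus genealogies are simulated (compiled code), one
   mutation per locus is placed uniformly on the marginal tree — the
   $\theta \to 0$ conditioning on segregation — and folded configuration
   frequencies are tabulated. Defaults: 21 grid points on $[0, 100]$,
   $10^5$ simulations per point (a few minutes on one core); the test
   suite and the acceptance script use reduced tables (9 points,
   $2\times10^4$ sims), which is ample for the factor-level recovery
   checks they make. Configurations observed with a smaller
   complete-case sample size than the table's `n` are rescaled and
   matched to the nearest stored configuration, with fallbacks counted;
   zero-count cells get a $0.5/n_{sims}$ floor before logging.

   The significance test permutes SNP positions (columns fixed) and
   re-maximizes. The test statistic is the maximized composite
   log-likelihood: under $\rho = 0$ the likelihood is exchangeable under
   position permutation, while genuine distance-structured LD fits the
   real arrangement better than any shuffle. (A re-maximized-$\hat\rho$
   statistic is available behind a flag, but permuting positions tends
   to *inflate* $\hat\rho$ — incoherent arrangements push the rate to
   the grid cap — so that variant has essentially no power; the
   likelihood statistic is the defensible default.)

## Clustering and geography

Strain relationships use Kimura two-parameter distances on the
concatenated fragments (pairwise deletion; saturated pairs reported as
undefined) and neighbor joining, with column-resampling bootstrap
support on internal bipartitions (fragment boundaries are ignored when
resampling, mirroring a concatenated-data analysis). NJ's occasional
negative branch lengths are clamped to zero with the deficit moved to
the sibling edge, preserving path lengths through the parent.

Geographic distances are haversine km; strains sharing a collection-site
name get a fixed within-site distance (1 km by default, generalizing the
convention used for a densely collected site). Isolation by distance is
a Mantel test: Pearson correlation of upper triangles with a null built
by jointly permuting rows and columns (strain labels) of one matrix —
never cell-wise — one-sided for positive association, add-one rule.

## Social statistics from chimeric fruiting bodies

Pyrosequencing peak heights are calibrated against mixtures of known
allele proportions by OLS (`fit_standard_curve()`, at least three
distinct proportions) and inverted with clipping to $[0,1]$
(out-of-range measurements counted).

For fruiting-body proportions $p_i$ of a focal strain with sample mean
$\bar p$ over bodies, each strain's relatedness in body $i$ is its
frequency deviation scaled by the maximum possible deviation, and the
global statistic weights the two strains by their shares:

$$r_{fb} = \frac{1}{N}\sum_i \left[p_i\frac{p_i-\bar p}{1-\bar p}
 + (1-p_i)\frac{\bar p - p_i}{\bar p}\right].$$

The published rendering of this formula is an unrendered equation image,
so the implementation is pinned instead by its verbal definition and
endpoint constraints: $r_{fb} = 0$ when all $p_i$ are equal (random
clustering), $r_{fb} = 1$ when every body is clonal, and
$\{0.9, 0.1\} \mapsto 0.64$. The same applies to dominance
($d = \mathrm{mean}(p_i) - p_o$, against the *measured* initial-mix
proportion, never an assumed 50:50) and Levene's statistic (mean
absolute deviation from the mean — the standard Levene transform). The
normalizing mean $\bar p$ is the mean over fruiting bodies, not $p_o$.
Marker-level statistics are averaged within pairs, with per-cell values
retained, since the published analysis does not state how its two
technical-replicate markers were combined.

Group comparisons (sympatric vs allopatric pairs) use a one-sided
permutation test on the difference of group means — the published
analysis does not name its test — with a Welch-style alternative left to
the user; regressions of $r_{fb}$ and $|d|$ on SNP divergence report
$R^2$, and a partition at the sample median divergence gives low/high
summaries.

## The synthetic study design

`simulate_study_design()` defines the study conditions every recovery
check runs under: 25 strains; 137 fragments of 400–600 bp; 94 on the
dense chromosome with start-to-start spacings drawn from a shifted
exponential truncated to 2.3–233.7 kb whose mean is solved to hit
55.6 kb; 43 fragments spread over the other five chromosomes in
proportion to their sizes (approximate published chromosome sizes,
34 Mb total); $\theta = 0.0008$ per site; a dense-chromosome $\rho$ of
40 with the same per-bp rate elsewhere; 2% missing calls; and a strain
table with 13 strains at one dense collection site. The coalescent
engine is a Hudson-style ancestral-recombination-graph simulation over
the whole chromosome with infinite-sites mutations confined to the
fragment windows; 0/1 alleles map to A→G transitions on a 78% AT
background (realistic transition-dominated divergence for K2P), and
descendant sets are integer bitmasks, which caps panels at 30 strains.

What the generator does *not* emulate: population structure or
demographic history (it is a neutral panmictic equilibrium model),
selection, gene conversion, sequencing error, and alignment artifacts.
Recovery tests passing on this generator therefore show the estimators
are correct under their own assumptions — not that real isolates satisfy
those assumptions. The interchromosomal baseline $r^2$ it produces is
the panmictic finite-sample value (~$1/n$), noticeably lower than the
published 0.136 baseline, which plausibly reflects structure or
inbreeding in the real sample.

The chimera generator is a clonal/mixed mixture: with probability `s` a
body is clonal (all focal strain with probability $p_o$), otherwise it
sits at $p_o$; truncated-Gaussian noise is added per marker. This model
was chosen because the expectation of the implemented $r_{fb}$ equals
`s` exactly, making recovery checks directly interpretable.

## Numerical conventions and problem sizes

Coordinates are 1-based inclusive. All randomized functions take an
explicit seed and are pure functions of it; `NULL` leaves the caller's
RNG stream untouched. Ties at the composite-likelihood argmax resolve
to the smallest grid value; distance-bin edges are left-closed. The
test suite runs its recovery checks at deliberately desk-scale sizes —
200 neutral replicates for the Tajima's D calibration, 50 study-design
replicates for the $\pi$ band, 50 replicates at true $\rho = 40$ and
100 null runs for the permutation-test calibrations, 30 contiguous
500 kb replicates for the moment-estimator recovery, a 9-point /
$2\times10^4$-sim lookup table — chosen so the whole suite completes in
a few minutes while keeping Monte-Carlo error far inside the asserted
bands. The pipeline (`run_full_analysis()`) logs every parameter and
seed and emits byte-stable JSON for a fixed configuration.

## Known limitations

The composite-likelihood table assumes one shared sample size; heavily
missing pairs are approximated by rescaled nearest configurations. The
moment estimator's marginal-variance approximation biases it upward,
and on sparse fragment layouts (most site pairs far apart, where the
model curve is nearly flat in $\rho$) its sampling distribution is very
wide — it is reliable on contiguous or densely surveyed regions and
should be read as an order-of-magnitude companion to the
composite-likelihood estimate elsewhere.
The ARG simulator is quadratic-ish in $\rho$ and intended for
chromosome-scale $\rho$ up to a few hundred, not genome-wide scans.
Bootstrap supports use strict bipartition matching on unrooted trees;
zero-length (identical-sequence) ties can make deeper joins arbitrary,
as in any NJ implementation.
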