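---
title: "chromTE: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromTE: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Across eukaryotes, regions of low recombination accumulate transposable
elements (TEs) because purifying selection against insertions is less
effective there. Lepidoptera are a striking exception: their smaller
chromosomes recombine *more* per megabase (each chromosome needs at least
one crossover regardless of length), yet they carry *denser* TEs. One
candidate mechanism is non-allelic homologous recombination (NAHR):
recombination between homologous TE copies at different loci deletes the
unique sequence between them, and because NAHR tracks the recombination
rate, small chromosomes would lose inter-TE sequence faster, progressively
compacting their TE landscape.

chromTE implements the statistics needed to interrogate this hypothesis on
chromosome-level assemblies and resequencing data, together with a
generative simulator in which the mechanism is switched on or off at will,
so that every statistic can be validated against known truth.

Three observable signatures distinguish the deletion mechanism:

1. **Density**: repeat density per chromosome is negatively correlated
   with chromosome length.
2. **Spacing ratio**: within each chromosome, the mean distance between
   adjacent *young* TEs (< 5% divergence from the library consensus) and
   between adjacent *old* TEs (5--10% divergence) both grow with
   chromosome size, but their ratio (young/old) *falls* with size --- old
   cohorts on small chromosomes have been compacted by deletion for
   longer, while fresh insertions alone would push the ratio the other
   way.
3. **Population genetics**: if instead weaker purifying selection on small
   chromosomes drove the pattern, the 0-fold/4-fold diversity ratio and
   the estimated strength of selection on deleterious mutations should
   covary with chromosome size. Testing this requires nucleotide
   diversity, degeneracy-classified sites and a DFE estimate per
   chromosome.

## Windowed densities and bootstrap summaries

Densities are computed in 100-kb windows (`window = 100000`), the standard
resolution for chromosome-scale repeat profiles: wide enough that window
density is not dominated by single insertions, narrow enough to give
dozens to hundreds of windows per chromosome for resampling. A trailing
partial window is kept only when it spans at least half a window
(`drop_partial_below = window/2`): shorter remnants give high-variance
density estimates, while discarding up to 50 kb systematically would bias
small chromosomes. Repeat and CDS densities use the *interval union* of
hits, never summed hit lengths, so nested and overlapping annotations
cannot push a density above 1. GC is computed over unambiguous bases only
(a window of Ns is `NA`), and soft-masked lowercase counts normally.

Chromosome-level means carry a percentile bootstrap CI: windows are
resampled with replacement, `B = 1000` replicates, equal weights for all
windows including a retained partial one, with the seed recorded in the
output. The suite verifies 90--98% empirical coverage of the true mean on
Normal window statistics (500 simulated chromosomes of 100 windows).

## Inter-TE spacing and the young/old ratio

Age classes partition divergence: young = [0, 5)%, old = [5, 10]%, more
diverged copies excluded. The old interval is closed at both ends; with
the shared boundary at 5% a copy at exactly 5% is old. Distances are
measured end-to-start within an age class after sorting by start
(ties broken by end): the intervening gap is precisely the sequence NAHR
would delete, which is why gap distance --- not midpoint distance --- is
the default (`mode = "start-to-start"` is available for comparability).
Overlapping or nested pairs get distance 0, copies of the other age class
between a pair do not break it, and the per-chromosome ratio is `NA`
whenever either class has fewer than two copies or the old mean is zero.
An exhaustive nearest-following-neighbour search reproduces the
sorted-adjacent distances on random instances in the test suite.

## Association tests

Spearman's rho is the Pearson correlation of mid-ranks. For n > 10 the
two-sided p-value uses the t approximation
`t = rho * sqrt((n-2)/(1-rho^2))`; for n <= 10 without ties the exact
permutation distribution is used. Lepidopteran chromosome counts (23--31)
put real analyses on the t branch; the exact branch keeps small synthetic
genomes honest. Benjamini--Hochberg correction is applied across an
explicitly declared family of tests per call --- adjusted values are not
comparable across families, so each report records its family label.
Multiple regression of repeat density on chromosome length, GC and CDS
density is ordinary least squares with an intercept; because the
question of interest is the *sign and significance* of the length effect after
controlling for composition, both raw and standardized coefficients are
reported (the predictors' units differ by orders of magnitude).

## Diversity with missing data

Nucleotide diversity follows the ratio-of-sums estimator popularized by
pixy: per site, differences are counted over all unordered pairs of
*called* alleles (`k` called alleles give `k(k-1)/2` comparisons), and a
window's pi is the summed differences over the summed comparisons of its
retained sites. A mean of per-site ratios would be biased when
missingness varies across sites; the ratio of sums is not, and the suite
checks exact equality with the naive average-pairwise-difference estimator
on fully called data. This requires an *all-sites* VCF (invariant sites
included) --- a variants-only VCF would silently shrink denominators.
Chromosome-level pi is the unweighted mean of window pi values, and the
0D/4D ratio divides these chromosome means; the chromosome-wide ratio of
sums is also emitted for comparison. Windows with zero comparisons (e.g.
no 4-fold sites) are dropped and counted.

Codon degeneracy is derived from the standard genetic code alone: a CDS
base is 4D when all three alternative bases are synonymous, 0D when none
is. Transcripts are assembled from GFF3/GTF CDS features respecting
strand and phase; transcripts whose CDS is not a multiple of 3 after
phase adjustment, or which contain an internal stop, are skipped with a
warning rather than guessed at. Sites labeled differently by overlapping
transcripts are `"conflicting"` and excluded from both the 0D and 4D BED
outputs --- the conservative choice for a degeneracy proxy. SNP effects
(synonymous/nonsynonymous) substitute the alternate allele into the
reference codon; indels and sites with conflicting transcripts are
`"other"`.

## Folded spectra and the gamma DFE

The folded site-frequency spectrum over minor-allele classes
1..floor(n/2) avoids ancestral-state polarization. Sites with more called
alleles than the target sample size are projected down hypergeometrically
(expected fractional class contributions; projection preserves each
site's polymorphic mass), sites with fewer are excluded.

The expected spectrum under genic selection uses the Poisson random field
density of segregating sites, normalized so the neutral case is exactly
`1/i`. It is integrated adaptively (relative tolerance 1e-8); for
strongly deleterious `S` the integral is split at the `x ~ 50/|S|`
boundary layer where all mass concentrates, and the density is evaluated
through `expm1` ratios in log space so it stays finite down to
`S = -1e6`. The gamma mixture over effects is computed on a fixed
82-point geometric grid of `|4Ns|` from 1e-3 to 1e5 (plus 0): the
spectrum at each grid point is independent of the gamma parameters, so
the grid is built once per sample size and each likelihood evaluation
only recomputes the gamma bin masses; the grid's shape error is ~2e-4
relative, negligible against sampling noise.

The fit maximizes a Poisson likelihood per frequency class with
per-class nuisance factors `r_i` (anchored `r_1 = 1`, profiled in closed
form) shared between the synonymous and nonsynonymous spectra --- the
classic nuisance-parameter alternative to fitting an explicit two-epoch
demography, answering the same question (relative selection strength
across chromosomes) at desk scale. Two design points matter:

* **Tied mutational scales.** When both spectra carry surveyed-site
  totals, the nonsynonymous scale is tied to the synonymous one through
  the shared per-site mutation rate, `theta_n = theta_s * L_n/L_s`. The
  *deficit* of nonsynonymous polymorphism then directly informs the
  deleterious mass. Without the tie, the folded spectrum's shape alone
  must identify `(beta, Es)`, and these sit on a nearly flat likelihood
  ridge: in our pilot simulations the free-scale fit recovered the shape
  `beta` well but scattered `Es` over orders of magnitude, while the tied
  fit recovers both (median over 50 replicates at
  `beta = 0.3, Es = 500, n = 20, L = 1e6, theta = 0.008`: beta 0.30,
  Es ~ 505, each replicate within +-30%). The free-scale model remains
  the fallback when `L` is unknown.
* **Bounded multi-start optimization.** L-BFGS-B from the 8 deterministic
  starts `beta in {0.1, 0.3, 1, 3} x Es in {10, 1000}`; an `Es` at its
  lower bound is flagged `neutral_boundary` (nonsynonymous spectrum
  indistinguishable from neutral). Profile-likelihood CIs for `Es` are
  optional (`profile_ci = TRUE`).

`Es` is reported as the mean *scaled* selection-coefficient magnitude
`E[-4Ns]` (with `S_mean = -Es` for the signed convention); unscaled `s`
requires an external `N_e`, and cross-chromosome comparisons use relative
ordering only.

## The synthetic-data generator

The generator is the package's ground truth, not a fixture: it embodies
the statistical structure the analyses assume and nothing more.

* **Two insertion epochs** (old then young) mirror the two divergence
  bins; divergences are drawn uniformly from [5,10]% and [0,5)%. Default
  rates are 80 and 40 copies/Mb with lognormal lengths around 0.7 kb
  (median 600 bp), giving ~9% of a chromosome in young+old TE bodies
  before deletion --- a realistic share for the recent, age-classifiable
  slice of a lepidopteran repeat landscape.
* **NAHR-like deletion** acts between the epochs, only on inter-TE unique
  sequence, never on TE bodies: each gap loses
  `Binomial(gap, delta(L))` bases with
  `delta(L) = del_rate * (L/1e7)^del_exp` clamped to [0, 0.9]. The
  default `del_rate = 0.3, del_exp = -1` makes a 5-Mb chromosome lose 60%
  of its unique inter-TE sequence and a 30-Mb one 10% --- a deliberately
  strong setting so the mechanism's qualitative signatures (both
  correlations negative) appear in essentially every simulated genome.
  Setting `del_rate = 0` with size-independent insertion rates yields the
  null: correlation signs split ~50/50.
* **Young insertions** land uniformly on unique sequence and add their
  length; insertions into existing TE bodies (nesting) are not modeled,
  since they would fragment old `.out` records without changing the
  spacing statistics the package studies. Chromosome length therefore
  obeys: final = initial - deleted + young-inserted bases, which the
  truth record lets tests verify exactly.
* **Genes** are non-overlapping, phase-correct CDS models (30% two-exon,
  both strands, no internal stops), so the degeneracy classifier runs on
  simulated output without special cases.
* **Population samples** are site-independent: a site segregates with
  probability `theta * sum(1/i)` and its sample allele count follows the
  neutral `1/i` spectrum (so expected per-site pairwise diversity equals
  `theta` exactly), while 0-fold sites use the gamma-DFE mixture
  spectrum. Genotypes pair the `2n` alleles and are masked at the
  missing rate. Default `theta = 0.006` sits inside the range observed
  in lepidopteran resequencing (5e-3 to 1.4e-2). No linkage is
  simulated: the diversity, SFS and DFE statistics consumed downstream
  are insensitive to LD, and independence keeps generation linear in
  genome length. Consequently, passing tests demonstrate estimator
  correctness and calibration under the assumed sampling model --- they
  do not probe LD-induced variance inflation, selection at linked sites,
  alignment or genotyping error, which real data carry.

All randomness flows through one seeded generator and the caller's RNG
state is restored afterwards; identical parameters and seed give
byte-identical output files.

## Problem sizes and runtime choices

The shipped verification suite uses miniature problem sizes chosen to
exercise every code path with comfortable statistical resolution: 3--4
chromosome fixtures of 25--120 kb with 4--8 diploids for end-to-end runs,
500 simulated chromosomes for bootstrap coverage, 50 replicates for DFE
recovery, and 200 seeds per scenario (20 chromosomes of 5--30 Mb each)
for the mechanism checks. These sizes put the full suite in the
few-minute range on a single core; all of them scale up by changing the
corresponding parameters.

## Known limitations

* Divergence is consumed as the `.out` "% div" column as-is; no Kimura
  correction is applied (use upstream tooling if calibrated ages are
  needed).
* The degeneracy classifier supports the standard nuclear code only.
* The DFE model has no beneficial mass and no explicit demography; `r_i`
  absorb demographic distortion but also any systematic genotyping bias
  shared between site classes.
* Per-chromosome DFE fits need thousands of coding SNPs to be
  informative; on the miniature fixtures they are illustrative only.
* The simulator's deletion acts between exactly two epochs; continuous
  insertion/deletion histories are out of scope.
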