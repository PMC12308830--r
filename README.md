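# chromTE

Chromosome-scale statistics for transposable-element (TE) organization,
nucleotide diversity and selection, built around a question from
lepidopteran genome evolution: **why do smaller chromosomes carry denser
TEs despite recombining more?** Classical theory predicts the opposite —
more recombination, more effective purifying selection, fewer fixed
insertions. One proposed resolution is non-allelic homologous
recombination (NAHR): crossovers between homologous TE copies at
different loci delete the unique sequence between them, and since small
chromosomes recombine more per Mb, they compact their TE landscape
faster.

The package is aimed at comparative and population genomicists working
with chromosome-level assemblies, RepeatMasker annotations and
resequencing data, and at anyone who wants the underlying statistics as
tested, reusable functions.

## What it computes

* **Windowed feature densities** — repeat (interval-union), GC and CDS
  density in 100-kb windows; per-chromosome means with percentile
  bootstrap CIs (*B* = 1000 over windows).
* **Inter-TE spacing** — adjacent-pair distances within divergence-based
  age classes (young < 5%, old 5–10% divergence) and the per-chromosome
  young/old ratio. Under the NAHR mechanism the ratio *falls* with
  chromosome size: old cohorts on small chromosomes have been compacted
  longest.
* **Association tests** — Spearman's ρ against chromosome length (exact
  permutation p for n ≤ 10, t approximation beyond) with
  Benjamini–Hochberg FDR across a declared family; OLS multiple
  regression of density on length, GC and CDS density with raw and
  standardized coefficients.
* **Diversity with missing data** — the ratio-of-sums estimator of π
  from all-sites VCFs (Σ pairwise differences / Σ pairwise comparisons
  over retained sites), 0-fold/4-fold codon-degeneracy site maps derived
  from the standard genetic code, per-chromosome π(0D)/π(4D) as a
  purifying-selection proxy.
* **DFE inference** — folded site-frequency spectra (hypergeometric
  projection) and maximum-likelihood estimation of a gamma distribution
  of deleterious fitness effects under a Poisson random field model, with
  per-frequency-class nuisance factors and mutational scales tied through
  the shared per-site rate, reporting the shape β and mean |4Nₑs| (Es).
* **A ground-truth simulator** — genomes with two TE insertion epochs,
  NAHR-like deletion of inter-TE gaps with size-dependent rate
  δ(L) = c·(L/10 Mb)^d, phase-correct gene models, and site-independent
  all-sites population VCFs with known θ and DFE, so every estimator can
  be validated end-to-end.

## Worked example

Simulate a ten-chromosome genome (5–30 Mb) with size-dependent deletion,
then recover both mechanism signatures:

```r
library(chromTE)

params <- te_landscape_params(
  chrom_lengths = round(seq(5e6, 30e6, length.out = 10)), seed = 1)
sim <- simulate_te_landscape(params)

win  <- repeat_density(make_windows(sim$chrom_sizes), sim$te)
summ <- chromosome_summary(win, "repeat_density", B = 1000, seed = 1)
sp   <- spacing_by_chromosome(sim$te)

tab <- merge(merge(sim$chrom_sizes,
                   summ[, c("chrom", "mean_stat", "ci_low", "ci_high")]),
             sp[, c("chrom", "ratio_young_over_old")])
print(tab, digits = 3)

ct <- spearman_test(tab$length, tab$mean_stat)
cr <- spearman_test(tab$length, tab$ratio_young_over_old)
```

Output:

```
   chrom   length mean_stat ci_low ci_high ratio_young_over_old
1  chr01  2253111    0.1665 0.1544  0.1785                 4.12
2  chr02  5099832    0.1197 0.1105  0.1294                 3.32
3  chr03  7964448    0.1091 0.1022  0.1166                 2.94
4  chr04 10821498    0.1007 0.0950  0.1060                 2.67
5  chr05 13717467    0.1056 0.1004  0.1116                 2.64
6  chr06 16562344    0.1028 0.0985  0.1068                 2.76
7  chr07 19371918    0.0943 0.0894  0.0987                 2.58
8  chr08 22253312    0.0931 0.0888  0.0972                 2.36
9  chr09 25115417    0.0936 0.0899  0.0973                 2.38
10 chr10 28004017    0.0947 0.0910  0.0984                 2.36

repeat density vs length:    rho = -0.879, p = 0.0016
young/old spacing vs length: rho = -0.952, p = 0.000108
```

`mean_stat` is the chromosome's mean 100-kb-window repeat density with
its bootstrap CI: the smallest chromosome is ~1.8× denser than the
largest, and the young/old spacing ratio falls from 4.1 to 2.4 with
size — both Spearman correlations negative, exactly the deletion
mechanism's signature. (chr01 started at 5 Mb and lost over half its
unique inter-TE sequence to the simulated deletion, hence its realized
2.25 Mb length.) Setting `del_rate = 0` in the parameters removes both
signals.

For real data the entry points are `read_repeatmasker()`,
`run_density_analysis()`, `run_spacing_analysis()` and
`run_popgen_analysis()`; each writes deterministic TSV report tables (see
the function help and the methods vignette in `vignettes/`).

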