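---
title: "Mapping mitonuclear epistasis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping mitonuclear epistasis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoscan)
```

## The scientific problem

Budding yeast spontaneously loses functional mitochondrial DNA at a
measurable rate: cells fixed for large mtDNA deletions still ferment but
cannot respire, forming small *petite* colonies next to the large *grande*
colonies of respiring cells.  The petite frequency of a strain — the
percentage of petite colonies among all colonies plated — is a quantitative
trait shaped by nuclear variants, by the mitochondrial genotype
(*mitotype*), and by their interaction (*mitonuclear epistasis*).

Detecting the interacting loci by association is hard with ordinary panels
because mitotypes and nuclear backgrounds are confounded.  The design this
package supports removes that confounding: a multiparent advanced-intercross
collection of haploid strains in which mtDNA inheritance is controlled, so
that every recombinant nuclear genome is replicated across several
alternative mitotypes (isonuclear replication).  With such a collection one
can fit, for every nuclear SNP, a model with both a main SNP term and a
SNP-by-mitotype interaction term, and attribute the trait to each source.

## The association model

For SNP $g$ with mitotype factor $M$ and covariates $X$ (mating type,
auxotrophy markers, genotype principal components, optional conditioning
genotypes), `scan_mitonuclear()` compares three nested models:

* $M_0$: `response ~ X + M`
* $M_1$: `response ~ X + M + g`
* $M_2$: `response ~ X + M + g + g:M`

The main-effect p-value is the nested comparison $M_0$ vs $M_1$; the
interaction p-value is $M_1$ vs $M_2$ with (levels$(M) - 1$) numerator
degrees of freedom.  The Gaussian family fits strain-level means by least
squares and uses F tests; the binomial family fits logit-link GLMs to
(petite, grande) colony counts and uses likelihood-ratio $\chi^2$ tests.
How one single fitted model should yield separate "main" and "interaction"
p-values is otherwise ambiguous; the nested formulation is well defined for
any number of mitotype levels and invariant to the factor reference coding.
The nuclear term may also be an arbitrary categorical background factor
(`mitonuclear_anova()`), which reproduces the classical two-way
nuclear-by-mitotype factorial ANOVA of cybrid panels inside the same
machinery.

Per-SNP edge cases are flagged rather than fitted: monomorphic SNPs
(`monomorphic`), SNPs collinear with the covariate or conditioning set
(`collinear`), and SNPs whose minor allele is absent from some mitotype
stratum of the analyzed rows, which lose interaction degrees of freedom
(`reduced_df`).  Strains with a missing call are dropped for that SNP only.
Exactly additive noiseless data yield a numerically zero residual
improvement; the scan reports statistic 0 and p = 1 in that case rather
than 0/0.

### The response scale

Petite counts are generated (and, mechanistically, arise) on the log-odds
scale: effects of nuclear and mitochondrial alleles multiply odds.  On the
percent scale an exactly logit-additive main effect therefore produces a
genuine, if modest, SNP-by-mitotype interaction wherever other loci shift
the mitotype baselines — a scale artifact, not epistasis.  The scan accepts
any response column, and `strain_petite_means()` provides two:

* `percent` — the mean petite frequency (0–100), the field's reporting
  convention and the scale of the effect-size statistic;
* `logit` — the empirical logit of pooled counts,
  $\log\left((x + 0.5)/(n - x + 0.5)\right)$, the scale on which the
  generative model is additive.

The workflow default scans on the logit scale and reports percent means
alongside.  Benchmarks of interaction detection are meaningful only on the
generative scale; this is a deliberate design decision, not a tuning knob.

### Multiple testing

`adjust_pvalues()` implements Bonferroni (per-test threshold
$\alpha/m$), Benjamini–Hochberg, and Storey q-values.  The Storey
estimator of the true-null proportion $\hat\pi_0$ evaluates
$\#\{p > \lambda\} / (m(1-\lambda))$ on the grid
$\lambda = 0.05, 0.10, \dots, 0.90$, smooths it with a cubic smoothing
spline (3 df), reads off the value at $\lambda = 0.90$ and clips it to
$(0, 1]$.  With $\pi_0$ fixed at 1, q-values coincide exactly with BH
adjusted values; this identity is kept under test.  Default reporting uses
FDR 0.1% for main effects and 5% for interactions, both configurable.

### Effect sizes and downstream grouping

The effect size of a main-effect SNP is
$\Delta = |f_0\,\bar p_0 - f_1\,\bar p_1|$: the absolute difference of the
allele frequencies weighted by the mean strain petite frequency (percent)
of each allele class.  Significant SNPs are mapped to genes if they fall
inside a CDS or within 250 bp 5' of the CDS (translation) start on the
gene's strand, and grouped into QTLs by single-linkage merging within a
25 kb window — roughly the linkage scale expected after seven intercross
generations.  Both windows are configurable.

## The simulator

The generator provides every input the analysis needs, with the statistical
structure the method assumes:

* **Founders** — 25 haploid founders drawn from 5 ancestral populations
  under a two-level (Balding–Nichols) allele-frequency model with
  differentiation $F_{ST} = 0.2$; ancestral frequencies uniform on
  (0.1, 0.9).  Mating types alternate, and MAT$\alpha$ founders carry the
  `arg8::URA3` auxotrophy marker used during diploid selection.
* **Recombination** — Poisson crossovers without interference (Haldane):
  the parental origin along a chromosome is a Markov chain whose switch
  probability between markers at distance $d$ cM is
  $(1 - e^{-2d/100})/2$.  No obligate crossover and no mutation; this is
  the simplest model consistent with what is known of the design.
* **Intercross** — 7 rounds of random MATa × MAT$\alpha$ mating at a
  population size of 10,000 progeny per round (default), then a sample of
  181 strains.  Mating type and the auxotrophy marker segregate as hidden
  loci at fixed chromosome-3 and chromosome-15 positions.  Founder
  ancestry is tracked per marker.  Marker-based selection steps are not
  simulated; they would perturb allele frequencies only near the marker
  loci.
* **Mitotype replication** — each strain is replicated across 3 mitotype
  labels with identical nuclear genotypes, mirroring mtDNA replacement by
  karyogamy-deficient crosses.
* **Phenotypes** — petite counts are Binomial(colonies, expit($\eta$))
  with $\eta$ = baseline logit + SNP effects + mitotype effects +
  interaction effects + covariate effects, 500 colonies per assay.
  Overdispersion $\phi > 1$ mixes the success probability through a Beta
  draw calibrated so the count variance is inflated by $\phi$; $\phi = 1$
  is exact binomial sampling (kept under a dispersion test).
* **Default genome** — the 16 yeast chromosome lengths with 1,200 markers
  spaced evenly in bp (0.35 cM/kb).  This is a deliberately scaled-down
  marker density relative to the ~25,000 sites of a fully sequenced
  collection; density is configurable and none of the statistical
  machinery depends on it.
* **Growth curves, qPCR, mtDNA** — logistic OD600 curves sampled every 15
  minutes (maximal slope $rK/4$ known analytically); Ct values
  $\mathrm{Ct} = a - \log_E(\text{template})$; AT-rich mitochondrial
  backbones (5% GC) with planted GC-cluster motif instances at
  non-overlapping positions.

What the generator does **not** emulate: chromosomal rearrangements,
variant-calling noise, linked selection during strain construction,
mitochondrial heteroplasmy or recombination, plate or batch effects, and
environment interactions.  Passing tests therefore demonstrate the
correctness and calibration of the statistical machinery under the model's
assumptions, not robustness to every artifact of real sequencing data.

### Seeds

Every stage draws from an independent child stream derived from the master
seed by a fixed hash of the stage name (`stage_seed()`), so any stage can
be re-run in isolation and whole runs are byte-identical for a given seed.

## SNP-table filtering

`build_snp_table()` applies, in order: merging of adjacent (consecutive-bp)
variant runs into one record keyed by the leftmost position with
concatenated allele labels; removal of variants within 20 kb of a
chromosome end (the "telomeric region" is not precisely defined in the
source protocols; 20 kb is a configurable convention); restriction to
biallelic records; and a minor-allele-frequency filter.  The MAF threshold
default is 0.05 with the boundary kept, and the filter report carries a
note flagging the convention, because published descriptions of comparable
pipelines state both "<5%" and ">0.5%" thresholds.  Missing calls are
excluded from frequency denominators; merged calls that disagree within a
strain become missing.  Every stage logs its in/out counts, and the counts
telescope.

## Benchmarks the package runs on itself

The acceptance suite (and `scripts/acceptance.R`) recomputes, from scratch:

1. the genome-wide Bonferroni threshold for 24,955 tests
   ($0.05/24955 \approx 2.0\times10^{-6}$);
2. the empirical type-I error of the interaction test at $\alpha = 0.05$
   over the null SNPs of the default 543-row collection.  Because linkage
   makes the per-draw empirical rate noisy, the rate is pooled over 10
   independent phenotype draws on the same collection; pooling reduces
   estimator variance without changing its expectation;
3. recovery of three planted interaction loci ($\delta = 1.5$ logit, MAF
   ≈ 0.3, mitotype-specific) at interaction q < 0.05 within 25 kb, over 20
   master seeds, together with the requirement that the planted main-effect
   locus ($\beta = 1$ logit) stays at its nominal false-positive rate in
   the interaction scan;
4. the conditioning experiment: with a large main-effect locus
   ($\beta = 2.5$) masking five small interaction loci ($\delta = 0.8$),
   adding the strongest main-association SNP as a covariate increases the
   number of interaction hits (paired sign test over 20 replicates).

Benchmark runs use an intercross population size of 2,000 progeny per
round: drift and LD decay at the sampled size of 181 strains are already
stable at that population size, and the benchmark conditions (strain and
colony numbers, effect sizes, rounds) are unchanged.  The planted loci are
chosen at the target MAF on distinct genomic regions **and** with realized
pairwise genotype correlation below 0.1, so that each planted effect is
attributable to its own locus; without that constraint, chance
finite-sample LD between a planted interaction locus and the main-effect
locus leaks true interaction signal into the main locus and would be
miscounted as a false positive.  In the masking experiment the conditioning
SNP is selected as the smallest main-effect p-value of the first scan —
the in-data analogue of conditioning on the top-effect locus.

## Numerical choices and degenerate inputs

* Nested-model statistics are clipped at zero; a residual improvement
  below $10^{-10}$ of the reduced-model residual is treated as exactly
  zero (statistic 0, p = 1).
* PCA mean-imputes missing genotypes per variant, centers, and truncates
  to the matrix rank with a warning when more components are requested.
* `storey_pi0()` is clipped to $(0, 1]$; q-values are monotone by
  construction (cumulative minimum over the descending p-order).
* The qPCR normalization regresses $1/\mathrm{Ct}$ of the candidate on
  $1/\mathrm{Ct}$ of the control.  When candidate and control templates
  are equal this fit is exact; when they are merely proportional the
  relation between the two reciprocals is a Möbius function that is only
  locally linear, so residuals are small but not identically zero.  The
  residual of a genuinely perturbed sample dominates either way.
* GC-cluster matching scans both strands with a configurable mismatch
  tolerance (default 2) and resolves overlaps greedily left-to-right
  (ties: position, class label, forward strand), so a palindromic motif
  and its reverse complement at one locus count once.  The bundled
  M1–M9 motif library is synthetic (mutually distant palindromes for
  unambiguous testing), not the published cluster consensus sequences;
  real analyses should supply their own library.

## Known limitations

* The Gaussian scan assumes homoskedastic residuals across mitotypes;
  strong unmodeled interaction variance concentrated in one mitotype makes
  the interaction F-test conservative in the affected contrasts.
* The binomial family is exact for the generative model but
  anti-conservative on real data with strain-level overdispersion;
  Gaussian-on-means is the robust default, the binomial family the
  count-faithful alternative.
* No kinship/mixed-model correction: population structure is handled by
  genotype principal components, which is adequate for an advanced
  intercross but not for structured natural panels.
* Genotype imputation, fine-mapping and GO enrichment are out of scope.
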