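---
title: "Methods: genomic selection in pedigreed multi-family populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic selection in pedigreed multi-family populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(orchardgs)
```

# The problem

Perennial fruit breeding discards most seedlings on *culling traits* —
productivity and external fruit appearance scored visually on an ordinal
1–5 scale — years before any full evaluation. Genomic selection replaces
that first phenotyping round: a *training population* with both phenotypes
and dense SNP genotypes yields a whole-genome prediction model, which is
then applied to *application families* that have only (sparse, imputed)
genotypes. This package implements that chain for the characteristic data
structure of such programmes: many interrelated full-sib families sharing
parents and ancestors, historic multi-year multi-location ordinal scores,
dense genotypes on the training set, and a small dedicated marker panel on
the selection candidates.

# Models and procedures

## Phenotype adjustment and training BLUPs

Training individuals are scored in one location over several seasons;
locations are connected only through a set of clonally replicated
*reference genotypes* scored everywhere. Adjustment is therefore
two-stage:

1. `estimate_environment_effects()` fits, per trait, a least-squares model
   to the reference records only: score ~ genotype + year + location, with
   treatment contrasts (first level of each factor pinned to zero).
   A joint model over all records is not identified here — only the
   reference clones link environments — which is why the two-stage design
   was chosen over a single mixed model.
2. `adjust_phenotypes()` subtracts the estimated year and location effects
   from every record and `adjusted_means()` averages each individual's
   records. Adjusted values may leave the raw [1, 5] range; that is
   expected and harmless, since scores are treated as continuous from here
   on. Treating ordinal scores as continuous follows standard practice for
   five-class traits whose adjusted distributions are roughly normal;
   threshold (probit) models are out of scope.

`reml_variance_components()` then fits the animal model
y = μ + a + e, a ~ N(0, **A**σ²ₐ), e ~ N(0, **I**σ²ₑ) by EM-REML on
Henderson's mixed-model equations, and `animal_model_blup()` returns the
BLUPs â used as training phenotypes. Narrow-sense heritability is
h² = σ²ₐ/(σ²ₐ + σ²ₑ).

Numerical notes:

* One eigendecomposition of **A** turns the coefficient matrix into an
  arrow matrix whose random-effect block is diagonal, so every EM
  iteration is O(n). Eigenvalues are floored at 1e−8, which also handles
  the singular **A** of clone groups.
* Convergence: relative change of both components below 1e−6; the
  low-level function defaults to 1000 iterations, but the per-trait
  wrapper allows 5000 because EM-REML typically needs ~2000 iterations on
  family data at this tolerance. Non-convergence returns the last iterate,
  flagged.
* Degenerate input (constant y) reports σ²ₐ = σ²ₑ = 0 and h² = 0 by
  convention.
* A caution on identifiability: with a handful of large full-sib families,
  the REML sampling error of h² at n ≈ 500 is itself ~0.15 (the package's
  tests verify the estimator against an independent one-dimensional
  profile-REML oracle, and measure recovery as a mean over replicates).
  Averaging multiple seasons per individual also raises the heritability
  of the *mean* above the per-record h²; the inflated per-trait h²
  estimates on pipeline runs of the small preset are exactly this effect,
  not an estimator bias.

## Relationship matrices

`build_a_matrix()` uses the tabular method: a_ij = (a_j,s(i) + a_j,d(i))/2
for earlier j, a_ii = 1 + a_s(i),d(i)/2, unknown parents contributing
zero. O(n²) is perfectly adequate at desk scale and is verified against a
gene-dropping kinship estimate.

`standardize_dosages()` and `compute_g()` build **G** = **W′W**/p where
w_im = (x_im − mean_m)/sd_m with moments taken over the *training*
individuals and the sd using the divide-by-N convention. Two exact
identities follow and are asserted in the tests: every individual's mean
relatedness to the training set is zero, and the mean training diagonal is
exactly 1. Divide-by-N (rather than N−1) is the declared convention
precisely because it makes the second identity exact. Markers monomorphic
in training are excluded consistently from both **G** and the regression
design. Top-k relatedness (`top_n_relatedness()`) sorts an individual's
relationships to the training set and averages the k largest; fractions
round to the nearest count, minimum 1, with ties broken by stable order.

## Family imputation

Application candidates are typed on a sparse panel (~3.7 cM spacing by
default). `phase_parents()` phases each parent's heterozygous sites per
chromosome with a greedy minimum-recombination chain: the allele a child
received from the parent is deducible whenever the child or the other
parent is homozygous, and adjacent heterozygous sites are linked in
coupling or repulsion by majority vote. Votes are aggregated over the ten
most recent phased sites — single-pair votes are too sparse with ten
informative offspring and produce chain flips. Haplotype labels are
arbitrary per chromosome; all downstream use is invariant to the swap.

`impute_offspring()` decodes, per chromosome, the hidden pair (paternal
haplotype origin, maternal haplotype origin): each origin is a two-state
Markov chain with Haldane switch probability r(d) = (1 − e^(−2d/100))/2
between adjacent markers, no interference, and a fresh start per
chromosome. Typed markers emit the observed dosage with genotyping-error
rate ε (default 0.01); at unphased parental sites the haplotype allele is
replaced by its expectation. Forward–backward posteriors fill untyped
markers with the posterior expected dosage; observed entries pass through
exactly; hard calls are rounded expectations. Offspring whose typed
markers are Mendelian-impossible at more than 5% of sites are flagged and
re-imputed with ε raised to 0.2. This family HMM is a deliberate,
transparent stand-in for a production imputation program; population-level
haplotype libraries are not implemented, so imputation quality rests
entirely on the parents being genotyped at high density — the regime in
which the design intends it to be used (hard-call concordance ≥ 0.90 at
the default panel, verified by a masking experiment in the tests).

`fill_sporadic_missing()` routes individuals with two genotyped parents
through the same HMM; only parentless individuals fall back on the
parent-compatible sibling majority vote with an allele-frequency
expectation as last resort. The vote rule alone ignores linkage and
plateaus near 70% concordance at heterozygous-by-heterozygous sites,
which is why the HMM route is the default wherever the pedigree allows
it.

## BayesCπ

`fit_bayescpi()` samples the posterior of y = μ1 + **W**β + e where each
marker effect is zero with probability 1 − π and N(0, σ²_β) with
probability π, σ²_β and σ²ₑ are scaled-inverse-χ², and π ~ Beta(1, 1). The
Gibbs sweep updates, in order: the intercept (conjugate normal), each
marker's inclusion indicator (Bernoulli from the conditional marginal
odds) and effect (conditional normal), σ²_β, π (Beta(1 + k, 1 + p − k)
given k included markers), and σ²ₑ. The sampler is compiled (Rcpp) and
draws from R's RNG, so `set.seed()` reproduces chains bit-exactly.

Declared choices the method names but does not pin down elsewhere:

* Prior degrees of freedom ν = 4.2 for both variances; scales partition
  var(y) by a prior heritability h²₀ = 0.5, spreading the genetic part
  over the number of markers expected in the model (prior mean π₀ = 0.5).
* Chain defaults 50 000 iterations / 10 000 burn-in / thinning 10;
  the tests and the acceptance script scale this down (typically 5 000 /
  1 000 / 5) after checking that two seeds agree on π̂ within 0.05.
* The regression design is centered on training means but *not* variance
  scaled; the GRM standardizes fully. These are different uses and are
  kept distinct.
* Reported effects are posterior means of the mixture draws (zeros
  included), so an effect's magnitude already carries its inclusion
  frequency. `relative_effects()` reports |β̂|/sd(y), the scale on which
  effect-size distributions are compared across traits.
* With π fixed at 1 the model is SNP-BLUP/ridge. The test-suite oracle
  conditions a second chain on the first chain's posterior-mean variances
  (`fixed_variances=`) because the *unconditional* posterior mean differs
  from ridge-at-mean-variances by a Jensen gap that no Monte-Carlo band
  can absorb; conditionally, the equality is exact and is checked against
  the closed form.

`predict_gbv()` centers application dosages with the training means stored
in the model (fractional imputed dosages are fine) and returns
ĝ = **W**β̂, intercept excluded.

## Evaluation

Accuracy is the Pearson correlation between ĝ and the observed ordinal
scores, computed within family (families sit in different locations, so
pooling would confound). The 95% interval is tanh(atanh(r) ± z/√(n−3));
`qnorm(0.975)` is used rather than the textbook 1.96 — they agree to four
decimals. A Spearman ρ is attached when |Fisher–Pearson skewness| of the
scores exceeds 1 (the "highly skewed" flag; the threshold is this
package's choice). Accuracy of predicting *phenotypes* is bounded by √h²:
`appendix_accuracy_decomposition()` verifies cor(ĝ, y) = cor(ĝ, TBV)·√h²
on synthetic data, and `accuracy_h2_regression()` fits the no-intercept
slope of accuracy on √h².

`selection_differential()` contrasts the k = 50 individuals with the most
favourable GBV against the k least favourable (realized differential) and
against the family mean (directional differential). Favourable direction
is a required per-trait declaration — defect traits (russet, cracking,
pre-harvest dropping) favour low scores. The two-sample test is Welch's
t-test: plain "Student" is under-specified and Welch reduces to it under
equal variances. Ties at the k-th rank break by stable input order.
Under permutation the differential is centred with calibrated type-I
error; both properties are exercised in the tests.

`aggregate_report()` reproduces the family-by-trait report shape:
per-family means over all traits and over the four symmetric-distribution
traits (attractiveness, fruit cropping, fruit size, per cent russet),
per-trait means, the global maximum, and mean CI lengths. Cells for traits
not scored in a family are skipped and counted, and every aggregate is
recomputable from its member cells — an invariant the tests assert.

# The synthetic world

`simulate_population()` generates what the analysis assumes, not more:

* **Pedigree** — founders, intermediate ancestors (children of founder
  pairs) and a pool of up to 24 inter-related parents; 20 training
  full-sib families (37-980 individuals total by configuration; the
  default totals ~980) and 5 application families of sizes
  662/172/269/109/178 whose parents are re-drawn from the training parent
  pool with probability 5/9 — the fraction of application parents that
  were also training parents in the motivating design.
* **Genome** — 17 chromosomes of 80 cM with ~460 evenly spaced markers
  each (~7 820 SNPs; the real map length is not published, so these are
  configurable defaults of the same magnitude). Founder haplotypes are
  drawn in linkage equilibrium; descendants recombine under Haldane's
  model without interference, so all LD is pedigree LD — deliberately so,
  matching the long within-family LD stretches such designs carry. The
  low-density panel is evenly spaced at ~1 marker/3.7 cM.
* **Traits** — `round(π_true · p)` causal SNPs per trait, effects scaled
  so the realized additive variance equals h² on a unit liability scale;
  ten traits with h² between 0.03 and 0.67 by default. Liability = TBV +
  year effect + location effect + N(0, 1 − h²); the ordinal score is 1 +
  the number of thresholds below the liability. Default thresholds put
  roughly quintile mass in each class; `skewed_thresholds()` concentrates
  ~75% in class 1 to mimic defect traits. Training individuals are scored
  at one location in every year, application individuals in one final
  year, and reference clones in every location × year cell.

What the generator does **not** emulate — and hence what a green test does
not establish: coalescent founder LD, mutation, dominance/epistasis
(the prediction model is additive by design), genotype × environment
interaction, array-specific genotyping artefacts, multi-allelic QTL, and
real-map marker density variation. Tests prove internal consistency of the
machinery and recovery of the simulation's own parameters; they cannot
certify accuracy on any particular real orchard population.

# Reproducibility

Every stochastic function takes a seed; `run_pipeline()` derives fixed
per-stage offsets from the single config seed, and the run manifest
records per-stage hashes so identical configs reproduce identical hashes.
The C++ sampler uses R's RNG stream for the same reason.

# Known limitations

* EM-REML is robust but slow near the boundary; badly identified designs
  (few, large families) can exhaust the iteration budget and return a
  flagged non-converged iterate.
* The phasing chain can mis-orient a chromosome segment when no offspring
  is informative across a gap; downstream dosage imputation degrades
  gracefully (the HMM treats such sites as unphased) but panel gaps over
  ~10 cM visibly reduce concordance, consistent with the decay the tests
  measure at 2/5/10/20 cM spacings.
* Per-family accuracies carry wide sampling intervals (length ≈ 0.35 even
  at n = 100); correlations between relatedness summaries and accuracy
  across a handful of families are descriptive, not inferential.
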