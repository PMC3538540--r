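---
title: "Methods: LD decay, haplotype blocks and population statistics in popld"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LD decay, haplotype blocks and population statistics in popld}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popld)
```

# Scope

`popld` characterizes linkage disequilibrium (LD) in structured diploid
populations genotyped on sparse regional SNP panels — the setting of breed
genetics, where a few dozen populations of 8–22 individuals each are typed
on a custom array covering a handful of megabase-scale regions. The package
covers the full chain: per-population SNP QC, pairwise LD from unphased
genotypes, decay-curve fitting with a half-decay summary, GWAS-informative
pair fractions, solid-spine haplotype blocks, per-population summary
statistics, cross-population differentiation with a neighbor-joining tree,
and a forward simulator that generates panels with the same design for
end-to-end validation.

# Quality control

QC is strictly per population: the same SNP can pass in one breed and fail
in another, because call rates, monomorphism and minor allele frequency
(MAF) are all population-specific properties. `apply_qc()` removes, in
order, SNPs with call rate < 80% (default), SNPs monomorphic among the
population's called genotypes, and SNPs with MAF below the cutoff. The
order is fixed so that the category counts in the report are reproducible:
a SNP is counted against the first filter it fails, and the four categories
always sum to the panel size. Two MAF cutoffs matter in practice, 0.05 and
0.1; the package treats 0.05 as the primary analysis level and uses the 0.1
level to quantify how much the stricter cutoff inflates the apparent LD
extent (below).

# Pairwise LD from unphased genotypes

For a pair of biallelic loci the package estimates the four haplotype
frequencies by the standard composite of direct counting plus EM: every
joint genotype except the double heterozygote determines its two haplotypes,
and the double-heterozygote count is split between coupling (AB/ab) and
repulsion (Ab/aB) according to its posterior under the current estimates,
iterated to convergence (tolerance 1e-10 on the largest frequency change,
cap 10,000 iterations). Three starts are used — an even 50/50 split and
coupling-/repulsion-biased splits (0.9/0.1) — and the solution with the
best likelihood is kept. The extra starts matter for phase-uninformative
tables: a table consisting only of double heterozygotes has its likelihood
maximized at perfect coupling or perfect repulsion (the two tie), while the
even start would sit at the symmetric saddle point; such tables are flagged
`degenerate` because the data carry no phase information. The estimator's
marginal allele frequencies always equal the observed ones, a property the
tests verify against a grid search over the single free phase parameter.

From the haplotype frequencies, `D = f_AB - p_A p_B`,
`r2 = D^2 / (p_A(1-p_A) p_B(1-p_B))`, and `|D'| = |D| / D_max` with the
usual frequency-dependent bound `D_max`. Since `D_max^2` never exceeds
`p_A(1-p_A)p_B(1-p_B)`, `r2 <= |D'|^2` holds for every pair, which the test
suite asserts on random tables.

Missing genotypes are handled by pairwise-complete deletion: each pair is
estimated from the individuals called at both loci, and the per-pair count
is reported. Pairs whose pairwise-complete subset leaves a locus
monomorphic are dropped and counted rather than reported as `r2 = 0` or
`NA` rows — whether to keep them is genuinely ambiguous, and dropping with
a counter keeps downstream summaries well defined.

`pairwise_ld_region()` computes all intra-chromosome pairs; the engine is
vectorized across pairs (genotype cell counts via indicator-matrix cross
products, EM updates on vectors), so panels of a few hundred SNPs per
region are interactive. `background_ld()` applies the same estimator to
all pairs of SNPs on *different* chromosomes — an empirical null for
unlinked loci, computed at MAF >= 0.1 where the large number of pairs makes
the cutoff immaterial.

# The decay model and its summary

Expected r2 under drift–recombination equilibrium follows the Hill–Weir
expression in the population recombination parameter `C` with a
sample-size adjustment in `n`:

$$E[r^2] = \frac{10 + C}{(2 + C)(11 + C)}
  \left[1 + \frac{(3 + C)(12 + 12C + C^2)}{n(2 + C)(11 + C)}\right].$$

The curve decreases strictly in `C`, from `(5/11)(1 + 18/(11n))` at `C = 0`
to the sampling floor `1/n`. `fit_decay()` sets `C = a d` with `d` the
inter-SNP distance in kb and minimizes the unbinned residual sum of squares
over the single coefficient `a > 0` — no distance binning and no weighting,
so every pair contributes equally. Because the model has one parameter, the
fit is a 1-D optimization: a coarse log-grid over `a` in `[1e-5, 1]` per kb
followed by golden-section refinement, which is deterministic and cannot be
trapped by a bad start. A binned mode (`binned = TRUE`, fitting per-bin
mean r2) exists for visual comparisons but is not the default: binning
discards the pair-level information and weights distance classes unevenly. Fits that pin to either grid boundary are flagged
non-converged: the lower boundary means no decay is observable within the
region (LD extends beyond the panel's range), the upper that the data sit
at the `1/n` floor everywhere.

Two design choices deserve explanation:

* **`n` counts individuals, not chromosomes.** With `n` the number of
  sampled diploids, the analytic half-decay level `(5/22)(1 + 18/(11n))`
  evaluates to 0.27 for n = 8–9, 0.26 for n = 12, and 0.25 for n = 14–19 —
  the levels conventionally reported for panels of this size. With
  `n = 2 x` individuals it does not. Callers preferring chromosome counts
  can pass `2 * n` explicitly.
* **The curve "maximum" is the `C -> 0` limit**, not the fitted value at
  the smallest observed distance. This makes the 50%-decay level a pure
  function of `n` — comparable across populations and independent of where
  the closest SNP pair happens to sit.

`half_decay()` halves that maximum and solves `E[r^2](a d, n)` for `d` by
bisection (tolerance 1e-6 kb). When the level is not reached within the
horizon (1000 kb by default) the distance is reported as the `>1000`
sentinel rather than an extrapolated number.

**MAF inflation.** The LD extent estimated at MAF >= 0.1 is systematically
longer than at MAF >= 0.05. `maf_inflation()` reports
`100 (d50(0.1) - d50(0.05)) / d50(0.1)`: the 0.1-based estimate is the
denominator, which keeps the percentage below 100 by construction whenever
the 0.1 extent is the larger. The alternative normalization (by the
0.05-based estimate) is defensible; the choice is fixed here and stated so
the numbers are comparable. For the ratio the half-decay distances are
solved without a horizon, so the statistic stays defined when a sentinel
would be printed.

**Informative fractions.** `informative_fractions()` reports, per half-open
distance class `[lo, hi)` kb (defaults 0–20, 20–40, 40–60, 60–80, 80–100,
100–200, 200–400, 400–600, 600–1000), the fraction of pairs with
`r2 >= 0.8` — pairs where one SNP effectively tags the other for
association mapping. Empty classes are reported as missing, not zero.

# Solid-spine haplotype blocks

A candidate interval `[i..j]` is a block when the *first* marker is in
strong LD (`|D'| >=` 0.8 by default) with every later marker of the
interval and the *last* marker is in strong LD with every earlier one;
intermediate-vs-intermediate pairs are deliberately unconstrained — that is
what distinguishes the solid-spine rule from confidence-interval block
definitions. The prose form of the rule ("first and last markers in strong
LD with all intermediate markers") is ambiguous about whether both
directions are required; the two-sided formalization above is used and the
greedy left-to-right search takes the longest valid interval from each
start, so blocks are maximal and non-overlapping. An exhaustive-enumeration
oracle in the test suite confirms the greedy search is exact. Pairs dropped
as monomorphic after pairwise deletion fail the threshold.

Within-block haplotype frequencies come from a multi-locus EM over phase
configurations. Blocks up to 8 markers are handled exactly (an individual
with `h` heterozygous sites contributes `2^(h-1)` phase configurations);
longer blocks use partition–ligation: consecutive sub-blocks of at most 8
markers are estimated separately, the top 20 haplotypes per side are
ligated, and the product space re-estimated. The 8/20 parameters trade
accuracy against memory and are configurable. Individuals with any missing
call inside a block are excluded from that block's EM — marginalizing over
missing sites would enlarge the configuration space for little gain at the
few-percent missingness these panels show. Haplotypes below the 0.01
display threshold are discarded before counting; the remaining set is
classified as the single *major* haplotype, *intermediate* haplotypes above
frequency 0.1, and a pooled *rare* remainder.

# Population statistics

* **Heterozygosity and inbreeding.** Per SNP, observed heterozygosity is
  the fraction of heterozygous calls; expected heterozygosity uses the
  small-sample correction `2p(1-p) 2n_c/(2n_c - 1)` (`n_c` called
  individuals). `Fis = 1 - Ho/He` from the per-region means.
* **Tajima's D** is computed phase-free: nucleotide diversity from allele
  frequencies (`sum 2p(1-p)` with the `n/(n-1)` sequence-count correction),
  Watterson's theta from the segregating-site count, and the canonical
  variance constants. Regions with no segregating site return `NA`. Note
  that D on array-ascertained SNPs inherits the panel's ascertainment; see
  the simulator section for the consequences.
* **Fst** uses the Hudson-type ratio-of-averages moment estimator with the
  per-SNP sample-size correction expressed in called diploid individuals.
  This is a deliberate replacement for model-based supervised estimates:
  it is assumption-light, symmetric, invariant to allele relabeling, and
  adequate for building a distance matrix. Estimates are clipped to
  `[0, 1]` for tree building with the raw values retained.
* **The NJ tree** is Saitou–Nei neighbor joining (via `ape::nj`) on the
  Fst matrix, with negative branch lengths clamped to zero. Tests verify
  exact recovery of topology and path lengths from additive matrices.
* **`feature_correlation()`** is a plain Pearson test between per-region LD
  extents and user-supplied genomic features (GC content, gene counts,
  repeat counts); the feature table is an input, not something the package
  retrieves.

# The synthetic-data generator

`emulate_study()` generates panels with the design the analysis assumes:
ten 1-Mb regions of ~150 SNPs with a third of them packed into the first
100 kb (for fine-scale decay estimation), ~23 populations of 8–22 diploids
founded from two diverged ancestral pools, genotype missingness of a few
percent, and a combined random-bred population derived by merging its two
components. Chromosome labels follow the panel convention, including an
`X` region that the `Auto` fitting scope excludes.

The machinery is forward Wright–Fisher simulation rather than coalescent:
two ancestral pools (default 100 diploids each) are assembled at linkage
equilibrium from a Beta(0.5, 0.5) frequency spectrum truncated to
[0.05, 0.95], separated by a drift perturbation of variance `F p(1-p)`
(default `F = 0.15`, chosen once as a realistic east–west divergence for
breed-scale data), and evolved 50 generations of random mating with
recombination (1e-8 per bp per generation) to accumulate background LD.
Each breed then draws its founders, passes through a bottleneck
(`bottleneck_Ne` diploids for `bottleneck_generations`) and expands to
`expansion_Ne` until sampling; regions share the pedigree within each
generation (independent assortment) while crossovers are Poisson with
uniform breakpoints per region. There is **no mutation during breed
history**: panel SNPs model pre-ascertained array markers. Demographies are
qualitative presets — `strong` (6 founders, bottleneck at 6), `moderate`
(15/15), `weak` (60/60, random-bred-like) — because real per-breed
demographic parameters are not known quantitatively; the presets are
labeled as such.

What the generator reproduces, and the tests confirm: stronger bottlenecks
give longer LD extents (median fitted d50 decreases strictly in bottleneck
Ne), fewer and longer solid-spine blocks with dominant major haplotypes,
and an east–west split in the Fst-based NJ tree. Sampled genotypes carry
their phased truth haplotypes, which serve as oracles for the EM tests.

What it deliberately does not reproduce: mutation influx and
ascertainment-scheme effects. One visible consequence is the sign of
Tajima's D — with pre-ascertained markers and no new mutation, a bottleneck
shifts surviving marker spectra toward intermediate frequencies, so
simulated breeds show *positive* D, whereas empirical array studies of
recently expanded breeds report strongly negative values driven by
mutation-fed expansion and cross-population ascertainment (markers
discovered elsewhere are rare in the genotyped breed). Passing tests
therefore validate the D statistic itself (checked against exact hand
evaluations), not the empirical sign pattern. Selection, migration and
admixture are likewise out of scope, though the configuration leaves room
for extensions.

# Numerical choices and degenerate inputs

* EM: tolerance 1e-10, cap 10,000 iterations, three starts,
  best-likelihood selection with ties to the earlier (even) start.
* Decay fit: log-grid `[1e-5, 1]` per kb, 61 points, golden-section
  refinement; boundary fits flagged non-converged and excluded from
  summaries.
* Half-decay: bisection to 1e-6 kb; `>horizon` sentinel instead of
  extrapolation.
* Blocks: threshold comparisons are `>=`; `NA` LD entries fail the
  threshold; singleton markers never form blocks.
* Fst: SNPs with fewer than two called individuals in either population
  are skipped, as are SNPs monomorphic in both.
* All simulation randomness flows through one seed; derived sub-seeds are
  deterministic functions of it, so every output is a pure function of the
  configuration.

# Problem sizes used by the test suite

The validation suite runs the full chain on reduced panels chosen to keep
the properties sharp while staying desk-scale: typically 2–3 regions of
30–70 SNPs, populations of 20–50 diploids, 10 seeds for directional
medians, 200 random tables for the EM-vs-grid oracle, 500 random matrices
for the block oracle, and 100 random trees for NJ recovery. The roster
emulation runs the full 23-population, 408-sample design over a reduced
SNP panel. These sizes are the package's own validation choices; the
functions themselves handle the full 10-region, 150-SNP design directly.

# Known limitations

* LD estimators assume random mating within population when resolving
  phase; strong inbreeding biases the double-heterozygote split.
* The decay model fits a single coefficient per scope; it cannot express
  recombination-rate variation within a region.
* Tajima's D from array SNPs is ascertainment-biased by construction; use
  it comparatively, not as an absolute demographic estimate.
* The Hudson-type Fst replaces model-based estimators; absolute values are
  not comparable across estimator families, though the induced tree
  topology is robust.
* X-chromosome genotypes are treated as diploid for all individuals unless
  male calls are excluded upstream; the `Auto` scope exists precisely to
  keep the X's elevated LD out of cross-population comparisons.
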