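---
title: "Methods: scanning contact zones for barrier loci and sexually selected variation"
author: "barrierscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning contact zones for barrier loci and sexually selected variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question and the design

When two sister species meet in a contact zone, loci that resist
interspecific gene flow ("barrier loci") stand out as outliers of
differentiation (F~ST~) and divergence (d~XY~). Separately, within one
species, genome-wide association can locate loci underlying sexually
selected traits such as male calling song and cuticular hydrocarbon (CHC)
pheromone profiles. The package's purpose is the combinatorial test:
compute both sets of candidate genes, then ask whether they overlap more
than chance — with introgression tests, demographic model comparison,
sweep scans and genotype–environment association as supporting evidence
for how gene flow and selection have shaped the zone.

Every stage is exercised on synthetic data whose truth is known. This
vignette documents the models, the defaults and their rationale, the
numerical choices, and what the synthetic data do and do not emulate.

# Data model

`GenotypeData` extends `RangedSummarizedExperiment`: the `"dosage"` assay
holds ALT-allele counts (0/1/2, `NA` for missing) for sites × samples;
`rowRanges` carries 1-based site coordinates, alleles and QUAL; `colData`
is the population map (population, species, context ∈ {allopatric,
sympatric}, latitude, longitude). Phased haplotypes, when present, are a
sites × 2·samples 0/1 matrix whose pair sums must equal the dosages
(enforced by the validity method). Internally all windowing arithmetic is
0-based half-open; VCF (1-based) and BED (0-based) are converted at the
boundary.

# Variant and sample filters

`applyFilters()` applies, in a fixed order: (1) per-call depth < 10 sets
the call missing; (2) a site is dropped when QUAL < 30, its missing
fraction exceeds 0.5, or its minor allele count falls below 3; (3) samples
missing at ≥ 0.5 of the retained sites are dropped; (4) MAC is re-checked
once after sample removal. The depth rule is applied per genotype call
rather than per site mean — with per-sample depth variation the per-call
rule is the stricter and more common reading, and the site-missingness
filter then catches low-depth sites as a side effect. Filtering is
idempotent, and the test suite checks the surviving site/sample sets
against an independent transcription of the rules.

# The synthetic contact zone

`simulateSnpDataset()` uses a hierarchical Balding–Nichols model for
unlinked SNPs. Per site, an ancestral frequency u ~ Uniform(0.05, 0.95);
each species draws its frequency from Beta(u(1−F)/F, (1−u)(1−F)/F) with
F = `F_between` (default 0.10, matching the weak genome-wide
differentiation typical of recently diverged field-cricket species);
barrier sites use `barrier_F` (default 0.5). Populations draw around their
species frequency with `F_within` (default 0.02 — shallow intraspecific
structure). Introgression is modeled as frequency mixing: sympatric
populations replace their frequency with (1−α)·own + α·other-species,
mimicking the target signal (elevated D in contact-zone populations)
without simulating full migration histories. Genotypes are
Binomial(2, freq), overlaid with missingness (2%), Poisson depth
(mean 30) and Gaussian site quality (mean 60).

The default sampling design is two species × (3 allopatric + 3 sympatric
populations) × 10 diploids, plus a 10-sample outgroup drawn at
F = 0.2 from the ancestral frequency and used only for polarization. The
design mirrors a transect with a shared contact zone; sample sizes are
desk-scale stand-ins for the hundreds of RAD-sequenced individuals a real
study would use.

What this generator does **not** emulate: linkage (sites are independent,
so window statistics average unlinked sites), mutation-model detail,
reference bias, and genotype-calling error structure beyond missingness.
Tests passing on these data show the estimators and the integration logic
are correct, not that any particular biological dataset will behave as
cleanly.

# Divergence statistics

`wcFst()` implements the Weir & Cockerham (1984) variance-components
estimator per site (components a, b, c from sample sizes, allele
frequencies and observed heterozygosity; missing calls excluded from the
counts). Monomorphic sites are undefined, not zero, and are excluded from
averages. Negative per-site estimates are retained by default (clamping is
an option); multi-site summaries report both the per-site mean (the
convention behind headline "average F~ST~" figures) and the
ratio-of-sums.

`windowDiversity()` computes π and d~XY~ in windows with callable-site
denominators: each variant site contributes its observed allele-pair
counts, each invariant callable site contributes comparisons with zero
differences. Without callable-site counts the denominator falls back to
variant sites only and is flagged — those values are not comparable across
windows with different callable fractions. `callOutliers()` uses the
empirical quantile with linear interpolation (R type 7); values at or
above the threshold are outliers, so ties are all included.

# Introgression

`pattersonD()` computes ABBA/BABA sums from population allele frequencies
polarized by the outgroup, with a delete-one jackknife over contiguous
equal-SNP blocks (default 20 blocks — the block count is not critical for
unlinked synthetic data and is configurable for real, linked data).
`enumerateTrios()` tests every population trio, orienting each so the
BBAA-like pattern is maximal and D ≥ 0, then applies the three-part rule:
Z > 3, BH-corrected q < 0.05 and D > 0.05. Sites where the outgroup is not
fixed are excluded from polarization by default.

# Demography

The four two-population models share nu1, nu2 (sizes relative to the
reference) and T1 (split time in units of 2N~ref~ generations); the
migration models add a symmetric rate m, active throughout (continuous),
only before T2 (ancestral), or only after T2 (secondary contact; T2 < T1
parameterized as a logistic fraction of T1 so the constraint can never be
violated during optimization).

Expected spectra come from a Monte Carlo structured coalescent rather than
a diffusion solver: genealogies are simulated backwards with per-deme
coalescence rate C(k,2)/nu and per-lineage migration rate m/2, branch
lengths accumulate into the joint-SFS cell of their subtended sample
configuration, and the mean over replicates (per unit θ) enters a Poisson
composite likelihood with θ profiled analytically. The model spectrum is
floored at a tiny positive value so observed mass in a cell the Monte
Carlo estimate left empty cannot produce −∞. Common random numbers (the
same seed at every likelihood evaluation) turn the noisy Monte Carlo
surface into a fixed surface that Nelder–Mead can descend reliably.

Fitting runs in consecutive rounds (default replicate counts 10/20/30/40);
each replicate perturbs the incumbent best parameters by log-uniform
fold-changes whose range shrinks by round (4×, 2×, 1.6×, 1.4×), and the
round's best seeds the next. The test suite uses reduced rounds (5/10) and
small spectra (8 + 8 haploid) — the estimator is the same at any size; the
reductions only set the problem sizes the checks run at. Model ranking is
by AIC with ΔAIC reported; ties prefer fewer parameters.

# Sweep scans

`ehhDecay()` computes extended haplotype homozygosity by refining identity
groups outward from the core; `ihsScan()` integrates EHH against physical
distance by the trapezoid rule in both directions (cutoff 0.05, both
configurable), giving iHH for each allele class and
iHS = ln(iHH~A~/iHH~D~). Sites whose EHH never falls below the cutoff
before the data end are flagged truncated and kept by default, since
synthetic regions are short. `standardizeIhs()` bins sites by derived
frequency (equal-width bins) and standardizes within bins using the
population (1/n) standard deviation, so a two-site bin standardizes to
exactly ±1; outliers are |iHS| at or above its empirical 99th percentile.

`simulateForwardRegion()` provides the haplotype data: a discrete
Wright–Fisher population with infinite-sites mutation, Poisson crossovers,
an optional additive selected site (fitnesses 1 : 1+s : 1+2s), a neutral
burn-in (default 4N generations) towards mutation–drift equilibrium, and
optional early stopping at a target derived frequency so the sweep is
sampled while still polymorphic. The scaled-down regime (N ≈ 100–200,
inflated μ and r) compresses the neutral coalescent to a few hundred
generations, so a *detectable* scaled sweep also needs a proportionally
large s: the sweep-recovery checks use s = 1 at N = 200 (2Ns = 400, the
scaled analogue of a strong natural sweep), sampled at frequency 0.85, and
pool the swept region with several neutral regions so the
frequency-bin standardization is dominated by neutral sites — exactly as a
genome-wide scan dwarfs any single swept region. At desk-scale weak
selection (2Ns ≈ 20) the ancestral allele class is itself bottlenecked by
the sweep and the signal is not separable; this is a property of the
scaled regime, not of the estimator.

# Association

`computeGrm()` builds the centered kinship K = ZZ'/2Σf(1−f).
`lmmWaldScan()` fits y = Wα + xβ + u + ε with u ~ N(0, σ²~g~K) by maximum
likelihood over the variance ratio λ = σ²~g~/σ²~e~ after a single
eigendecomposition of K: a 25-point log-spaced grid on [1e−5, 1e5]
(evaluated for all SNPs at once with BLAS-level residualization) followed
by per-SNP Brent refinement in the bracketing interval. ML rather than
REML keeps the profile closed-form; with K = I the Wald p-values reduce
exactly to closed-form OLS, which the tests assert to 1e−6. The
multi-trait CHC analysis combines per-trait z-scores into an omnibus
Σz² ~ χ²(T) — an approximation to a full multivariate mixed model that is
exact when traits are uncorrelated given covariates, and bounded against a
multivariate-regression oracle in the tests. "Bonferroni–Hochberg"
correction is read as Benjamini–Hochberg FDR (the procedure that produces
"corrected p" in step-up form); Bonferroni is also exposed.

# Genotype–environment association

`fitLatentFactors()` alternates a ridge estimate of per-SNP environmental
effects B (penalty default 1e−5·n~sites~) with a rank-K truncated SVD of
the residual; K defaults to the study's choice of 6 and is deliberately a
configuration parameter (cross-entropy selection of K is out of scope).
`geaScan()` then re-tests each SNP against [environment, factors],
calibrates z² by the genomic inflation factor (median z²/0.4549) and
applies the dual criterion: calibrated p < 0.001 for **both** latitude and
longitude, with no further multiplicity correction — deliberately
conservative. Note that when the environmental axis is collinear with the
main axis of population structure (two species split along latitude), no
factor model can separate drift from cline; the calibration then absorbs
median inflation but power and error rates degrade. The calibration checks
therefore use environments independent of structure; the power checks use
within-species transects where the confounding is mild.

# Structure

`ldPrune()` mirrors PLINK's `--indep-pairwise` in SNP-count units
(window 50, step 10, r² > 0.01), dropping the member of an offending pair
with more missing data, then the later position. The original flag
semantics are SNP-count windows, so those units are implemented;
bp-windows would need positions that the unlinked generator does not make
meaningful. `admixtureAls()` estimates ancestry by least squares on
dosage/2 with Q rows constrained to the simplex (exact per-row
active-set solves — K is small, so the 2^K − 1 support enumeration is
cheap) and F clamped to [0,1] by coordinate descent; both steps are exact
minimizations, so the objective is monotone non-increasing, which the
tests assert. This is a least-squares stand-in for the binomial
block-relaxation of the original ADMIXTURE algorithm: simpler, convex in
each block, and adequate for the synthetic recovery checks (a 50/50
hybrid's ancestry is recovered within ±0.05). Cross-validation over K is
out of scope; K is a parameter.

# Integration

`scanPlan()` derives the five standard comparisons from the population
map: (1) species A vs B overall, (2) in allopatry only, (3) in sympatry
only, (4) contexts within species A, (5) contexts within species B.
`runScanPlan()` runs site F~ST~ (and windowed d~XY~ for the
between-species comparisons), calls 99th-quantile outliers, maps genes,
and intersects F~ST~ with d~XY~ outlier genes into the "best-supported"
set. `overlapReport()` produces pairwise and full gene-set intersections
(with unions, so inclusion–exclusion is checkable), Welch two-sample
t-tests comparing windows containing trait-associated SNPs against the
background (Welch because window classes have unequal sizes and
variances; the source analyses say only "two-sample t-tests"), and
Wilcoxon rank-sum tests of trait-associated-gene F~ST~ in sympatric vs
allopatric comparisons. A gene is "outlier" if any overlapping SNP or
window is an outlier (union semantics); a window is "trait-associated" if
it contains at least one SNP passing corrected p < 0.05.

The planted-overlap fixture (`plantedOverlapDataset()`) makes the
integration claim falsifiable: pure barrier genes are contiguous clusters
of strongly diverged sites; dual-role loci are diverged between species
(species B near fixation) yet held at intermediate frequency within the
focal species, so they are simultaneously F~ST~ outliers and mappable
QTLs; QTL-only loci are intermediate-frequency and undiverged. Each
planted QTL drives its own song trait at a fixed variance fraction
(default 20%), and body-size covariates are generated correlated with a
non-QTL trait so covariate correction is exercised without absorbing a
planted signal. For the dual-role check the background divergence is
lowered to F = 0.05: the Balding–Nichols tail at F = 0.10 occasionally
produces neutral sites with estimated F~ST~ above the ceiling attainable
by any site that stays polymorphic within one species (≈ 0.5), which
would make the dual-role recall depend on luck rather than on the method.

# Numerical and edge-case conventions

* Monomorphic sites: undefined F~ST~, skipped in LMM and GEA scans (no
  test statistic), masked SFS corners.
* Quantile thresholds: type-7 interpolation; ties at the threshold are all
  flagged.
* Jackknife SE = 0 with non-zero D reports Z = ∞ with a warning rather
  than NA, so the condition is visible downstream.
* All generators are exactly reproducible from (configuration, seed); the
  coalescent, forward simulator and EHH kernels are compiled (Rcpp) and
  draw from R's RNG stream so `set.seed()` governs them too.

# Known limitations

* The unlinked site-level generator cannot test window statistics against
  linked-data expectations; only the haplotype engine carries LD.
* The Monte Carlo likelihood surface has O(1/√reps) noise; with common
  random numbers this biases parameter estimates slightly at small reps
  (the recovery checks allow 25% relative error at 1000 reps).
* The omnibus multi-trait test is conservative-to-approximate under
  strong residual trait correlation.
* The GEA model shares the fundamental confounding limit of all
  latent-factor methods when environment and structure are collinear.
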