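---
title: "Methods: proteome-wide two-sample MR in protmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteome-wide two-sample MR in protmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protmr)
```

## The inference problem

Two-sample Mendelian randomization treats genetic variants as randomized
proxies for an exposure. For a protein whose plasma level is influenced
by variants near its encoding gene (cis-pQTLs), a variant satisfying the
instrumental-variable assumptions — associated with the protein,
independent of confounders, affecting the outcome only through the
protein — identifies the causal effect of the protein on a disease
outcome from two independent GWAS summary tables. `protmr` operates
entirely on summary statistics: per variant, the exposure effect
$\hat\beta_{Xj}$ (SE $\sigma_{Xj}$) and the outcome effect
$\hat\beta_{Yj}$ (SE $\sigma_{Yj}$) on the log-odds scale.

## Instrument selection

Selection composes five filters, in order; all thresholds live in
`selection_config()` and each step's kept count is logged.

* **Genome-wide significance**, exposure $p < 5\times10^{-8}$, strict
  inequality.
* **MHC exclusion**: chromosome 6, 28,477,897–33,448,354 bp inclusive.
  The MHC's extreme long-range LD makes clumped "independent" variants
  unreliable, so the region is excluded wholesale.
* **Cis window**: within 1 Mb of the gene *body* (start and end), not
  the TSS — the literal reading of "within 1 Mb of the gene"; both ends
  inclusive. Coordinates are 1-based inclusive everywhere; BED input is
  converted on read.
* **LD clumping**: greedy, p-value-ranked (ties broken lexicographically
  by variant id for determinism), removing variants with $r^2 > 0.001$
  within 10,000 kb of a kept index variant. The LD source is an explicit
  `ld_matrix` (dense or block specification) supplied by the caller or
  the simulator; the package never computes LD from genotypes, which
  keeps every analysis deterministic and download-free.
* **Weak-instrument screen**: per-variant $F = (\hat\beta/\hat\sigma)^2$,
  keeping $F > 10$. The squared z-ratio is used because the screen is
  applied per variant to summary statistics.

After matching against the outcome, instruments with outcome
$p < 5\times10^{-8}$ are removed (`exclude_outcome_associated()`), as are
instruments absent from the outcome table — no LD-proxy lookup is
attempted.

## Harmonization

Variants are matched by id only. Identical allele pairs are kept;
swapped pairs negate the outcome beta and complement its frequency;
complementary-strand codings (non-palindromic only) are resolved when
`allow_strand_flip` is on. Palindromic variants (A/T, C/G) cannot be
strand-resolved from alleles, so they are kept only when both effect
allele frequencies are available, both fall outside the ambiguity zone
$(0.42, 0.58)$, and both sit on the same side of 0.5 after label-based
alignment; everything else is dropped and logged. The half-width 0.08 is
the common two-sample-MR default and is configurable
(`harmonization_config()`); whether an original analysis inferred strand
or dropped all palindromes is usually unknowable, and both policies are
reachable here. Records without frequencies are treated as unresolvable
palindromes — the conservative choice.

## Estimators

With ratios $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ and
first-order weights $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$ (the standard
two-sample convention: $\sigma_{Xj}$ is ignored in the weight but used
by the bootstrap and MR-PRESSO):

* **IVW**: $\hat\theta = \sum w_j\hat\theta_j / \sum w_j$, fixed-effect
  SE $(\sum w_j)^{-1/2}$. The primary model is multiplicative random
  effects: the SE is scaled by $\sqrt{Q/(L-1)}$, floored at 1
  (configurable off). The floor matches the common implementation: the
  random-effects SE never falls below the fixed-effect SE under
  under-dispersion. Reporting always includes both models; a
  conditional fixed-vs-random switch on the heterogeneity p-value is
  deliberately not used, because the primary framework is multiplicative
  random effects. A single instrument reduces to the Wald ratio.
* **Cochran's Q** on the ratios against $\chi^2_{L-1}$ ($L \ge 2$).
* **MR-Egger** ($L \ge 3$): WLS of $\hat\beta_{Yj}$ on
  $\hat\beta_{Xj}$ with free intercept after orienting all exposure
  effects positive (the intercept test is orientation-dependent; the
  orientation is internal to the fit and never mutates the stored set).
  SEs carry the multiplicative overdispersion factor $\max(1, \hat\sigma)$
  and p-values use $t_{L-2}$ — the small-$L$ convention.
* **Weighted median** ($L \ge 3$): sorted ratios, cumulative normalized
  weights taken at interval midpoints, linear interpolation at 0.5. SE
  by parametric bootstrap: both effect sides resampled from their
  reported normal distributions, the point estimator recomputed, the SD
  of the replicates taken; 1,000 iterations by default.
* **Weighted mode** ($L \ge 3$): argmax of a weighted Gaussian KDE of
  the ratios with bandwidth
  $\varphi \cdot 0.9\min(\mathrm{sd}, \mathrm{IQR}/1.34)L^{-1/5}$
  ($\varphi = 1$ by default); degenerate bandwidth returns the common
  ratio. SE by the same bootstrap.
* **MR-PRESSO** ($L \ge 4$): observed
  $\mathrm{RSS} = \sum_j (\hat\beta_{Yj} - \hat\theta_{(-j)}\hat\beta_{Xj})^2/\sigma_{Yj}^2$
  with leave-one-out fixed-effect IVW estimates; the null distribution
  re-simulates both effect sides and recomputes the leave-one-out fits.
  The global p is the exceedance proportion; per-variant outlier
  p-values are Bonferroni-adjusted by $L$ and flagged below 0.05, after
  which an outlier-corrected IVW is reported.

P-values are two-sided and floored at the smallest positive double. All
stochastic components take an explicit seed (`estimator_config(seed =)`),
are single-threaded, and reproduce byte-identically; stochastic calls
without a seed are an error rather than silently irreproducible.

## Screening

`run_proteome()` fits each protein and BH-adjusts the primary
(IVW-MRE) p-values. The FDR family is the set of proteins with a
successful fit in the current run — not the assayed panel — because a
protein without instruments contributes no test; the family size is
reported alongside the counts. `run_phewas()` excludes outcomes with
fewer than 50 cases (configurable) before any fitting, re-harmonizes the
fixed instruments per outcome, and BH-adjusts across retained outcomes;
outcomes are fit marginally, with no cross-outcome correlation model.
`bh_fdr()` delegates to `stats::p.adjust(method = "BH")` with missing
entries excluded from the family.

## The synthetic-study generator

`simulate_study()` emulates the structure of a large plasma-proteome
exposure panel against a rare binary outcome. Defaults: 35,559 exposure
samples; 1,543 cases and 391,037 controls; 5 instruments per protein.
Per protein it generates a gene interval, 5 LD-block leads in the cis
window, correlated satellites (exchangeable within-block correlation at
the z-score level), null cis variants, and significant MHC decoys on
chromosome 6; the chromosome-6 gene is placed just distal to the MHC so
its decoys survive the cis filter and only the MHC exclusion removes
them.

Effects sit on the standardized-genotype scale, giving the closed-form
SE $(2\,\mathrm{maf}(1-\mathrm{maf})\,n)^{-1/2}$; binary outcomes use
the effective sample size $n_1 n_0/(n_1+n_0)$, which preserves the
log-odds signal-to-noise structure without individual-level logistic
simulation. True lead effects exceed the genome-wide-significance effect
size by a uniform multiplier in $(1.6, 3)$, chosen so that detection at
the exposure sample size is essentially certain while per-variant F
statistics stay in a realistic range (roughly 75–270). The outcome model
is $\beta_{Yj} = \theta\beta_{Xj} + \alpha_j$ with $\alpha_j$ zero,
$N(0,\tau^2)$ (balanced) or sign-oriented $N(\mu,\tau^2)$
(directional); the directional draw is oriented by the sign of the true
exposure effect because directional pleiotropy is defined per
exposure-increasing allele — without this, random allele coding would
cancel the direction and the Egger intercept would have nothing to
recover.

Outcome allele representation is scrambled at configured rates (EA/OA
swaps by default; strand flips optional and never applied to
palindromes, for which a strand flip is not representation-invariant).
Scrambling and observation noise use separate RNG substreams, so a
scrambled and a clean outcome from the same seed carry identical
underlying associations — the basis of the harmonization-invariance
tests.

What the generator does **not** emulate: realistic MAF spectra,
annotation-aware genetic architecture, sample overlap between studies,
LD beyond exchangeable blocks, genome-build mismatches, or indels.
Passing tests therefore demonstrate correctness of the estimators and
pipeline logic under the assumed generating model, not robustness to
every artifact of real GWAS data.

## Numerical and design choices

* Validation is total at the boundary: rows violating the
  variant-association invariants (non-ACGT or identical alleles,
  non-positive SE, p outside (0,1], frequency outside [0,1], duplicate
  ids) are dropped and counted on read, so downstream code never checks
  them again. Indels are dropped because the harmonization rules are
  defined for SNVs.
* Clumping ties broken by variant id; greedy order is p-ascending.
* Weighted-median interpolation at an exact knot returns the knot value,
  so equal weights at odd $L$ give the plain median.
* Formatting (two-decimal ORs, two-significant-digit scientific
  p-values, e.g. `3.96E-05`) happens only in the reporting layer;
  stored values keep full precision.
* Problem sizes in the validation suite — 1,000 replicates for effect
  recovery, 2,000 for type-I error, 500 for robustness ordering, 200
  seeds of 200-protein screens for FDR calibration — were chosen to give
  Monte-Carlo standard errors small enough for 3-SE acceptance bands
  while keeping each suite in the minutes range on one CPU.

## Known limitations

No colocalization, Steiger filtering, multivariable MR or MR-RAPS; no
LD-proxy rescue of instruments missing in the outcome; no VCF input or
genome-build liftover; variant matching by id only. The per-variant
$F$ screen is a heuristic, not a formal weak-instrument correction; with
few instruments the Egger intercept test has little power, and the
weighted mode's bandwidth rule is a convention whose tuning constant is
exposed but not optimized.
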