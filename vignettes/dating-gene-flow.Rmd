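---
title: "Dating archaic-modern gene flow from divergence and haplotype length"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating archaic-modern gene flow from divergence and haplotype length}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleodater)
```

## The dating model

The package dates the most recent common ancestor (TMRCA) of two
chromosomes — typically one sampled from an ancient genome and one from a
present-day individual — from two kinds of evidence that accumulate as
clocks since their common ancestor:

* **Pairwise differences.** Over `N` jointly callable bases, the number of
  nucleotide differences `D` between two chromosomes is Poisson with mean
  `θN·T`, where `θ = 4·Ne·µ` is the population-scaled mutation rate and
  time `T` is measured in units of `2·Ne` generations.
* **Shared-haplotype length.** Recombination whittles down the haplotype
  shared by the two lineages; its length `L` (bp) is modeled as
  Gamma(2, 2·ρ·T) with `ρ = 4·Ne·r` the population-scaled recombination
  rate and `r` the local per-bp per-generation crossover rate
  (1 cM/Mb = 1e-8).

With the standard exponential coalescent prior `T ~ Exp(1)` (rate 1 on the
`2·Ne`-generation time scale), both observations are conjugate, so the
posterior of `T` is a gamma distribution in all three configurations:

| evidence            | shape α   | rate β              |
|---------------------|-----------|---------------------|
| differences only    | `D + 1`   | `θN + 1`            |
| length only         | `3`       | `2ρL + 1`           |
| joint               | `D + 3`   | `θN + 2ρL + 1`      |

The rate decomposes additively into the mutation mass
(`scaled_theta()`), the recombination mass (`scaled_rho()`), and the
prior's 1 — which is why the joint posterior is simply the product of the
two likelihoods with a single prior.

### Branch shortening for ancient samples

An individual who died `S` years ago stopped accumulating mutations at
that point, so the na&iuml;ve posterior is biased downward. The package's
correction truncates the posterior below at `S/2` (in scaled time) and
adds `S/2` to both the expectation and the quantiles. The posterior mean
then has the closed form

$$
E = \frac{1}{\beta}\left(\alpha +
    \frac{(\beta S/2)^{\alpha} e^{-\beta S/2}}
         {\Gamma(\alpha,\, \beta S/2)}\right) + \frac{S}{2},
$$

with $\Gamma(\alpha, x)$ the upper incomplete gamma function. This is
identically $E[T \mid T \ge S/2] + S/2$, which is how
`truncated_gamma_mean()` is tested: an independent oracle integrates the
truncated density directly (for integer shapes the integral reduces to a
finite factorial sum after a binomial expansion) and the two agree to
better than 1e-8 in relative error across shapes 1–20, rates 0.5–100 and
truncation points up to one coalescent unit.

The truncation point is `S/2`, not `S`: on the `2·Ne`-generation scale a
calendar interval of `S` years on one branch corresponds to `S/2` units of
pairwise time, and a single consistent choice must be used for the mean
and the quantiles. With this convention, expectations and the 2.5%/97.5%
truncated-gamma quantiles (`qtrunc_gamma()`, then shifted by `S/2`)
produce mutually consistent point estimates and intervals; this is the
convention the package adopts throughout.

Confidence intervals are equal-tailed 95% intervals of the truncated
gamma, computed through the upper tail so they remain accurate when the
truncation removes nearly all posterior mass.

### The ×2 fixed-allele correction

When a haplotype's defining alleles are fixed in one of the two
populations, recombination events occurring in that population leave no
visible trace: every exchange swaps identical alleles. Only half of the
pairwise recombination opportunity is then observable, and the
length-only age estimate must be doubled. `date_from_haplotype_length()`
exposes this as an explicit `fixed_in_modern` flag — never applied
implicitly — and doubles the point estimate and both CI endpoints after
the full computation (truncation, shift, conversion to years). The flag
is recorded in the returned object.

### Incomplete lineage sorting

A haplotype shared between two diverged groups need not come from gene
flow: it can be a remnant of shared ancestral variation. Under that
null, the shared tract is broken by recombination over the whole branch
length `T` (generations) separating the two sampled lineages since the
population split, and its expected length is `1/(r·T)` bp
(`ils_expected_length()`). The tract length is modeled as
Gamma(2, 1/L_expected), so the probability of observing a tract at least
as long as the one seen is the survival function
`exp(-x)(1+x)`, `x = observed/expected` (`ils_tail_probability()`).
`ils_test()` evaluates this across several recombination maps and reports
the most conservative (largest) tail probability. Only the branch to the
*older* group's sample is counted when the fixation time of the defining
alleles in the other group is unknown — a conservative choice that
lengthens the expected tract and inflates the tail probability.

## Parameters and defaults

| parameter | default | units | why |
|-----------|---------|-------|-----|
| `ne`      | 10,000  | diploid individuals | standard long-term human effective size; enters both scalings and the time conversion |
| `mu`      | 1.45e-8 | mutations/bp/generation | pedigree-based human rate |
| `gen_years` | 29    | years | human generation interval |
| `window_bp` | 276,000 | bp | divergence-scan window matching the focal haplotype's span |
| `min_calls` | 10,000 | bp | discard windows with fewer jointly called bases |
| sweep threshold | 0.025 | cM | genetic length not reached by neutral segments |
| trajectory spacing | 50,000 | bp | thins linked ascertained sites |

One scaled time unit equals `2·Ne·gen_years` years (580,000 years at the
defaults). Years are carried as floats end to end; rounding to integer
kya (`as_kya()`, round-half-even) happens only at presentation.
Local mutation rates can be cross-checked against trio data with
`local_mutation_rate()` (de novo counts over twice the region length
times the trio count).

## Genotype-matrix procedures

`genotype_matrix()` stores polarized derived-allele dosages for a mixed
panel: diploid genotypes and pseudo-haploid (ploidy 1) representations of
low-coverage ancient genomes, which carry one randomly sampled
high-quality base per position, sampled upstream — the matrix never
re-samples them. Polarization uses the 3-of-4 great-ape consensus rule
(`call_ancestral()`): the ancestral allele must be carried by at least
three of four ape reference assemblies, with at most one missing or
discordant.

`pairwise_differences()` draws one allele per individual at unphased
heterozygous sites. The draws come from a private RNG stream seeded by
the user seed together with the sorted sample pair and the region, so
counts are reproducible, symmetric in the two samples, and independent of
call order; the caller's RNG state is left untouched. The spacing filter
of the trajectory test is greedy in coordinate order (leftmost site kept
first); `r2_linkage()` uses genotype-dosage correlation, which requires
no phasing and reduces to the standard haplotype r² for haploid data.
An EM-based haplotype-frequency estimator was considered and not
implemented: for the tagging decisions made here (thresholded r² against
an anchor dosage) the dosage correlation is monotone in the quantity of
interest and far simpler to reason about.

`split_deepest_clades()` defines the two deepest clades by the pair of
chromosomes with the most pairwise differences (ties broken
lexicographically by sample name, making the result deterministic) and
assigns the rest by shared derived alleles — at least two shared with one
definer and at most one with the other — excluding potential recombinants
that would bias cross-clade divergence downward.

In the trajectory test (`frequency_trajectory_test()`), "carries the
derived allele" means at least one derived allele — a heterozygote
counts as a carrier. Missingness is counted in alleles (a missing diploid
call is two missing alleles) with cohort-specific caps; the default caps
(1 of 4 early alleles, 2 of 6 late alleles) mirror the cohort sizes of
the motivating Neandertal analysis. Transversions-only is the default
because post-mortem cytosine deamination inflates apparent C↔T/G↔A
changes in ancient DNA.

## Enrichment test

`permutation_enrichment()` draws `n_draw` records from a
missense-variant database without replacement per replicate (the draw is
a subset of distinct database records; at genome scale the distinction
from with-replacement sampling is negligible, but without-replacement is
exact for small synthetic databases where the test is validated against
complete enumeration). Three statistics are tracked per replicate: the
number of drawn variants in any target-set gene (a variant in several
set genes counts once), the maximum number of variants landing in a
single set gene, and the number of set genes hit. The per-gene
statistics are computed over the target gene set, matching how the
observed values are defined. One-tailed p-values count replicates at or
above the observed value; a zero count prints as `< 1/reps`.

Gene sets come from keyword matching on ontology term names
(case-insensitive substring, obsolete terms excluded) joined to GAF
annotations. `NOT`-qualified annotations are excluded by default
(toggle: `exclude_not`), since they assert non-association. No
ontology-graph propagation is performed: annotations are matched to the
keyword-selected terms directly. Propagation along `is_a` edges would
only add genes annotated to descendants of matched terms, and because
term names usually contain their parents' keywords the practical
difference is small; the direct match keeps the gene set reproducible
from the two input files alone.

## Synthetic data: what it emulates and what it does not

`simulate_dating_observables()` inverts the dating model exactly:
`T ~ Exp(1)` truncated at `S/2`, `D | T ~ Poisson(θN·T)`,
`L | T ~ Gamma(2, 2ρT)`. Because generator and estimator share the same
probability model, posterior 95% intervals must cover the true `T` at
the nominal rate — the package checks 95% ± 2% over 10,000 replicates —
and any miscalibration indicates an implementation defect, not model
misfit. The flip side: passing this test says nothing about model
adequacy on real genomes, where recombination hotspots, gene conversion
and mutation-rate variation violate the homogeneous-clock assumptions.

`simulate_genotype_matrix()` plants known structure — an introgressed
block whose carriers share every block allele, trajectory sites with
prescribed cohort carriers, i.i.d. background sites with a uniform
derived-allele frequency, per-cohort missingness — so the scan procedures
can be tested for exact recovery. It makes no attempt to mimic real
linkage disequilibrium decay, population structure, or demographic
history; a coalescent simulator can be plugged in upstream where that
matters. `simulate_variant_db()` builds databases with an exact in-set
record fraction so the permutation test can be checked against
closed-form hypergeometric expectations and full enumeration.
`write_fixture_bundle()` serializes a complete input set (VCF, BED
masks, sample sheet, map, variant DB, GAF/OBO, JSON manifest with the
ground truth); files regenerate byte-identically from the same seed.

## Numerical choices

* Incomplete-gamma ratios are evaluated in log space via the regularized
  upper tail (`pgamma(log.p = TRUE, lower.tail = FALSE)`), stable for
  `βS/2` far beyond the posterior bulk and for shapes up to ~100.
* Truncated quantiles are computed through the upper tail,
  `qgamma((1-p)·Q0, lower.tail = FALSE)`, avoiding catastrophic
  cancellation when the truncation point sits deep in the distribution.
* Map repair fills a gap with the arithmetic mean of the two flanking
  window rates, truncates partially overlapping windows to start at the
  predecessor's end, and drops fully contained windows; the operation is
  idempotent and preserves the covered span exactly. No extrapolation
  beyond the first and last windows — queries outside coverage error
  rather than guess.
* Region strings as printed in genome-browser coordinates parse so that
  length = end − start; all interval arithmetic is 0-based half-open
  internally.
* Degenerate inputs fail loudly: zero callable bases, zero-length
  haplotypes, monomorphic sites in r², all-identical chromosomes in
  clade splitting, and an empty ascertainment in the trajectory test
  (which reports an `NA` proportion rather than 0/0).

## Problem sizes used in the test suite

The suite favors small, sharply checkable instances: exact enumeration
oracles run on 10-variant databases (45 possible draws), scan fixtures
use tens of sites and at most a dozen samples, and the two stochastic
calibration checks use 10,000 replicates (CI coverage) and 10,000
permutation replicates (agreement with enumeration within 3/√reps).
These sizes give the stochastic checks standard errors well below the
asserted tolerances while keeping the whole suite under about ten
seconds.

## Known limitations

* Constant `Ne` and a single panmictic coalescent prior; no demography,
  no MCMC, no phasing. Population growth or structure shifts the prior
  mass and would bias dates derived from it.
* The haplotype-length clock assumes the tract is delimited exactly;
  call errors at tract edges propagate into `L` and hence into β.
* The ILS test conditions on a point estimate of the local recombination
  rate per map; rate uncertainty is handled only by comparing maps.
* Pseudo-haploid sampling of low-coverage genomes trades power for
  robustness; heterozygous sites in such samples are invisible.
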