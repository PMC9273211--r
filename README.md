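# paleodater

Tools for dating gene flow between archaic and modern human populations
from genome sequence data, and for the companion analyses such a study
needs: an incomplete-lineage-sorting (ILS) test for shared haplotypes,
recombination-map repair and genetic-length queries, polarized
genotype-matrix scans (informative-site ascertainment, window divergence,
r²-based haplotype tagging, clade splitting, cohort allele-frequency
trajectories), a permutation test for enrichment of missense variants in
a Gene Ontology-derived gene set, and seeded synthetic-data generators so
every stage runs and is testable offline.

## The model

The TMRCA `T` of two chromosomes (scaled in units of `2·Ne` generations)
is dated from two conjugate clocks under an `Exp(1)` coalescent prior:

* `D` pairwise differences over `N` jointly called bases:
  `D | T ~ Poisson(θN·T)`, `θ = 4·Ne·µ`;
* a shared haplotype of length `L` bp at local recombination rate `r`:
  `L | T ~ Gamma(2, 2ρT)`, `ρ = 4·Ne·r`.

The posterior is `Gamma(α, β)` with `α = D + 1, β = θN + 1`
(differences), `α = 3, β = 2ρL + 1` (length), or
`α = D + 3, β = θN + 2ρL + 1` (joint). For an ancient sample that died
`S` years ago, the posterior is truncated below at `S/2` (scaled) and
shifted by `S/2`, giving the posterior mean

    E = (1/β)·(α + (βS/2)^α · e^(−βS/2) / Γ(α, βS/2)) + S/2

with `Γ(α,·)` the upper incomplete gamma function; 95% CIs are truncated
gamma quantiles plus the same shift. When the haplotype's alleles are
fixed in one population, half of the recombination opportunity is
invisible and the length-only estimate is doubled (explicit
`fixed_in_modern` flag).

Under ILS rather than gene flow, a shared tract over branch length `T`
generations has expected length `1/(r·T)` and its observed length is
tested against `Gamma(2, 1/L_expected)`.

## Worked example

Dating a haplotype shared between an archaic genome (sampled ~80 kya,
hence branch shortening `S = 80,000` years) and present-day carriers,
from 7 differences over 36,106 jointly called bases and a 102 kb shared
haplotype at 0.169 cM/Mb:

```r
library(paleodater)
p <- coalescent_params(ne = 10000, mu = 1.45e-8, gen_years = 29)

tmrca_from_divergence(diff_count(7, 36106), p, s_years = 80000)
#> TMRCA estimate: 251.5 kya (95% CI 131.4-421.3 kya)
#>   gamma posterior: alpha = 8, beta = 21.9415 (thetaN = 20.9415, 2rhoL = 0.0000)
#>   branch shortening S = 80000 years

tmrca_joint(diff_count(7, 36106), haplotype_obs(102000, 0.169), p,
            s_years = 80000)
#> TMRCA estimate: 202.4 kya (95% CI 118.0-317.3 kya)
#>   gamma posterior: alpha = 10, beta = 35.7319 (thetaN = 20.9415, 2rhoL = 13.7904)
#>   branch shortening S = 80000 years
```

The joint estimate is younger and tighter than the divergence-only one:
the long shared haplotype is evidence against an old common ancestor.

Is a 276 kb shared haplotype explicable without gene flow? Over the
~510 ky separating the two groups' sampled lineages (17,586 generations
of 29 years):

```r
ils_test(276000, c(0.148, 0.191), split_years = 550000,
         sample_age_years = 40000)$p_max
#> [1] 0.006211171
```

Even under the more conservative map the tract is far longer than ILS
can plausibly produce, so shared ancestral variation is rejected and
gene flow remains as the explanation.

Every estimator also runs on synthetic data with known truth, e.g.
`simulate_dating_observables()` draws `(T, D, L)` triples from the
generative model so CI calibration can be verified, and
`write_fixture_bundle()` emits a complete VCF/BED/TSV/GAF/OBO input set
from a seed.

A thin command-line wrapper over the same functions is installed at
`inst/cli/paleodater` (subcommands `date-divergence`, `date-length`,
`date-joint`, `ils-test`, `repair-map`, `genetic-length`, `enrich`,
`simulate`; JSON output).

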