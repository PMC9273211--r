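#' Coalescent scaling parameters
#'
#' Bundles the constants that convert between coalescent time (scaled in
#' units of 2 Ne generations) and calendar years: the diploid effective
#' population size, the per-base per-generation mutation rate, and the
#' generation time. One scaled time unit equals `2 * ne * gen_years` years.
#'
#' The defaults (Ne = 10,000, mu = 1.45e-8 mutations/bp/generation,
#' 29-year generations) are the values used throughout the package's
#' worked analyses of archaic human genomes.
#'
#' @param ne Diploid effective population size (individuals, > 0).
#' @param mu Mutation rate (mutations per base pair per generation, > 0).
#' @param gen_years Generation time in years (> 0).
#'
#' @return An object of class `coalescent_params`.
#' @examples
#' p <- coalescent_params()
#' years_per_scaled_unit(p)  # 580,000 years per unit of 2*Ne generations
#' @export
coalescent_params <- function(ne = 10000, mu = 1.45e-8, gen_years = 29) {
  stopifnot(is.numeric(ne), length(ne) == 1L, ne > 0,
            is.numeric(mu), length(mu) == 1L, mu > 0,
            is.numeric(gen_years), length(gen_years) == 1L, gen_years > 0)
  structure(list(ne = ne, mu = mu, gen_years = gen_years),
            class = "coalescent_params")
}

#' @rdname coalescent_params
#' @param params A `coalescent_params` object.
#' @export
years_per_scaled_unit <- function(params) {
  stopifnot(inherits(params, "coalescent_params"))
  2 * params$ne * params$gen_years
}

#' @export
print.coalescent_params <- function(x, ...) {
  cat(sprintf("coalescent_params: Ne = %g, mu = %g /bp/gen, generation = %g y\n",
              x$ne, x$mu, x$gen_years))
  cat(sprintf("  1 scaled time unit (2*Ne generations) = %g years\n",
              years_per_scaled_unit(x)))
  invisible(x)
}

#' Pairwise-difference observation
#'
#' The number of nucleotide differences `d` between two (pseudo-)haploid
#' sequences over `n` jointly callable bases.
#'
#' @param d Number of pairwise differences (integer >= 0).
#' @param n Number of bases with genotype calls in both samples (> 0).
#' @return An object of class `diff_count`.
#' @export
diff_count <- function(d, n) {
  stopifnot(is.numeric(d), length(d) == 1L, d >= 0, d == round(d),
            is.numeric(n), length(n) == 1L, n > 0, d <= n)
  structure(list(d = as.integer(d), n = n), class = "diff_count")
}

#' Shared-haplotype observation
#'
#' The physical length of the haplotype shared by two chromosomes and the
#' local recombination rate, as used by the haplotype-length clock.
#'
#' @param length_bp Shared haplotype length in base pairs (> 0).
#' @param rate_cmmb Local recombination rate in cM/Mb (>= 0);
#'   1 cM/Mb = 1e-8 crossovers per bp per generation.
#' @return An object of class `haplotype_obs`.
#' @export
haplotype_obs <- function(length_bp, rate_cmmb) {
  stopifnot(is.numeric(length_bp), length(length_bp) == 1L, length_bp > 0,
            is.numeric(rate_cmmb), length(rate_cmmb) == 1L, rate_cmmb >= 0)
  structure(list(length_bp = length_bp, rate_cmmb = rate_cmmb),
            class = "haplotype_obs")
}

#' Population-scaled mutation mass over the callable bases
#'
#' Returns theta * N = 4 * Ne * mu * N, the expected scaled number of
#' mutations over `n_callable` jointly called bases per scaled time unit.
#'
#' @inheritParams years_per_scaled_unit
#' @param n_callable Number of bases called in both samples (> 0).
#' @return Unitless scaled mutation mass.
#' @examples
#' scaled_theta(coalescent_params(), 36106)  # 20.94148
#' @export
scaled_theta <- function(params, n_callable) {
  stopifnot(inherits(params, "coalescent_params"),
            is.numeric(n_callable), length(n_callable) == 1L, n_callable > 0)
  4 * params$ne * params$mu * n_callable
}

#' Population-scaled recombination mass of a shared haplotype
#'
#' Returns 2 * rho * L = 2 * (4 * Ne * r_bp) * L with
#' r_bp = rate_cmmb * 1e-8 crossovers per bp per generation. This is the
#' rate-parameter contribution of the shared-haplotype length to the
#' gamma posterior of the coalescence time.
#'
#' @inheritParams years_per_scaled_unit
#' @param obs A [haplotype_obs()].
#' @return Unitless scaled recombination mass.
#' @examples
#' scaled_rho(coalescent_params(), haplotype_obs(102000, 0.169))  # 13.7904
#' @export
scaled_rho <- function(params, obs) {
  stopifnot(inherits(params, "coalescent_params"), inherits(obs, "haplotype_obs"))
  r_bp <- obs$rate_cmmb * 1e-8
  2 * (4 * params$ne * r_bp) * obs$length_bp
}

#' Branch length in generations between a population split and a sample
#'
#' @param split_years Age of the population split (years before present).
#' @param sample_age_years Age of the sampled individual (years before
#'   present); must be younger than the split.
#' @param gen_years Generation time in years.
#' @return Number of generations, rounded to the nearest integer.
#' @examples
#' branch_generations(550000, 40000, 29)  # 17586
#' @export
branch_generations <- function(split_years, sample_age_years, gen_years = 29) {
  stopifnot(split_years > sample_age_years, sample_age_years >= 0, gen_years > 0)
  round((split_years - sample_age_years) / gen_years)
}

#' De novo mutation rate from trio counts in a region
#'
#' Estimates the per-bp per-generation mutation rate of a region as the
#' number of de novo mutations observed in probands divided by twice the
#' region length and the number of trios.
#'
#' @param n_de_novo Number of de novo mutations observed (>= 0).
#' @param region_length_bp Region length in bp (> 0).
#' @param n_trios Number of parent-offspring trios (> 0).
#' @return Mutation rate per bp per generation.
#' @export
local_mutation_rate <- function(n_de_novo, region_length_bp, n_trios) {
  stopifnot(n_de_novo >= 0, region_length_bp > 0, n_trios > 0)
  n_de_novo / (2 * region_length_bp * n_trios)
}
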