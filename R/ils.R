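#' Expected length of a haplotype shared through incomplete lineage sorting
#'
#' Under neutrality, a haplotype inherited from the common ancestral
#' population of two groups is broken down by recombination over the summed
#' branch length T (generations) separating the two sampled lineages since
#' the split. Its expected length is 1 / (r_bp * T) with
#' r_bp = rate_cmmb * 1e-8 crossovers per bp per generation.
#'
#' @param rate_cmmb Local recombination rate in cM/Mb (> 0).
#' @param t_generations Summed branch length since the split, in
#'   generations (> 0).
#' @return Expected shared tract length in bp.
#' @examples
#' ils_expected_length(0.191, 17586)  # ~29,771 bp
#' @export
ils_expected_length <- function(rate_cmmb, t_generations) {
  stopifnot(rate_cmmb > 0, t_generations > 0)
  1 / (rate_cmmb * 1e-8 * t_generations)
}

#' Tail probability of an ILS-shared tract being as long as observed
#'
#' The length of a tract shared through incomplete lineage sorting is
#' modeled as Gamma(shape = 2, rate = 1 / L_expected). Returns the
#' probability that such a tract is at least as long as the observed one,
#' i.e. the survival function exp(-x) * (1 + x) with
#' x = observed / expected.
#'
#' @param observed_bp Observed shared tract length in bp (>= 0).
#' @param expected_bp Expected ILS tract length in bp (> 0), e.g. from
#'   [ils_expected_length()].
#' @return Probability in `[0, 1]`.
#' @export
ils_tail_probability <- function(observed_bp, expected_bp) {
  stopifnot(all(observed_bp >= 0), all(expected_bp > 0))
  stats::pgamma(observed_bp, shape = 2, rate = 1 / expected_bp,
                lower.tail = FALSE)
}

#' Incomplete-lineage-sorting test for a shared haplotype
#'
#' Convenience wrapper: computes the branch length in generations from the
#' population split time and the age of the sampled carrier, the expected
#' ILS tract length at each supplied recombination rate, and the tail
#' probability of the observed tract under each. The test statistic is the
#' maximum tail probability across rates (the most conservative map).
#'
#' @param observed_bp Observed shared haplotype length in bp.
#' @param rates_cmmb One or more local recombination rates (cM/Mb).
#' @param split_years Population split time (years before present).
#' @param sample_age_years Age of the haplotype carrier (years before
#'   present).
#' @param gen_years Generation time in years.
#' @return A list with `t_generations`, a per-rate data frame
#'   (`rate_cmmb`, `expected_bp`, `p`), and `p_max`.
#' @examples
#' ils_test(276000, c(0.148, 0.191), 550000, 40000)
#' @export
ils_test <- function(observed_bp, rates_cmmb, split_years, sample_age_years,
                     gen_years = 29) {
  t_gen <- branch_generations(split_years, sample_age_years, gen_years)
  exp_bp <- vapply(rates_cmmb, ils_expected_length, numeric(1),
                   t_generations = t_gen)
  p <- ils_tail_probability(observed_bp, exp_bp)
  list(t_generations = t_gen,
       per_rate = data.frame(rate_cmmb = rates_cmmb, expected_bp = exp_bp,
                             p = p),
       p_max = max(p))
}
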