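#' Gamma posterior specification for a coalescence time
#'
#' The posterior of the scaled coalescence time under the conjugate model
#' is Gamma(shape = alpha, rate = beta) with
#' `beta = theta_n + two_rho_l + 1`: an Exp(1) coalescent prior plus the
#' scaled mutation mass of the compared bases and the scaled recombination
#' mass of the shared haplotype.
#'
#' @param alpha Gamma shape (>= 1).
#' @param theta_n Scaled mutation mass theta*N (>= 0); see [scaled_theta()].
#' @param two_rho_l Scaled recombination mass 2*rho*L (>= 0);
#'   see [scaled_rho()].
#' @return An object of class `posterior_spec` with fields `alpha`,
#'   `theta_n`, `two_rho_l` and `beta`.
#' @export
posterior_spec <- function(alpha, theta_n = 0, two_rho_l = 0) {
  stopifnot(alpha >= 1, theta_n >= 0, two_rho_l >= 0)
  structure(list(alpha = alpha, theta_n = theta_n, two_rho_l = two_rho_l,
                 beta = theta_n + two_rho_l + 1),
            class = "posterior_spec")
}

tmrca_estimate <- function(point_years, ci_low_years, ci_high_years,
                           spec, s_years, doubled) {
  stopifnot(ci_low_years <= point_years, point_years <= ci_high_years,
            point_years >= s_years / 2)
  structure(list(point_years = point_years,
                 ci_low_years = ci_low_years,
                 ci_high_years = ci_high_years,
                 spec = spec, s_years = s_years, doubled = doubled),
            class = "tmrca_estimate")
}

#' @export
print.tmrca_estimate <- function(x, ...) {
  cat(sprintf("TMRCA estimate: %.1f kya (95%% CI %.1f-%.1f kya)\n",
              x$point_years / 1000, x$ci_low_years / 1000,
              x$ci_high_years / 1000))
  cat(sprintf("  gamma posterior: alpha = %g, beta = %.4f (thetaN = %.4f, 2rhoL = %.4f)\n",
              x$spec$alpha, x$spec$beta, x$spec$theta_n, x$spec$two_rho_l))
  cat(sprintf("  branch shortening S = %g years%s\n", x$s_years,
              if (isTRUE(x$doubled)) "; x2 fixed-allele correction applied" else ""))
  invisible(x)
}

#' Round an estimate to integer kya for presentation
#'
#' @param x A `tmrca_estimate` or a vector of years.
#' @return Integer thousands of years (round half to even).
#' @export
as_kya <- function(x) {
  if (inherits(x, "tmrca_estimate"))
    x <- c(point = x$point_years, ci_low = x$ci_low_years,
           ci_high = x$ci_high_years)
  round(x / 1000)
}

# Shared dating engine: truncated-gamma mean and 2.5/97.5% quantiles,
# shifted by S/2 and converted to years; optional x2 correction applied
# to point and CI after the shift.
.date_gamma <- function(spec, params, s_years, doubled = FALSE,
                        ci_level = 0.95) {
  stopifnot(inherits(spec, "posterior_spec"), s_years >= 0)
  ypu <- years_per_scaled_unit(params)
  s_scaled <- s_years / ypu
  half <- s_scaled / 2
  point <- truncated_gamma_mean(spec$alpha, spec$beta, s_scaled)
  lo <- qtrunc_gamma((1 - ci_level) / 2, spec$alpha, spec$beta, half) + half
  hi <- qtrunc_gamma(1 - (1 - ci_level) / 2, spec$alpha, spec$beta, half) + half
  f <- if (doubled) 2 else 1
  tmrca_estimate(f * point * ypu, f * lo * ypu, f * hi * ypu,
                 spec, s_years, doubled)
}

#' Date a common ancestor from pairwise differences
#'
#' Posterior of the TMRCA of two chromosomes given D pairwise differences
#' over N jointly called bases: Gamma(D + 1, theta*N + 1), truncated below
#' at S/2 (in scaled time) and shifted by S/2 to correct for the branch
#' shortening S of an ancient sample.
#'
#' @param diff A [diff_count()].
#' @param params A [coalescent_params()].
#' @param s_years Branch shortening in years (age of the ancient sample;
#'   0 for two present-day samples).
#' @return A `tmrca_estimate` with point and 95% CI in years.
#' @examples
#' tmrca_from_divergence(diff_count(7, 36106), coalescent_params(),
#'                       s_years = 80000)
#' @export
tmrca_from_divergence <- function(diff, params, s_years = 0) {
  stopifnot(inherits(diff, "diff_count"), s_years >= 0)
  spec <- posterior_spec(diff$d + 1, theta_n = scaled_theta(params, diff$n))
  .date_gamma(spec, params, s_years)
}

#' Date gene flow from the length of a shared haplotype
#'
#' Posterior of the TMRCA given only the length L of the shared haplotype:
#' Gamma(3, 2*rho*L + 1), truncated and shifted by S/2 as in
#' [tmrca_from_divergence()]. When the haplotype carries alleles fixed in
#' modern humans, recombination on the modern branch is invisible and the
#' estimate (point and CI) is doubled after the full computation; request
#' this with `fixed_in_modern = TRUE`.
#'
#' @param obs A [haplotype_obs()].
#' @inheritParams tmrca_from_divergence
#' @param fixed_in_modern Apply the x2 fixed-allele correction.
#' @return A `tmrca_estimate`.
#' @examples
#' date_from_haplotype_length(haplotype_obs(102000, 0.169),
#'                            coalescent_params(), s_years = 40000)
#' @export
date_from_haplotype_length <- function(obs, params, s_years = 0,
                                       fixed_in_modern = FALSE) {
  stopifnot(inherits(obs, "haplotype_obs"), s_years >= 0)
  spec <- posterior_spec(3, two_rho_l = scaled_rho(params, obs))
  .date_gamma(spec, params, s_years, doubled = isTRUE(fixed_in_modern))
}

#' Date a common ancestor jointly from differences and haplotype length
#'
#' Combines both observations: Gamma(D + 3, theta*N + 2*rho*L + 1),
#' truncated and shifted by S/2. The rate decomposes additively into the
#' mutation and recombination masses plus the Exp(1) prior.
#'
#' @inheritParams tmrca_from_divergence
#' @param obs A [haplotype_obs()].
#' @return A `tmrca_estimate`.
#' @examples
#' tmrca_joint(diff_count(7, 36106), haplotype_obs(102000, 0.169),
#'             coalescent_params(), s_years = 80000)
#' @export
tmrca_joint <- function(diff, obs, params, s_years = 0) {
  stopifnot(inherits(diff, "diff_count"), inherits(obs, "haplotype_obs"),
            s_years >= 0)
  spec <- posterior_spec(diff$d + 3,
                         theta_n = scaled_theta(params, diff$n),
                         two_rho_l = scaled_rho(params, obs))
  .date_gamma(spec, params, s_years)
}
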