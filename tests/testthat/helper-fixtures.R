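# Hand-built genotype matrices for scan-level tests.

# All-haploid matrix from a calls matrix (sites x samples).
make_haploid_gm <- function(pos, calls, anc = NULL, der = NULL,
                            chrom = "chr1", mask_start = 0,
                            mask_end = max(pos) + 100) {
  n <- length(pos)
  if (is.null(anc)) anc <- rep("A", n)
  if (is.null(der)) der <- rep("C", n)
  nm <- colnames(calls)
  samples <- data.frame(name = nm, ploidy = 1L, cohort = "test",
                        age_years = 0)
  masks <- stats::setNames(lapply(nm, function(s)
    data.frame(chrom = chrom, start = mask_start, end = mask_end)), nm)
  genotype_matrix(data.frame(chrom = chrom, pos = pos, anc = anc, der = der),
                  samples, calls, masks)
}

# Mixed-ploidy matrix; ploidy/cohort/age given per sample.
make_gm <- function(pos, calls, ploidy, cohort = NULL, age = NULL,
                    anc = NULL, der = NULL, chrom = "chr1",
                    masks = NULL, mask_end = max(pos) + 100) {
  n <- length(pos)
  if (is.null(anc)) anc <- rep("A", n)
  if (is.null(der)) der <- rep("C", n)
  nm <- colnames(calls)
  if (is.null(cohort)) cohort <- rep("test", length(nm))
  if (is.null(age)) age <- rep(0, length(nm))
  samples <- data.frame(name = nm, ploidy = as.integer(ploidy),
                        cohort = cohort, age_years = age)
  if (is.null(masks))
    masks <- stats::setNames(lapply(nm, function(s)
      data.frame(chrom = chrom, start = 0, end = mask_end)), nm)
  genotype_matrix(data.frame(chrom = chrom, pos = pos, anc = anc, der = der),
                  samples, calls, masks)
}

# Independent oracle for E[T | T >= S/2] + S/2. Shifting the integration
# variable to u = t - c cancels the e^(-beta*c) factor, and for integer
# shape the binomial expansion of (c + u)^(alpha-1) reduces both
# truncated-gamma integrals to finite sums of factorial terms: the
# integral evaluated exactly, sharing no code path with the package's
# incomplete-gamma formula.
num_trunc_mean <- function(alpha, beta, s_scaled) {
  stopifnot(alpha == round(alpha), alpha >= 1)
  cc <- s_scaled / 2
  k <- 0:(alpha - 1)
  co <- choose(alpha - 1, k) * cc^(alpha - 1 - k)
  den <- sum(co * factorial(k) / beta^(k + 1))
  num <- sum(co * factorial(k + 1) / beta^(k + 2))
  cc + num / den + cc
}
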