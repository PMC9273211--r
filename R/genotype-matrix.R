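#' Polarized genotype matrix
#'
#' A container for biallelic sites polarized against an outgroup-derived
#' ancestral allele, across a panel of diploid and pseudo-haploid samples
#' with per-sample callable masks.
#'
#' @param sites Data frame with columns `chrom`, `pos` (1-based position,
#'   strictly increasing within a chromosome), `anc` and `der` (ancestral
#'   and derived bases).
#' @param samples Data frame with columns `name`, `ploidy` (1 for
#'   pseudo-haploid low-coverage samples, 2 for diploid genotypes),
#'   `cohort` (free label) and `age_years`.
#' @param calls Integer matrix sites x samples of derived-allele counts in
#'   `0..ploidy`, `NA` for missing; column names must match sample names.
#' @param masks Named list (one entry per sample) of data frames
#'   `chrom, start, end` giving callable intervals, 0-based half-open.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, samples, calls, masks) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "anc", "der") %in% names(sites)),
            is.data.frame(samples),
            all(c("name", "ploidy", "cohort", "age_years") %in% names(samples)),
            is.matrix(calls),
            nrow(calls) == nrow(sites), ncol(calls) == nrow(samples))
  if (is.null(colnames(calls))) colnames(calls) <- samples$name
  stopifnot(identical(colnames(calls), samples$name))
  stopifnot(all(samples$ploidy %in% c(1L, 2L)))
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions not strictly increasing on ", ch)
  }
  over <- sweep(calls, 2, samples$ploidy, ">")
  if (any(over, na.rm = TRUE)) stop("derived-allele count exceeds ploidy")
  if (any(calls < 0, na.rm = TRUE)) stop("negative derived-allele count")
  stopifnot(is.list(masks), all(samples$name %in% names(masks)))
  structure(list(sites = sites, samples = samples, calls = calls,
                 masks = masks[samples$name]),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples (%d haploid, %d diploid)\n",
              nrow(x$sites), nrow(x$samples), sum(x$samples$ploidy == 1L),
              sum(x$samples$ploidy == 2L)))
  cat("  cohorts:", paste(sprintf("%s (%d)", names(table(x$samples$cohort)),
                                  table(x$samples$cohort)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Transition / transversion classification of a polarized site
#'
#' Transitions are the purine and pyrimidine exchanges A<->G and C<->T;
#' everything else is a transversion.
#'
#' @param anc,der Ancestral and derived bases.
#' @return Logical vector, `TRUE` for transitions.
#' @export
is_transition <- function(anc, der) {
  pair <- paste0(pmin(toupper(anc), toupper(der)),
                 pmax(toupper(anc), toupper(der)))
  pair %in% c("AG", "CT")
}

# Mask of one sample on one chromosome as an IRanges (1-based closed).
.mask_ranges <- function(gm, sample, chrom) {
  m <- gm$masks[[sample]]
  m <- m[m$chrom == chrom, , drop = FALSE]
  IRanges::IRanges(start = m$start + 1L, end = m$end)
}

# Intersection of two samples' masks within a region; returns an IRanges.
.joint_callable <- function(gm, a, b, reg) {
  win <- IRanges::IRanges(start = reg$start + 1L, end = reg$end)
  ab <- IRanges::intersect(.mask_ranges(gm, a, reg$chrom),
                           .mask_ranges(gm, b, reg$chrom))
  IRanges::intersect(ab, win)
}

#' Number of bases callable in both of two samples within a region
#'
#' @param gm A [genotype_matrix()].
#' @param a,b Sample names.
#' @param reg A [region()].
#' @return Width of the callable-mask intersection in bp.
#' @export
joint_callable_length <- function(gm, a, b, reg) {
  sum(IRanges::width(.joint_callable(gm, a, b, reg)))
}

# Indices of sites falling inside a region (positions treated against the
# region's half-open span).
.sites_in_region <- function(gm, reg) {
  which(gm$sites$chrom == reg$chrom &
          gm$sites$pos > reg$start & gm$sites$pos <= reg$end)
}

# TRUE for sites (by index) covered by the callable IRanges set.
.sites_in_ranges <- function(gm, idx, ranges) {
  if (length(idx) == 0L) return(logical(0))
  pos <- IRanges::IRanges(start = gm$sites$pos[idx], width = 1L)
  IRanges::overlapsAny(pos, ranges)
}

# Run code under a private RNG stream, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible, order-independent stream seed from a user seed
# and a string key (e.g. sorted sample pair + region).
.stream_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * (seq_along(utf8ToInt(key)) %% 97 + 1))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Sample one allele (0 = ancestral, 1 = derived) per site for one sample;
# heterozygous diploid calls draw uniformly, everything else is
# deterministic. Assumes an active RNG stream.
.sample_alleles <- function(dosage, ploidy) {
  out <- as.integer(dosage == ploidy)
  het <- !is.na(dosage) & dosage > 0L & dosage < ploidy
  out[het] <- stats::rbinom(sum(het), 1L, 0.5)
  out[is.na(dosage)] <- NA_integer_
  out
}
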