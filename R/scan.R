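#' Ancestral-allele call from four great-ape reference bases
#'
#' The ancestral allele is the base carried by at least three of the four
#' ape reference assemblies, allowing a third allele or missing information
#' in at most one of them; otherwise the ancestral state is undefined.
#'
#' @param ape_alleles Character vector of length 4 (bases; `NA` for
#'   missing).
#' @return The ancestral base, or `NA_character_` if undefined.
#' @examples
#' call_ancestral(c("C", "C", "C", "T"))   # "C"
#' call_ancestral(c("C", "C", NA, "C"))    # "C"
#' call_ancestral(c("C", "C", "T", "T"))   # NA
#' @export
call_ancestral <- function(ape_alleles) {
  stopifnot(length(ape_alleles) == 4L)
  tab <- table(toupper(ape_alleles[!is.na(ape_alleles)]))
  if (length(tab) && max(tab) >= 3L) names(tab)[which.max(tab)]
  else NA_character_
}

#' Ascertain informative sites against a reference population
#'
#' Keeps sites where every called allele in the reference population is
#' derived (with at least one call) and at least one of the named
#' high-coverage archaic samples carries at least one derived allele.
#'
#' @param gm A [genotype_matrix()].
#' @param reference_pop Sample names of the reference population (e.g. an
#'   African panel in which the alleles are fixed derived).
#' @param archaic_set Sample names of high-coverage archaic genomes.
#' @return Integer vector of site indices.
#' @export
ascertain_informative_sites <- function(gm, reference_pop, archaic_set) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (length(reference_pop) == 0L) stop("empty reference population")
  stopifnot(all(reference_pop %in% gm$samples$name),
            all(archaic_set %in% gm$samples$name))
  ref <- gm$calls[, reference_pop, drop = FALSE]
  pl <- matrix(gm$samples$ploidy[match(reference_pop, gm$samples$name)],
               nrow = nrow(ref), ncol = length(reference_pop), byrow = TRUE)
  ref_fixed <- rowSums(!is.na(ref)) > 0L &
    rowSums(ref != pl, na.rm = TRUE) == 0L
  arc <- gm$calls[, archaic_set, drop = FALSE]
  arc_derived <- rowSums(arc >= 1L, na.rm = TRUE) > 0L
  which(ref_fixed & arc_derived)
}

#' Pairwise differences between two samples in a region
#'
#' Counts mismatches between one sampled allele per individual over the
#' variant sites falling in the intersection of the two samples' callable
#' masks within the region; `n` is the length of that intersection in bp.
#' At unphased heterozygous sites one allele is drawn uniformly from a
#' stream seeded by (`seed`, sorted sample pair, region), so the count is
#' reproducible and symmetric in the two samples.
#'
#' @param gm A [genotype_matrix()].
#' @param a,b Sample names.
#' @param reg A [region()].
#' @param seed Integer seed for the heterozygote allele draws.
#' @return A [diff_count()].
#' @export
pairwise_differences <- function(gm, a, b, reg, seed = 1L) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(reg, "genome_region"),
            a %in% gm$samples$name, b %in% gm$samples$name, a != b)
  callable <- .joint_callable(gm, a, b, reg)
  n <- sum(IRanges::width(callable))
  if (n == 0L) stop("no jointly callable bases for ", a, " and ", b,
                    " in region")
  idx <- .sites_in_region(gm, reg)
  idx <- idx[.sites_in_ranges(gm, idx, callable)]
  da <- gm$calls[idx, a]
  db <- gm$calls[idx, b]
  ok <- !is.na(da) & !is.na(db)
  idx <- idx[ok]; da <- da[ok]; db <- db[ok]
  pair <- sort(c(a, b))
  key <- paste(pair[1], pair[2], reg$chrom, reg$start, reg$end, sep = "|")
  alleles <- .with_seed(.stream_seed(seed, key), {
    pl <- gm$samples$ploidy[match(pair, gm$samples$name)]
    d1 <- .sample_alleles(gm$calls[idx, pair[1]], pl[1])
    d2 <- .sample_alleles(gm$calls[idx, pair[2]], pl[2])
    list(d1, d2)
  })
  diff_count(sum(alleles[[1]] != alleles[[2]]), n)
}

#' Window divergence scan between two samples
#'
#' Tiles the chromosome of the query region into non-overlapping windows,
#' computes pairwise differences in each, discards windows with fewer than
#' `min_calls` jointly callable bases, and reports the rank fraction of a
#' query region: the proportion of retained windows with at least as many
#' differences as the query.
#'
#' @inheritParams pairwise_differences
#' @param query A [region()] to rank against the window distribution.
#' @param window_bp Window size in bp.
#' @param min_calls Minimum jointly callable bases to retain a window.
#' @return A list with `windows` (data frame `start, end, d, n`), `query`
#'   (a [diff_count()]), and `rank_fraction`.
#' @export
window_divergence <- function(gm, a, b, query, window_bp = 276000,
                              min_calls = 10000, seed = 1L) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(query, "genome_region"))
  chrom <- query$chrom
  span <- range(c(gm$masks[[a]]$start[gm$masks[[a]]$chrom == chrom],
                  gm$masks[[a]]$end[gm$masks[[a]]$chrom == chrom],
                  gm$masks[[b]]$start[gm$masks[[b]]$chrom == chrom],
                  gm$masks[[b]]$end[gm$masks[[b]]$chrom == chrom]))
  starts <- seq(span[1], span[2] - 1, by = window_bp)
  rows <- lapply(starts, function(s) {
    e <- min(s + window_bp, span[2])
    dc <- tryCatch(pairwise_differences(gm, a, b, region(chrom, s, e), seed),
                   error = function(err) NULL)
    if (is.null(dc)) return(NULL)
    data.frame(start = s, end = e, d = dc$d, n = dc$n)
  })
  win <- do.call(rbind, rows)
  if (!is.null(win)) win <- win[win$n >= min_calls, , drop = FALSE]
  if (is.null(win) || nrow(win) == 0L) {
    warning("no window reaches ", min_calls, " jointly callable bases")
    return(list(windows = data.frame(start = numeric(0), end = numeric(0),
                                     d = integer(0), n = numeric(0)),
                query = NULL, rank_fraction = NA_real_))
  }
  qd <- pairwise_differences(gm, a, b, query, seed)
  list(windows = win, query = qd,
       rank_fraction = sum(win$d >= qd$d) / nrow(win))
}

# Pairwise difference counts over called sites between haploid columns.
.haploid_diff <- function(calls, x, y) {
  cx <- calls[, x]; cy <- calls[, y]
  ok <- !is.na(cx) & !is.na(cy)
  sum(cx[ok] != cy[ok])
}

#' Split chromosomes into the two deepest clades of a region
#'
#' Identifies the pair of chromosomes with the largest number of pairwise
#' differences (ties broken by lexicographic sample-name order) and assigns
#' every other chromosome to one of the two groups they define: a
#' chromosome joins a group if it shares at least two derived alleles with
#' that group's defining chromosome but at most one with the other
#' definer. Chromosomes matching neither rule (potential recombinants) are
#' excluded.
#'
#' @param gm A [genotype_matrix()]; all samples in `sample_set` must be
#'   haploid (phased chromosomes or pseudo-haploids).
#' @param sample_set Names of the chromosomes to split (>= 3).
#' @param reg Optional [region()] restricting the sites used.
#' @return A list with `definers`, `group_a`, `group_b` (each including
#'   its definer) and `excluded`.
#' @export
split_deepest_clades <- function(gm, sample_set, reg = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"), length(sample_set) >= 3L,
            all(sample_set %in% gm$samples$name))
  pl <- gm$samples$ploidy[match(sample_set, gm$samples$name)]
  if (any(pl != 1L)) stop("clade splitting requires haploid chromosomes")
  idx <- if (is.null(reg)) seq_len(nrow(gm$sites)) else .sites_in_region(gm, reg)
  calls <- gm$calls[idx, sample_set, drop = FALSE]
  pairs <- utils::combn(sort(sample_set), 2)
  dvec <- apply(pairs, 2, function(p) .haploid_diff(calls, p[1], p[2]))
  if (max(dvec) == 0L) stop("all chromosomes identical; no deepest pair")
  best <- which(dvec == max(dvec))[1L]  # pairs are in lexicographic order
  def_a <- pairs[1, best]; def_b <- pairs[2, best]
  shared_derived <- function(x, y) {
    cx <- calls[, x]; cy <- calls[, y]
    sum(!is.na(cx) & !is.na(cy) & cx == 1L & cy == 1L)
  }
  others <- setdiff(sample_set, c(def_a, def_b))
  group_a <- def_a; group_b <- def_b; excluded <- character(0)
  for (s in others) {
    sa <- shared_derived(s, def_a); sb <- shared_derived(s, def_b)
    if (sa >= 2L && sb <= 1L) group_a <- c(group_a, s)
    else if (sb >= 2L && sa <= 1L) group_b <- c(group_b, s)
    else excluded <- c(excluded, s)
  }
  list(definers = c(def_a, def_b), group_a = group_a, group_b = group_b,
       excluded = excluded)
}

#' Mean cross-clade divergence
#'
#' Mean pairwise difference count between the two groups of a
#' [split_deepest_clades()] result, optionally restricted to sites called
#' in all of `restrict_to` (e.g. the high-coverage archaic genomes).
#'
#' @param gm A [genotype_matrix()].
#' @param split Result of [split_deepest_clades()].
#' @param reg Optional [region()].
#' @param restrict_to Optional sample names whose calls must all be
#'   present at a site for it to be counted.
#' @return Mean number of differences across all cross-group pairs.
#' @export
cross_clade_divergence <- function(gm, split, reg = NULL, restrict_to = NULL) {
  idx <- if (is.null(reg)) seq_len(nrow(gm$sites)) else .sites_in_region(gm, reg)
  if (!is.null(restrict_to)) {
    keep <- rowSums(is.na(gm$calls[idx, restrict_to, drop = FALSE])) == 0L
    idx <- idx[keep]
  }
  calls <- gm$calls[idx, , drop = FALSE]
  d <- outer(split$group_a, split$group_b,
             Vectorize(function(x, y) .haploid_diff(calls, x, y)))
  mean(d)
}

#' Linkage disequilibrium r-squared between two sites
#'
#' Squared Pearson correlation of derived-allele dosage across samples
#' (haploid alleles or unphased diploid genotype dosages).
#'
#' @param gm A [genotype_matrix()].
#' @param site_i,site_j Site indices.
#' @param sample_set Sample names (default: all).
#' @return r-squared in `[0, 1]`.
#' @export
r2_linkage <- function(gm, site_i, site_j, sample_set = NULL) {
  if (is.null(sample_set)) sample_set <- gm$samples$name
  x <- gm$calls[site_i, sample_set]
  y <- gm$calls[site_j, sample_set]
  ok <- !is.na(x) & !is.na(y)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    stop("monomorphic site in sample set")
  stats::cor(x[ok], y[ok])^2
}

#' Tag a haplotype by linkage to anchor sites
#'
#' Carriers are the samples bearing the derived allele at every anchor
#' site. Starting from the anchor span, the tagged run is extended site by
#' site in both directions while each site's r-squared with the anchor
#' dosage (minimum derived dosage over the anchors) exceeds the threshold;
#' monomorphic sites stop the extension.
#'
#' @param gm A [genotype_matrix()].
#' @param anchor_sites Site indices of the ascertained anchor alleles.
#' @param r2_threshold Strict r-squared threshold for tagging.
#' @param sample_set Sample names (default: all).
#' @return A list with `carriers`, `tagged_sites` (indices),
#'   `first_pos`, `last_pos` and `span_bp` (first-to-last tagged
#'   position).
#' @export
tag_haplotype <- function(gm, anchor_sites, r2_threshold, sample_set = NULL) {
  stopifnot(length(anchor_sites) >= 1L)
  if (is.null(sample_set)) sample_set <- gm$samples$name
  calls <- gm$calls[, sample_set, drop = FALSE]
  anchor_dosage <- apply(calls[anchor_sites, , drop = FALSE], 2, min)
  carriers <- sample_set[!is.na(anchor_dosage) & anchor_dosage >= 1L]
  site_r2 <- function(i) {
    x <- calls[i, ]
    ok <- !is.na(x) & !is.na(anchor_dosage)
    if (sum(ok) < 2L || stats::sd(x[ok]) == 0 ||
        stats::sd(anchor_dosage[ok]) == 0) return(NA_real_)
    stats::cor(x[ok], anchor_dosage[ok])^2
  }
  lo <- min(anchor_sites); hi <- max(anchor_sites)
  chrom <- gm$sites$chrom[lo]
  while (lo > 1L && gm$sites$chrom[lo - 1L] == chrom &&
         isTRUE(site_r2(lo - 1L) > r2_threshold)) lo <- lo - 1L
  while (hi < nrow(gm$sites) && gm$sites$chrom[hi + 1L] == chrom &&
         isTRUE(site_r2(hi + 1L) > r2_threshold)) hi <- hi + 1L
  tagged <- lo:hi
  list(carriers = carriers, tagged_sites = tagged,
       first_pos = gm$sites$pos[lo], last_pos = gm$sites$pos[hi],
       span_bp = gm$sites$pos[hi] - gm$sites$pos[lo])
}

#' Archaic-linked alleles in flanking regions
#'
#' In regions flanking a focal haplotype, reports sites whose derived
#' allele is present in at least one archaic genome, absent from the
#' outgroup population, and carried — among the remaining (modern) panel —
#' only by the focal carriers.
#'
#' @param gm A [genotype_matrix()].
#' @param focal_carriers Modern samples carrying the focal haplotype.
#' @param archaic_set Archaic sample names.
#' @param outgroup_pop Outgroup population sample names (e.g. Africans).
#' @param flank_regions List of [region()]s adjacent to the focal span.
#' @return Data frame `site, chrom, pos` of qualifying sites.
#' @export
archaic_linked_alleles <- function(gm, focal_carriers, archaic_set,
                                   outgroup_pop, flank_regions) {
  if (inherits(flank_regions, "genome_region"))
    flank_regions <- list(flank_regions)
  modern <- setdiff(gm$samples$name, c(archaic_set, outgroup_pop))
  idx <- sort(unique(unlist(lapply(flank_regions, function(r)
    .sites_in_region(gm, r)))))
  keep <- vapply(idx, function(i) {
    arc <- gm$calls[i, archaic_set]
    if (!any(arc >= 1L, na.rm = TRUE)) return(FALSE)
    outg <- gm$calls[i, outgroup_pop]
    if (any(outg >= 1L, na.rm = TRUE)) return(FALSE)
    mod <- gm$calls[i, modern]
    mod_carriers <- modern[!is.na(mod) & mod >= 1L]
    length(mod_carriers) > 0L && all(mod_carriers %in% focal_carriers)
  }, logical(1))
  data.frame(site = idx[keep], chrom = gm$sites$chrom[idx[keep]],
             pos = gm$sites$pos[idx[keep]])
}

#' Cohort scheme for the allele-frequency-trajectory test
#'
#' Defines three dated cohorts and the ascertainment filters for
#' [frequency_trajectory_test()]. The defaults mirror an analysis of
#' Neandertal genomes: three early individuals contributing four alleles
#' (filter if more than one missing), five late individuals contributing
#' six alleles (filter if three or more missing), at least three late
#' carriers, 50 kb spacing, transversions only.
#'
#' @param early,mid,late Disjoint sample-name sets, oldest to youngest.
#' @param max_missing_early Maximum missing alleles tolerated in the early
#'   cohort.
#' @param max_missing_late Maximum missing alleles tolerated in the late
#'   cohort.
#' @param min_late_carriers Late individuals that must carry the derived
#'   allele for a site to count as a frequency rise.
#' @param min_spacing_bp Greedy left-to-right minimum spacing between
#'   ascertained sites.
#' @param transversions_only Restrict to transversions (immune to
#'   ancient-DNA cytosine deamination).
#' @return An object of class `cohort_scheme`.
#' @export
cohort_scheme <- function(early, mid, late, max_missing_early = 1L,
                          max_missing_late = 2L, min_late_carriers = 3L,
                          min_spacing_bp = 50000, transversions_only = TRUE) {
  stopifnot(length(early) > 0L, length(mid) > 0L, length(late) > 0L)
  if (length(intersect(early, mid)) || length(intersect(early, late)) ||
      length(intersect(mid, late))) stop("cohorts must be disjoint")
  structure(list(early = early, mid = mid, late = late,
                 max_missing_early = max_missing_early,
                 max_missing_late = max_missing_late,
                 min_late_carriers = min_late_carriers,
                 min_spacing_bp = min_spacing_bp,
                 transversions_only = transversions_only),
            class = "cohort_scheme")
}

#' Allele-frequency-trajectory test across dated cohorts
#'
#' Ascertains sites where all called early-cohort alleles are ancestral
#' (with at most `max_missing_early` missing alleles), the derived allele
#' is seen at least once in both the mid and late cohorts (with at most
#' `max_missing_late` missing late alleles), optionally restricted to
#' transversions, and thinned greedily left-to-right to a minimum spacing.
#' The statistic is the proportion of ascertained sites at which at least
#' `min_late_carriers` late individuals carry the derived allele —
#' a null distribution of frequency rises against which a focal
#' haplotype's rise can be judged.
#'
#' @param gm A [genotype_matrix()].
#' @param scheme A [cohort_scheme()].
#' @return A list with `n_ascertained`, `n_passing`, `proportion` (`NA`
#'   if nothing is ascertained), `sites` (ascertained indices) and
#'   `passing` (logical per ascertained site).
#' @export
frequency_trajectory_test <- function(gm, scheme) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(scheme, "cohort_scheme"))
  stopifnot(all(c(scheme$early, scheme$mid, scheme$late) %in% gm$samples$name))
  ploidy_of <- function(s) gm$samples$ploidy[match(s, gm$samples$name)]
  alleles_missing <- function(cols) {
    pl <- matrix(ploidy_of(cols), nrow = nrow(gm$calls), ncol = length(cols),
                 byrow = TRUE)
    rowSums(pl * is.na(gm$calls[, cols, drop = FALSE]))
  }
  early <- gm$calls[, scheme$early, drop = FALSE]
  mid <- gm$calls[, scheme$mid, drop = FALSE]
  late <- gm$calls[, scheme$late, drop = FALSE]
  ok <- rowSums(early, na.rm = TRUE) == 0L &
    rowSums(!is.na(early)) > 0L &
    alleles_missing(scheme$early) <= scheme$max_missing_early &
    rowSums(mid >= 1L, na.rm = TRUE) > 0L &
    rowSums(late >= 1L, na.rm = TRUE) > 0L &
    alleles_missing(scheme$late) <= scheme$max_missing_late
  if (scheme$transversions_only)
    ok <- ok & !is_transition(gm$sites$anc, gm$sites$der)
  idx <- which(ok)
  # greedy spacing, leftmost kept first, per chromosome
  if (length(idx) > 1L && scheme$min_spacing_bp > 0) {
    keep <- logical(length(idx))
    last_chrom <- ""; last_pos <- -Inf
    for (k in seq_along(idx)) {
      ch <- gm$sites$chrom[idx[k]]; p <- gm$sites$pos[idx[k]]
      if (ch != last_chrom || p - last_pos >= scheme$min_spacing_bp) {
        keep[k] <- TRUE; last_chrom <- ch; last_pos <- p
      }
    }
    idx <- idx[keep]
  }
  if (length(idx) == 0L)
    return(list(n_ascertained = 0L, n_passing = 0L, proportion = NA_real_,
                sites = integer(0), passing = logical(0)))
  passing <- rowSums(late[idx, , drop = FALSE] >= 1L, na.rm = TRUE) >=
    scheme$min_late_carriers
  list(n_ascertained = length(idx), n_passing = sum(passing),
       proportion = sum(passing) / length(idx), sites = idx,
       passing = passing)
}
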