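test_that("ancestral allele follows the 3-of-4 great-ape rule", {
  expect_equal(call_ancestral(c("C", "C", "C", "T")), "C")
  expect_equal(call_ancestral(c("C", "C", NA, "C")), "C")
  expect_true(is.na(call_ancestral(c("C", "C", "T", "T"))))
  expect_true(is.na(call_ancestral(c("C", "C", NA, NA))))
  expect_equal(call_ancestral(c("a", "A", "A", "G")), "A")
  expect_error(call_ancestral(c("C", "C", "C")))
})

test_that("transitions are A<->G and C<->T regardless of orientation", {
  expect_true(all(is_transition(c("A", "G", "C", "T"), c("G", "A", "T", "C"))))
  expect_false(any(is_transition(c("A", "A", "C", "G"), c("C", "T", "G", "T"))))
})

test_that("informative sites require fixed derived reference plus a derived archaic", {
  calls <- rbind(c(2L, 2L, 2L, 1L),   # kept: ref fixed derived, archaic het
                 c(2L, 2L, 2L, 0L),   # dropped: archaic ancestral
                 c(2L, 1L, 2L, 2L),   # dropped: one ancestral ref allele
                 c(2L, NA, 2L, 2L))   # kept: missing ref call tolerated
  colnames(calls) <- c("ref1", "ref2", "ref3", "arc1")
  gm <- make_gm(pos = c(10, 20, 30, 40), calls = calls,
                ploidy = c(2, 2, 2, 2))
  idx <- ascertain_informative_sites(gm, c("ref1", "ref2", "ref3"), "arc1")
  expect_equal(idx, c(1L, 4L))
  expect_error(ascertain_informative_sites(gm, character(0), "arc1"))
  # adding archaic samples never shrinks the set
  calls2 <- cbind(calls, arc2 = c(0L, 2L, 0L, 0L))
  gm2 <- make_gm(pos = c(10, 20, 30, 40), calls = calls2,
                 ploidy = rep(2, 5))
  idx2 <- ascertain_informative_sites(gm2, c("ref1", "ref2", "ref3"),
                                      c("arc1", "arc2"))
  expect_true(all(idx %in% idx2))
})

test_that("pairwise differences count mismatches over the joint callable mask", {
  calls <- cbind(a = c(2L, 0L, 2L, 0L, 2L), b = c(2L, 0L, 2L, 0L, 2L))
  gm <- make_gm(pos = c(10, 20, 30, 40, 50), calls = calls, ploidy = c(2, 2),
                mask_end = 100)
  reg <- region("chr1", 0, 100)
  dc <- pairwise_differences(gm, "a", "b", reg)
  expect_equal(dc$d, 0L)
  expect_equal(dc$n, 100)
  # opposite homozygotes differ everywhere
  calls2 <- cbind(a = rep(2L, 5), b = rep(0L, 5))
  gm2 <- make_gm(pos = c(10, 20, 30, 40, 50), calls = calls2,
                 ploidy = c(2, 2), mask_end = 100)
  expect_equal(pairwise_differences(gm2, "a", "b", reg)$d, 5L)
  expect_error(pairwise_differences(gm2, "a", "b", region("chr1", 200, 300)))
})

test_that("heterozygote sampling is symmetric, seeded, and binomial in expectation", {
  k <- 40
  calls <- cbind(het = rep(1L, k), hom = rep(2L, k))
  gm <- make_gm(pos = seq(10, by = 10, length.out = k), calls = calls,
                ploidy = c(2, 2), mask_end = 1000)
  reg <- region("chr1", 0, 1000)
  d1 <- pairwise_differences(gm, "het", "hom", reg, seed = 7)
  d2 <- pairwise_differences(gm, "hom", "het", reg, seed = 7)
  expect_identical(d1$d, d2$d)  # symmetric given the seed
  expect_identical(d1$d, pairwise_differences(gm, "het", "hom", reg,
                                              seed = 7)$d)
  ds <- vapply(1:200, function(s)
    pairwise_differences(gm, "het", "hom", reg, seed = s)$d, integer(1))
  # D ~ Binomial(k, 1/2): mean k/2, sd sqrt(k)/2
  expect_equal(mean(ds), k / 2, tolerance = 0.05)
  expect_gt(stats::sd(ds), 0.5 * sqrt(k) / 2)
  expect_lt(stats::sd(ds), 2.0 * sqrt(k) / 2)
})

test_that("difference counts ignore sites outside the joint mask", {
  pos <- c(10, 20, 30, 990)
  calls <- cbind(a = c(2L, 0L, 2L, 2L), b = c(0L, 0L, 2L, 0L))
  masks <- list(a = data.frame(chrom = "chr1", start = 0, end = 100),
                b = data.frame(chrom = "chr1", start = 0, end = 500))
  gm <- make_gm(pos, calls, ploidy = c(2, 2), masks = masks)
  dc <- pairwise_differences(gm, "a", "b", region("chr1", 0, 1000))
  expect_equal(dc$n, 100)  # intersection of masks and region
  expect_equal(dc$d, 1L)   # site at 990 outside both masks is ignored
})

test_that("window divergence ranks a query against the genome-wide tiling", {
  # deterministic haploid pair: window i of 10 kb carries i differences
  n_win <- 8
  pos <- unlist(lapply(seq_len(n_win), function(i)
    (i - 1) * 10000 + seq_len(i) * 100))
  calls <- cbind(a = rep(0L, length(pos)), b = rep(1L, length(pos)))
  masks <- list(a = data.frame(chrom = "chr1", start = 0, end = 80000),
                b = data.frame(chrom = "chr1", start = 0, end = 80000))
  gm <- make_haploid_gm(pos, calls, mask_end = 80000)
  gm$masks <- masks
  res <- window_divergence(gm, "a", "b", query = region("chr1", 70000, 80000),
                           window_bp = 10000, min_calls = 1000)
  expect_equal(nrow(res$windows), n_win)
  expect_equal(res$windows$d, seq_len(n_win))
  expect_equal(res$rank_fraction, 1 / n_win)  # query is the top window
  mid <- window_divergence(gm, "a", "b", query = region("chr1", 30000, 40000),
                           window_bp = 10000, min_calls = 1000)
  expect_equal(mid$rank_fraction, 5 / n_win)  # windows 4..8 have D >= 4
  expect_warning(
    empty <- window_divergence(gm, "a", "b",
                               query = region("chr1", 0, 10000),
                               window_bp = 10000, min_calls = 1e6),
    "callable")
  expect_equal(nrow(empty$windows), 0L)
  expect_true(is.na(empty$rank_fraction))
})

test_that("clade splitting finds the deepest pair and excludes recombinants", {
  # definers: x = derived at sites 1-3, y = derived at sites 4-6
  calls <- cbind(x = c(1L, 1L, 1L, 0L, 0L, 0L),
                 y = c(0L, 0L, 0L, 1L, 1L, 1L),
                 near_x = c(1L, 1L, 0L, 0L, 0L, 0L),
                 recomb = c(1L, 1L, 0L, 1L, 1L, 0L),
                 blank = c(0L, 0L, 0L, 0L, 0L, 0L))
  gm <- make_haploid_gm(pos = 1:6 * 10, calls = calls)
  sp <- split_deepest_clades(gm, colnames(calls))
  expect_setequal(sp$definers, c("x", "y"))
  expect_true("near_x" %in% sp$group_a || "near_x" %in% sp$group_b)
  in_x_group <- if ("x" %in% sp$group_a) sp$group_a else sp$group_b
  expect_true("near_x" %in% in_x_group)
  expect_setequal(sp$excluded, c("recomb", "blank"))  # 2-with-each and 0-with-both
  same <- make_haploid_gm(pos = 1:3 * 10,
                          calls = cbind(a = rep(1L, 3), b = rep(1L, 3),
                                        c = rep(1L, 3)))
  expect_error(split_deepest_clades(same, c("a", "b", "c")), "identical")
  expect_error(split_deepest_clades(gm, c("x", "y")))
  d <- cross_clade_divergence(gm, sp)
  expect_gt(d, 0)
})

test_that("clade splitting separates two planted clades perfectly", {
  set.seed(11)
  n_per <- 6
  calls <- matrix(0L, 40, 2 * n_per)
  colnames(calls) <- sprintf("h%02d", seq_len(2 * n_per))
  calls[1:15, 1:n_per] <- 1L
  calls[21:35, n_per + 1:n_per] <- 1L
  noise <- matrix(stats::rbinom(length(calls), 1L, 0.02), nrow(calls))
  calls[noise == 1L] <- 1L
  gm <- make_haploid_gm(pos = seq_len(40) * 100, calls = calls)
  sp <- split_deepest_clades(gm, colnames(calls))
  groups <- list(sp$group_a, sp$group_b)
  clade1 <- sprintf("h%02d", 1:n_per)
  hit <- vapply(groups, function(g) all(clade1 %in% g), logical(1))
  expect_true(any(hit))
  expect_setequal(c(sp$group_a, sp$group_b, sp$excluded), colnames(calls))
  expect_length(intersect(sp$group_a, sp$group_b), 0)
})

test_that("r-squared linkage is a dosage correlation with sign invariance", {
  dup <- rbind(c(2L, 2L, 0L, 0L, 1L, 2L),
               c(2L, 2L, 0L, 0L, 1L, 2L))
  colnames(dup) <- paste0("i", 1:6)
  gm0 <- make_gm(pos = c(10, 20), calls = dup, ploidy = rep(2, 6))
  expect_equal(r2_linkage(gm0, 1, 2), 1.0)
  compl <- rbind(c(2L, 0L, 1L, 2L, 0L), c(0L, 2L, 1L, 0L, 2L))
  colnames(compl) <- paste0("i", 1:5)
  gmc <- make_gm(pos = c(10, 20), calls = compl, ploidy = rep(2, 5))
  expect_equal(r2_linkage(gmc, 1, 2), 1.0)  # complementary columns
  mono <- rbind(c(1L, 1L, 1L), c(0L, 1L, 0L))
  colnames(mono) <- paste0("i", 1:3)
  gmm <- make_haploid_gm(pos = c(10, 20), calls = mono)
  expect_error(r2_linkage(gmm, 1, 2), "monomorphic")
  set.seed(9)
  big <- matrix(stats::rbinom(2 * 500, 1, 0.5), nrow = 2)
  colnames(big) <- paste0("i", 1:500)
  gmb <- make_haploid_gm(pos = c(10, 20), calls = big)
  expect_lt(r2_linkage(gmb, 1, 2), 0.05)  # independent sites
})

test_that("haplotype tagging recovers a planted introgressed block", {
  gm <- simulate_genotype_matrix(
    cohorts = list(mod = list(n = 12, ploidy = 2L, age_years = 0,
                              missing_rate = 0),
                   arc = list(n = 4, ploidy = 1L, age_years = 60000,
                              missing_rate = 0)),
    n_background_sites = 150,
    planted = list(start = 400000, end = 500000, n_sites = 50,
                   carriers = c("mod_1", "mod_2", "arc_1")),
    seed = 7)
  truth <- attr(gm, "truth")
  anchors <- which(gm$sites$pos %in% truth$planted_positions)
  tg <- tag_haplotype(gm, anchors, 0.8)
  expect_setequal(tg$carriers, c("mod_1", "mod_2", "arc_1"))
  # span equals the planted block, at most one flanking site of slack
  i_lo <- min(tg$tagged_sites); i_hi <- max(tg$tagged_sites)
  expect_lte(min(anchors) - i_lo, 1)
  expect_lte(i_hi - max(anchors), 1)
  # strict threshold of 1 collapses the span to the anchors
  strict <- tag_haplotype(gm, anchors, 1.0)
  expect_equal(range(strict$tagged_sites), range(anchors))
  expect_equal(strict$span_bp,
               max(truth$planted_positions) - min(truth$planted_positions))
})

test_that("archaic-linked alleles are shared with archaics, absent from the outgroup, and private to carriers", {
  calls <- cbind(arc1 = c(1L, 1L, 0L, 1L),
                 out1 = c(0L, 2L, 0L, 0L),
                 out2 = c(0L, 0L, 0L, 0L),
                 mod1 = c(1L, 1L, 1L, 0L),
                 mod2 = c(0L, 0L, 0L, 2L))
  gm <- make_gm(pos = c(110, 120, 130, 140), calls = calls,
                ploidy = c(1, 2, 2, 2, 2))
  hits <- archaic_linked_alleles(gm, focal_carriers = "mod1",
                                 archaic_set = "arc1",
                                 outgroup_pop = c("out1", "out2"),
                                 flank_regions = region("chr1", 100, 200))
  # site 1: archaic + carrier-only -> reported
  # site 2: also in outgroup -> excluded; site 3: absent from archaics;
  # site 4: carried by a non-focal modern -> excluded
  expect_equal(hits$pos, 110)
})

test_that("the trajectory test reproduces a hand-enumerated fixture", {
  early <- c("e1", "e2", "eh")       # two pseudo-haploids + one diploid = 4 alleles
  mid <- c("m1", "m2", "mh")         # 4 alleles
  late <- c("l1", "l2", "l3", "l4", "lh")  # 4 haploid + 1 diploid = 6 alleles
  nm <- c(early, mid, late)
  ploidy <- c(1, 1, 2, 1, 1, 2, 1, 1, 1, 1, 2)
  mk <- function(e, m, l) c(e, m, l)
  calls <- rbind(
    mk(c(0, 0, 0), c(1, 0, 0), c(1, 1, 1, 0, 0)),  # asc, 3 late carriers: pass
    mk(c(0, 0, 0), c(0, 1, 2), c(1, 1, 1, 1, 2)),  # asc, 5 carriers: pass
    mk(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0, 0, 0)),  # asc, 1 carrier: fail
    mk(c(0, 0, 0), c(0, 0, 2), c(1, 1, 0, 0, 0)),  # asc, 2 carriers: fail
    mk(c(0, 0, 0), c(1, 1, 0), c(0, 1, 1, 0, 0)),  # asc, 2 carriers: fail
    mk(c(1, 0, 0), c(1, 0, 0), c(1, 1, 1, 1, 0)))  # early derived: not asc
  storage.mode(calls) <- "integer"
  colnames(calls) <- nm
  gm <- make_gm(pos = c(1, 2, 3, 4, 5, 6) * 60000, calls = calls,
                ploidy = ploidy, anc = rep("A", 6), der = rep("C", 6),
                mask_end = 1e6)
  sch <- cohort_scheme(early, mid, late, min_spacing_bp = 50000)
  res <- frequency_trajectory_test(gm, sch)
  expect_equal(res$n_ascertained, 5L)
  expect_equal(res$n_passing, 2L)
  expect_equal(res$proportion, 0.4)
})

test_that("trajectory filters respect missingness, transitions and spacing", {
  early <- c("e1", "e2", "eh"); mid <- c("m1", "m2", "mh")
  late <- c("l1", "l2", "l3", "l4", "lh")
  nm <- c(early, mid, late)
  ploidy <- c(1, 1, 2, 1, 1, 2, 1, 1, 1, 1, 2)
  base <- c(0, 0, 0, 1, 0, 0, 1, 1, 1, 0, 0)
  calls <- rbind(base,                                    # clean: ascertained
                 replace(base, 1:2, NA),                  # 2 early alleles missing
                 replace(base, 7:9, NA),                  # 3 late alleles missing
                 base,                                    # transition site
                 base)                                    # too close to previous
  storage.mode(calls) <- "integer"
  colnames(calls) <- nm
  gm <- make_gm(pos = c(100000, 200000, 300000, 400000, 430000),
                calls = calls, ploidy = ploidy,
                anc = rep("A", 5), der = c("C", "C", "C", "G", "C"),
                mask_end = 1e6)
  sch <- cohort_scheme(early, mid, late, min_spacing_bp = 50000)
  res <- frequency_trajectory_test(gm, sch)
  expect_equal(unname(res$sites), c(1L, 5L))  # site 5 passes spacing once 4 is dropped
  # relaxing the spacing filter never decreases the ascertained count
  sch0 <- cohort_scheme(early, mid, late, min_spacing_bp = 0)
  expect_gte(frequency_trajectory_test(gm, sch0)$n_ascertained,
             res$n_ascertained)
  # all late individuals derived everywhere -> proportion 1
  all_der <- gm
  all_der$calls[, late] <- rep(c(1L, 1L, 1L, 1L, 2L),
                               each = nrow(all_der$calls))
  r2 <- frequency_trajectory_test(all_der, sch0)
  expect_equal(r2$proportion, 1)
  # nothing ascertained -> NA proportion
  none <- gm
  none$calls[, "e1"] <- 1L
  r3 <- frequency_trajectory_test(none, sch0)
  expect_equal(r3$n_ascertained, 0L)
  expect_true(is.na(r3$proportion))
  expect_error(cohort_scheme(early, early, late))
})
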