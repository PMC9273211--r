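#' Simulate (TMRCA, differences, haplotype length) triples
#'
#' Draws from the generative model whose exact posterior is the
#' truncated-gamma estimator used for dating: the scaled coalescence time
#' T is Exp(1) truncated below at S/2; given T, the number of pairwise
#' differences is Poisson(theta*N*T) and the shared haplotype length is
#' Gamma(2, 2*rho*T) with rho = 4*Ne*r_bp. Because the model is conjugate,
#' the posterior Gamma(D + 3, theta*N + 2*rho*L + 1) truncated at S/2 is
#' exact, which makes parameter-recovery tests sharp.
#'
#' @param params A [coalescent_params()].
#' @param n_callable Jointly callable bases for the difference count.
#' @param rate_cmmb Local recombination rate (cM/Mb, > 0).
#' @param s_years Branch shortening in years (>= 0).
#' @param n_reps Number of triples.
#' @param seed Integer seed.
#' @return Data frame with `t_true` (scaled time), `d` and `l` (bp).
#' @export
simulate_dating_observables <- function(params, n_callable, rate_cmmb,
                                        s_years = 0, n_reps = 1000L,
                                        seed = 1L) {
  stopifnot(inherits(params, "coalescent_params"), rate_cmmb > 0,
            s_years >= 0, n_reps >= 1L)
  theta_n <- scaled_theta(params, n_callable)
  rho_bp <- 4 * params$ne * rate_cmmb * 1e-8
  s_scaled <- s_years / years_per_scaled_unit(params)
  .with_seed(seed, {
    t_true <- s_scaled / 2 + stats::rexp(n_reps)
    data.frame(t_true = t_true,
               d = stats::rpois(n_reps, theta_n * t_true),
               l = stats::rgamma(n_reps, shape = 2, rate = 2 * rho_bp * t_true))
  })
}

.base_partner <- function(anc, transition) {
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  tv <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"),
             T = c("A", "G"))
  if (transition) unname(ts[anc]) else sample(tv[[anc]], 1L)
}

#' Simulate a polarized genotype matrix with known ground truth
#'
#' Emulates a panel of modern and archaic samples over one genomic region:
#' background biallelic sites with a shared derived-allele frequency drawn
#' uniformly per site, an optional planted introgressed haplotype whose
#' carriers share the derived allele at every block site (non-carriers
#' carry none), optional planted trajectory sites (all early-cohort
#' alleles ancestral, named mid/late carriers derived, transversions),
#' per-cohort missingness, and full-region callable masks. The planted
#' structure is returned in `attr(, "truth")`.
#'
#' @param cohorts Named list; each element a list with `n`, `ploidy`
#'   (1 or 2), `age_years` and `missing_rate`.
#' @param chrom Chromosome name.
#' @param region_start,region_end Region bounds (0-based half-open).
#' @param n_background_sites Number of background sites.
#' @param planted Optional list `start, end, n_sites, carriers` (sample
#'   names) describing the introgressed block.
#' @param planted_trajectory Optional list `n_sites, spacing,
#'   mid_carriers, late_carriers` describing rising-frequency sites.
#' @param ts_fraction Fraction of background sites that are transitions.
#' @param seed Integer seed.
#' @return A [genotype_matrix()] with a `truth` attribute.
#' @export
simulate_genotype_matrix <- function(cohorts, chrom = "chr15",
                                     region_start = 0, region_end = 1e6,
                                     n_background_sites = 200L,
                                     planted = NULL,
                                     planted_trajectory = NULL,
                                     ts_fraction = 2 / 3, seed = 1L) {
  stopifnot(length(cohorts) > 0L, region_end > region_start)
  if (n_background_sites < 1L && is.null(planted) &&
      is.null(planted_trajectory)) stop("empty matrix requested")
  samples <- do.call(rbind, lapply(names(cohorts), function(cn) {
    co <- cohorts[[cn]]
    data.frame(name = sprintf("%s_%d", cn, seq_len(co$n)),
               ploidy = as.integer(co$ploidy), cohort = cn,
               age_years = co$age_years)
  }))
  missing_rate <- unlist(lapply(cohorts, function(co)
    rep(co$missing_rate, co$n)))
  .with_seed(seed, {
    traj_pos <- if (!is.null(planted_trajectory)) {
      region_start + planted_trajectory$spacing *
        seq_len(planted_trajectory$n_sites)
    } else numeric(0)
    if (length(traj_pos) && max(traj_pos) > region_end)
      stop("trajectory sites exceed the region")
    plant_pos <- if (!is.null(planted)) {
      stopifnot(planted$start >= region_start, planted$end <= region_end,
                all(planted$carriers %in% samples$name))
      sort(sample(seq(planted$start + 1, planted$end), planted$n_sites))
    } else numeric(0)
    bg_pool <- setdiff(seq(region_start + 1, region_end),
                       c(traj_pos, plant_pos))
    bg_pos <- sort(sample(bg_pool, n_background_sites))
    pos <- sort(c(bg_pos, plant_pos, traj_pos))
    kind <- rep("background", length(pos))
    kind[pos %in% plant_pos] <- "planted"
    kind[pos %in% traj_pos] <- "trajectory"
    anc <- sample(c("A", "C", "G", "T"), length(pos), replace = TRUE)
    der <- vapply(seq_along(pos), function(i) {
      transition <- if (kind[i] == "trajectory") FALSE
      else stats::runif(1) < ts_fraction
      .base_partner(anc[i], transition)
    }, character(1))
    calls <- matrix(NA_integer_, length(pos), nrow(samples),
                    dimnames = list(NULL, samples$name))
    freq <- stats::runif(length(pos))
    for (j in seq_len(nrow(samples))) {
      calls[, j] <- stats::rbinom(length(pos), samples$ploidy[j], freq)
    }
    if (!is.null(planted)) {
      i <- which(kind == "planted")
      carrier <- samples$name %in% planted$carriers
      calls[i, carrier] <- rep(samples$ploidy[carrier], each = length(i))
      calls[i, !carrier] <- 0L
    }
    if (!is.null(planted_trajectory)) {
      i <- which(kind == "trajectory")
      carriers <- c(planted_trajectory$mid_carriers,
                    planted_trajectory$late_carriers)
      stopifnot(all(carriers %in% samples$name))
      carrier <- samples$name %in% carriers
      calls[i, carrier] <- rep(samples$ploidy[carrier], each = length(i))
      calls[i, !carrier] <- 0L
    }
    drop <- matrix(stats::runif(length(calls)) <
                     rep(missing_rate, each = length(pos)),
                   length(pos), nrow(samples))
    calls[drop] <- NA_integer_
    masks <- stats::setNames(lapply(samples$name, function(s)
      data.frame(chrom = chrom, start = region_start, end = region_end)),
      samples$name)
    gm <- genotype_matrix(
      sites = data.frame(chrom = chrom, pos = pos, anc = anc, der = der),
      samples = samples, calls = calls, masks = masks)
    attr(gm, "truth") <- list(
      planted = planted, planted_positions = plant_pos,
      trajectory_positions = traj_pos, background_positions = bg_pos)
    gm
  })
}

#' Simulate a variant-to-gene database with a known in-set fraction
#'
#' Builds a database of `n_records` variants where exactly
#' `round(n_records * set_fraction)` records belong to a target gene set,
#' supporting exact-enumeration checks of the permutation test.
#'
#' @param n_records Database size.
#' @param set_fraction Fraction of records in the target set, in (0, 1).
#' @param n_set_genes Number of target genes.
#' @param n_bg_genes Number of background genes.
#' @param multi_gene_rate Fraction of records listing a second gene (drawn
#'   from the same in/out class so the in-set fraction is preserved).
#' @param seed Integer seed.
#' @return A list with `db` (a [variant_db()]) and `gene_set`.
#' @export
simulate_variant_db <- function(n_records = 1600L, set_fraction = 1 / 16,
                                n_set_genes = 8L, n_bg_genes = 200L,
                                multi_gene_rate = 0, seed = 1L) {
  stopifnot(set_fraction > 0, set_fraction < 1, n_records >= 2L)
  n_in <- round(n_records * set_fraction)
  set_genes <- sprintf("SET%03d", seq_len(n_set_genes))
  bg_genes <- sprintf("BG%04d", seq_len(n_bg_genes))
  .with_seed(seed, {
    gene1 <- c(sample(set_genes, n_in, replace = TRUE),
               sample(bg_genes, n_records - n_in, replace = TRUE))
    extra <- stats::runif(n_records) < multi_gene_rate
    gene2 <- ifelse(seq_len(n_records) <= n_in,
                    sample(set_genes, n_records, replace = TRUE),
                    sample(bg_genes, n_records, replace = TRUE))
    genes <- ifelse(extra & gene2 != gene1, paste(gene1, gene2, sep = ";"),
                    gene1)
    ord <- sample.int(n_records)
    list(db = variant_db(sprintf("v%06d", seq_len(n_records)), genes[ord]),
         gene_set = set_genes)
  })
}

.gt_string <- function(dosage, ploidy) {
  if (ploidy == 2L) {
    out <- c("0/0", "0/1", "1/1")[dosage + 1L]
    out[is.na(dosage)] <- "./."
  } else {
    out <- as.character(dosage)
    out[is.na(dosage)] <- "."
  }
  out
}

#' Write a genotype matrix as a VCF with an ancestral-allele INFO tag
#'
#' REF is the ancestral and ALT the derived base, and `AA=` records the
#' ancestral allele, so derived-allele dosages round-trip through
#' [read_vcf_subset()].
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @export
write_genotype_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", unique(gm$sites$chrom)),
               "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$samples$name), collapse = "\t")),
             con)
  gt <- vapply(seq_len(nrow(gm$samples)), function(j)
    .gt_string(gm$calls[, j], gm$samples$ploidy[j]),
    character(nrow(gm$sites)))
  lines <- paste(gm$sites$chrom, gm$sites$pos, ".", gm$sites$anc,
                 gm$sites$der, ".", "PASS",
                 paste0("AA=", gm$sites$anc), "GT",
                 apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Write a complete synthetic fixture bundle
#'
#' Emits, under `out_dir`: a VCF of the simulated genotype matrix, one BED
#' callable mask per sample, a sample sheet TSV, a recombination-map TSV,
#' a variant database TSV, minimal GAF/OBO fixtures, and a JSON manifest
#' with the seed and planted ground truth. All files are plain text and
#' regenerate byte-identically from the same seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed driving every generator.
#' @param cohorts,planted Passed to [simulate_genotype_matrix()].
#' @return Invisibly, the manifest as a list.
#' @export
write_fixture_bundle <- function(out_dir, seed = 1L,
                                 cohorts = list(
                                   african = list(n = 6, ploidy = 2L,
                                                  age_years = 0,
                                                  missing_rate = 0),
                                   archaic = list(n = 3, ploidy = 1L,
                                                  age_years = 60000,
                                                  missing_rate = 0.05)),
                                 planted = list(start = 400000, end = 500000,
                                                n_sites = 20,
                                                carriers = c("african_1",
                                                             "archaic_1"))) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  gm <- simulate_genotype_matrix(cohorts, planted = planted, seed = seed)
  write_genotype_vcf(gm, file.path(out_dir, "genotypes.vcf"))
  for (s in gm$samples$name) {
    utils::write.table(gm$masks[[s]],
                       file.path(out_dir, "masks", paste0(s, ".bed")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  utils::write.table(gm$samples, file.path(out_dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  map <- recomb_map(data.frame(chrom = "chr15",
                               start = c(0, 400000, 700000),
                               end = c(400000, 700000, 1000000),
                               rate = c(0.2, 0.15, 0.25)),
                    name = "synthetic-map")
  write_recomb_map(map, file.path(out_dir, "map.tsv"))
  dbs <- simulate_variant_db(seed = seed)
  utils::write.table(dbs$db, file.path(out_dir, "variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c("!gaf-version: 2.2",
               paste("DB", "ID1", "GENE1", "", "GO:0000001", "REF", "IEA",
                     "", "P", "", "", "protein", "taxon:9606", "20210101",
                     "DB", sep = "\t"),
               paste("DB", "ID2", "GENE2", "NOT", "GO:0000001", "REF", "IEA",
                     "", "P", "", "", "protein", "taxon:9606", "20210101",
                     "DB", sep = "\t"),
               paste("DB", "ID3", "GENE3", "", "GO:0000002", "REF", "IEA",
                     "", "P", "", "", "protein", "taxon:9606", "20210101",
                     "DB", sep = "\t")),
             file.path(out_dir, "annotations.gaf"))
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: GO:0000001", "name: mitotic spindle assembly",
               "", "[Term]", "id: GO:0000002", "name: nuclear pore complex",
               "", "[Term]", "id: GO:0000003",
               "name: spindle pole (obsolete)", "is_obsolete: true"),
             file.path(out_dir, "terms.obo"))
  manifest <- list(seed = seed,
                   truth = attr(gm, "truth"),
                   samples = gm$samples$name,
                   gene_set = dbs$gene_set)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
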