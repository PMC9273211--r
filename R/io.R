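#' Read a polarized genotype-matrix fragment from a VCF
#'
#' Reads biallelic SNVs (indels and multi-allelic records are skipped with
#' a message), extracts GT-derived allele dosages, and polarizes them
#' against an ancestral-allele table: sites whose ancestral base equals
#' REF keep the ALT dosage as the derived count, sites where it equals ALT
#' are flipped, and sites matching neither are dropped. Without a table,
#' the `AA=` INFO tag is used when present, else REF is assumed ancestral.
#'
#' @param path Path to a VCF (4.x) file.
#' @param reg Optional [region()] to subset to.
#' @param samples Optional sample names to keep; an error lists any that
#'   are absent from the file.
#' @param ancestral Optional data frame `chrom, pos, anc`.
#' @param sample_sheet Optional data frame `name, ploidy, cohort,
#'   age_years`; without it, ploidy is inferred from the GT separator and
#'   cohort/age default to `"unknown"`/0.
#' @param masks Optional named list of mask data frames `chrom, start,
#'   end`; defaults to one interval spanning the retained sites per
#'   sample.
#' @return A [genotype_matrix()].
#' @export
read_vcf_subset <- function(path, reg = NULL, samples = NULL,
                            ancestral = NULL, sample_sheet = NULL,
                            masks = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  snv <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snv)
  if (n_skipped > 0L)
    message(n_skipped, " non-SNV or multi-allelic record(s) skipped")
  fix <- fix[snv, , drop = FALSE]
  gt <- gt[snv, , drop = FALSE]
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(gt))
    if (length(missing))
      stop("samples absent from VCF: ", paste(missing, collapse = ", "))
    gt <- gt[, samples, drop = FALSE]
  }
  pos <- as.numeric(fix$POS)
  if (!is.null(reg)) {
    keep <- fix$CHROM == reg$chrom & pos > reg$start & pos <= reg$end
    if (!any(keep)) warning("no records in the requested region")
    fix <- fix[keep, , drop = FALSE]
    gt <- gt[keep, , drop = FALSE]
    pos <- pos[keep]
  }
  # ancestral allele per retained site
  aa <- rep(NA_character_, nrow(fix))
  if (!is.null(ancestral)) {
    m <- match(paste(fix$CHROM, pos), paste(ancestral$chrom, ancestral$pos))
    aa <- ancestral$anc[m]
  } else {
    info <- vcfR::getINFO(v)[snv]
    if (!is.null(reg)) info <- info[keep]
    hit <- regmatches(info, regexpr("AA=[ACGT]", info))
    has <- grepl("AA=[ACGT]", info)
    aa[has] <- sub("AA=", "", regmatches(info, regexpr("AA=[ACGT]", info)))
    aa[!has] <- fix$REF[!has]
  }
  flip <- !is.na(aa) & aa == fix$ALT
  ok <- !is.na(aa) & (aa == fix$REF | flip)
  if (any(!ok)) message(sum(!ok), " site(s) dropped: ancestral allele ",
                        "matches neither REF nor ALT")
  fix <- fix[ok, , drop = FALSE]; gt <- gt[ok, , drop = FALSE]
  pos <- pos[ok]; flip <- flip[ok]; aa <- aa[ok]
  ploidy_from_gt <- vapply(seq_len(ncol(gt)), function(j) {
    g <- gt[, j]
    if (any(grepl("[/|]", g))) 2L else 1L
  }, integer(1))
  if (!is.null(sample_sheet)) {
    m <- match(colnames(gt), sample_sheet$name)
    if (anyNA(m)) stop("sample sheet is missing: ",
                       paste(colnames(gt)[is.na(m)], collapse = ", "))
    samp <- sample_sheet[m, c("name", "ploidy", "cohort", "age_years")]
  } else {
    samp <- data.frame(name = colnames(gt), ploidy = ploidy_from_gt,
                       cohort = "unknown", age_years = 0)
  }
  rownames(samp) <- NULL
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt),
                   dimnames = list(NULL, colnames(gt)))
  for (j in seq_len(ncol(gt))) {
    parts <- strsplit(gt[, j], "[/|]")
    dosage[, j] <- vapply(parts, function(p) {
      if (length(p) == 0L || anyNA(p) || any(p == ".")) NA_integer_
      else sum(p == "1")
    }, integer(1))
  }
  der <- ifelse(flip, fix$REF, fix$ALT)
  if (any(flip)) {
    pl <- matrix(samp$ploidy, nrow(dosage), ncol(dosage), byrow = TRUE)
    dosage[flip, ] <- pl[flip, ] - dosage[flip, , drop = FALSE]
  }
  if (is.null(masks)) {
    span <- if (length(pos)) {
      data.frame(chrom = unique(fix$CHROM), start = min(pos) - 1,
                 end = max(pos))
    } else data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0))
    masks <- stats::setNames(lapply(samp$name, function(s) span), samp$name)
  }
  ord <- order(fix$CHROM, pos)
  genotype_matrix(
    sites = data.frame(chrom = fix$CHROM[ord], pos = pos[ord],
                       anc = aa[ord], der = der[ord]),
    samples = samp, calls = dosage[ord, , drop = FALSE], masks = masks)
}

#' Read a sample sheet TSV
#'
#' @param path TSV with header `name ploidy cohort age_years`.
#' @return A data frame.
#' @export
read_sample_sheet <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c("character", "integer", "character",
                                        "numeric"))
  names(d) <- c("name", "ploidy", "cohort", "age_years")
  d
}

#' Read per-sample BED callable masks from a directory
#'
#' @param dir Directory containing `<sample>.bed` files (0-based
#'   half-open, no header).
#' @param sample_names Sample names to read.
#' @return Named list of data frames `chrom, start, end`.
#' @export
read_sample_masks <- function(dir, sample_names) {
  stats::setNames(lapply(sample_names, function(s) {
    d <- utils::read.table(file.path(dir, paste0(s, ".bed")), sep = "\t",
                           col.names = c("chrom", "start", "end"),
                           colClasses = c("character", "numeric", "numeric"))
    d
  }), sample_names)
}

#' Read back a fixture bundle written by [write_fixture_bundle()]
#'
#' @param dir Bundle directory.
#' @return A [genotype_matrix()] reconstructed from the VCF, masks and
#'   sample sheet.
#' @export
read_fixture_bundle <- function(dir) {
  sheet <- read_sample_sheet(file.path(dir, "samples.tsv"))
  masks <- read_sample_masks(file.path(dir, "masks"), sheet$name)
  read_vcf_subset(file.path(dir, "genotypes.vcf"), sample_sheet = sheet,
                  masks = masks)
}

.report_row <- function(name, x) {
  if (inherits(x, "tmrca_estimate")) {
    data.frame(name = name, type = "tmrca",
               value = x$point_years / 1000,
               ci_low = x$ci_low_years / 1000,
               ci_high = x$ci_high_years / 1000,
               detail = sprintf("alpha=%g;beta=%.4f;S=%g;doubled=%s",
                                x$spec$alpha, x$spec$beta, x$s_years,
                                x$doubled))
  } else if (inherits(x, "enrichment_result")) {
    data.frame(name = name, type = "enrichment", value = x$p_total,
               ci_low = NA_real_, ci_high = NA_real_,
               detail = sprintf("p_ge2=%g;p_ge3=%g;p_ngenes=%g;reps=%d",
                                x$p_ge2, x$p_ge3, x$p_ngenes, x$reps))
  } else {
    data.frame(name = name, type = "value", value = as.numeric(x)[1],
               ci_low = NA_real_, ci_high = NA_real_, detail = "")
  }
}

#' Write a machine- and human-readable run report
#'
#' Serializes a named list of results (TMRCA estimates, enrichment
#' results, plain numbers) to `<prefix>.json` (complete, including
#' posterior parameters, branch shortening and thresholds) and a
#' `<prefix>.tsv` summary table.
#'
#' @param results Named list of results.
#' @param out_dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the paths of the two files.
#' @export
run_report <- function(results, out_dir, prefix = "report") {
  stopifnot(is.list(results), !is.null(names(results)),
            all(nzchar(names(results))))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  strip <- function(x) {
    if (inherits(x, "enrichment_result")) x$replicate_stats <- NULL
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  json_path <- file.path(out_dir, paste0(prefix, ".json"))
  jsonlite::write_json(lapply(results, strip), json_path,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  tsv_path <- file.path(out_dir, paste0(prefix, ".tsv"))
  tab <- do.call(rbind, Map(.report_row, names(results), results))
  utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(json = json_path, tsv = tsv_path))
}
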