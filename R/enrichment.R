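#' Read ontology terms from an OBO (basic) file
#'
#' Minimal reader extracting `id`, `name` and the obsolete flag from
#' `[Term]` stanzas of an OBO-format ontology.
#'
#' @param path Path to an OBO file.
#' @return A data frame `id, name, obsolete` of class `ontology_terms`.
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "[Term]")
  if (length(starts) == 0L) stop("no [Term] stanzas in ", path)
  bounds <- c(starts, length(lines) + 1L)
  recs <- lapply(seq_along(starts), function(k) {
    block <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    grab <- function(tag) {
      hit <- grep(paste0("^", tag, ": "), block, value = TRUE)
      if (length(hit)) sub(paste0("^", tag, ": "), "", hit[1L]) else NA_character_
    }
    data.frame(id = grab("id"), name = grab("name"),
               obsolete = identical(grab("is_obsolete"), "true"))
  })
  out <- do.call(rbind, recs)
  out <- out[!is.na(out$id), , drop = FALSE]
  if (anyDuplicated(out$id)) stop("duplicate term ids in ", path)
  structure(out, class = c("ontology_terms", "data.frame"))
}

#' Read gene-to-term annotations from a GAF 2.x file
#'
#' Minimal reader keeping the gene symbol (column 3), qualifier (column 4)
#' and term id (column 5). Rows whose qualifier contains `NOT` are dropped
#' by default, since they assert the absence of an association.
#'
#' @param path Path to a GAF file (comment lines start with `!`).
#' @param exclude_not Drop `NOT`-qualified annotations.
#' @return A data frame `gene, term` of class `annotation_set`.
#' @export
read_gaf <- function(path, exclude_not = TRUE) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  gene <- vapply(fields, `[`, character(1), 3L)
  qual <- vapply(fields, `[`, character(1), 4L)
  term <- vapply(fields, `[`, character(1), 5L)
  keep <- if (exclude_not) !grepl("NOT", qual, fixed = TRUE) else TRUE
  out <- unique(data.frame(gene = gene[keep], term = term[keep]))
  rownames(out) <- NULL
  structure(out, class = c("annotation_set", "data.frame"))
}

#' Select ontology terms by keyword
#'
#' Case-insensitive substring match on term names; obsolete terms are
#' excluded.
#'
#' @param terms An `ontology_terms` data frame from [read_obo()].
#' @param keyword Non-empty keyword, e.g. `"spindle"`.
#' @return Character vector of term ids.
#' @export
select_terms_by_keyword <- function(terms, keyword) {
  stopifnot(is.character(keyword), nzchar(keyword))
  hit <- grepl(keyword, terms$name, ignore.case = TRUE, fixed = FALSE) &
    !terms$obsolete
  terms$id[hit]
}

#' Genes annotated to any of a set of terms
#'
#' @param annotations An `annotation_set` from [read_gaf()].
#' @param term_set Character vector of term ids.
#' @return Sorted character vector of gene symbols (each gene once).
#' @export
genes_for_terms <- function(annotations, term_set) {
  sort(unique(annotations$gene[annotations$term %in% term_set]))
}

#' Variant-to-gene database
#'
#' @param variant_id Character vector of variant identifiers.
#' @param genes Character vector of gene symbols, `;`-separated for
#'   variants overlapping several genes.
#' @return A data frame of class `variant_db`.
#' @export
variant_db <- function(variant_id, genes) {
  stopifnot(length(variant_id) == length(genes), !any(is.na(genes)),
            all(nzchar(genes)))
  structure(data.frame(variant_id = variant_id, genes = genes),
            class = c("variant_db", "data.frame"))
}

#' @rdname variant_db
#' @param path TSV file `variant_id<TAB>gene[;gene2...]` with a header
#'   line.
#' @export
read_variant_db <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = "character")
  variant_db(d[[1]], d[[2]])
}

# Per-record list of unique gene symbols.
.db_genes <- function(db) {
  lapply(strsplit(db$genes, ";", fixed = TRUE), unique)
}

#' Expected number of sampled variants falling in a gene set
#'
#' Hypergeometric mean: `n_draw` times the fraction of database records
#' belonging to at least one gene of the set.
#'
#' @param db A [variant_db()].
#' @param gene_set Character vector of target genes.
#' @param n_draw Number of variants drawn.
#' @return Expected count.
#' @export
expected_in_set <- function(db, gene_set, n_draw) {
  stopifnot(n_draw <= nrow(db))
  in_set <- vapply(.db_genes(db), function(g) any(g %in% gene_set),
                   logical(1))
  n_draw * mean(in_set)
}

#' Permutation test for enrichment of variants in a gene set
#'
#' Draws `n_draw` database records without replacement per replicate and
#' records three statistics: the number of drawn variants belonging to any
#' gene of the set (a variant hitting several set genes counts once), the
#' maximum number of drawn variants accumulating in a single set gene, and
#' the number of set genes hit at least once. One-tailed p-values count
#' replicates with a statistic at least as large as the observed value;
#' the multi-hit p-values use the fixed thresholds of two and three
#' variants in one gene.
#'
#' @param db A [variant_db()].
#' @param gene_set Character vector of target genes.
#' @param observed Named list with observed statistics `total` (variants
#'   in set genes), `max_per_gene`, and `n_genes` (set genes hit).
#' @param n_draw Variants drawn per replicate.
#' @param reps Number of replicates.
#' @param seed Integer seed.
#' @return An object of class `enrichment_result`: the observed
#'   statistics, `reps`, p-values `p_total`, `p_ge2`, `p_ge3`,
#'   `p_ngenes` (0 is reported by `print()` as `< 1/reps`), the expected
#'   in-set count, and the per-replicate statistics.
#' @export
permutation_enrichment <- function(db, gene_set,
                                   observed = list(total = 11L,
                                                   max_per_gene = 3L,
                                                   n_genes = 8L),
                                   n_draw = 96L, reps = 1000L, seed = 1L) {
  stopifnot(inherits(db, "variant_db"))
  if (n_draw > nrow(db)) stop("n_draw exceeds database size")
  genes <- .db_genes(db)
  set_genes <- lapply(genes, function(g) g[g %in% gene_set])
  in_set <- lengths(set_genes) > 0L
  stats <- .with_seed(seed, {
    t(vapply(seq_len(reps), function(r) {
      take <- sample.int(nrow(db), n_draw)
      hit <- unlist(set_genes[take])
      per_gene <- if (length(hit)) max(table(hit)) else 0L
      c(total = sum(in_set[take]), max_per_gene = as.integer(per_gene),
        n_genes = length(unique(hit)))
    }, integer(3)))
  })
  p <- function(x, obs) sum(x >= obs) / reps
  structure(list(observed = observed, reps = reps,
                 p_total = p(stats[, "total"], observed$total),
                 p_ge2 = p(stats[, "max_per_gene"], 2L),
                 p_ge3 = p(stats[, "max_per_gene"], 3L),
                 p_ngenes = p(stats[, "n_genes"], observed$n_genes),
                 expected_in_set = expected_in_set(db, gene_set, n_draw),
                 replicate_stats = stats),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  fmt <- function(p) if (p == 0) sprintf("< %g", 1 / x$reps) else sprintf("= %.3g", p)
  cat(sprintf("Permutation enrichment (%d replicates)\n", x$reps))
  cat(sprintf("  observed: %d variants in set genes (%.2f expected), max %d in one gene, %d genes hit\n",
              x$observed$total, x$expected_in_set, x$observed$max_per_gene,
              x$observed$n_genes))
  cat(sprintf("  p(total >= %d) %s\n", x$observed$total, fmt(x$p_total)))
  cat(sprintf("  p(some gene >= 2) %s\n", fmt(x$p_ge2)))
  cat(sprintf("  p(some gene >= 3) %s\n", fmt(x$p_ge3)))
  cat(sprintf("  p(genes hit >= %d) %s\n", x$observed$n_genes, fmt(x$p_ngenes)))
  invisible(x)
}
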