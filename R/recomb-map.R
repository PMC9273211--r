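#' Genomic region
#'
#' Regions are stored with `length = end - start` base pairs; region
#' strings as commonly printed ("chr15:40,818,035-41,094,166") parse to
#' `start` and `end` equal to the printed numbers, so the printed interval
#' chr15:40,818,035-41,094,166 has length 276,131 bp.
#'
#' @param chrom Chromosome name.
#' @param start Region start.
#' @param end Region end (> start).
#' @return An object of class `genome_region`.
#' @export
region <- function(chrom, start, end) {
  stopifnot(is.character(chrom), length(chrom) == 1L,
            is.numeric(start), is.numeric(end), end > start, start >= 0)
  structure(list(chrom = chrom, start = as.numeric(start),
                 end = as.numeric(end)), class = "genome_region")
}

#' @rdname region
#' @param x A region string such as `"chr15:40,818,035-41,094,166"`
#'   (en dash accepted).
#' @export
parse_region <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- gsub(",", "", x)
  x <- gsub("–", "-", x)  # en dash as printed in papers
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))[[1]]
  if (length(m) != 4L) stop("cannot parse region string: ", x)
  region(m[2], as.numeric(m[3]), as.numeric(m[4]))
}

#' @rdname region
#' @export
region_length <- function(x) {
  stopifnot(inherits(x, "genome_region"))
  x$end - x$start
}

#' @export
print.genome_region <- function(x, ...) {
  cat(sprintf("%s:%s-%s (%s bp)\n", x$chrom,
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              format(region_length(x), big.mark = ",")))
  invisible(x)
}

#' Windowed recombination map
#'
#' A recombination map is an ordered set of windows
#' `(chrom, start, end, rate)` with rates in cM/Mb. Within each chromosome
#' the windows must be sorted, non-overlapping and non-empty; maps lifted
#' between assemblies usually violate this and must first go through
#' [repair_lifted_map()].
#'
#' @param windows A data frame with columns `chrom`, `start`, `end`,
#'   `rate` (cM/Mb).
#' @param name Optional map label.
#' @return An object of class `recomb_map`.
#' @export
recomb_map <- function(windows, name = "map") {
  stopifnot(is.data.frame(windows),
            all(c("chrom", "start", "end", "rate") %in% names(windows)))
  windows <- windows[order(windows$chrom, windows$start), , drop = FALSE]
  rownames(windows) <- NULL
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, ]
    if (any(w$end <= w$start)) stop("empty window on ", ch)
    if (nrow(w) > 1L && any(w$start[-1L] < w$end[-nrow(w)]))
      stop("overlapping windows on ", ch, "; run repair_lifted_map() first")
  }
  if (any(windows$rate < 0)) stop("negative recombination rate")
  structure(list(windows = windows, name = name), class = "recomb_map")
}

#' @export
print.recomb_map <- function(x, ...) {
  cat(sprintf("recomb_map '%s': %d windows on %d chromosome(s), mean rate %.3f cM/Mb\n",
              x$name, nrow(x$windows), length(unique(x$windows$chrom)),
              mean(x$windows$rate)))
  invisible(x)
}

#' Read / write a recombination map as TSV
#'
#' Format: tab-separated `chrom start end rate_cMMb` with one header line.
#'
#' @param path File path.
#' @param name Map label (defaults to the file name).
#' @return `read_recomb_map()` returns a `recomb_map`.
#' @export
read_recomb_map <- function(path, name = basename(path)) {
  w <- utils::read.table(path, header = TRUE, sep = "\t",
                         col.names = c("chrom", "start", "end", "rate"),
                         colClasses = c("character", "numeric", "numeric",
                                        "numeric"))
  recomb_map(w, name = name)
}

#' @rdname read_recomb_map
#' @param map A `recomb_map`.
#' @export
write_recomb_map <- function(map, path) {
  stopifnot(inherits(map, "recomb_map"))
  w <- map$windows
  names(w) <- c("chrom", "start", "end", "rate_cMMb")
  utils::write.table(w, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Repair a lifted-over recombination map
#'
#' Lifting a map between genome assemblies leaves gaps and overlaps between
#' adjacent windows. The repair rule: the rate in a gap between two
#' consecutive windows is the arithmetic mean of the two flanking rates; a
#' window that overlaps the previous window is truncated (its start raised
#' to the previous end), and dropped entirely if the previous window fully
#' contains it. The repair is idempotent.
#'
#' @param raw_windows Data frame `chrom, start, end, rate`, sorted by
#'   (chrom, start); or a `recomb_map` (already valid, returned repaired).
#' @param name Map label.
#' @return A valid `recomb_map`.
#' @export
repair_lifted_map <- function(raw_windows, name = "map") {
  if (inherits(raw_windows, "recomb_map")) {
    name <- raw_windows$name
    raw_windows <- raw_windows$windows
  }
  stopifnot(is.data.frame(raw_windows),
            all(c("chrom", "start", "end", "rate") %in% names(raw_windows)))
  pieces <- lapply(split(raw_windows, raw_windows$chrom), function(w) {
    if (is.unsorted(w$start)) stop("windows not sorted by start")
    out <- w[1L, c("chrom", "start", "end", "rate"), drop = FALSE]
    for (i in seq_len(nrow(w))[-1L]) {
      prev_end <- out$end[nrow(out)]
      cur <- w[i, c("chrom", "start", "end", "rate"), drop = FALSE]
      if (cur$end <= prev_end) next                      # fully contained
      if (cur$start < prev_end) cur$start <- prev_end    # truncate overlap
      if (cur$start > prev_end) {                        # fill gap
        gap <- data.frame(chrom = cur$chrom, start = prev_end,
                          end = cur$start,
                          rate = (out$rate[nrow(out)] + cur$rate) / 2)
        out <- rbind(out, gap)
      }
      out <- rbind(out, cur)
    }
    out
  })
  res <- do.call(rbind, pieces)
  rownames(res) <- NULL
  recomb_map(res, name = name)
}

# bp overlap of each map window with a region, for one chromosome
.map_overlaps <- function(reg, map) {
  w <- map$windows[map$windows$chrom == reg$chrom, , drop = FALSE]
  if (nrow(w) == 0L) return(w)
  ov_start <- pmax(w$start, reg$start)
  ov_end <- pmin(w$end, reg$end)
  keep <- ov_end > ov_start
  data.frame(bp = (ov_end - ov_start)[keep], rate = w$rate[keep])
}

#' Mean recombination rate of a region
#'
#' Length-weighted mean rate of the map windows overlapping the region;
#' with several maps, the unweighted mean of the per-map rates (the usual
#' way to average across maps built from different data).
#'
#' @param reg A [region()].
#' @param maps A `recomb_map` or a list of them.
#' @return Rate in cM/Mb.
#' @export
mean_rate <- function(reg, maps) {
  stopifnot(inherits(reg, "genome_region"))
  if (inherits(maps, "recomb_map")) maps <- list(maps)
  per_map <- vapply(maps, function(m) {
    ov <- .map_overlaps(reg, m)
    if (nrow(ov) == 0L)
      stop("region has no overlap with map '", m$name, "'")
    sum(ov$bp * ov$rate) / sum(ov$bp)
  }, numeric(1))
  mean(per_map)
}

#' Genetic length of a region
#'
#' Sum over map windows of overlap_bp * rate * 1e-6 cM. Parts of the
#' region outside map coverage contribute nothing (no extrapolation).
#'
#' @inheritParams mean_rate
#' @param map A `recomb_map`.
#' @return Genetic length in cM.
#' @export
genetic_length <- function(reg, map) {
  stopifnot(inherits(reg, "genome_region"), inherits(map, "recomb_map"))
  ov <- .map_overlaps(reg, map)
  if (nrow(ov) == 0L) stop("region has no overlap with map '", map$name, "'")
  sum(ov$bp * ov$rate) * 1e-6
}

#' Classify a segment as a sweep candidate by genetic length
#'
#' Segments where archaic genomes fall outside present-day variation are
#' candidates for a selective sweep when their genetic length exceeds a
#' threshold not reached in neutral simulations (default 0.025 cM, strict
#' inequality).
#'
#' @inheritParams genetic_length
#' @param threshold_cm Genetic-length threshold in cM.
#' @return Logical: `TRUE` if genetic length > threshold.
#' @export
classify_sweep_candidate <- function(reg, map, threshold_cm = 0.025) {
  genetic_length(reg, map) > threshold_cm
}
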