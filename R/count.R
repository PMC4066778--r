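#' Directionally extend reads to fragment length
#'
#' A forward read covers `[pos5, pos5 + f)`; a reverse read covers the `f`
#' bases ending at its 5' end inclusive, `[pos5 - f + 1, pos5 + 1)`. Either
#' way the extended fragment has width exactly `f` and represents the
#' sonicated DNA fragment the read came from.
#'
#' @param reads Read tibble (`chrom`, `pos5`, `strand`).
#' @param f Fragment length in bp (>= 1).
#' @return An interval tibble.
#' @export
extend_reads <- function(reads, f = 100) {
  stopifnot(f >= 1)
  fwd <- reads$strand == "+"
  raw_start <- ifelse(fwd, reads$pos5, reads$pos5 - f + 1L)
  ## fragments running off the chromosome start are clipped, keeping the
  ## 5' anchor fixed
  tibble::tibble(
    chrom = reads$chrom,
    start = as.integer(pmax(raw_start, 0L)),
    end = as.integer(raw_start + f)
  )
}

## Column-bind per-library count vectors onto a feature frame, dropping
## all-zero rows when requested.
bind_counts <- function(features, counts_list, drop_empty = FALSE) {
  out <- features
  for (lab in names(counts_list)) out[[lab]] <- as.integer(counts_list[[lab]])
  if (drop_empty) {
    keep <- rowSums(count_matrix(out)) > 0
    out <- out[keep, , drop = FALSE]
  }
  out
}

#' Count extended fragments overlapping sliding windows
#'
#' Windows of a fixed `width` start at every multiple of `spacing` from 0;
#' with equal widths, midpoint spacing equals start spacing. Each read is
#' directionally extended to `f` bp and counted into every window its
#' fragment overlaps, so a window's count includes reads lying immediately
#' upstream on their own strand. Windows with zero counts in all libraries
#' are omitted from the result.
#'
#' @param read_libs Named list of read tibbles, one per library.
#' @param genome_length Genome length in bp.
#' @param width Window width in bp (1 for sharp TF analyses, 150 for
#'   histone marks).
#' @param spacing Distance between successive window starts in bp.
#' @param f Fragment extension length in bp.
#' @return A count tibble over non-empty windows.
#' @export
count_windows <- function(read_libs, genome_length, width = 1, spacing = 50,
                          f = 100) {
  stopifnot(width >= 1, spacing >= 1, f >= 1, length(read_libs) >= 1)
  n_win <- as.integer((genome_length - 1) %/% spacing + 1)
  counts <- lapply(read_libs, function(reads) {
    frag <- extend_reads(reads, f)
    ## window j (0-based) covers [j*spacing, j*spacing + width); a fragment
    ## [s, e) hits windows with j*spacing < e and j*spacing + width > s.
    j_min <- (frag$start - width) %/% spacing + 1L
    j_max <- (frag$end - 1L) %/% spacing
    j_min <- pmax(j_min, 0L)
    j_max <- pmin(j_max, n_win - 1L)
    ok <- j_min <= j_max
    delta <- integer(n_win + 1L)
    add <- tabulate(j_min[ok] + 1L, nbins = n_win + 1L)
    sub <- tabulate(j_max[ok] + 2L, nbins = n_win + 1L)
    cumsum(add - sub)[seq_len(n_win)]
  })
  total <- Reduce(`+`, counts)
  keep <- which(total > 0)
  features <- tibble::tibble(
    chrom = if (length(read_libs[[1]]$chrom) > 0) read_libs[[1]]$chrom[1] else "chrSim",
    start = (keep - 1L) * as.integer(spacing),
    end = pmin((keep - 1L) * as.integer(spacing) + as.integer(width),
      as.integer(genome_length))
  )
  bind_counts(features, lapply(counts, `[`, keep))
}

#' Count 5' read ends within intervals
#'
#' The count for an interval is the number of reads whose 5' end lies in
#' `[start, end)`, regardless of strand. This is the counting rule used for
#' peak intervals.
#'
#' @param read_libs Named list of read tibbles.
#' @param intervals Interval tibble.
#' @return A count tibble with one row per input interval (order preserved).
#' @export
count_5prime <- function(read_libs, intervals) {
  validate_intervals(intervals)
  stopifnot(nrow(intervals) >= 1)
  ir <- as_iranges(intervals)
  counts <- lapply(read_libs, function(reads) {
    n <- integer(nrow(intervals))
    for (ch in unique(intervals$chrom)) {
      i <- which(intervals$chrom == ch)
      pos <- reads$pos5[reads$chrom == ch]
      n[i] <- IRanges::countOverlaps(
        ir[i], IRanges::IRanges(start = pos + 1L, width = 1L)
      )
    }
    n
  })
  bind_counts(intervals[, c("chrom", "start", "end")], counts)
}

#' Count 5' read ends into contiguous genomic bins
#'
#' Disjoint tiling `[k * bin_size, (k + 1) * bin_size)`; every read falls in
#' exactly one bin, so column sums equal library sizes. Used to build the
#' large-bin count table for normalization.
#'
#' @param read_libs Named list of read tibbles.
#' @param genome_length Genome length in bp.
#' @param bin_size Bin width in bp.
#' @return A count tibble over all bins (including empty ones).
#' @export
count_bins <- function(read_libs, genome_length, bin_size = 10000) {
  stopifnot(bin_size >= 1)
  n_bin <- as.integer((genome_length - 1) %/% bin_size + 1)
  counts <- lapply(read_libs, function(reads) {
    tabulate(reads$pos5 %/% bin_size + 1L, nbins = n_bin)
  })
  start <- (seq_len(n_bin) - 1L) * as.integer(bin_size)
  features <- tibble::tibble(
    chrom = if (length(read_libs[[1]]$chrom) > 0) read_libs[[1]]$chrom[1] else "chrSim",
    start = start,
    end = pmin(start + as.integer(bin_size), as.integer(genome_length))
  )
  bind_counts(features, counts)
}

#' Filter low-abundance features before testing
#'
#' Drops features whose total count across libraries falls below
#' `min_total`, and optionally those whose average log2 count-per-million
#' (computed with a 0.5 prior count against effective library sizes) falls
#' below `min_ave_log_cpm`. Low-abundance windows represent non-specific
#' background where differential binding is not expected; removing them
#' reduces the multiple-testing burden without affecting type I error. The
#' abundance filter is meant for real data and is off by default.
#'
#' @param counts Count tibble.
#' @param min_total Minimum total count across libraries.
#' @param min_ave_log_cpm Optional minimum average log2 CPM (`NULL` = off).
#' @param lib_sizes Effective library sizes for the CPM computation;
#'   defaults to column sums.
#' @return The filtered count tibble.
#' @export
filter_features <- function(counts, min_total = 20, min_ave_log_cpm = NULL,
                            lib_sizes = NULL) {
  m <- count_matrix(counts)
  keep <- rowSums(m) >= min_total
  if (!is.null(min_ave_log_cpm)) {
    if (is.null(lib_sizes)) lib_sizes <- colSums(m)
    keep <- keep & ave_log_cpm(counts, lib_sizes) >= min_ave_log_cpm
  }
  counts[keep, , drop = FALSE]
}
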