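#' Construct a tibble of genomic intervals
#'
#' Intervals are zero-based and half-open throughout the package: an interval
#' covers bases `start, start + 1, ..., end - 1`, matching the BED convention.
#' Adjacent intervals (one ending where the next starts) never overlap.
#'
#' @param chrom Character vector of chromosome identifiers.
#' @param start,end Integer vectors of 0-based half-open coordinates;
#'   `end > start >= 0` is required for every row.
#'
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @export
#' @examples
#' genomic_intervals("chr1", 0, 100)
genomic_intervals <- function(chrom, start, end) {
  x <- tibble::tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end)
  )
  validate_intervals(x)
  x
}

validate_intervals <- function(x, what = "interval") {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  bad <- which(x$start < 0 | x$end <= x$start)
  if (length(bad) > 0) {
    stop(sprintf(
      "invalid %s at row %d: start=%d, end=%d (need 0 <= start < end)",
      what, bad[1], x$start[bad[1]], x$end[bad[1]]
    ), call. = FALSE)
  }
  invisible(x)
}

#' Pairwise interval overlap test
#'
#' Tests whether paired intervals overlap under half-open semantics:
#' rows overlap iff they share a chromosome and
#' `max(start) < min(end)`. Inputs are recycled row-wise like vectors.
#'
#' @param a,b Interval tibbles (`chrom`, `start`, `end`) with one or the
#'   same number of rows.
#'
#' @return Logical vector.
#' @export
#' @examples
#' interval_overlaps(genomic_intervals("chr1", 0, 10), genomic_intervals("chr1", 9, 20))
interval_overlaps <- function(a, b) {
  validate_intervals(a)
  validate_intervals(b)
  same <- a$chrom == b$chrom
  same & (pmax(a$start, b$start) < pmin(a$end, b$end))
}

## IRanges is 1-based closed; [start, end) maps to IRanges(start + 1, end).
as_iranges <- function(x) {
  IRanges::IRanges(start = x$start + 1L, end = x$end)
}

from_iranges <- function(ir, chrom) {
  tibble::tibble(
    chrom = chrom,
    start = IRanges::start(ir) - 1L,
    end = IRanges::end(ir)
  )
}

#' Overlap join between two interval sets
#'
#' Finds every (query, subject) pair of truly overlapping intervals
#' (adjacency excluded), chromosome by chromosome.
#'
#' @param query,subject Interval tibbles.
#' @return A tibble with integer columns `query` and `subject` holding row
#'   indices into the respective inputs.
#' @export
overlap_join <- function(query, subject) {
  validate_intervals(query)
  validate_intervals(subject)
  out <- lapply(intersect(unique(query$chrom), unique(subject$chrom)), function(ch) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    hits <- IRanges::findOverlaps(
      as_iranges(query[qi, ]), as_iranges(subject[si, ]),
      minoverlap = 1L
    )
    tibble::tibble(
      query = qi[S4Vectors_from(hits)],
      subject = si[S4Vectors_to(hits)]
    )
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$query, .data$subject)
}

# queryHits/subjectHits without importing S4Vectors wholesale
S4Vectors_from <- function(hits) methods::slot(hits, "from")
S4Vectors_to <- function(hits) methods::slot(hits, "to")

## Single-linkage clustering of intervals by overlap: returns an integer
## cluster id per row. Adjacent-but-not-overlapping intervals stay separate.
cluster_intervals <- function(x) {
  validate_intervals(x)
  ids <- integer(nrow(x))
  offset <- 0L
  for (ch in unique(x$chrom)) {
    i <- which(x$chrom == ch)
    ir <- as_iranges(x[i, ])
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    hit <- IRanges::findOverlaps(ir, red, minoverlap = 1L)
    ids[i] <- offset + S4Vectors_to(hit)
    offset <- offset + length(red)
  }
  ids
}
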