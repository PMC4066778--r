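#' Read and write BED interval files
#'
#' BED3 (optionally with name and score columns) with the native 0-based
#' half-open convention. `write_bed()` emits BED3 or, when `scores` is
#' supplied, BED6 with a dot name, the score in column 5 and a dot strand.
#'
#' @param path File path.
#' @return `read_bed()` returns an interval tibble (`chrom`, `start`, `end`),
#'   with a `score` column when the file has one.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop(sprintf("malformed BED line %d: fewer than 3 fields", which(nf < 3)[1]),
      call. = FALSE
    )
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | end <= start)
  if (length(bad) > 0) {
    stop(sprintf("malformed BED line %d: invalid interval", bad[1]), call. = FALSE)
  }
  out <- tibble::tibble(
    chrom = vapply(fields, `[[`, "", 1L),
    start = start, end = end
  )
  if (all(nf >= 5)) {
    out$score <- as.numeric(vapply(fields, `[[`, "", 5L))
  }
  out
}

#' @param intervals Interval tibble to write.
#' @param scores Optional numeric score per interval (BED column 5; the
#'   package writes -log10 q-values here for detected regions).
#' @rdname read_bed
#' @export
write_bed <- function(intervals, path, scores = NULL) {
  validate_intervals(intervals)
  if (is.null(scores)) {
    lines <- sprintf("%s\t%d\t%d", intervals$chrom, intervals$start, intervals$end)
  } else {
    stopifnot(length(scores) == nrow(intervals))
    lines <- sprintf(
      "%s\t%d\t%d\t.\t%g\t.",
      intervals$chrom, intervals$start, intervals$end, scores
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read and write stranded 5' read positions
#'
#' Reads are point events: a chromosome, the 0-based position of the 5' end,
#' and a strand (`+` forward, `-` reverse). Stored as headerless TSV with
#' those three columns.
#'
#' @param path File path.
#' @return A read tibble (`chrom`, `pos5`, `strand`).
#' @export
read_reads <- function(path) {
  x <- readr::read_tsv(path,
    col_names = c("chrom", "pos5", "strand"),
    col_types = readr::cols(
      chrom = readr::col_character(),
      pos5 = readr::col_integer(),
      strand = readr::col_character()
    ),
    progress = FALSE
  )
  bad <- which(!x$strand %in% c("+", "-"))
  if (length(bad) > 0) {
    stop(sprintf("unknown strand symbol %s on line %d", x$strand[bad[1]], bad[1]),
      call. = FALSE
    )
  }
  x
}

#' @param reads Read tibble to write.
#' @rdname read_reads
#' @export
write_reads <- function(reads, path) {
  stopifnot(all(c("chrom", "pos5", "strand") %in% names(reads)))
  stopifnot(all(reads$strand %in% c("+", "-")))
  readr::write_tsv(reads[, c("chrom", "pos5", "strand")], path, col_names = FALSE)
  invisible(path)
}

#' Read and write count tables
#'
#' A count table is a tibble with feature coordinates (`chrom`, `start`,
#' `end`) followed by one integer column of counts per library. On disk it
#' is a TSV with a header row.
#'
#' @param path File path.
#' @return A count tibble.
#' @export
read_counts <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(),
    .default = readr::col_integer()
  ), progress = FALSE)
  validate_intervals(x, "count feature")
  x
}

#' @param counts Count tibble to write.
#' @rdname read_counts
#' @export
write_counts <- function(counts, path) {
  validate_intervals(counts, "count feature")
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Extract the count matrix / feature intervals from a count tibble
#'
#' @param counts A count tibble (`chrom`, `start`, `end`, one column per
#'   library).
#' @return `count_matrix()`: an integer matrix (features x libraries);
#'   `feature_intervals()`: the `chrom`/`start`/`end` columns.
#' @export
count_matrix <- function(counts) {
  libs <- setdiff(names(counts), c("chrom", "start", "end"))
  m <- as.matrix(counts[, libs, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- NULL
  m
}

#' @rdname count_matrix
#' @export
feature_intervals <- function(counts) {
  counts[, c("chrom", "start", "end")]
}

#' Import stranded 5' read positions from a BAM file
#'
#' Extracts the 5'-end position and strand of every mapped alignment,
#' converting to the package's 0-based convention: the 5' end of a reverse
#' read is the rightmost aligned base. Requires the Rsamtools package.
#' Intended for real-data use; all analyses in this package consume the
#' same read tibble regardless of source.
#'
#' @param path Path to a BAM file.
#' @return A read tibble (`chrom`, `pos5`, `strand`).
#' @export
read_reads_bam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("read_reads_bam() requires the Rsamtools package", call. = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  par <- Rsamtools::ScanBamParam(
    flag = flag, what = c("rname", "pos", "strand", "qwidth")
  )
  b <- Rsamtools::scanBam(path, param = par)[[1]]
  fwd <- as.character(b$strand) == "+"
  tibble::tibble(
    chrom = as.character(b$rname),
    pos5 = as.integer(ifelse(fwd, b$pos - 1L, b$pos + b$qwidth - 2L)),
    strand = ifelse(fwd, "+", "-")
  )
}
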