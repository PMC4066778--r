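#' Simes' combined P-value
#'
#' Combines `n` P-values into evidence against the global null that none of
#' the underlying hypotheses is false: with the values sorted increasingly,
#' `p_s = min_r { n * p_(r) / r }`, capped at 1. Provides weak family-wise
#' error control over the set and is robust to the positive correlations
#' typical of overlapping windows.
#'
#' @param p Numeric vector of P-values in (0, 1]; must be non-empty.
#' @return A single combined P-value.
#' @export
#' @examples
#' simes_p(c(0.01, 0.04, 0.9)) # 0.03
simes_p <- function(p) {
  if (length(p) == 0) stop("cannot combine an empty set of P-values", call. = FALSE)
  n <- length(p)
  min(1, min(n * sort(p) / seq_len(n)))
}

#' Benjamini-Hochberg adjusted P-values
#'
#' Step-up FDR adjustment, `q_(i) = min_{j >= i} { m * p_(j) / j }` capped
#' at 1, returned in the original order. Wraps [stats::p.adjust()].
#'
#' @param p Numeric vector of P-values.
#' @return Adjusted values (q-values), same length and order.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Merge significant windows into regions (sliding-window summarization)
#'
#' The sliding-window method's reporting step: windows are BH-adjusted at
#' the window level, those at or below the FDR threshold are kept, and
#' detected windows are single-linkage merged when they lie less than
#' `max_gap` bp apart (a gap of exactly `max_gap` keeps them separate) and
#' share a direction of fold change. Note the FDR guarantee here applies to
#' windows, not to the merged regions.
#'
#' @param results Per-window results tibble (from [ql_ftest()] or
#'   `tidy(db_test(...))`): needs `chrom`, `start`, `end`, `logFC`,
#'   `pvalue`.
#' @param fdr Window-level FDR threshold.
#' @param max_gap Maximum gap for merging, in bp (strict inequality).
#' @return A region tibble: `chrom`, `start`, `end`, `n_windows`,
#'   `direction` (+1/-1), `best_p`.
#' @export
merge_db_windows <- function(results, fdr = 0.05, max_gap = 100) {
  q <- bh_adjust(results$pvalue)
  hit <- results[q <= fdr, , drop = FALSE]
  if (nrow(hit) == 0) {
    return(tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      n_windows = integer(), direction = integer(), best_p = numeric()
    ))
  }
  hit$direction <- ifelse(hit$logFC >= 0, 1L, -1L)
  hit <- dplyr::arrange(hit, .data$chrom, .data$direction, .data$start)
  new_run <- c(TRUE, hit$chrom[-1] != hit$chrom[-nrow(hit)] |
    hit$direction[-1] != hit$direction[-nrow(hit)] |
    hit$start[-1] - hit$end[-nrow(hit)] >= max_gap)
  ## starts are sorted within chrom x direction, so gap to the previous
  ## window is start - cummax(previous ends); with equal widths plain end works
  run <- cumsum(new_run)
  out <- dplyr::summarise(dplyr::group_by(hit, run = run),
    chrom = .data$chrom[1],
    start = min(.data$start),
    end = max(.data$end),
    n_windows = dplyr::n(),
    direction = .data$direction[1],
    best_p = min(.data$pvalue),
    .groups = "drop"
  )
  dplyr::arrange(out[, -1], .data$chrom, .data$start)
}

#' Hybrid region-level inference: Simes over peak clusters
#'
#' Aggregates window results into one cluster per peak: every window
#' overlapping a peak belongs to that peak's cluster (a window overlapping
#' several peaks contributes to each). Each cluster's member window
#' P-values are combined with Simes' method, and the BH procedure is
#' applied across clusters, so the FDR is controlled over detected genomic
#' regions rather than windows. Peaks overlapped by no tested window are
#' omitted.
#'
#' @param results Per-window results tibble (`chrom`, `start`, `end`,
#'   `logFC`, `pvalue`). Windows need not be pre-filtered to those
#'   overlapping peaks; the overlap is taken here.
#' @param peaks Peak interval tibble (`chrom`, `start`, `end`).
#' @return A region tibble with one row per peak cluster: the peak
#'   interval, `n_windows`, `combined_p`, `qvalue` and `direction` (sign of
#'   the member window with the smallest P-value).
#' @export
hybrid_regions <- function(results, peaks) {
  empty <- tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    n_windows = integer(), combined_p = numeric(), qvalue = numeric(),
    direction = integer()
  )
  if (nrow(peaks) == 0 || nrow(results) == 0) return(empty)
  hits <- overlap_join(results, peaks)
  if (nrow(hits) == 0) return(empty)
  member <- tibble::tibble(
    peak = hits$subject,
    pvalue = results$pvalue[hits$query],
    logFC = results$logFC[hits$query]
  )
  agg <- dplyr::summarise(dplyr::group_by(member, .data$peak),
    n_windows = dplyr::n(),
    combined_p = simes_p(.data$pvalue),
    direction = ifelse(.data$logFC[which.min(.data$pvalue)][1] >= 0, 1L, -1L),
    .groups = "drop"
  )
  out <- tibble::tibble(
    chrom = peaks$chrom[agg$peak],
    start = peaks$start[agg$peak],
    end = peaks$end[agg$peak],
    n_windows = agg$n_windows,
    combined_p = agg$combined_p,
    qvalue = bh_adjust(agg$combined_p),
    direction = agg$direction
  )
  dplyr::arrange(out, .data$chrom, .data$start)
}

## DB regions of a truth table, as an interval tibble.
db_regions <- function(truth) {
  truth[truth$is_db, c("chrom", "start", "end"), drop = FALSE]
}

#' Observed window-level FDR
#'
#' The proportion of detected windows lying outside the regions of DB true
#' peaks (0 when nothing is detected).
#'
#' @param detected Interval tibble of detected windows.
#' @param truth Truth tibble from [build_truth()].
#' @return A proportion.
#' @export
observed_fdr_window <- function(detected, truth) {
  if (nrow(detected) == 0) return(0)
  db <- db_regions(truth)
  if (nrow(db) == 0) return(1)
  inside <- unique(overlap_join(detected, db)$query)
  1 - length(inside) / nrow(detected)
}

#' Observed region-level FDR
#'
#' A true peak counts as detected when it is overlapped by at least one
#' detected region (or window); the observed region-level FDR is the
#' proportion of detected true peaks that are not DB. Detected regions
#' overlapping no true peak at all (background false positives) also count
#' as false discoveries. Returns 0 when nothing is detected.
#'
#' @param detected Interval tibble of detected regions (or windows).
#' @param truth Truth tibble.
#' @return A proportion.
#' @export
observed_fdr_region <- function(detected, truth) {
  if (nrow(detected) == 0) return(0)
  hits <- overlap_join(detected, truth)
  hit_truth <- unique(hits$subject)
  n_bg <- nrow(detected) - length(unique(hits$query))
  n_det <- length(hit_truth) + n_bg
  if (n_det == 0) return(0)
  (sum(!truth$is_db[hit_truth]) + n_bg) / n_det
}

#' Count detected DB true peaks (detection power)
#'
#' The number of DB true peaks overlapped by at least one detected region.
#'
#' @param detected Interval tibble of detected regions.
#' @param truth Truth tibble.
#' @return An integer count.
#' @export
power_count <- function(detected, truth) {
  if (nrow(detected) == 0) return(0L)
  db <- db_regions(truth)
  if (nrow(db) == 0) return(0L)
  length(unique(overlap_join(detected, db)$subject))
}
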