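#' Call peaks with a simplified Poisson scan
#'
#' A deliberately minimal enrichment caller in the mould of classic ChIP-seq
#' peak callers. Each read's 5' end is shifted by half the fragment length
#' towards the fragment centre (`+f/2` forward, `-f/2` reverse). The genome
#' is scanned with windows of width `scan_width` every `step` bp; the window
#' P-value is the upper-tail Poisson probability of its shifted-read count
#' at a rate `lambda` set by the larger of the genome-wide read density and
#' the local density over a `local_width` neighbourhood, scaled to the
#' window width. In two-sample mode (a `control` library is given) the rate
#' comes instead from the control's local density scaled by the library-size
#' ratio (taking the max over nested 1/5/10 kbp control neighbourhoods),
#' floored at the control's genome-wide rate, so the caller detects
#' enrichment of the treatment over the control. Windows with
#' `P <= seed_p` are merged when overlapping or adjacent into peaks; each
#' peak's reported P-value is then recomputed from the shifted-read count
#' over the whole merged region against the background rate scaled to the
#' region width, and only peaks at or below `max_pvalue` are reported. The
#' summit is the centre of the best seed window.
#'
#' @param reads Read tibble (the treatment library).
#' @param genome_length Genome length in bp.
#' @param f Average fragment length in bp; the shift is `f/2`.
#' @param control Optional read tibble for two-sample calling.
#' @param step Scan step in bp (default `f/4`).
#' @param scan_width Scan window width in bp (default `2 * f`, the span of
#'   a fragment-length window either side of a shifted position).
#' @param seed_p Seed threshold: windows at or below it enter peaks.
#' @param local_width Width of the local background neighbourhood in bp.
#' @param max_pvalue Output cutoff: only peaks whose recomputed P-value is
#'   at or below this are reported (the emulated caller's default).
#' @return A tibble of peaks: `chrom`, `start`, `end`, `summit`, `pvalue`,
#'   sorted by position. Empty input gives an empty tibble.
#' @export
call_peaks <- function(reads, genome_length, f = 100, control = NULL,
                       step = NULL, scan_width = NULL, seed_p = 0.1,
                       local_width = 10000, max_pvalue = 1e-5) {
  if (is.null(step)) step <- max(1L, f %/% 4L)
  if (is.null(scan_width)) scan_width <- 2L * f
  stopifnot(scan_width %% step == 0, local_width %% step == 0)
  empty <- tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    summit = integer(), pvalue = numeric()
  )
  if (nrow(reads) == 0) return(empty)
  chrom <- reads$chrom[1]
  L <- as.numeric(genome_length)
  two_sample <- !is.null(control)
  if (two_sample && nrow(control) == 0) {
    stop("control library is empty", call. = FALSE)
  }

  scan <- scan_windows(reads, control, genome_length, f, step, scan_width,
    local_width
  )
  seed <- which(scan$p <= seed_p & scan$count > 0)
  if (length(seed) == 0) return(empty)

  ## windows overlap or touch when their starts differ by <= scan_width
  w_cells <- scan_width %/% step
  run <- cumsum(c(1L, diff(seed) > w_cells))
  starts <- (seed - 1L) * step
  seeds <- tibble::tibble(run = run, start = starts, p = scan$p[seed])
  peaks <- dplyr::summarise(dplyr::group_by(seeds, .data$run),
    pk_start = min(.data$start),
    pk_end = max(.data$start) + scan_width,
    pk_summit = .data$start[which.min(.data$p)][1] + scan_width %/% 2L,
    .groups = "drop"
  )
  start <- as.integer(peaks$pk_start)
  end <- as.integer(pmin(peaks$pk_end, L))

  ## the reported peak P-value is recomputed over the merged region: the
  ## shifted-read count across the whole peak against the background rate
  ## scaled to the region width
  lo_cell <- start %/% as.integer(step) + 1L
  hi_cell <- (end - 1L) %/% as.integer(step) + 1L
  count <- scan$csum[hi_cell + 1L] - scan$csum[lo_cell - 1L + 1L]
  centre <- (start + end) / 2
  width <- end - start
  bg_csum <- if (two_sample) scan$ccsum else scan$csum
  bg_n <- if (two_sample) nrow(control) else nrow(reads)
  ## dynamic local background: in two-sample mode the max over the peak
  ## region itself and nested 1/5/10 kbp control neighbourhoods, so that a
  ## matching control peak masks the call; single-sample mode uses only the
  ## wide neighbourhood (the peak's own enrichment must not mask itself)
  lw <- if (two_sample) c(0, 1000, 5000, local_width) else local_width
  rate <- Reduce(pmax, lapply(lw, function(w) {
    local_rate(bg_csum, centre, pmax(w, width), step)
  }))
  rate <- pmax(rate, bg_n / L)
  ratio <- if (two_sample) nrow(reads) / nrow(control) else 1
  lambda <- rate * width * ratio
  pvalue <- stats::ppois(count - 1, lambda, lower.tail = FALSE)

  out <- tibble::tibble(
    chrom = chrom,
    start = start,
    end = end,
    summit = as.integer(peaks$pk_summit),
    pvalue = pmax(pvalue, 1e-300)
  )
  out[out$pvalue <= max_pvalue, , drop = FALSE]
}

## Sliding-window Poisson scan: counts, background lambda and P-value per
## window, plus the cumulative cell sums reused for peak-level statistics.
scan_windows <- function(reads, control, genome_length, f, step, scan_width,
                         local_width) {
  L <- as.numeric(genome_length)
  cells <- shifted_cell_counts(reads, f, step, genome_length)
  n_cell <- length(cells)
  w_cells <- scan_width %/% step
  n_win <- max(n_cell - w_cells + 1L, 0L)
  csum <- c(0, cumsum(as.numeric(cells)))
  if (n_win == 0) {
    return(list(
      count = numeric(0), lambda = numeric(0), p = numeric(0),
      csum = csum, ccsum = NULL
    ))
  }
  count <- csum[(w_cells + 1L):(w_cells + n_win)] - csum[seq_len(n_win)]
  if (is.null(control)) {
    rate <- scan_lambda(csum, n_win, w_cells, step, local_width,
      n_reads = nrow(reads), L = L
    )
    lambda <- rate * scan_width
    ccsum <- NULL
  } else {
    ## two-sample mode: the control supplies the background rate, taken as
    ## the max over nested local windows (down to 1 kbp) so the control's
    ## own peak density masks matching enrichment, floored at its
    ## genome-wide rate and scaled by the library-size ratio
    ccells <- shifted_cell_counts(control, f, step, genome_length)
    ccsum <- c(0, cumsum(as.numeric(ccells)))
    widths <- unique(pmin(c(scan_width, 1000, 5000, local_width), local_width))
    widths <- widths[widths %% step == 0]
    rate <- Reduce(pmax, lapply(widths, function(w) {
      scan_lambda(ccsum, n_win, w_cells, step, w,
        n_reads = nrow(control), L = L
      )
    }))
    lambda <- rate * scan_width * nrow(reads) / nrow(control)
  }
  list(
    count = count, lambda = lambda,
    p = stats::ppois(count - 1, lambda, lower.tail = FALSE),
    csum = csum, ccsum = ccsum
  )
}

## Background rate (reads per bp) over a window of `width` bp centred at
## each of the given positions, clamped to the genome.
local_rate <- function(csum, centre, width, step) {
  n_cell <- length(csum) - 1L
  c_cell <- centre / step
  half <- width / step / 2
  lo <- pmax(1L, as.integer(ceiling(c_cell - half + 0.5)))
  hi <- pmin(n_cell, as.integer(floor(c_cell + half + 0.5)))
  (csum[hi + 1L] - csum[lo]) / ((hi - lo + 1L) * step)
}

## Counts of shifted 5' positions per step-sized cell.
shifted_cell_counts <- function(reads, f, step, genome_length) {
  shift <- ifelse(reads$strand == "+", f %/% 2L, -(f %/% 2L))
  pos <- pmin(pmax(reads$pos5 + shift, 0L), as.integer(genome_length) - 1L)
  n_cell <- as.integer((genome_length - 1) %/% step + 1)
  tabulate(pos %/% step + 1L, nbins = n_cell)
}

## Per-window background rate (reads per bp): max of the genome-wide rate
## and the rate over a local_width neighbourhood centred on the window.
scan_lambda <- function(csum, n_win, w_cells, step, local_width, n_reads, L) {
  l_cells <- local_width %/% step
  n_cell <- length(csum) - 1L
  centre <- seq_len(n_win) + (w_cells - 1L) / 2
  lo <- pmax(1L, as.integer(ceiling(centre - l_cells / 2)))
  hi <- pmin(n_cell, as.integer(floor(centre + l_cells / 2)))
  local_rate <- (csum[hi + 1L] - csum[lo]) / ((hi - lo + 1L) * step)
  pmax(n_reads / L, local_rate)
}

#' Consolidate peak calls across libraries or groups
#'
#' Implements the seven consolidation strategies for turning per-library or
#' per-group peak calls into a single peak list. Peaks are matched across
#' units by single-linkage overlap clustering; each cluster is one logical
#' peak, and a unit with no overlapping call contributes a peak-calling
#' P-value of 1. The consolidated P-value per cluster is:
#'
#' * strategy 1 (per-library union) and 4 (per-group union): the minimum;
#' * strategy 2 (per-library intersection) and 5 (per-group intersection):
#'   the maximum;
#' * strategy 3 (in at least two libraries): the second-smallest;
#' * strategy 6 (two-sample between groups, union over directions): the
#'   smaller of the two directional P-values where calls overlap;
#' * strategy 7 (single call on the all-pooled library): the value itself.
#'
#' The threshold `tau` is then set to the `C`-th smallest consolidated
#' P-value so that at most `C` peaks are retained (all peaks are retained
#' if fewer are available); alternatively a fixed `tau` may be given.
#'
#' @param peak_sets List of peak tibbles from [call_peaks()]: one per
#'   library (strategies 1-3), one per group-pooled library (4-5), one per
#'   enrichment direction (6), or a single set (7).
#' @param strategy Integer 1-7.
#' @param C Number of peaks to retain (mutually exclusive with `tau`).
#' @param tau Fixed consolidated P-value threshold.
#' @return A tibble (`chrom`, `start`, `end`, `cons_p`) of retained peak
#'   clusters, sorted by position, with attributes `strategy`, `tau`, `C`.
#' @export
consolidate_peaks <- function(peak_sets, strategy, C = NULL, tau = NULL) {
  stopifnot(strategy %in% 1:7)
  if (!is.null(C) && C <= 0) stop("C must be positive", call. = FALSE)
  if (is.null(C) && is.null(tau)) stop("supply C or tau", call. = FALSE)
  n_units <- length(peak_sets)
  expected <- switch(as.character(strategy),
    "4" = 2L, "5" = 2L, "6" = 2L, "7" = 1L, NA_integer_
  )
  if (!is.na(expected) && n_units != expected) {
    stop(sprintf("strategy %d expects %d peak set(s)", strategy, expected),
      call. = FALSE
    )
  }
  names(peak_sets) <- as.character(seq_along(peak_sets))
  all <- dplyr::bind_rows(peak_sets, .id = "unit")
  if (nrow(all) == 0) {
    out <- tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      cons_p = numeric()
    )
    attr(out, "strategy") <- strategy
    attr(out, "tau") <- NA_real_
    attr(out, "C") <- C
    return(out)
  }
  cl <- cluster_intervals(all)
  n_cl <- max(cl)
  ## per-cluster pi for each unit (min over that unit's member peaks), 1 if absent
  pi_mat <- matrix(1, n_cl, n_units)
  u <- as.integer(all$unit)
  ord <- order(u, cl, all$pvalue)
  first <- !duplicated(cbind(u[ord], cl[ord]))
  pi_mat[cbind(cl[ord][first], u[ord][first])] <- all$pvalue[ord][first]

  cons <- switch(as.character(strategy),
    "1" = , "4" = , "6" = do.call(pmin, asplit(pi_mat, 2)),
    "2" = , "5" = do.call(pmax, asplit(pi_mat, 2)),
    "3" = apply(pi_mat, 1, function(v) sort(v, partial = 2)[2]),
    "7" = pi_mat[, 1]
  )
  span <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(
      cl = cl, chrom = all$chrom, start = all$start, end = all$end
    ), .data$cl),
    chrom = .data$chrom[1], start = min(.data$start), end = max(.data$end),
    .groups = "drop"
  )
  out <- tibble::tibble(
    chrom = span$chrom, start = span$start, end = span$end,
    cons_p = cons[span$cl]
  )
  if (!is.null(C)) {
    keep <- order(out$cons_p, out$start)[seq_len(min(C, nrow(out)))]
    tau <- out$cons_p[keep[length(keep)]]
    out <- out[sort(keep), , drop = FALSE]
  } else {
    out <- out[out$cons_p <= tau, , drop = FALSE]
  }
  out <- dplyr::arrange(out, .data$start)
  attr(out, "strategy") <- strategy
  attr(out, "tau") <- tau
  attr(out, "C") <- C
  out
}

#' Map empirical peaks onto overlapping true peaks
#'
#' Returns the rows of `truth` overlapped by at least one peak, the re-mapping
#' used before counting so that every method is evaluated over the same
#' (true) intervals.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`).
#' @param truth Truth tibble from [build_truth()].
#' @return Subset of `truth` rows, in genomic order.
#' @export
overlap_true_peaks <- function(peaks, truth) {
  if (nrow(peaks) == 0) return(truth[0, , drop = FALSE])
  hits <- overlap_join(peaks, truth)
  truth[sort(unique(hits$subject)), , drop = FALSE]
}

#' Pool read libraries
#'
#' @param read_libs List of read tibbles.
#' @return A single read tibble containing all reads.
#' @export
pool_reads <- function(read_libs) {
  dplyr::bind_rows(read_libs)
}
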