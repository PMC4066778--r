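#' Simulation study of type I error for the seven peak-calling strategies
#'
#' Repeats the null transcription-factor simulation (all peaks non-DB) and
#' measures, for each consolidation strategy, the proportion of DB-test
#' P-values falling below each nominal threshold. Per iteration: simulate;
#' call peaks per strategy's units; consolidate to the `C` best; map the
#' retained empirical peaks onto overlapping true peaks; count 5' ends over
#' the true intervals; filter totals below 20; run the QL F-test. The
#' reference analysis (`"RA"`) applies the counting and test to `C`
#' uniformly sampled true peaks, bypassing peak calling. All strategies
#' share each iteration's simulated data, so between-strategy contrasts are
#' paired.
#'
#' @param strategies Subset of `c("RA", 1:7)`.
#' @param n_peaks Number of true peaks `N`.
#' @param x0 NB mean per library.
#' @param C Number of peaks retained per strategy (and RA sample size).
#' @param n_iter Simulation iterations.
#' @param thresholds Nominal error thresholds to evaluate.
#' @param seed Base seed; iteration `i` uses `seed + i`.
#' @param f Fragment length.
#' @param n_reps Replicates per group.
#' @param dispersion_df Dispersion degrees of freedom.
#' @return An `experiment_report` tibble: `strategy`, `threshold`, `mean`,
#'   `se`, `n_iter`.
#' @export
run_type1 <- function(strategies = c("RA", 1:7), n_peaks = 50000, x0 = 20,
                      C = 10000, n_iter = 10,
                      thresholds = c(0.01, 0.05, 0.1), seed = 1, f = 100,
                      n_reps = 2, dispersion_df = 20) {
  strategies <- as.character(strategies)
  stopifnot(all(strategies %in% c("RA", as.character(1:7))))
  numeric_strat <- as.integer(strategies[strategies != "RA"])
  rows <- list()
  for (it in seq_len(n_iter)) {
    cfg <- sim_config(
      N = n_peaks, x0 = x0, mode = "TF", f = f, n_reps = n_reps,
      dispersion_df = dispersion_df, seed = seed + it
    )
    if (length(numeric_strat) == 0) {
      ## counts-only fast path: true-interval counts equal the NB draws
      set.seed(cfg$seed)
      truth <- build_truth(cfg)
      counts <- simulate_counts(truth, n_reps)
      lib_sizes <- colSums(count_matrix(counts))
      sim <- list(truth = truth, counts = counts, lib_sizes = lib_sizes)
    } else {
      ds <- simulate_dataset(cfg)
      sim <- list(
        truth = ds$truth, counts = ds$counts, reads = ds$reads,
        design = ds$design, lib_sizes = effective_sizes(ds$design),
        genome_length = ds$genome_length
      )
    }
    labels <- names(sim$counts)[-(1:3)]
    design <- tibble::tibble(label = labels, group = substr(labels, 1, 1))

    calls <- type1_peak_calls(sim, numeric_strat, f)
    for (s in strategies) {
      if (s == "RA") {
        idx <- sort(sample(n_peaks, min(C, n_peaks)))
        sel <- sim$counts[idx, , drop = FALSE]
      } else {
        cons <- consolidate_peaks(calls$sets[[s]], as.integer(s), C = C)
        hit <- overlap_true_peaks(cons, sim$truth)
        sel <- count_5prime(sim$reads, hit[, c("chrom", "start", "end")])
      }
      sel <- filter_features(sel, min_total = 20)
      res <- ql_ftest(sel, design, lib_sizes = sim$lib_sizes)
      for (th in thresholds) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          strategy = s, threshold = th, iter = it,
          value = mean(res$pvalue < th)
        )
      }
    }
  }
  report(dplyr::bind_rows(rows), c("strategy", "threshold"), "type1")
}

## Peak calls for the units each requested strategy needs.
type1_peak_calls <- function(sim, strategies, f) {
  sets <- list()
  if (length(strategies) == 0) return(list(sets = sets))
  L <- sim$genome_length
  groups <- substr(names(sim$reads), 1, 1)
  need_lib <- any(strategies %in% 1:3)
  need_grp <- any(strategies %in% 4:6)
  per_lib <- if (need_lib) lapply(sim$reads, call_peaks, genome_length = L, f = f)
  pooled_grp <- if (need_grp) {
    lapply(split(sim$reads, groups), function(ls) pool_reads(ls))
  }
  grp_calls <- if (any(strategies %in% 4:5)) {
    lapply(pooled_grp, call_peaks, genome_length = L, f = f)
  }
  two_sample <- if (6 %in% strategies) {
    list(
      call_peaks(pooled_grp[[1]], L, f = f, control = pooled_grp[[2]]),
      call_peaks(pooled_grp[[2]], L, f = f, control = pooled_grp[[1]])
    )
  }
  pooled_all <- if (7 %in% strategies) {
    list(call_peaks(pool_reads(sim$reads), L, f = f))
  }
  for (s in strategies) {
    sets[[as.character(s)]] <- switch(as.character(s),
      "1" = , "2" = , "3" = per_lib,
      "4" = , "5" = grp_calls,
      "6" = two_sample,
      "7" = pooled_all
    )
  }
  list(sets = sets)
}

#' Simulation study of window- versus region-level FDR control
#'
#' Simulates data with balanced DB spike-ins and compares, at each window
#' spacing, the sliding-window method (BH across windows; detected windows
#' interpreted both window-wise and region-wise) with the hybrid approach
#' (Simes over windows clustered by pooled-library peaks, BH across
#' clusters). Reported metrics: `window_fdr` (proportion of detected
#' windows outside DB true-peak regions), `region_fdr` (proportion of
#' detected true peaks that are non-DB, plus detections overlapping no true
#' peak).
#'
#' @param modes `"TF"`, `"histone"` or both.
#' @param spacings Window spacings (bp) to evaluate.
#' @param n_peaks,n_db,x0,x1,x2 Simulation intensities (`n_db` per
#'   direction).
#' @param fdr Nominal FDR threshold.
#' @param n_iter Iterations.
#' @param seed Base seed; iteration `i` uses `seed + i`.
#' @param f Fragment length.
#' @param call_threshold Peak-calling P-value cutoff for the pooled-library
#'   peaks that define hybrid clusters.
#' @return An `experiment_report` tibble: `mode`, `spacing`, `method`,
#'   `metric`, `mean`, `se`, `n_iter`.
#' @export
run_fdr <- function(modes = c("TF", "histone"), spacings = c(25, 50, 100),
                    n_peaks = 20000, n_db = 1500, x0 = 50, x1 = 90, x2 = 10,
                    fdr = 0.05, n_iter = 10, seed = 1, f = 100,
                    call_threshold = 1e-5) {
  rows <- list()
  for (mode in modes) {
    width <- if (mode == "TF") 1 else 150
    for (it in seq_len(n_iter)) {
      cfg <- sim_config(
        N = n_peaks, x0 = x0, N_db = n_db, x1 = x1, x2 = x2, mode = mode,
        f = f, seed = seed + it
      )
      sim <- simulate_dataset(cfg)
      peaks <- call_peaks(pool_reads(sim$reads), sim$genome_length,
        f = f, max_pvalue = call_threshold
      )
      for (sp in spacings) {
        cm <- count_windows(sim$reads, sim$genome_length,
          width = width, spacing = sp, f = f
        )
        cm <- filter_features(cm, min_total = 20)
        res <- ql_ftest(cm, sim$design,
          lib_sizes = effective_sizes(sim$design), ql = "classic"
        )
        det_w <- res[bh_adjust(res$pvalue) <= fdr, , drop = FALSE]
        hyb <- hybrid_regions(res, peaks)
        det_h <- hyb[hyb$qvalue <= fdr, , drop = FALSE]
        add <- tibble::tibble(
          mode = mode, spacing = sp, iter = it,
          method = c("sliding", "sliding", "hybrid"),
          metric = c("window_fdr", "region_fdr", "region_fdr"),
          value = c(
            observed_fdr_window(det_w, sim$truth),
            observed_fdr_region(det_w, sim$truth),
            observed_fdr_region(det_h, sim$truth)
          )
        )
        rows[[length(rows) + 1L]] <- add
      }
    }
  }
  report(dplyr::bind_rows(rows), c("mode", "spacing", "method", "metric"), "fdr")
}

#' Simulation study of relative detection power with background reads
#'
#' Simulates weaker peaks on top of negative-binomial background blocks and
#' compares the pure peak-based method (count 5' ends over empirical
#' pooled-library peak intervals, QL test, BH across peaks) against the
#' hybrid approach, at a common FDR threshold. Reports each method's
#' observed region-level FDR and its power (number of DB true peaks
#' overlapped by a detection).
#'
#' @param modes `"TF"`, `"histone"` or both; intensities default per mode
#'   (`x0 = 15, 25/5` for TF, `x0 = 30, 50/10` for histone).
#' @param n_peaks,n_db Peak counts (`n_db` per direction).
#' @param spacing Window spacing for the hybrid window grid.
#' @param fdr Nominal FDR threshold.
#' @param n_iter Iterations.
#' @param seed Base seed.
#' @param f Fragment length.
#' @param call_threshold Peak-calling P-value cutoff.
#' @return An `experiment_report` tibble: `mode`, `method`, `metric`,
#'   `mean`, `se`, `n_iter`.
#' @export
run_performance <- function(modes = c("TF", "histone"), n_peaks = 20000,
                            n_db = 500, spacing = 50, fdr = 0.05,
                            n_iter = 10, seed = 1, f = 100,
                            call_threshold = 1e-5) {
  rows <- list()
  for (mode in modes) {
    width <- if (mode == "TF") 1 else 150
    xs <- if (mode == "TF") c(15, 25, 5) else c(30, 50, 10)
    for (it in seq_len(n_iter)) {
      cfg <- sim_config(
        N = n_peaks, x0 = xs[1], N_db = n_db, x1 = xs[2], x2 = xs[3],
        mode = mode, f = f, background = TRUE, seed = seed + it
      )
      sim <- simulate_dataset(cfg)
      eff <- effective_sizes(sim$design)
      peaks <- call_peaks(pool_reads(sim$reads), sim$genome_length,
        f = f, max_pvalue = call_threshold
      )

      ## peak-based: test counts over the empirical peak intervals
      pk_counts <- count_5prime(sim$reads, peaks[, c("chrom", "start", "end")])
      pk_counts <- filter_features(pk_counts, min_total = 20)
      pk_res <- ql_ftest(pk_counts, sim$design, lib_sizes = eff, ql = "classic")
      det_p <- pk_res[bh_adjust(pk_res$pvalue) <= fdr, , drop = FALSE]

      ## hybrid: window-level test, Simes within peak clusters
      cm <- count_windows(sim$reads, sim$genome_length,
        width = width, spacing = spacing, f = f
      )
      cm <- filter_features(cm, min_total = 20)
      res <- ql_ftest(cm, sim$design, lib_sizes = eff, ql = "classic")
      hyb <- hybrid_regions(res, peaks)
      det_h <- hyb[hyb$qvalue <= fdr, , drop = FALSE]

      rows[[length(rows) + 1L]] <- tibble::tibble(
        mode = mode, iter = it,
        method = rep(c("peak", "hybrid"), each = 2),
        metric = rep(c("region_fdr", "power"), 2),
        value = c(
          observed_fdr_region(det_p, sim$truth),
          power_count(det_p, sim$truth),
          observed_fdr_region(det_h, sim$truth),
          power_count(det_h, sim$truth)
        )
      )
    }
  }
  report(dplyr::bind_rows(rows), c("mode", "method", "metric"), "performance")
}

## Aggregate per-iteration values into mean +/- SE rows.
report <- function(values, by, experiment) {
  out <- dplyr::summarise(
    dplyr::group_by(values, dplyr::across(dplyr::all_of(by))),
    mean = mean(.data$value),
    se = stats::sd(.data$value) / sqrt(dplyr::n()),
    n_iter = dplyr::n(),
    .groups = "drop"
  )
  attr(out, "experiment") <- experiment
  attr(out, "iterations") <- values
  class(out) <- c("experiment_report", class(out))
  out
}
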