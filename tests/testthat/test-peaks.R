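test_that("a strong isolated peak is called once, containing its centre", {
  set.seed(31)
  L <- 200000
  centre <- 100000
  peak <- place_reads(80, centre, mode = "TF", f = 100)
  bg <- random_reads(200, L) # sparse background, 0.001 reads/bp
  pk <- call_peaks(dplyr::bind_rows(peak, bg), L)
  expect_equal(nrow(pk), 1)
  expect_true(pk$start < centre && pk$end > centre)
  expect_true(pk$summit > centre - 100 && pk$summit < centre + 100)
  expect_lt(pk$pvalue, 1e-10)
  # empty library
  expect_equal(nrow(call_peaks(peak[0, ], L)), 0)
})

test_that("window-level null P-values are stochastically >= uniform", {
  set.seed(32)
  L <- 1e6
  reads <- random_reads(4000, L) # homogeneous Poisson background
  sw <- dbregions:::scan_windows(reads, NULL, L, 100, 25, 200, 10000)
  # upper-tail Poisson P-values are discrete and conservative: the observed
  # exceedance of any threshold must not exceed the threshold itself
  for (thr in c(0.01, 0.05, 0.1)) {
    expect_lte(mean(sw$p <= thr), thr + 3 * sqrt(thr * (1 - thr) / length(sw$p)))
  }
  # ... and no peaks survive the caller's output cutoff
  expect_equal(nrow(call_peaks(reads, L)), 0)
})

test_that("two-sample calling is calibrated when treatment equals control", {
  set.seed(33)
  L <- 500000
  peaks <- place_reads(rep(60, 10), (1:10) * 40000, mode = "TF", f = 100)
  lib <- dplyr::bind_rows(peaks, random_reads(500, L))
  # identical treatment and control: matching enrichment must be masked
  expect_equal(nrow(call_peaks(lib, L, control = lib)), 0)
  # a genuinely differential locus is still found
  extra <- place_reads(120, 250000, mode = "TF", f = 100)
  treated <- dplyr::bind_rows(lib, extra)
  pk <- call_peaks(treated, L, control = lib)
  expect_equal(nrow(pk), 1)
  expect_true(pk$start < 250000 && pk$end > 250000)
  expect_error(call_peaks(lib, L, control = lib[0, ]), "control")
})

test_that("consolidation implements min / max / second-smallest with absences", {
  iv <- function(p) tibble::tibble(
    chrom = "c", start = 1000L, end = 1400L, summit = 1200L, pvalue = p
  )
  sets3 <- list(iv(0.2), iv(0.5), iv(1.0))
  expect_equal(consolidate_peaks(sets3, 1, C = 5)$cons_p, 0.2)
  expect_equal(consolidate_peaks(sets3, 2, C = 5)$cons_p, 1.0)
  expect_equal(consolidate_peaks(sets3, 3, C = 5)$cons_p, 0.5)
  # an absent call contributes pi = 1
  sets_abs <- list(iv(0.2), iv(0.5), iv(0.5)[0, ])
  expect_equal(consolidate_peaks(sets_abs, 2, C = 5)$cons_p, 1.0)
  expect_equal(consolidate_peaks(sets_abs, 3, C = 5)$cons_p, 0.5)
  # group strategies take two sets; strategy 7 takes one
  expect_equal(consolidate_peaks(list(iv(0.3), iv(0.6)), 5, C = 5)$cons_p, 0.6)
  expect_equal(consolidate_peaks(list(iv(0.3), iv(0.6)), 6, C = 5)$cons_p, 0.3)
  expect_equal(consolidate_peaks(list(iv(0.42)), 7, C = 5)$cons_p, 0.42)
  expect_error(consolidate_peaks(list(iv(0.3)), 4, C = 5), "expects 2")
  expect_error(consolidate_peaks(sets3, 1, C = 0), "positive")
})

test_that("tau retains exactly the C best consolidated peaks", {
  set.seed(34)
  n <- 120
  one <- tibble::tibble(
    chrom = "c", start = (1:n) * 1000L, end = (1:n) * 1000L + 300L,
    summit = (1:n) * 1000L + 150L, pvalue = runif(n)
  )
  cons <- consolidate_peaks(list(one), 7, C = 100)
  expect_equal(nrow(cons), 100)
  expect_equal(attr(cons, "tau"), sort(one$pvalue)[100])
  expect_true(all(cons$cons_p <= attr(cons, "tau")))
  # fewer candidates than C: all retained
  all_kept <- consolidate_peaks(list(one), 7, C = 500)
  expect_equal(nrow(all_kept), n)
})

test_that("intersection-based consolidations are nested within union-based", {
  set.seed(35)
  sets <- lapply(1:4, function(i) {
    keep <- sort(sample(50, 35))
    tibble::tibble(
      chrom = "c", start = keep * 1000L, end = keep * 1000L + 400L,
      summit = keep * 1000L + 200L, pvalue = 10^-runif(length(keep), 1, 12)
    )
  })
  tau <- 1e-4
  key <- function(x) paste(x$start, x$end)
  s1 <- consolidate_peaks(sets, 1, tau = tau)
  s2 <- consolidate_peaks(sets, 2, tau = tau)
  s3 <- consolidate_peaks(sets, 3, tau = tau)
  expect_true(all(key(s2) %in% key(s3)))
  expect_true(all(key(s3) %in% key(s1)))
})

test_that("empirical peaks re-map onto the true peaks they overlap", {
  truth <- tibble::tibble(
    chrom = "chrSim", start = c(1000L, 5000L, 9000L),
    end = c(1201L, 5201L, 9201L), is_db = FALSE
  )
  pk <- tibble::tibble(chrom = "chrSim", start = c(900L, 5100L), end = c(1100L, 5300L))
  hit <- overlap_true_peaks(pk, truth)
  expect_equal(hit$start, c(1000L, 5000L))
  expect_equal(nrow(overlap_true_peaks(pk[0, ], truth)), 0)
})
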