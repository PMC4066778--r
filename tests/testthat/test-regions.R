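test_that("Simes combination matches its definition and brute force", {
  expect_equal(simes_p(0.04), 0.04)
  expect_equal(simes_p(c(0.01, 0.04, 0.90)), 0.03)
  expect_equal(simes_p(c(1, 1)), 1)
  expect_error(simes_p(numeric(0)), "empty")
  set.seed(61)
  for (i in 1:50) {
    p <- runif(sample(1:12, 1))
    expect_equal(simes_p(p), brute_simes(p))
    expect_equal(simes_p(p), simes_p(sample(p))) # permutation invariant
    expect_lte(simes_p(p), length(p) * min(p))
    expect_gte(simes_p(p), min(p))
    # Simes equals the smallest BH-adjusted value
    expect_equal(simes_p(p), min(stats::p.adjust(p, "BH")))
  }
})

test_that("BH adjustment matches the brute-force threshold scan", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.7), 0.7)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(62)
  for (i in 1:30) {
    p <- runif(sample(1:12, 1))
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("window merging respects gap and direction rules", {
  win <- function(start, logFC, pvalue) tibble::tibble(
    chrom = "c", start = start, end = start + 10L, logFC = logFC,
    pvalue = pvalue
  )
  # two significant windows 50 bp apart, same sign: one region
  res <- dplyr::bind_rows(win(0L, 1, 1e-6), win(60L, 2, 1e-6))
  m <- merge_db_windows(res, fdr = 0.05, max_gap = 100)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 0L)
  expect_equal(m$end, 70L)
  expect_equal(m$n_windows, 2L)
  # opposite signs: two regions
  res2 <- dplyr::bind_rows(win(0L, 1, 1e-6), win(60L, -2, 1e-6))
  expect_equal(nrow(merge_db_windows(res2)), 2)
  # gap exactly max_gap: kept apart (strict inequality)
  res3 <- dplyr::bind_rows(win(0L, 1, 1e-6), win(110L, 1, 1e-6))
  expect_equal(nrow(merge_db_windows(res3, max_gap = 100)), 2)
  res4 <- dplyr::bind_rows(win(0L, 1, 1e-6), win(109L, 1, 1e-6))
  expect_equal(nrow(merge_db_windows(res4, max_gap = 100)), 1)
  # windows failing the window-level FDR never enter regions
  res5 <- dplyr::bind_rows(win(0L, 1, 1e-6), win(500L, 1, 0.9))
  expect_equal(nrow(merge_db_windows(res5)), 1)
})

test_that("hybrid clusters combine member windows with Simes and BH", {
  peaks <- tibble::tibble(
    chrom = "c", start = c(100L, 1000L), end = c(300L, 1200L)
  )
  win <- function(start, p) tibble::tibble(
    chrom = "c", start = start, end = start + 10L, logFC = 1, pvalue = p
  )
  res <- dplyr::bind_rows(
    win(150L, 0.01), win(200L, 0.04), win(250L, 0.90), # peak 1
    win(1100L, 0.20), # peak 2
    win(5000L, 1e-8) # overlaps no peak: ignored
  )
  hyb <- hybrid_regions(res, peaks)
  expect_equal(nrow(hyb), 2)
  expect_equal(hyb$combined_p, c(0.03, 0.20))
  expect_equal(hyb$qvalue, bh_adjust(c(0.03, 0.20)))
  expect_equal(hyb$n_windows, c(3L, 1L))
  # a window overlapping two peaks contributes to both clusters
  touching <- tibble::tibble(
    chrom = "c", start = c(0L, 150L), end = c(200L, 400L)
  )
  hyb2 <- hybrid_regions(win(160L, 0.02), touching)
  expect_equal(nrow(hyb2), 2)
  expect_equal(hyb2$combined_p, c(0.02, 0.02))
  # peaks with no tested window are omitted
  hyb3 <- hybrid_regions(win(150L, 0.5), peaks)
  expect_equal(nrow(hyb3), 1)
})

test_that("observed FDR metrics implement the worked definitions", {
  truth <- tibble::tibble(
    chrom = "c", start = c(0L, 1000L, 2000L), end = c(100L, 1100L, 2100L),
    is_db = c(TRUE, FALSE, FALSE)
  )
  iv <- function(start, end) tibble::tibble(chrom = "c", start = start, end = end)
  # 18 windows in the DB region + 2 outside: window FDR 0.10
  det <- dplyr::bind_rows(
    iv(seq(0L, 85L, by = 5L), seq(5L, 90L, by = 5L)),
    iv(c(1000L, 1010L), c(1005L, 1015L))
  )
  expect_equal(observed_fdr_window(det, truth), 0.10)
  # but only 2 regions were hit and one is a false positive: region FDR 0.5
  expect_equal(observed_fdr_region(det, truth), 0.5)
  # nothing detected: both conventions give 0
  expect_equal(observed_fdr_window(det[0, ], truth), 0)
  expect_equal(observed_fdr_region(det[0, ], truth), 0)
  # detections overlapping no true peak count as false positives
  bgdet <- iv(5000L, 5100L)
  expect_equal(observed_fdr_region(bgdet, truth), 1)
  expect_equal(
    observed_fdr_region(dplyr::bind_rows(iv(0L, 50L), bgdet), truth), 0.5
  )
})

test_that("power counts DB true peaks overlapped by detections", {
  truth <- tibble::tibble(
    chrom = "c", start = c(0L, 1000L, 2000L), end = c(100L, 1100L, 2100L),
    is_db = c(TRUE, TRUE, FALSE)
  )
  iv <- function(start, end) tibble::tibble(chrom = "c", start = start, end = end)
  expect_equal(power_count(iv(integer(0), integer(0)), truth), 0L)
  # one wide region overlapping both DB truths counts each of them
  expect_equal(power_count(iv(50L, 1050L), truth), 2L)
  expect_equal(power_count(iv(2050L, 2060L), truth), 0L)
})
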