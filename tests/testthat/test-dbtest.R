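test_that("average log2 CPM stays finite and shifts with library size", {
  cm <- tibble::tibble(
    chrom = "c", start = 0L, end = 10L, a = 0L, b = 0L
  )
  expect_true(is.finite(ave_log_cpm(cm, lib_sizes = c(1e6, 1e6))))
  cm2 <- tibble::tibble(chrom = "c", start = 0L, end = 10L, a = 10L, b = 10L)
  lo <- ave_log_cpm(cm2, lib_sizes = c(1e6, 1e6))
  hi <- ave_log_cpm(cm2, lib_sizes = c(2e6, 2e6))
  expect_equal(lo - hi, 1, tolerance = 0.05)
})

test_that("closed-form two-group NB fit matches edgeR's GLM fit", {
  set.seed(51)
  group <- c("A", "A", "B", "B")
  # equal effective sizes within each group: the closed form is the MLE
  eff <- c(2e6, 2e6, 1.5e6, 1.5e6)
  for (i in 1:20) {
    y <- rnbinom(4, mu = runif(1, 5, 50), size = 10)
    phi <- runif(1, 0.01, 0.3)
    mine <- fit_nb_glm(y, group, eff, phi)
    ref <- edgeR::glmFit(
      matrix(y, 1),
      design = stats::model.matrix(~ factor(group)),
      dispersion = phi, lib.size = eff, prior.count = 0
    )
    expect_equal(mine$deviance, as.numeric(ref$deviance), tolerance = 1e-6)
    expect_equal(mine$fitted, as.numeric(ref$fitted.values), tolerance = 1e-6)
  }
  # Poisson limit: closed form is exact for any offsets
  effu <- c(1e6, 2e6, 1e6, 1.5e6)
  y <- c(12L, 30L, 7L, 9L)
  mine0 <- fit_nb_glm(y, group, effu, 0)
  ref0 <- edgeR::glmFit(
    matrix(y, 1),
    design = stats::model.matrix(~ factor(group)),
    dispersion = 1e-12, lib.size = effu, prior.count = 0
  )
  expect_equal(mine0$fitted, as.numeric(ref0$fitted.values), tolerance = 1e-4)

  # perfect fit: zero deviance; offset-weighted rates
  fit <- fit_nb_glm(c(10L, 10L, 10L, 10L), group, rep(1e6, 4), 0.1)
  expect_equal(fit$deviance, 0)
  expect_equal(fit$df_residual, 2)
  fit2 <- fit_nb_glm(c(10L, 20L, 5L, 5L), c("A", "A", "B", "B"),
    c(1e6, 2e6, 1e6, 1e6), 0.05
  )
  expect_equal(unname(fit2$rates["A"]), 1e-5)
})

test_that("dispersion trend recovers constant truth and clamps outside range", {
  set.seed(52)
  N <- 5000
  phi <- sample_dispersion(N, 20)
  mu <- exp(runif(N, log(10), log(200)))
  m <- matrix(rnbinom(N * 4, mu = rep(mu, 4), size = 1 / rep(phi, 4)), nrow = N)
  cm <- tibble::tibble(
    chrom = "c", start = (seq_len(N) - 1L) * 10L, end = seq_len(N) * 10L
  )
  cm[c("A1", "A2", "B1", "B2")] <- as.data.frame(m)
  tr <- estimate_trend(cm, toy_design(), lib_sizes = colSums(m))
  expect_true(all(tr$table$dispersion > 0.03 & tr$table$dispersion < 0.09))
  # clamped evaluation beyond the fitted abundance range
  rng <- range(tr$table$ave_log_cpm)
  expect_equal(tr$interpolate(rng[2] + 10), tr$interpolate(rng[2]))
  expect_equal(tr$interpolate(rng[1] - 10), tr$interpolate(rng[1]))

  # near-Poisson data yield a near-zero trend
  m0 <- matrix(rpois(2000 * 4, 50), nrow = 2000)
  cm0 <- tibble::tibble(
    chrom = "c", start = (seq_len(2000) - 1L) * 10L, end = seq_len(2000) * 10L
  )
  cm0[c("A1", "A2", "B1", "B2")] <- as.data.frame(m0)
  tr0 <- estimate_trend(cm0, toy_design(), lib_sizes = colSums(m0))
  expect_true(all(tr0$table$dispersion < 0.01))
})

test_that("QL F-test handles degenerate, strong and permuted inputs", {
  set.seed(53)
  N <- 500
  m <- matrix(rnbinom(N * 4, mu = 30, size = 18), nrow = N)
  m[1, ] <- c(25L, 25L, 25L, 25L) # identical counts: no evidence at all
  m[2, ] <- c(60L, 55L, 5L, 4L) # strong DB
  cm <- tibble::tibble(
    chrom = "c", start = (seq_len(N) - 1L) * 1000L, end = seq_len(N) * 1000L
  )
  cm[c("A1", "A2", "B1", "B2")] <- as.data.frame(m)
  # equal effective sizes so that identical counts mean identical rates
  eq <- rep(round(mean(colSums(m))), 4)
  res <- quiet(ql_ftest(cm, toy_design(), lib_sizes = eq))
  expect_equal(res$F[1], 0, tolerance = 1e-8)
  expect_equal(res$pvalue[1], 1)
  expect_lt(res$pvalue[2], 1e-3)
  expect_true(all(res$pvalue > 0 & res$pvalue <= 1))

  # exchangeability: permuting libraries together with the design changes nothing
  perm <- c(2, 4, 1, 3)
  cmp <- cm
  cmp[c("A1", "A2", "B1", "B2")] <- as.data.frame(m[, perm])
  dperm <- toy_design()
  dperm$group <- c("A", "A", "B", "B")[perm] # library k carries old perm[k]'s group
  resp <- quiet(ql_ftest(cmp, dperm, lib_sizes = eq[1] + numeric(4)))
  expect_equal(resp$pvalue, res$pvalue, tolerance = 1e-10)
  expect_equal(resp$F, res$F, tolerance = 1e-8)
})

test_that("monotonicity: widening the group difference cannot raise the P-value", {
  set.seed(54)
  N <- 400
  m <- matrix(rnbinom(N * 4, mu = 40, size = 18), nrow = N)
  build <- function(delta) {
    mm <- m
    mm[1, ] <- as.integer(c(40 + delta, 40 + delta, 40 - delta, 40 - delta))
    cm <- tibble::tibble(
      chrom = "c", start = (seq_len(N) - 1L) * 1000L, end = seq_len(N) * 1000L
    )
    cm[c("A1", "A2", "B1", "B2")] <- as.data.frame(mm)
    quiet(ql_ftest(cm, toy_design(), lib_sizes = colSums(m)))$pvalue[1]
  }
  ps <- vapply(c(0, 5, 10, 20, 30), build, 0)
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("db_test returns a tidy-able fit with sensible summaries", {
  sim <- simulate_dataset(
    sim_config(N = 300, x0 = 30, N_db = 30, x1 = 50, x2 = 10, seed = 55)
  )
  fit <- quiet(db_test(sim$counts, sim$design))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("chrom", "start", "end", "logFC", "F", "pvalue") %in% names(td)))
  expect_equal(nrow(td), 300)
  gl <- glance(fit)
  expect_equal(gl$n_features, 300)
  expect_gt(gl$n_significant, 20) # most of the 60 DB peaks are strong
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
  p2 <- plot_dispersion_trend(fit)
  expect_s3_class(p2, "ggplot")
})
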