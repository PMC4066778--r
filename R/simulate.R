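#' Simulation configuration for a two-group ChIP-seq experiment
#'
#' Describes a replicated two-group experiment on an artificial single
#' chromosome. `N` true peaks are laid out at least `peak_spacing` apart;
#' per-peak fragment counts are negative-binomial with inverse-chi-squared
#' dispersions, and `N_db` peaks per direction receive balanced differential
#' binding (means `x1`/`x2` with `x1 + x2 = 2 * x0`, so average abundance is
#' independent of DB status).
#'
#' @param N Number of true peaks.
#' @param x0 NB mean (fragments per library) for non-DB peaks.
#' @param N_db Number of DB peaks *per direction*; `2 * N_db` peaks are DB
#'   in total, the same number enriched in each group.
#' @param x1,x2 NB means for the two groups at a DB peak; required when
#'   `N_db > 0` and constrained to `x1 + x2 == 2 * x0`.
#' @param mode `"TF"` (sharp, strand-bimodal placement over +/- `f` bp) or
#'   `"histone"` (diffuse, strand-independent placement over `hist_width` bp).
#' @param f Average fragment length in bp.
#' @param hist_width Width of histone-mark enrichment in bp.
#' @param peak_spacing Minimum separation between successive peak centres (bp).
#' @param n_reps Biological replicates per group.
#' @param dispersion_df Degrees of freedom of the inverse-chi-squared
#'   dispersion distribution (mean dispersion `1 / (df - 2)`).
#' @param background `NULL` for no non-specific enrichment, or a list with
#'   elements `block` (bp), `mu_low`, `mu_high` giving NB background blocks
#'   whose means are uniform on `[mu_low, mu_high]`. `background = TRUE`
#'   selects the default `list(block = 2000, mu_low = 10, mu_high = 50)`.
#' @param seed Optional RNG seed applied by [simulate_dataset()].
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' sim_config(N = 100, x0 = 20)
sim_config <- function(N, x0, N_db = 0, x1 = NULL, x2 = NULL,
                       mode = c("TF", "histone"), f = 100, hist_width = 1000,
                       peak_spacing = 10000, n_reps = 2, dispersion_df = 20,
                       background = NULL, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(N >= 1, x0 >= 0, N_db >= 0, 2 * N_db <= N, f >= 1, n_reps >= 1)
  if (dispersion_df <= 2) {
    stop("dispersion_df must exceed 2 (mean dispersion undefined otherwise)",
      call. = FALSE
    )
  }
  if (N_db > 0) {
    if (is.null(x1) || is.null(x2)) {
      stop("x1 and x2 are required when N_db > 0", call. = FALSE)
    }
    if (!isTRUE(all.equal(x1 + x2, 2 * x0))) {
      stop("x1 + x2 must equal 2 * x0 so abundance is independent of DB",
        call. = FALSE
      )
    }
  }
  if (isTRUE(background)) {
    background <- list(block = 2000, mu_low = 10, mu_high = 50)
  }
  if (!is.null(background)) {
    stopifnot(all(c("block", "mu_low", "mu_high") %in% names(background)))
  }
  structure(
    list(
      N = as.integer(N), N_db = as.integer(N_db), x0 = x0, x1 = x1, x2 = x2,
      mode = mode, f = as.integer(f), hist_width = as.integer(hist_width),
      peak_spacing = as.integer(peak_spacing), n_reps = as.integer(n_reps),
      dispersion_df = dispersion_df, background = background, seed = seed
    ),
    class = "sim_config"
  )
}

#' Sample NB dispersions from an inverse-chi-squared distribution
#'
#' Dispersions are the reciprocals of chi-squared variates, `1 / X` with
#' `X ~ chisq(df)`, giving `E[phi] = 1 / (df - 2)` (about 0.056 at the
#' default 20 df).
#'
#' @param n Number of draws.
#' @param df Degrees of freedom; must exceed 2.
#' @return Positive numeric vector of dispersions.
#' @export
sample_dispersion <- function(n, df = 20) {
  if (df <= 2) stop("df must exceed 2", call. = FALSE)
  1 / stats::rchisq(n, df = df)
}

#' Lay out the ground-truth peak set
#'
#' Peak centres sit at `c_i = i * peak_spacing` on a single chromosome of
#' length `(N + 2) * peak_spacing`. `N_db` randomly chosen peaks get group
#' means `(x1, x2)` and `N_db` further peaks get the swapped `(x2, x1)`,
#' so DB truth is exactly balanced between directions. The true region of a
#' TF peak spans `f` bp either side of the centre; a histone peak spans
#' `hist_width / 2` either side (end-inclusive, stored half-open).
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per peak: `peak`, `chrom`, `start`, `end`,
#'   `centre`, `mu1`, `mu2`, `phi`, `is_db`, plus a `genome_length`
#'   attribute.
#' @export
build_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  N <- config$N
  centre <- config$peak_spacing * seq_len(N)
  half <- if (config$mode == "TF") config$f else config$hist_width %/% 2L
  mu1 <- rep(config$x0, N)
  mu2 <- rep(config$x0, N)
  is_db <- rep(FALSE, N)
  if (config$N_db > 0) {
    db <- sample(N, 2L * config$N_db)
    up1 <- db[seq_len(config$N_db)]
    up2 <- db[config$N_db + seq_len(config$N_db)]
    mu1[up1] <- config$x1
    mu2[up1] <- config$x2
    mu1[up2] <- config$x2
    mu2[up2] <- config$x1
    is_db[db] <- TRUE
  }
  out <- tibble::tibble(
    peak = seq_len(N),
    chrom = "chrSim",
    start = as.integer(centre - half),
    end = as.integer(centre + half + 1L),
    centre = as.integer(centre),
    mu1 = mu1, mu2 = mu2,
    phi = sample_dispersion(N, config$dispersion_df),
    is_db = is_db
  )
  attr(out, "genome_length") <- as.integer((N + 2) * config$peak_spacing)
  out
}

#' Simulate per-peak NB fragment counts
#'
#' One independent NB draw per peak and library, with the peak's group mean
#' and a dispersion shared across all libraries of that peak.
#'
#' @param truth Truth tibble from [build_truth()].
#' @param n_reps Replicates per group.
#' @return A count tibble (`chrom`, `start`, `end`, then one column per
#'   library labelled `A1..An`, `B1..Bn`).
#' @export
simulate_counts <- function(truth, n_reps = 2) {
  N <- nrow(truth)
  out <- truth[, c("chrom", "start", "end")]
  for (g in c("A", "B")) {
    mu <- if (g == "A") truth$mu1 else truth$mu2
    for (r in seq_len(n_reps)) {
      out[[paste0(g, r)]] <- draw_nb(mu, truth$phi)
    }
  }
  out
}

## NB draw that tolerates phi = 0 (Poisson limit) and mu = 0.
draw_nb <- function(mu, phi) {
  n <- length(mu)
  phi <- rep_len(phi, n)
  y <- integer(n)
  pois <- phi <= 0
  if (any(pois)) y[pois] <- stats::rpois(sum(pois), mu[pois])
  if (any(!pois)) {
    y[!pois] <- stats::rnbinom(sum(!pois), mu = mu[!pois], size = 1 / phi[!pois])
  }
  y
}

## Split n reads evenly between strands; odd leftovers go to the forward
## strand with probability 1/2. Returns forward counts.
even_strand_split <- function(n) {
  n %/% 2L + stats::rbinom(length(n), 1L, 0.5) * (n %% 2L)
}

#' Place reads around peak centres
#'
#' TF mode: reads split evenly between strands; forward 5' ends fall at
#' `centre - f * X` and reverse 5' ends at `centre + f * X` with
#' `X ~ Beta(2, 2)`, reproducing strand bimodality. Histone mode: 5' ends
#' fall at `centre + width * (X - 1/2)` with a uniform, position-independent
#' strand. Continuous positions are rounded to the nearest base.
#'
#' @param n Read count per peak (vector, recycled against `centre`).
#' @param centre Peak centre positions (bp).
#' @param mode `"TF"` or `"histone"`.
#' @param f Fragment length (bp), TF mode.
#' @param width Enrichment width (bp), histone mode.
#' @param chrom Chromosome label.
#' @return A read tibble (`chrom`, `pos5`, `strand`).
#' @export
place_reads <- function(n, centre, mode = c("TF", "histone"), f = 100,
                        width = 1000, chrom = "chrSim") {
  mode <- match.arg(mode)
  n <- as.integer(rep_len(n, max(length(n), length(centre))))
  centre <- rep_len(as.numeric(centre), length(n))
  if (mode == "TF") {
    nf <- even_strand_split(n)
    nr <- n - nf
    fwd <- round(rep(centre, nf) - f * stats::rbeta(sum(nf), 2, 2))
    rev <- round(rep(centre, nr) + f * stats::rbeta(sum(nr), 2, 2))
    out <- tibble::tibble(
      chrom = chrom,
      pos5 = as.integer(c(fwd, rev)),
      strand = rep(c("+", "-"), c(sum(nf), sum(nr)))
    )
  } else {
    total <- sum(n)
    pos <- round(rep(centre, n) + width * (stats::rbeta(total, 2, 2) - 0.5))
    out <- tibble::tibble(
      chrom = chrom,
      pos5 = as.integer(pos),
      strand = sample(c("+", "-"), total, replace = TRUE)
    )
  }
  out
}

#' Simulate non-specific background reads
#'
#' The genome is partitioned into contiguous blocks; each block draws a mean
#' from `U(mu_low, mu_high)` and a dispersion from the inverse-chi-squared
#' distribution, both shared by all libraries so the background is never
#' differentially bound. Per-library block counts are NB; read positions are
#' uniform within the block with evenly split strands.
#'
#' @param genome_length Genome length in bp.
#' @param n_libraries Number of libraries to generate.
#' @param block Block size in bp.
#' @param mu_low,mu_high Range of per-block NB means.
#' @param dispersion_df Dispersion degrees of freedom.
#' @return A list of read tibbles, one per library.
#' @export
simulate_background <- function(genome_length, n_libraries, block = 2000,
                                mu_low = 10, mu_high = 50, dispersion_df = 20) {
  nblock <- as.integer(ceiling(genome_length / block))
  bstart <- (seq_len(nblock) - 1L) * as.integer(block)
  bend <- pmin(bstart + as.integer(block), as.integer(genome_length))
  mu <- stats::runif(nblock, mu_low, mu_high)
  phi <- sample_dispersion(nblock, dispersion_df)
  lapply(seq_len(n_libraries), function(j) {
    k <- draw_nb(mu, phi)
    nf <- even_strand_split(k)
    lo <- rep(bstart, k)
    hi <- rep(bend, k)
    pos <- as.integer(floor(stats::runif(sum(k), lo, hi)))
    strand <- unlist(lapply(seq_len(nblock), function(b) {
      rep(c("+", "-"), c(nf[b], k[b] - nf[b]))
    }), use.names = FALSE)
    tibble::tibble(chrom = "chrSim", pos5 = pos, strand = strand)
  })
}

#' Simulate a complete two-group ChIP-seq data set
#'
#' Runs the whole generator: truth layout, per-peak NB counts, read
#' placement per library (so each library's per-peak read totals equal the
#' count matrix exactly), optional background reads, and the experiment
#' design with unit normalization factors. Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_dataset` with elements `truth`, `counts`,
#'   `reads` (named list of read tibbles), `design` (tibble: `label`,
#'   `group`, `lib_size`, `norm_factor`), `genome_length` and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  truth <- build_truth(config)
  genome_length <- attr(truth, "genome_length")
  counts <- simulate_counts(truth, config$n_reps)
  labels <- names(counts)[-(1:3)]
  bg <- if (!is.null(config$background)) {
    simulate_background(
      genome_length, length(labels),
      block = config$background$block,
      mu_low = config$background$mu_low,
      mu_high = config$background$mu_high,
      dispersion_df = config$dispersion_df
    )
  }
  reads <- lapply(seq_along(labels), function(j) {
    r <- place_reads(
      counts[[labels[j]]], truth$centre,
      mode = config$mode, f = config$f, width = config$hist_width
    )
    if (!is.null(bg)) r <- dplyr::bind_rows(r, bg[[j]])
    r$pos5 <- pmin(pmax(r$pos5, 0L), as.integer(genome_length) - 1L)
    r
  })
  names(reads) <- labels
  design <- tibble::tibble(
    label = labels,
    group = substr(labels, 1, 1),
    lib_size = vapply(reads, nrow, 0L),
    norm_factor = 1
  )
  structure(
    list(
      truth = truth, counts = counts, reads = reads, design = design,
      genome_length = genome_length, config = config
    ),
    class = "sim_dataset"
  )
}
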