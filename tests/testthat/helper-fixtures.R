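## Small fixtures shared across test files; everything is generated in code.

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

## A tiny two-group design with unit normalization factors.
toy_design <- function(n_reps = 2, lib_size = 1e6) {
  labels <- paste0(rep(c("A", "B"), each = n_reps), seq_len(n_reps))
  tibble::tibble(
    label = labels, group = substr(labels, 1, 1),
    lib_size = lib_size, norm_factor = 1
  )
}

## Random read library on one chromosome.
random_reads <- function(n, genome_length, chrom = "chrT") {
  tibble::tibble(
    chrom = chrom,
    pos5 = sample.int(genome_length, n, replace = TRUE) - 1L,
    strand = sample(c("+", "-"), n, replace = TRUE)
  )
}

## Brute-force fragment-vs-window overlap counter (the oracle for
## count_windows): a plain double loop over extended fragments and windows.
brute_count_windows <- function(reads, genome_length, width, spacing, f) {
  frag <- extend_reads(reads, f)
  n_win <- (genome_length - 1) %/% spacing + 1
  out <- integer(n_win)
  for (j in seq_len(n_win)) {
    ws <- (j - 1) * spacing
    we <- min(ws + width, genome_length)
    for (i in seq_len(nrow(frag))) {
      if (max(frag$start[i], ws) < min(frag$end[i], we)) out[j] <- out[j] + 1L
    }
  }
  out
}

## Brute-force BH adjustment: for each p, the smallest FDR level at which a
## step-up scan over all thresholds would reject it.
brute_bh <- function(p) {
  m <- length(p)
  vapply(seq_along(p), function(i) {
    cand <- vapply(seq_len(m), function(k) {
      thr <- sort(p)[k]
      if (p[i] <= thr) m * thr / k else Inf
    }, 0)
    min(1, min(cand))
  }, 0)
}

## Brute-force Simes combination by direct evaluation of the definition.
brute_simes <- function(p) {
  n <- length(p)
  ps <- sort(p)
  min(1, min(vapply(seq_len(n), function(r) n * ps[r] / r, 0)))
}
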