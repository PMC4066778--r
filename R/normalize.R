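#' TMM scaling factors from large-bin counts, without precision weighting
#'
#' Estimates trimmed-mean-of-M-values scaling factors from counts in large
#' genomic bins (10 kbp by default elsewhere in the package). Large equal
#' bins give every genomic region equal representation, and precision
#' weighting is disabled so that all M-values contribute equally; the
#' trimming (30% of M-values in total, 5% of A-values) tolerates up to 30%
#' of bins being differentially bound in either single direction. Bins with
#' a zero count in either member of a pairwise comparison are dropped from
#' that comparison. The reference library is the one whose upper-quartile
#' scaled count is closest to the mean across libraries. Factors are
#' rescaled to have unit geometric mean. Computation is delegated to
#' [edgeR::calcNormFactors()] with `doWeighting = FALSE`.
#'
#' @param bin_counts Count tibble of bin counts (one column per library).
#' @param lib_sizes Raw library sizes; default column sums.
#' @return A tibble (`label`, `lib_size`, `norm_factor`) with attribute
#'   `reference` (index of the reference library).
#' @export
tmm_factors <- function(bin_counts, lib_sizes = NULL) {
  m <- count_matrix(bin_counts)
  stopifnot(ncol(m) >= 2)
  if (is.null(lib_sizes)) lib_sizes <- colSums(m)
  if (any(colSums(m) == 0)) stop("a library has all-zero bins", call. = FALSE)
  ## reference: library whose upper-quartile count/size is nearest the mean
  f75 <- apply(m, 2, function(x) stats::quantile(x, 0.75)) / lib_sizes
  ref <- which.min(abs(f75 - mean(f75)))
  fac <- edgeR::calcNormFactors(m,
    lib.size = lib_sizes, method = "TMM",
    refColumn = ref, doWeighting = FALSE
  )
  out <- tibble::tibble(
    label = colnames(m),
    lib_size = as.numeric(lib_sizes),
    norm_factor = as.numeric(fac)
  )
  attr(out, "reference") <- ref
  out
}

#' Effective library sizes
#'
#' The effective size of a library is the product of its raw size and its
#' normalization factor; all downstream testing uses effective sizes as
#' offsets. In simulations the factors are unity (the balanced DB design
#' introduces no composition bias) so effective and raw sizes coincide.
#'
#' @param design Design tibble with `lib_size` and `norm_factor` columns
#'   (e.g. from a `sim_dataset`, or [tmm_factors()] output).
#' @return Named numeric vector of effective sizes.
#' @export
effective_sizes <- function(design) {
  stopifnot(all(c("lib_size", "norm_factor") %in% names(design)))
  stopifnot(all(design$norm_factor > 0))
  out <- design$lib_size * design$norm_factor
  names(out) <- design$label
  out
}
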