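#' Downsample hypermutated spectra
#'
#' Proportionally reduces the counts of samples whose total mutation burden
#' exceeds `threshold`, leaving all other samples untouched. Each class count
#' c of a hypermutated sample becomes `floor(c * threshold / total + 0.5)`
#' (deterministic half-up rounding), so the resulting total lies within C/2
#' of the threshold (C = number of classes) and per-class proportions move by
#' at most 1/threshold.
#'
#' Downsampling markedly reduces false positives (and run time) for SBS-96
#' data; the benchmarked default threshold there is 3000. For ID-83 data
#' downsampling degrades accuracy and is off by default in [hdp_fit()].
#'
#' @param catalog A [mutation_catalog()].
#' @param threshold Positive integer target total per sample.
#' @return A `mutation_catalog` with reduced counts.
#' @examples
#' sc <- catalog_scheme("SBS96")
#' m <- matrix(100L, sc$n_classes, 1, dimnames = list(sc$class_labels, "s1"))
#' ds <- downsample_spectra(mutation_catalog(m, sc), 3000)
#' sum(ds$counts)
#' @export
downsample_spectra <- function(catalog, threshold) {
  stopifnot(inherits(catalog, "mutation_catalog"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold <= 0 || threshold != round(threshold))
    stop("threshold must be a positive integer", call. = FALSE)
  counts <- catalog$counts
  tot <- colSums(counts)
  for (j in which(tot > threshold)) {
    scaled <- counts[, j] * (threshold / tot[j])
    counts[, j] <- as.integer(floor(scaled + 0.5))
  }
  mutation_catalog(counts, catalog$scheme, catalog$sample_groups)
}
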