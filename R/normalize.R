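#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed against a geometric-mean
#' reference gene profile: `factor_s = median_g(c_gs / geomean_g)`, using only
#' genes with nonzero counts in every sample, then rescaled so the factors'
#' geometric mean is 1.
#'
#' @param counts Count tibble (`gene_id` + sample columns) or matrix.
#' @return Named numeric vector of positive size factors (one per sample).
#' @export
size_factors_median_ratio <- function(counts) {
  m <- as_count_matrix(counts)
  if (any(colSums(m) == 0)) abort("sample with all-zero counts")
  ref_genes <- rowSums(m > 0) == ncol(m)
  if (!any(ref_genes)) abort("no gene is nonzero in every sample")
  logm <- log(m[ref_genes, , drop = FALSE])
  log_geo <- rowMeans(logm)
  f <- apply(logm, 2, function(col) exp(median(col - log_geo)))
  f / exp(mean(log(f)))
}

#' Transcripts per million (TPM)
#'
#' `TPM_gs = (c_gs / L_g) / sum_h(c_hs / L_h) * 1e6`. A sample with zero
#' counts everywhere gets TPM 0 by convention. `log2(TPM + 1)` is the unit
#' used downstream for coexpression work.
#'
#' @param counts Count tibble or matrix (genes x samples).
#' @param lengths Named vector of gene lengths in bp (or vector in row order).
#' @param log2 If `TRUE`, return `log2(TPM + 1)`.
#' @return Tibble `gene_id` + one column per sample.
#' @export
compute_tpm <- function(counts, lengths, log2 = FALSE) {
  m <- as_count_matrix(counts)
  if (!is.null(names(lengths))) lengths <- lengths[rownames(m)]
  if (any(is.na(lengths)) || any(lengths <= 0)) {
    abort("gene lengths must be positive for every gene")
  }
  rate <- m / lengths
  denom <- colSums(rate)
  tpm <- sweep(rate, 2, ifelse(denom == 0, 1, denom), `/`) * 1e6
  tpm[, denom == 0] <- 0
  if (log2) tpm <- log2(tpm + 1)
  matrix_to_tibble(tpm)
}
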