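#' Empirical-Bayes-style dispersion estimation
#'
#' Genewise method-of-moments negative-binomial dispersions on normalized
#' counts, pooled across design cells, then shrunk toward a mean-dispersion
#' trend. For each gene, `alpha_raw = max(0, (s2 - mu) / mu^2)` where `s2` is
#' the replicate variance pooled over cells and `mu` the overall normalized
#' mean; the trend is a lowess fit of `alpha_raw` against `log(mu)`; the
#' shrunken value is the weighted average
#' `w * raw + (1 - w) * trend` with `w = df / (df + prior_df)`.
#'
#' @param counts Count tibble or matrix (genes x samples).
#' @param groups Factor/vector of design cells (one entry per sample);
#'   replicates share a level.
#' @param size_factors Optional size factors; computed by
#'   [size_factors_median_ratio()] when missing.
#' @param prior_df Prior degrees of freedom for shrinkage (default 10,
#'   moderate shrinkage).
#' @return Tibble `gene_id`, `mean`, `raw`, `trend`, `shrunken`, `df`.
#' @export
estimate_dispersions <- function(counts, groups, size_factors = NULL,
                                 prior_df = 10) {
  m <- as_count_matrix(counts)
  groups <- as.factor(groups)
  if (length(groups) != ncol(m)) abort("groups must match sample columns")
  reps <- table(groups)
  if (all(reps < 2)) abort("need >= 2 replicates in at least one design cell")
  sf <- size_factors %||% size_factors_median_ratio(m)
  norm <- sweep(m, 2, sf, `/`)

  keep <- names(reps)[reps >= 2]
  df <- sum(reps[keep] - 1)
  ss <- matrix(0, nrow(m), 1)
  for (g in keep) {
    sub <- norm[, groups == g, drop = FALSE]
    mu_c <- rowMeans(sub)
    ss <- ss + rowSums((sub - mu_c)^2)
  }
  s2 <- as.vector(ss) / df
  mu <- rowMeans(norm)
  raw <- ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), 0)

  ok <- mu > 0
  trend <- rep(0, nrow(m))
  if (length(unique(log(mu[ok]))) >= 2) {
    lo <- lowess(log(mu[ok]), raw[ok], f = 0.5)
    trend[ok] <- pmax(approx(lo$x, lo$y, xout = log(mu[ok]), rule = 2,
                             ties = mean)$y, 0)
  } else {
    # degenerate: all genes share one mean; the trend is flat
    trend[ok] <- mean(raw[ok])
  }
  w <- df / (df + prior_df)
  shrunken <- w * raw + (1 - w) * trend

  tibble(gene_id = rownames(m), mean = unname(mu), raw = unname(raw),
         trend = unname(trend), shrunken = unname(shrunken), df = df)
}
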