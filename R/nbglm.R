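#' Negative-binomial GLM for one gene
#'
#' Log-link NB regression with fixed dispersion, fitted by iteratively
#' reweighted least squares, with per-sample offsets (log size factors).
#' Coefficients and standard errors are reported in log2 units; p-values are
#' two-sided Wald normal on `z = beta / SE`.
#'
#' @param y Count vector (one gene across samples).
#' @param design Model matrix (full rank).
#' @param offsets Per-sample offsets on the natural-log scale (e.g.
#'   `log(size_factors)`); default 0.
#' @param alpha NB dispersion; `alpha` near 0 fits a Poisson GLM.
#' @return Tibble with one row per coefficient: `term`, `log2fc`, `se`, `z`,
#'   `p`, `converged`, `flagged` (separation / non-convergence).
#' @export
fit_nb_glm <- function(y, design, offsets = NULL, alpha = 0) {
  design <- as.matrix(design)
  if (qr(design)$rank < ncol(design)) abort("design matrix not full rank")
  offsets <- offsets %||% rep(0, length(y))
  fam <- if (alpha < 1e-8) poisson(link = "log") else
    MASS::negative.binomial(theta = 1 / alpha, link = "log")
  fit <- suppressWarnings(
    glm.fit(design, y, family = fam, offset = offsets,
            control = list(epsilon = 1e-8, maxit = 100))
  )
  p <- ncol(design)
  beta <- fit$coefficients
  covmat <- tryCatch(chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]),
                     error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(covmat), 0))
  flagged <- !fit$converged | !is.finite(beta) | abs(beta) > 20
  beta_cl <- pmin(pmax(beta, -20), 20)
  z <- beta_cl / se
  pval <- 2 * pnorm(-abs(z))
  pval[!fit$converged] <- NA_real_
  tibble(
    term = colnames(design) %||% paste0("b", seq_len(p)),
    log2fc = unname(beta_cl) / log(2),
    se = unname(se) / log(2),
    z = unname(z),
    p = unname(pval),
    converged = fit$converged,
    flagged = unname(flagged)
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment. `NA`/`NaN` entries propagate without affecting the
#' ranks of the remaining p-values.
#'
#' @param p Vector of p-values in \[0, 1\] (NAs allowed).
#' @return Vector of BH-adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Per-gene differential expression for a two-group contrast
#'
#' Fits the NB GLM `~ group` gene by gene with median-of-ratios offsets and
#' shrunken dispersions, and tests the group coefficient by Wald test.
#'
#' @param counts Count tibble or matrix (genes x samples), already subset to
#'   the samples of interest.
#' @param group 0/1 (or two-level factor) vector: 1 = mutant, 0 = reference.
#' @param dispersions Optional named vector of per-gene dispersions; computed
#'   via [estimate_dispersions()] with `group` as cells when missing.
#' @param size_factors Optional size factors.
#' @return Tibble `gene_id`, `log2fc`, `se`, `p`, `fdr`, `flagged`.
#' @export
de_two_group <- function(counts, group, dispersions = NULL,
                         size_factors = NULL) {
  m <- as_count_matrix(counts)
  grp <- as.numeric(as.factor(group)) - 1
  if (length(unique(grp)) != 2) abort("group must have exactly 2 levels")
  sf <- size_factors %||% size_factors_median_ratio(m)
  if (is.null(dispersions)) {
    dt <- estimate_dispersions(m, groups = grp, size_factors = sf)
    dispersions <- setNames(dt$shrunken, dt$gene_id)
  }
  X <- cbind(intercept = 1, group = grp)
  off <- log(sf)
  res <- purrr::map(seq_len(nrow(m)), function(g) {
    f <- fit_nb_glm(m[g, ], X, offsets = off,
                    alpha = dispersions[rownames(m)[g]])
    f[f$term == "group", ]
  })
  res <- bind_rows(res)
  tibble(gene_id = rownames(m), log2fc = res$log2fc, se = res$se, p = res$p,
         fdr = bh_adjust(res$p), flagged = res$flagged)
}

#' Call differentially expressed genes
#'
#' Applies the DEG rule: `up` when `log2FC > lfc` and `FDR < fdr`, `down`
#' when `log2FC < -lfc` and `FDR < fdr`, otherwise `ns`. Thresholds are
#' strict inequalities. All genes are retained with a status.
#'
#' @param de_table Tibble with `gene_id`, `log2fc`, `fdr` (e.g. from
#'   [de_two_group()]).
#' @param lfc Absolute log2 fold-change threshold (default 1).
#' @param fdr FDR threshold (default 0.05).
#' @return The input with a `status` column (`up`/`down`/`ns`).
#' @export
call_degs <- function(de_table, lfc = 1, fdr = 0.05) {
  lfc_thr <- lfc
  fdr_thr <- fdr
  mutate(de_table, status = dplyr::case_when(
    !is.na(.data$fdr) & .data$log2fc > .env$lfc_thr &
      .data$fdr < .env$fdr_thr ~ "up",
    !is.na(.data$fdr) & .data$log2fc < -.env$lfc_thr &
      .data$fdr < .env$fdr_thr ~ "down",
    TRUE ~ "ns"
  ))
}

#' Mutant-versus-WT differential expression at one timepoint
#'
#' The standard per-timepoint contrast of the factorial design: samples of
#' one mutant genotype against wild-type at a given timepoint, with
#' dispersions estimated from all genotype cells of that timepoint (pooled)
#' and FDR controlled per (timepoint, contrast) family.
#'
#' @param counts Full count tibble (`gene_id` + samples).
#' @param design Full sample design.
#' @param genotype Mutant genotype label (as in `design$genotype`).
#' @param timepoint Timepoint to analyse.
#' @param lfc,fdr DEG thresholds passed to [call_degs()].
#' @return A DEG tibble (`gene_id`, `log2fc`, `se`, `p`, `fdr`, `flagged`,
#'   `status`) of class `endonet_deg`.
#' @export
de_timepoint <- function(counts, design, genotype, timepoint,
                         lfc = 1, fdr = 0.05) {
  check_design(design)
  if (!genotype %in% design$genotype) abort("unknown genotype contrast")
  m <- as_count_matrix(counts)
  tp <- design$timepoint == timepoint
  sf_all <- size_factors_median_ratio(m[, design$sample_id[tp], drop = FALSE])
  disp <- estimate_dispersions(
    m[, design$sample_id[tp], drop = FALSE],
    groups = design$genotype[tp], size_factors = sf_all)
  sel <- tp & design$genotype %in% c("WT", genotype)
  out <- de_two_group(
    m[, design$sample_id[sel], drop = FALSE],
    group = as.integer(design$genotype[sel] == genotype),
    dispersions = setNames(disp$shrunken, disp$gene_id),
    size_factors = sf_all[design$sample_id[sel]])
  out <- call_degs(out, lfc = lfc, fdr = fdr)
  attr(out, "genotype") <- genotype
  attr(out, "timepoint") <- timepoint
  class(out) <- c("endonet_deg", class(out))
  out
}

#' @export
tidy.endonet_deg <- function(x, ...) {
  as_tibble(unclass2(x))
}

#' @export
glance.endonet_deg <- function(x, ...) {
  tibble(
    genotype = attr(x, "genotype"), timepoint = attr(x, "timepoint"),
    n_genes = nrow(x),
    n_up = sum(x$status == "up"), n_down = sum(x$status == "down")
  )
}

unclass2 <- function(x) {
  class(x) <- setdiff(class(x), "endonet_deg")
  x
}
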