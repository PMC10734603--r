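#' Factorial interaction test between two TF loci
#'
#' Per-gene NB GLM `~ x_A + x_B + x_A:x_B` with log size-factor offsets at
#' one timepoint. The interaction coefficient (log2 units) is the difference
#' between the log2 fold change of the A mutation in the B-mutant background
#' and in the B-wild-type background. A composite factor such as
#' `"nkd1+nkd2"` maps samples to all-constituent-mutant (1) versus otherwise,
#' and the design is restricted to genotypes where the constituents are
#' jointly wild-type or jointly mutant (a clean 2x2).
#'
#' @param counts Count tibble (`gene_id` + samples) or matrix.
#' @param design Sample design (see [generate_design()]).
#' @param factor_a,factor_b Locus names (`"nkd1"`, `"nkd2"`, `"o2"`) or a
#'   composite `"nkd1+nkd2"`.
#' @param timepoint Timepoint to analyse.
#' @param genes Optional gene ids restricting the tested set (e.g. the
#'   union of DEGs at this timepoint); BH runs across this set.
#' @param dispersions Optional named per-gene dispersions; estimated from the
#'   timepoint's genotype cells when missing.
#' @param fdr FDR threshold for the `affected` flag (default 0.05).
#' @return Tibble `gene_id`, `pair`, `timepoint`, `delta_log2fc`, `se`, `p`,
#'   `fdr`, `affected`, `flagged`.
#' @export
test_pairwise_interaction <- function(counts, design, factor_a, factor_b,
                                      timepoint, genes = NULL,
                                      dispersions = NULL, fdr = 0.05) {
  check_design(design)
  m <- as_count_matrix(counts)
  loci <- c("nkd1", "nkd2", "o2")
  des <- design[design$timepoint == timepoint, ]
  xa <- composite_indicator(des, factor_a, loci)
  xb <- composite_indicator(des, factor_b, loci)

  keep <- rep(TRUE, nrow(des))
  for (f in c(factor_a, factor_b)) {
    parts <- strsplit(f, "+", fixed = TRUE)[[1]]
    if (length(parts) > 1) {
      joint <- rowSums(as.matrix(des[, parts]))
      keep <- keep & (joint == 0 | joint == length(parts))
    }
  }
  des <- des[keep, ]
  xa <- xa[keep]
  xb <- xb[keep]
  if (length(unique(xa)) < 2 || length(unique(xb)) < 2) {
    abort("both factors must vary in the design at this timepoint")
  }
  if (length(unique(paste(xa, xb))) < 4) {
    abort("composite factor leaves fewer than 4 genotype cells")
  }
  m <- m[, des$sample_id, drop = FALSE]
  if (!is.null(genes)) m <- m[intersect(genes, rownames(m)), , drop = FALSE]

  sf <- size_factors_median_ratio(m)
  if (is.null(dispersions)) {
    dt <- estimate_dispersions(m, groups = paste(xa, xb), size_factors = sf)
    dispersions <- setNames(dt$shrunken, dt$gene_id)
  }
  X <- cbind(intercept = 1, a = xa, b = xb, ab = xa * xb)
  off <- log(sf)
  res <- bind_rows(purrr::map(seq_len(nrow(m)), function(g) {
    f <- fit_nb_glm(m[g, ], X, offsets = off,
                    alpha = dispersions[rownames(m)[g]])
    f[f$term == "ab", ]
  }))
  pair <- paste0(factor_a, ":", factor_b)
  out <- tibble(
    gene_id = rownames(m), pair = pair, timepoint = timepoint,
    delta_log2fc = res$log2fc, se = res$se, p = res$p,
    fdr = bh_adjust(res$p)
  )
  out$affected <- !is.na(out$fdr) & out$fdr < fdr
  out$flagged <- res$flagged
  out
}

#' Genotype-level module expression profile
#'
#' For one module at one timepoint: each gene is z-scored across the
#' timepoint's samples, per-genotype values are replicate means, and
#' genotypes are compared by pairwise t-tests paired by gene, summarized as
#' compact significance letters at p < 0.05 (non-overlapping letters indicate
#' a significant difference; unadjusted, matching plain pairwise t-tests).
#'
#' @param log_expr Log-expression tibble or matrix (genes x all samples).
#' @param partition Partition tibble (`gene_id`, `module`).
#' @param module Module label to profile.
#' @param design Sample design.
#' @param timepoint Timepoint.
#' @return List of class `genotype_profile`: `values` (gene x genotype
#'   z-means), `means` (per-genotype means), `letters`, `pairwise_p`
#'   (tibble), `underpowered` (fewer than 3 genes).
#' @export
module_genotype_profile <- function(log_expr, partition, module, design,
                                    timepoint) {
  check_design(design)
  m <- as_expr_matrix(log_expr)
  genes <- partition$gene_id[partition$module == module]
  genes <- intersect(genes, rownames(m))
  if (length(genes) == 0) abort("module empty at this timepoint")
  des <- design[design$timepoint == timepoint, ]
  sub <- m[genes, des$sample_id, drop = FALSE]
  keep <- apply(sub, 1, sd) > 0
  sub <- sub[keep, , drop = FALSE]
  z <- t(scale(t(sub)))
  genotypes <- unique(des$genotype)
  vals <- vapply(genotypes, function(g) {
    rowMeans(z[, des$sample_id[des$genotype == g], drop = FALSE])
  }, numeric(nrow(z)))
  if (nrow(z) == 1) vals <- matrix(vals, 1, dimnames = list(rownames(z),
                                                            genotypes))
  means <- colMeans(vals)
  underpowered <- nrow(vals) < 3
  pw <- crossing(g1 = genotypes, g2 = genotypes)
  pw <- filter(pw, match(.data$g1, genotypes) < match(.data$g2, genotypes))
  pw$p <- purrr::map2_dbl(pw$g1, pw$g2, function(a, b) {
    if (underpowered) return(NA_real_)
    d <- vals[, a] - vals[, b]
    if (sd(d) == 0) return(if (all(d == 0)) 1 else 0)
    t.test(d)$p.value
  })
  letters <- cld_letters(means, pw, alpha = 0.05)
  structure(list(values = vals, means = means, letters = letters,
                 pairwise_p = pw, underpowered = underpowered,
                 module = module, timepoint = timepoint),
            class = "genotype_profile")
}

# Compact letter display: sweep over groups sorted by mean; each maximal run
# of mutually non-significant groups gets one letter.
cld_letters <- function(means, pairwise_p, alpha = 0.05) {
  g <- names(sort(means))
  nonsig <- function(a, b) {
    p <- pairwise_p$p[(pairwise_p$g1 == a & pairwise_p$g2 == b) |
                      (pairwise_p$g1 == b & pairwise_p$g2 == a)]
    length(p) == 0 || is.na(p[1]) || p[1] >= alpha
  }
  all_nonsig <- function(idx) {
    if (length(idx) < 2) return(TRUE)
    pairs <- utils::combn(idx, 2)
    all(vapply(seq_len(ncol(pairs)), function(k)
      nonsig(g[pairs[1, k]], g[pairs[2, k]]), logical(1)))
  }
  segments <- list()
  for (i in seq_along(g)) {
    j <- i
    while (j < length(g) && all_nonsig(i:(j + 1))) j <- j + 1
    seg <- i:j
    contained <- any(vapply(segments, function(s) all(seg %in% s), logical(1)))
    if (!contained) segments[[length(segments) + 1]] <- seg
  }
  out <- setNames(rep("", length(g)), g)
  for (s in seq_along(segments)) {
    out[g[segments[[s]]]] <- paste0(out[g[segments[[s]]]], letters[s])
  }
  out[names(means)]
}

#' Classify module-level epistasis
#'
#' Given a genotype profile and a factor pair, computes per-gene genotype
#' deltas relative to wild-type (`d_A`, `d_B`, `d_AB`, z-units) and
#' classifies the interaction with paired t-tests over genes at 0.05, with
#' precedence suppression > enhancement > additive:
#' * suppression - one single-mutant effect is significant but vanishes in
#'   the other mutant background (`d_AB - d_A` not significant while `d_B`
#'   is, or symmetrically);
#' * enhancement - the double deviates significantly from `d_A + d_B`, with
#'   larger magnitude and the same sign;
#' * additive - the double does not deviate significantly from `d_A + d_B`;
#' * inconclusive - otherwise.
#'
#' @param profile A [module_genotype_profile()] result containing WT, both
#'   single(-equivalent) genotypes, and the double(-equivalent) genotype.
#' @param factor_a,factor_b Locus names or composite (`"nkd1+nkd2"`).
#' @return Tibble `module`, `pair`, `class`, `d_a`, `d_b`, `d_ab` of class
#'   `epistasis_call`.
#' @export
classify_epistasis <- function(profile, factor_a, factor_b) {
  lab <- function(ind) genotype_label(ind[1], ind[2], ind[3])
  ind_of <- function(fs) {
    v <- c(nkd1 = 0, nkd2 = 0, o2 = 0)
    v[strsplit(fs, "+", fixed = TRUE)[[1]]] <- 1
    v
  }
  ga <- lab(ind_of(factor_a))
  gb <- lab(ind_of(factor_b))
  gab <- lab(pmin(ind_of(factor_a) + ind_of(factor_b), 1))
  need <- c("WT", ga, gb, gab)
  if (!all(need %in% colnames(profile$values))) {
    abort(paste0("profile missing genotype(s): ",
                 paste(setdiff(need, colnames(profile$values)),
                       collapse = ", ")))
  }
  v <- profile$values
  dA <- v[, ga] - v[, "WT"]
  dB <- v[, gb] - v[, "WT"]
  dAB <- v[, gab] - v[, "WT"]
  tp <- function(x) {
    if (length(x) < 3 || sd(x) == 0) {
      return(if (all(x == 0)) 1 else 0)
    }
    t.test(x)$p.value
  }
  sig <- function(x) tp(x) < 0.05
  d_a <- mean(dA); d_b <- mean(dB); d_ab <- mean(dAB)
  inter <- dAB - dA - dB
  suppression <- (sig(dB) && !sig(dAB - dA)) || (sig(dA) && !sig(dAB - dB))
  enhancement <- sig(inter) && abs(d_ab) > abs(d_a + d_b) &&
    sign(d_ab) == sign(d_a + d_b)
  cls <- if (suppression) "suppression" else if (enhancement) "enhancement"
    else if (!sig(inter)) "additive" else "inconclusive"
  out <- tibble(module = profile$module,
                pair = paste0(factor_a, ":", factor_b),
                class = cls, d_a = d_a, d_b = d_b, d_ab = d_ab)
  class(out) <- c("epistasis_call", class(out))
  out
}

#' Module enrichment of interaction-affected genes
#'
#' Upper-tail hypergeometric test of the overlap between interaction-affected
#' genes and each coexpression module, reported as `-log10(p)`.
#'
#' @param affected_genes Character vector of affected gene ids (subset of
#'   `universe`).
#' @param partition Partition tibble (`gene_id`, `module`).
#' @param universe Character vector of all tested gene ids.
#' @return Tibble `module`, `size`, `overlap`, `p`, `neg_log10_p`.
#' @export
interaction_module_enrichment <- function(affected_genes, partition,
                                          universe) {
  if (!all(affected_genes %in% universe)) {
    abort("affected_genes must be a subset of universe")
  }
  mods <- sort(unique(partition$module[partition$module > 0]))
  out <- purrr::map(mods, function(mo) {
    members <- intersect(partition$gene_id[partition$module == mo], universe)
    if (length(members) == 0) return(NULL)
    k <- length(intersect(affected_genes, members))
    p <- hypergeometric_overlap(affected_genes, members, length(universe))
    tibble(module = mo, size = length(members), overlap = k, p = p,
           neg_log10_p = -log10(p))
  })
  bind_rows(out)
}
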