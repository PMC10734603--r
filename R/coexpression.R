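#' Signed coexpression adjacency
#'
#' `a_ij = ((1 + cor(x_i, x_j)) / 2) ^ beta` with Pearson correlation, so
#' anti-correlated genes get adjacency near 0. The soft power `beta` defaults
#' to 10 for pooled-timepoint networks (use 7/9/7 for 8/12/16 DAP
#' single-timepoint networks).
#'
#' @param expr Log-expression tibble (`gene_id` + samples) or matrix
#'   (genes x samples). Zero-variance genes are an error; remove them first
#'   (see [drop_zero_variance()]).
#' @param beta Soft-thresholding power.
#' @return Symmetric adjacency matrix in \[0, 1\] with unit diagonal.
#' @export
signed_adjacency <- function(expr, beta = 10) {
  m <- as_expr_matrix(expr)
  if (ncol(m) < 3) abort("need >= 3 samples")
  v <- apply(m, 1, var)
  if (any(v == 0)) {
    abort(paste0("zero-variance genes present: ",
                 paste(head(rownames(m)[v == 0], 5), collapse = ", ")))
  }
  a <- ((1 + cor(t(m))) / 2)^beta
  diag(a) <- 1
  a
}

#' Drop zero-variance genes from an expression table
#'
#' @param expr Log-expression tibble or matrix.
#' @return Same shape minus constant genes; the dropped ids are reported in a
#'   message.
#' @export
drop_zero_variance <- function(expr) {
  m <- as_expr_matrix(expr)
  v <- apply(m, 1, var)
  if (any(v == 0)) {
    message("dropping ", sum(v == 0), " zero-variance gene(s): ",
            paste(head(rownames(m)[v == 0], 10), collapse = ", "))
  }
  out <- m[v > 0, , drop = FALSE]
  if (is_tibble(expr) || is.data.frame(expr)) matrix_to_tibble(out) else out
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' connectivities `k_i = sum_{u != i} a_iu`; the diagonal is set to 1.
#' (Unsigned TOM on a signed adjacency.)
#'
#' @param adjacency Symmetric adjacency matrix in \[0, 1\].
#' @return Symmetric TOM matrix in \[0, 1\].
#' @export
topological_overlap <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10)) {
    abort("adjacency must be symmetric")
  }
  a <- adjacency
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect coexpression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut at a fixed quantile of the dendrogram merge heights; clusters smaller
#' than `min_size` are dissolved to the unassigned label 0. Labels are dense
#' positive integers ordered by decreasing module size.
#'
#' @param tom TOM matrix from [topological_overlap()].
#' @param min_size Minimum module size (default 60).
#' @param cut_quantile Quantile of merge heights at which to cut the tree
#'   (default 0.7; the cut must fall above the within-module merges but below
#'   the late merges that attach uncorrelated genes, and is usually followed
#'   by [refine_membership()]).
#' @return Tibble `gene_id`, `module` (0 = unassigned), with the minimum size
#'   recorded in attribute `min_size`.
#' @export
cluster_modules <- function(tom, min_size = 60, cut_quantile = 0.7) {
  d <- stats::as.dist(1 - tom)
  tree <- hclust(d, method = "average")
  h <- quantile(tree$height, cut_quantile)
  raw <- cutree(tree, h = h)
  partition <- relabel_partition(raw, min_size)
  out <- tibble(gene_id = rownames(tom), module = partition)
  if (all(out$module == 0)) warn("all genes unassigned (no module >= min_size)")
  attr(out, "min_size") <- min_size
  out
}

# Dissolve small clusters to 0 and relabel 1..K by size descending
# (ties broken by first appearance for determinism).
relabel_partition <- function(labels, min_size) {
  sizes <- table(labels)
  keep <- names(sizes)[sizes >= min_size]
  labels[!(labels %in% keep)] <- 0L
  kept <- labels[labels != 0]
  if (length(kept) == 0) return(rep(0L, length(labels)))
  sizes <- sort(table(kept), decreasing = TRUE)
  newlab <- setNames(seq_along(sizes), names(sizes))
  out <- ifelse(labels == 0, 0L, as.integer(newlab[as.character(labels)]))
  out
}

#' Module eigengenes
#'
#' The eigengene of a module is the first right singular vector of its
#' standardized (per-gene mean 0, sd 1 across samples) expression submatrix:
#' a unit-norm per-sample profile summarizing the module. The sign is
#' aligned so the eigengene correlates non-negatively with the module's mean
#' standardized expression. The fraction of variance explained by the first
#' component is reported.
#'
#' @param expr Log-expression tibble or matrix (genes x samples).
#' @param partition Partition tibble (`gene_id`, `module`) from
#'   [cluster_modules()].
#' @return List with `eigengenes` (module x sample matrix, rownames
#'   `"M<k>"`), `var_explained` (named vector).
#' @export
compute_eigengenes <- function(expr, partition) {
  m <- as_expr_matrix(expr)
  mods <- sort(unique(partition$module[partition$module > 0]))
  me <- matrix(NA_real_, length(mods), ncol(m),
               dimnames = list(paste0("M", mods), colnames(m)))
  ve <- setNames(numeric(length(mods)), paste0("M", mods))
  for (i in seq_along(mods)) {
    genes <- partition$gene_id[partition$module == mods[i]]
    sub <- m[genes, , drop = FALSE]
    v <- apply(sub, 1, var)
    if (any(v == 0)) {
      warn(paste0("module ", mods[i], ": dropping ", sum(v == 0),
                  " zero-variance gene(s)"))
      sub <- sub[v > 0, , drop = FALSE]
    }
    if (nrow(sub) < 2) abort("module with < 2 usable genes")
    x <- t(scale(t(sub)))  # genes x samples, standardized per gene
    sv <- svd(x, nu = 0, nv = 1)
    e <- sv$v[, 1]
    if (cor(e, colMeans(x)) < 0) e <- -e
    me[i, ] <- e
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = me, var_explained = ve)
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the module pair with the smallest eigengene
#' dissimilarity `1 - cor(ME_p, ME_q)` while that dissimilarity is below
#' `merge_threshold`, recomputing eigengenes after every merge. Terminates in
#' at most (initial module count - 1) merges.
#'
#' @param expr Log-expression tibble or matrix.
#' @param partition Partition tibble (`gene_id`, `module`).
#' @param merge_threshold Dissimilarity threshold (0.1 pooled, 0.3
#'   per-timepoint in the default analysis; 0 disables merging).
#' @return Updated partition tibble (labels re-densified by size).
#' @export
merge_close_modules <- function(expr, partition, merge_threshold = 0.1) {
  part <- partition$module
  names(part) <- partition$gene_id
  repeat {
    mods <- sort(unique(part[part > 0]))
    if (length(mods) < 2 || merge_threshold <= 0) break
    me <- compute_eigengenes(expr,
                             tibble(gene_id = names(part), module = part))
    cm <- cor(t(me$eigengenes))
    diss <- 1 - cm
    diag(diss) <- Inf
    ij <- which(diss == min(diss), arr.ind = TRUE)[1, ]
    if (diss[ij[1], ij[2]] >= merge_threshold) break
    from <- mods[max(ij)]
    to <- mods[min(ij)]
    part[part == from] <- to
  }
  out <- tibble(gene_id = names(part),
                module = relabel_partition(unname(part), 1))
  attr(out, "min_size") <- attr(partition, "min_size")
  out
}

#' Refine a module partition by eigengene membership
#'
#' Reassigns every gene by its correlation with the module eigengenes (kME):
#' a gene belongs to the module with its highest kME when that kME is at
#' least `min_kme` (so the eigengene explains at least `min_kme^2` of its
#' variance), and is unassigned otherwise. Eigengenes are recomputed between
#' iterations. This cleans up two artifacts of a static tree cut: loosely
#' attached background genes inside module clusters, and genuine module
#' genes stranded below the cut.
#'
#' @param expr Log-expression tibble or matrix (genes x samples).
#' @param partition Partition tibble (`gene_id`, `module`).
#' @param min_kme Minimum eigengene correlation for assignment (default 0.5).
#' @param iterations Refinement passes (default 2).
#' @param min_size Modules falling below this size after refinement are
#'   dissolved (defaults to the partition's recorded `min_size`, else 2).
#' @return Refined partition tibble (labels re-densified by size).
#' @export
refine_membership <- function(expr, partition, min_kme = 0.5,
                              iterations = 2, min_size = NULL) {
  m <- as_expr_matrix(expr)
  min_size <- min_size %||% attr(partition, "min_size") %||% 2
  part <- partition
  for (it in seq_len(iterations)) {
    if (!any(part$module > 0)) break
    me <- compute_eigengenes(m, part)
    kme <- cor(t(m), t(me$eigengenes))
    mods <- as.integer(sub("^M", "", colnames(kme)))
    best <- max.col(kme, ties.method = "first")
    bestv <- kme[cbind(seq_len(nrow(kme)), best)]
    lab <- ifelse(bestv >= min_kme, mods[best], 0L)
    part <- tibble(gene_id = rownames(m), module = lab)
  }
  out <- tibble(gene_id = part$gene_id,
                module = relabel_partition(part$module, min_size))
  attr(out, "min_size") <- attr(partition, "min_size")
  out
}

#' Module membership (kME) and hub genes
#'
#' `kME_gm = cor(expression of gene g, eigengene of module m)` (Pearson).
#' A gene is a hub when its kME with its own assigned module exceeds 0.8
#' (strict); unassigned genes get kME values but are never hubs.
#'
#' @param expr Log-expression tibble or matrix.
#' @param eigengenes Result of [compute_eigengenes()] (or its `eigengenes`
#'   matrix).
#' @param partition Partition tibble (`gene_id`, `module`).
#' @param hub_kme Hub threshold (default 0.8).
#' @return Tibble `gene_id`, `module`, one `kME_M<k>` column per module,
#'   `kme_own`, `hub`.
#' @export
module_membership <- function(expr, eigengenes, partition, hub_kme = 0.8) {
  m <- as_expr_matrix(expr)
  me <- if (is.list(eigengenes)) eigengenes$eigengenes else eigengenes
  kme <- cor(t(m), t(me))  # genes x modules
  colnames(kme) <- paste0("kME_", rownames(me))
  mod <- partition$module[match(rownames(m), partition$gene_id)]
  own <- rep(NA_real_, nrow(m))
  has <- mod > 0 & paste0("M", mod) %in% rownames(me)
  own[has] <- kme[cbind(which(has), match(paste0("M", mod[has]),
                                          rownames(me)))]
  out <- tibble(gene_id = rownames(m), module = mod)
  out <- bind_cols(out, as_tibble(kme))
  out$kme_own <- own
  out$hub <- !is.na(own) & own > hub_kme
  out
}

#' Correlation of module eigengenes with TF expression
#'
#' Pearson correlation of each module eigengene with the log-expression of
#' each regulator gene, with the two-sided t-test
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` and significance stars at
#' 0.05 / 0.01 / 0.001.
#'
#' @param eigengenes Eigengene matrix (modules x samples) or
#'   [compute_eigengenes()] result.
#' @param tf_expr Tibble or matrix of regulator log-expression
#'   (TFs x samples, same sample order).
#' @return Tibble `module`, `tf`, `r`, `p`, `stars`.
#' @export
module_tf_correlation <- function(eigengenes, tf_expr) {
  me <- if (is.list(eigengenes)) eigengenes$eigengenes else eigengenes
  tf <- as_expr_matrix(tf_expr)
  n <- ncol(me)
  if (n < 3) abort("need >= 3 samples")
  if (ncol(tf) != n) abort("sample mismatch between eigengenes and tf_expr")
  grid <- crossing(module = rownames(me), tf = rownames(tf))
  out <- purrr::pmap(list(grid$module, grid$tf), function(mo, tfn) {
    r <- cor(me[mo, ], tf[tfn, ])
    tstat <- r * sqrt(n - 2) / sqrt(max(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    tibble(module = mo, tf = tfn, r = r, p = p,
           stars = dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**",
                                    p < 0.05 ~ "*", TRUE ~ ""))
  })
  bind_rows(out)
}

#' Full coexpression analysis
#'
#' Runs adjacency, TOM, clustering, eigengenes, merging, membership and
#' (optionally) module-TF correlation in one call.
#'
#' @param expr Log-expression tibble (`gene_id` + samples).
#' @param beta Soft power.
#' @param min_size Minimum module size.
#' @param merge_threshold Eigengene merge threshold.
#' @param cut_quantile Tree-cut quantile.
#' @param min_kme Membership threshold for [refine_membership()] (`NULL`
#'   disables refinement).
#' @param tf_expr Optional regulator expression for [module_tf_correlation()].
#' @return Object of class `coexpression_fit`: list with `partition`,
#'   `eigengenes`, `var_explained`, `membership`, `tf_correlation`,
#'   `parameters`.
#' @export
coexpression_network <- function(expr, beta = 10, min_size = 60,
                                 merge_threshold = 0.1, cut_quantile = 0.7,
                                 min_kme = 0.5, tf_expr = NULL) {
  expr <- drop_zero_variance(expr)
  adj <- signed_adjacency(expr, beta = beta)
  tom <- topological_overlap(adj)
  part <- cluster_modules(tom, min_size = min_size,
                          cut_quantile = cut_quantile)
  part <- merge_close_modules(expr, part, merge_threshold = merge_threshold)
  if (!is.null(min_kme) && any(part$module > 0)) {
    part <- refine_membership(expr, part, min_kme = min_kme,
                              min_size = min_size)
  }
  has_mod <- any(part$module > 0)
  me <- if (has_mod) compute_eigengenes(expr, part) else
    list(eigengenes = matrix(0, 0, ncol(as_expr_matrix(expr))),
         var_explained = numeric(0))
  memb <- if (has_mod) module_membership(expr, me, part) else NULL
  tfc <- if (has_mod && !is.null(tf_expr)) module_tf_correlation(me, tf_expr)
    else NULL
  structure(list(
    partition = part, eigengenes = me$eigengenes,
    var_explained = me$var_explained, membership = memb,
    tf_correlation = tfc,
    parameters = list(beta = beta, min_size = min_size,
                      merge_threshold = merge_threshold,
                      cut_quantile = cut_quantile, min_kme = min_kme)
  ), class = "coexpression_fit")
}

#' @export
print.coexpression_fit <- function(x, ...) {
  k <- sum(unique(x$partition$module) > 0)
  cat("Coexpression network: ", nrow(x$partition), " genes, ", k,
      " modules (beta = ", x$parameters$beta, ", min size = ",
      x$parameters$min_size, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.coexpression_fit <- function(x, ...) {
  if (is.null(x$membership)) return(x$partition)
  select(x$membership, "gene_id", "module", "kme_own", "hub")
}

#' @export
glance.coexpression_fit <- function(x, ...) {
  tibble(
    n_genes = nrow(x$partition),
    n_modules = sum(unique(x$partition$module) > 0),
    n_unassigned = sum(x$partition$module == 0),
    n_hubs = if (is.null(x$membership)) 0L else sum(x$membership$hub),
    beta = x$parameters$beta,
    min_size = x$parameters$min_size,
    merge_threshold = x$parameters$merge_threshold
  )
}
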