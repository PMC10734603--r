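# Internal helpers shared across modules.

# Deterministic seed derivation: one user-facing seed, split per sub-generator
# by a fixed label so partial regeneration is stable. Result stays < 2^31.
split_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629L)
}

# Count matrix in "genes x samples" matrix form from a tibble with gene_id
# column, or pass-through for a matrix with rownames.
as_count_matrix <- function(counts) {
  if (is.matrix(counts)) {
    if (is.null(rownames(counts))) abort("count matrix needs gene_id rownames")
    return(counts)
  }
  if (!"gene_id" %in% names(counts)) abort("counts need a gene_id column")
  m <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  rownames(m) <- counts$gene_id
  storage.mode(m) <- "double"
  m
}

# Expression tibble (gene_id + sample columns) -> matrix, same convention.
as_expr_matrix <- as_count_matrix

matrix_to_tibble <- function(m, id_col = "gene_id") {
  out <- as_tibble(m, .name_repair = "minimal")
  out[[id_col]] <- rownames(m)
  out[, c(id_col, setdiff(names(out), id_col))]
}

check_design <- function(design) {
  need <- c("sample_id", "nkd1", "nkd2", "o2", "timepoint", "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss) > 0) {
    abort(paste0("design is missing columns: ", paste(miss, collapse = ", ")))
  }
  invisible(design)
}

# Genotype label from the three mutant indicators, WT when all 0.
genotype_label <- function(nkd1, nkd2, o2) {
  lab <- paste0(ifelse(nkd1 == 1, "nkd1 ", ""),
                ifelse(nkd2 == 1, "nkd2 ", ""),
                ifelse(o2 == 1, "o2 ", ""))
  lab <- trimws(lab)
  ifelse(lab == "", "WT", lab)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
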