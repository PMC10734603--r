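#' Assign binding peaks to target genes by TSS window
#'
#' A peak is assigned to every gene whose TSS lies within `window` bp
#' (inclusive) of the peak midpoint `floor((start + end) / 2)` (0-based
#' half-open peaks; the 1-based TSS is converted at the boundary). The signed
#' distance is midpoint minus TSS, oriented by gene strand (positive =
#' downstream of the TSS in the gene's direction).
#'
#' @param peaks Peak tibble (`peak_id`, `chrom`, `start`, `end`).
#' @param annotation Annotation tibble (`gene_id`, `chrom`, `tss`, `strand`).
#' @param window Window half-width in bp (default 3000).
#' @return List with `assignments` (tibble `peak_id`, `gene_id`, `distance`),
#'   `genes` (tibble `gene_id`, `n_peaks`), `summary` (tibble: peaks
#'   assigned, genes targeted, singlet vs multi-copy gene counts).
#' @export
assign_peaks_to_targets <- function(peaks, annotation, window = 3000) {
  unknown <- setdiff(unique(peaks$chrom), unique(annotation$chrom))
  if (length(unknown) > 0) {
    abort(paste0("peak chromosomes absent from annotation: ",
                 paste(unknown, collapse = ", ")))
  }
  pk <- mutate(peaks, mid = floor((.data$start + .data$end) / 2))
  ann <- mutate(annotation, tss0 = .data$tss - 1L)
  hits <- inner_join(select(pk, "peak_id", "chrom", "mid"),
                     select(ann, "gene_id", "chrom", "tss0", "strand"),
                     by = "chrom", relationship = "many-to-many")
  hits <- mutate(hits, distance = (.data$mid - .data$tss0) *
                   ifelse(.data$strand == "+", 1L, -1L))
  hits <- filter(hits, abs(.data$distance) <= window)
  assignments <- select(hits, "peak_id", "gene_id", "distance")
  genes <- count(assignments, .data$gene_id, name = "n_peaks")
  summary <- tibble(
    n_peaks_assigned = dplyr::n_distinct(assignments$peak_id),
    n_genes_targeted = nrow(genes),
    n_genes_singlet = sum(genes$n_peaks == 1),
    n_genes_multi = sum(genes$n_peaks >= 2)
  )
  list(assignments = assignments, genes = genes, summary = summary)
}

#' Classify peak genomic locations
#'
#' Each peak gets exactly one category, tested in order:
#' `promoter1k` (midpoint within 1 kb of a TSS), `promoter3k` (within 3 kb),
#' `genic` (midpoint inside a gene body), `distal_intergenic` (for every
#' gene: outside the body, more than 3 kb upstream of the gene and more than
#' 300 bp downstream, strand-relative), else `other`.
#'
#' @param peaks Peak tibble.
#' @param annotation Annotation tibble.
#' @return The peaks with a `location` column.
#' @export
classify_peak_locations <- function(peaks, annotation) {
  if (nrow(annotation) == 0) abort("annotation is empty")
  mid <- floor((peaks$start + peaks$end) / 2)
  loc <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    ann <- annotation[annotation$chrom == peaks$chrom[i], ]
    if (nrow(ann) == 0) {
      loc[i] <- "distal_intergenic"
      next
    }
    d_tss <- abs(mid[i] - (ann$tss - 1L))
    in_body <- mid[i] >= (ann$start - 1L) & mid[i] < ann$end
    # strand-relative gaps to each gene
    up_gap <- ifelse(ann$strand == "+", (ann$start - 1L) - mid[i],
                     mid[i] - (ann$end - 1L))
    down_gap <- ifelse(ann$strand == "+", mid[i] - (ann$end - 1L),
                       (ann$start - 1L) - mid[i])
    distal_ok <- !in_body &
      (up_gap <= 0 | up_gap > 3000) & (down_gap <= 0 | down_gap > 300)
    loc[i] <- if (min(d_tss) <= 1000) "promoter1k"
      else if (min(d_tss) <= 3000) "promoter3k"
      else if (any(in_body)) "genic"
      else if (all(distal_ok)) "distal_intergenic"
      else "other"
  }
  mutate(peaks, location = loc)
}

#' Scan a genome for a degenerate consensus motif
#'
#' Exact degenerate (IUPAC) matching of the consensus on both strands (the
#' reverse complement is scanned for minus-strand sites); overlapping matches
#' are all reported. Sites are summarized by nearest-TSS distance, per-gene
#' copy counts within the TSS window, and the genome-wide fraction of sites
#' within the window.
#'
#' @param genome Named `Biostrings::DNAStringSet` or named character vector
#'   (uppercase ACGTN).
#' @param pattern Degenerate consensus, e.g. `"TTTGTCYT"` (IUPAC; `[CT]`
#'   style classes are converted).
#' @param annotation Annotation tibble for TSS distances (optional).
#' @param window TSS window in bp (default 3000).
#' @return List with `sites` (tibble `chrom`, `start` 0-based, `end`,
#'   `strand`, `nearest_tss_distance`), `per_gene` (tibble `gene_id`,
#'   `n_sites`), `n_sites` total and `fraction_near_tss`.
#' @export
scan_consensus_sites <- function(genome, pattern = "TTTGTCYT",
                                 annotation = NULL, window = 3000) {
  pattern <- gsub("\\[CT\\]", "Y", pattern)
  pattern <- gsub("\\[AG\\]", "R", pattern)
  if (is.character(genome)) {
    for (i in seq_along(genome)) {
      bad <- regexpr("[^ACGTN]", genome[[i]])
      if (bad > 0) {
        abort(paste0("non-ACGTN character in ", names(genome)[i],
                     " at position ", bad))
      }
    }
    genome <- Biostrings::DNAStringSet(genome)
  } else {
    for (i in seq_along(genome)) {
      s <- as.character(genome[[i]])
      bad <- regexpr("[^ACGTN]", s)
      if (bad > 0) {
        abort(paste0("non-ACGTN character in ", names(genome)[i],
                     " at position ", bad))
      }
    }
  }
  pat <- Biostrings::DNAString(pattern)
  rc <- Biostrings::reverseComplement(pat)
  res <- list()
  for (i in seq_along(genome)) {
    chrom <- names(genome)[i]
    fwd <- Biostrings::matchPattern(pat, genome[[i]], fixed = FALSE)
    rev <- Biostrings::matchPattern(rc, genome[[i]], fixed = FALSE)
    res[[length(res) + 1]] <- tibble(
      chrom = chrom,
      start = c(BiocGenerics::start(fwd), BiocGenerics::start(rev)) - 1L,
      end = c(BiocGenerics::end(fwd), BiocGenerics::end(rev)),
      strand = rep(c("+", "-"), c(length(fwd), length(rev)))
    )
  }
  sites <- arrange(bind_rows(res), .data$chrom, .data$start)
  per_gene <- tibble(gene_id = character(), n_sites = integer())
  frac <- NA_real_
  if (!is.null(annotation) && nrow(sites) > 0) {
    mid <- floor((sites$start + sites$end) / 2)
    near <- rep(NA_integer_, nrow(sites))
    for (ch in unique(sites$chrom)) {
      tss <- annotation$tss[annotation$chrom == ch] - 1L
      idx <- which(sites$chrom == ch)
      if (length(tss) == 0) next
      near[idx] <- vapply(mid[idx], function(x) min(abs(x - tss)),
                          numeric(1))
    }
    sites$nearest_tss_distance <- near
    frac <- mean(!is.na(near) & near <= window)
    fake <- mutate(sites, peak_id = paste0("site_", row_number()),
                   score = 0)
    asn <- assign_peaks_to_targets(fake, annotation, window = window)
    per_gene <- rename(asn$genes, n_sites = "n_peaks")
  }
  list(sites = sites, per_gene = per_gene, n_sites = nrow(sites),
       fraction_near_tss = frac)
}

#' Overlap of bound genes with DEG sets
#'
#' Upper-tail hypergeometric test of each (TF bound-gene set, genotype DEG
#' set) overlap against a gene universe; pairs with `p < 1e-6` are flagged
#' significant and the overlapping genes are the potential direct targets.
#'
#' @param bound_genes Named list of gene-id vectors per TF.
#' @param deg_sets Named list of DEG gene-id vectors per genotype (or a
#'   single vector).
#' @param universe Character vector of all genes (or its size).
#' @return Tibble `tf`, `genotype`, `n_bound`, `n_deg`, `overlap`, `p`,
#'   `significant`, `targets` (list-column of overlapping gene ids).
#' @export
call_direct_targets <- function(bound_genes, deg_sets, universe) {
  n_univ <- if (is.numeric(universe)) universe else length(universe)
  if (!is.list(deg_sets)) deg_sets <- list(deg = deg_sets)
  grid <- crossing(tf = names(bound_genes), genotype = names(deg_sets))
  out <- purrr::pmap(list(grid$tf, grid$genotype), function(tf, gt) {
    b <- unique(bound_genes[[tf]])
    d <- unique(deg_sets[[gt]])
    ov <- intersect(b, d)
    p <- if (length(d) == 0) 1 else
      stats::phyper(length(ov) - 1, length(b), n_univ - length(b),
                    length(d), lower.tail = FALSE)
    tibble(tf = tf, genotype = gt, n_bound = length(b), n_deg = length(d),
           overlap = length(ov), p = p, significant = p < 1e-6,
           targets = list(ov))
  })
  bind_rows(out)
}

#' Differential chromatin accessibility
#'
#' Reuses the NB GLM engine on peak counts: per-peak two-group contrast
#' (mutant versus reference genotype), `up` = more open (positive log2FC,
#' FDR < 0.05, strict), `down` = more closed, cross-tabulated by promoter
#' (within 3 kb of a TSS) versus nonpromoter location.
#'
#' @param atac Peak tibble with per-sample count columns.
#' @param atac_design Accessibility design (`sample_id`, `genotype`, ...).
#' @param genotype Mutant genotype label.
#' @param reference Reference genotype label (default `"WT"`).
#' @param annotation Annotation tibble for the location split.
#' @param dap_peaks Optional peak tibble; overlap with these peaks is flagged.
#' @return Tibble `peak_id`, `log2fc`, `p`, `fdr`, `direction`
#'   (`up`/`down`/`ns`), `location` (`promoter`/`nonpromoter`),
#'   `overlaps_dap`.
#' @export
differential_accessibility <- function(atac, atac_design, genotype,
                                       reference = "WT", annotation = NULL,
                                       dap_peaks = NULL) {
  sel <- atac_design$genotype %in% c(reference, genotype)
  des <- atac_design[sel, ]
  if (min(table(des$genotype)) < 2) {
    abort("need >= 2 replicates per genotype")
  }
  m <- as.matrix(atac[des$sample_id])
  rownames(m) <- atac$peak_id
  res <- de_two_group(m, group = as.integer(des$genotype == genotype))
  res <- rename(res, peak_id = "gene_id")
  res <- mutate(res, direction = dplyr::case_when(
    !is.na(.data$fdr) & .data$fdr < 0.05 & .data$log2fc > 0 ~ "up",
    !is.na(.data$fdr) & .data$fdr < 0.05 & .data$log2fc < 0 ~ "down",
    TRUE ~ "ns"
  ))
  if (!is.null(annotation)) {
    loc <- classify_peak_locations(atac, annotation)
    res$location <- ifelse(loc$location %in% c("promoter1k", "promoter3k"),
                           "promoter", "nonpromoter")
  }
  if (!is.null(dap_peaks)) {
    ov <- overlap_peak_sets(atac, dap_peaks)
    res$overlaps_dap <- res$peak_id %in% ov$pairs$peak_id_a
  }
  res
}

#' Overlap two peak sets
#'
#' Two peaks overlap when they share at least 1 bp on the same chromosome
#' (half-open coordinates; no reciprocal-fraction requirement).
#'
#' @param set_a,set_b Peak tibbles.
#' @return List with `pairs` (tibble `peak_id_a`, `peak_id_b`),
#'   `n_a_overlapping` (count of A peaks with >= 1 overlap) and
#'   `n_b_overlapping`.
#' @export
overlap_peak_sets <- function(set_a, set_b) {
  pairs <- list()
  for (ch in intersect(unique(set_a$chrom), unique(set_b$chrom))) {
    a <- set_a[set_a$chrom == ch, ]
    b <- set_b[set_b$chrom == ch, ]
    ra <- IRanges::IRanges(start = a$start + 1L, end = a$end)
    rb <- IRanges::IRanges(start = b$start + 1L, end = b$end)
    hit <- IRanges::findOverlaps(ra, rb, minoverlap = 1L)
    if (length(hit) > 0) {
      pairs[[length(pairs) + 1]] <- tibble(
        peak_id_a = a$peak_id[S4Vectors::queryHits(hit)],
        peak_id_b = b$peak_id[S4Vectors::subjectHits(hit)]
      )
    }
  }
  pairs <- if (length(pairs) > 0) bind_rows(pairs) else
    tibble(peak_id_a = character(), peak_id_b = character())
  list(pairs = pairs,
       n_a_overlapping = dplyr::n_distinct(pairs$peak_id_a),
       n_b_overlapping = dplyr::n_distinct(pairs$peak_id_b))
}
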