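#' Read gene annotation from GFF3
#'
#' Parses a GFF3 file and keeps `gene`-type features, deriving a strand-aware
#' transcription start site (TSS) for each gene: the feature start on the
#' `+` strand, the feature end on the `-` strand. Coordinates are 1-based
#' inclusive as in GFF3.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `tss`, `length` (bp, `end - start + 1`).
#' @details Records without a strand are dropped with a warning; duplicated
#'   gene ids are an error. A file without gene features yields an empty
#'   annotation with a warning.
#' @export
read_gff3_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  if (length(gr) == 0) {
    warn("no gene features found in GFF3; returning empty annotation")
    return(tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  tss = integer(), length = integer()))
  }
  strand <- as.character(BiocGenerics::strand(gr))
  no_strand <- strand == "*"
  if (any(no_strand)) {
    warn(paste0(sum(no_strand), " gene record(s) without strand dropped"))
    gr <- gr[!no_strand]
    strand <- strand[!no_strand]
  }
  ids <- gr$ID
  if (is.null(ids)) ids <- gr$Name
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate gene_id in annotation: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  start <- BiocGenerics::start(gr)
  end <- BiocGenerics::end(gr)
  tibble(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = as.integer(start),
    end = as.integer(end),
    strand = strand,
    tss = as.integer(ifelse(strand == "+", start, end)),
    length = as.integer(end - start + 1L)
  )
}

#' Write gene annotation to GFF3
#'
#' Writes gene features only (the inverse of [read_gff3_annotation()]).
#'
#' @param annotation Tibble as returned by [read_gff3_annotation()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gff3_annotation <- function(annotation, path) {
  lines <- c(
    "##gff-version 3",
    sprintf("%s\tendonet\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            annotation$chrom, annotation$start, annotation$end,
            annotation$strand, annotation$gene_id)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read peaks from BED
#'
#' Reads BED3+ intervals (0-based, half-open). Column 4 is taken as `peak_id`
#' (autogenerated when absent), column 5 as `score`; any further columns are
#' kept under their header-less positional names `extra1`, `extra2`, ... unless
#' `count_cols` names them.
#'
#' @param path Path to a BED file.
#' @param count_cols Optional character vector naming per-sample count columns
#'   (BED columns 7+ in order).
#' @return A tibble with `peak_id`, `chrom`, `start`, `end`, `score` and any
#'   extra columns.
#' @export
read_bed_peaks <- function(path, count_cols = NULL) {
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE, comment = "#")
  if (nrow(raw) == 0) {
    return(tibble(peak_id = character(), chrom = character(),
                  start = integer(), end = integer(), score = double()))
  }
  if (ncol(raw) < 3) abort("BED needs at least 3 columns")
  out <- tibble(
    chrom = as.character(raw[[1]]),
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]])
  )
  bad <- which(out$start >= out$end)
  if (length(bad) > 0) {
    abort(paste0("BED interval with start >= end at line ", bad[1],
                 " (", out$chrom[bad[1]], ":", out$start[bad[1]], "-",
                 out$end[bad[1]], ")"))
  }
  out$peak_id <- if (ncol(raw) >= 4) as.character(raw[[4]]) else
    paste0("peak_", seq_len(nrow(raw)))
  out$score <- if (ncol(raw) >= 5) as.numeric(raw[[5]]) else 0
  if (ncol(raw) >= 6) out$strand <- as.character(raw[[6]])
  if (ncol(raw) >= 7) {
    extra <- raw[, 7:ncol(raw), drop = FALSE]
    nms <- count_cols %||% paste0("extra", seq_len(ncol(extra)))
    if (length(nms) != ncol(extra)) abort("count_cols length mismatch")
    names(extra) <- nms
    out <- bind_cols(out, extra)
  }
  select(out, "peak_id", "chrom", "start", "end", "score",
         dplyr::everything())
}

#' Write peaks to BED
#'
#' Writes BED6 (name = `peak_id`, strand `.` unless present) plus any columns
#' named in `count_cols` as additional fields. Round-trips with
#' [read_bed_peaks()].
#'
#' @param peaks Peak tibble (`peak_id`, `chrom`, `start`, `end`, `score`).
#' @param path Output path.
#' @param count_cols Optional character vector of extra columns to append.
#' @return The path, invisibly.
#' @export
write_bed_peaks <- function(peaks, path, count_cols = NULL) {
  if (any(peaks$start >= peaks$end)) abort("peak with start >= end")
  df <- data.frame(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = peaks$peak_id, score = peaks$score,
    strand = if ("strand" %in% names(peaks)) peaks$strand else
      rep(".", nrow(peaks)),
    check.names = FALSE
  )
  if (nrow(peaks) == 0) df <- df[0, ]
  for (cc in count_cols) df[[cc]] <- peaks[[cc]]
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a gene count matrix with its sample design
#'
#' Reads a genes-by-samples TSV (first column `gene_id`, header row of sample
#' ids) and a design TSV, checks that every design sample is present, enforces
#' integer counts, and reorders columns to the design's sample order.
#'
#' @param path Counts TSV path.
#' @param design_path Design TSV path (columns `sample_id`, `nkd1`, `nkd2`,
#'   `o2`, `timepoint`, `replicate`).
#' @return A list with `counts` (tibble, gene_id + samples in design order)
#'   and `design` (tibble).
#' @export
read_counts <- function(path, design_path) {
  counts <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  design <- readr::read_tsv(design_path, show_col_types = FALSE,
                            progress = FALSE)
  check_design(design)
  if (names(counts)[1] != "gene_id") names(counts)[1] <- "gene_id"
  missing <- setdiff(design$sample_id, names(counts))
  if (length(missing) > 0) {
    abort(paste0("design samples missing from counts: ",
                 paste(missing, collapse = ", ")))
  }
  vals <- as.matrix(counts[design$sample_id])
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals != round(vals))) {
    abort("counts must be non-negative integers")
  }
  counts <- counts[, c("gene_id", design$sample_id)]
  list(counts = counts, design = design)
}

#' Write a count matrix and design to TSV
#'
#' @param counts Count tibble (`gene_id` + sample columns).
#' @param design Sample design tibble.
#' @param counts_path,design_path Output paths.
#' @return `counts_path`, invisibly.
#' @export
write_counts <- function(counts, design, counts_path, design_path) {
  readr::write_tsv(counts, counts_path, progress = FALSE)
  readr::write_tsv(design, design_path, progress = FALSE)
  invisible(counts_path)
}
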