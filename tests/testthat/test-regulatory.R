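# One-gene annotation helper (1-based inclusive coordinates).
one_gene <- function(tss = 10000, strand = "+", len = 2000,
                     chrom = "chr1", gene_id = "g1") {
  if (strand == "+") {
    start <- tss
    end <- tss + len - 1
  } else {
    end <- tss
    start <- tss - len + 1
  }
  tibble::tibble(gene_id = gene_id, chrom = chrom, start = start, end = end,
                 strand = strand, tss = tss, length = len)
}

peak_at <- function(mid, width = 200, chrom = "chr1", id = "p1") {
  tibble::tibble(peak_id = id, chrom = chrom,
                 start = mid - width %/% 2, end = mid + width %/% 2,
                 score = 1)
}

test_that("TSS-window assignment is inclusive at the boundary", {
  ann <- one_gene(10000, "+")
  near <- assign_peaks_to_targets(peak_at(8500), ann)
  expect_equal(near$assignments$gene_id, "g1")
  expect_equal(abs(near$assignments$distance), 1499)

  boundary <- assign_peaks_to_targets(peak_at(9999 - 3000), ann)
  expect_equal(nrow(boundary$assignments), 1)      # exactly 3000: assigned
  outside <- assign_peaks_to_targets(peak_at(9999 - 3001), ann)
  expect_equal(nrow(outside$assignments), 0)       # 3001: strict window

  spanning <- assign_peaks_to_targets(peak_at(10000), ann)
  expect_equal(nrow(spanning$assignments), 1)

  expect_error(assign_peaks_to_targets(peak_at(100, chrom = "chrX"), ann),
               "chrX")
})

test_that("assignment equals the brute-force all-pairs scan", {
  cfg <- sim_config(n_genes = 300, module_sizes = integer(0),
                    n_chromosomes = 3, chrom_length = 8e5)
  ann <- generate_annotation(cfg, seed = 13)$annotation
  set.seed(13)
  n <- 500
  peaks <- tibble::tibble(
    peak_id = paste0("p", seq_len(n)),
    chrom = sample(paste0("chr", 1:3), n, TRUE),
    start = sample.int(8e5 - 300, n))
  peaks$end <- peaks$start + 200L
  peaks$score <- 1
  fast <- assign_peaks_to_targets(peaks, ann)$assignments

  brute <- list()
  for (i in seq_len(n)) {
    mid <- floor((peaks$start[i] + peaks$end[i]) / 2)
    for (j in seq_len(nrow(ann))) {
      if (peaks$chrom[i] != ann$chrom[j]) next
      if (abs(mid - (ann$tss[j] - 1)) <= 3000) {
        brute[[length(brute) + 1]] <-
          paste(peaks$peak_id[i], ann$gene_id[j])
      }
    }
  }
  expect_setequal(paste(fast$peak_id, fast$gene_id), unlist(brute))
})

test_that("every peak gets exactly one location category, in rule order", {
  ann <- dplyr::bind_rows(
    one_gene(10000, "+", len = 20000, gene_id = "gA"),
    one_gene(60000, "-", len = 2000, chrom = "chr1", gene_id = "gB"))
  picks <- dplyr::bind_rows(
    peak_at(9500, id = "prom1k"),        # 499 bp from gA TSS
    peak_at(12500, id = "prom3k"),       # 2501 bp from TSS, inside body
    peak_at(25000, id = "genic"),        # in gA body, > 3 kb from both TSS
    peak_at(200000, id = "distal"),      # far from everything
    peak_at(56500, id = "near_gB")       # 3.5 kb upstream-of-TSS side of gB
  )
  out <- classify_peak_locations(picks, ann)
  expect_equal(out$location[out$peak_id == "prom1k"], "promoter1k")
  expect_equal(out$location[out$peak_id == "prom3k"], "promoter3k")
  expect_equal(out$location[out$peak_id == "genic"], "genic")
  expect_equal(out$location[out$peak_id == "distal"], "distal_intergenic")

  # category partition property on generated data
  cfg <- sim_config(n_genes = 150, module_sizes = integer(0),
                    n_chromosomes = 2, chrom_length = 6e5)
  ann2 <- generate_annotation(cfg, seed = 10)$annotation
  pk <- generate_peaks(cfg, ann2, seed = 10)
  all_peaks <- dplyr::bind_rows(pk$dap)
  got <- classify_peak_locations(all_peaks, ann2)
  expect_true(all(got$location %in%
    c("promoter1k", "promoter3k", "genic", "distal_intergenic", "other")))
  expect_equal(nrow(got), nrow(all_peaks))

  expect_error(classify_peak_locations(picks, ann[0, ]), "empty")
})

test_that("consensus scanning is degenerate, stranded, and validated", {
  g <- Biostrings::DNAStringSet(c(chr1 = "TTTGTCCTAAAATTTGTCAT"))
  hits <- scan_consensus_sites(g, "TTTGTC[CT]T")
  expect_equal(hits$n_sites, 1)          # TTTGTCAT does not match (A not in YT)
  expect_equal(hits$sites$strand, "+")
  expect_equal(hits$sites$start, 0)

  rc <- Biostrings::DNAStringSet(c(chr1 = "CCCAAGACAAACCC"))
  hits_rc <- scan_consensus_sites(rc, "TTTGTC[CT]T")
  expect_equal(hits_rc$n_sites, 1)
  expect_equal(hits_rc$sites$strand, "-")

  expect_error(scan_consensus_sites(c(chr1 = "ACGTQACGT")), "position 5")
})

test_that("site counts are strand-symmetric under reverse complement", {
  set.seed(77)
  s <- paste(sample(c("A", "C", "G", "T"), 20000, TRUE), collapse = "")
  fwd <- Biostrings::DNAStringSet(stats::setNames(s, "chr1"))
  rev <- Biostrings::DNAStringSet(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s))))
  names(rev) <- "chr1"
  expect_equal(scan_consensus_sites(fwd)$n_sites,
               scan_consensus_sites(rev)$n_sites)
})

test_that("motif sites near TSS are summarized per gene", {
  cfg <- sim_config(n_genes = 60, module_sizes = integer(0),
                    n_chromosomes = 2, chrom_length = 2e5)
  gen <- generate_annotation(cfg, seed = 5)
  res <- scan_consensus_sites(gen$genome, annotation = gen$annotation)
  expect_true(res$n_sites > 0)
  expect_true(res$fraction_near_tss >= 0 && res$fraction_near_tss <= 1)
  expect_true(all(res$per_gene$n_sites >= 1))
})

test_that("direct-target calling matches the enumeration oracle", {
  universe <- paste0("g", 1:10)
  bound <- list(tf1 = paste0("g", 1:4))
  degs <- list(mutA = paste0("g", c(1, 2, 3, 7, 8)))
  out <- call_direct_targets(bound, degs, universe)
  expect_equal(out$overlap, 3)
  expect_equal(out$p, 66 / 252, tolerance = 1e-12)
  expect_equal(out$p, hyper_oracle(10, 4, 5, 3), tolerance = 1e-12)
  expect_setequal(out$targets[[1]], paste0("g", 1:3))

  disj <- call_direct_targets(list(tf1 = paste0("g", 1:4)),
                              list(m = paste0("g", 5:6)), universe)
  expect_equal(disj$overlap, 0)
  expect_equal(disj$p, 1)

  empty <- call_direct_targets(bound, list(m = character(0)), universe)
  expect_equal(empty$p, 1)
  expect_false(empty$significant)
})

test_that("differential accessibility finds planted opening peaks", {
  cfg <- sim_config(
    n_genes = 80, module_sizes = integer(0), n_chromosomes = 2,
    chrom_length = 5e5, n_accessibility_peaks = 120,
    accessibility_effects = tibble::tibble(
      locus = "nkd1", n_peaks = 25, log2fc = 1.5, location = "promoter"))
  gen <- generate_annotation(cfg, seed = 30)
  pk <- generate_peaks(cfg, gen$annotation, seed = 30, n_acc_replicates = 3)
  res <- differential_accessibility(pk$atac, pk$atac_design, "nkd1",
                                    annotation = gen$annotation)
  planted <- pk$atac_truth$peak_id
  expect_gte(mean(res$direction[res$peak_id %in% planted] == "up"), 0.7)
  expect_true(all(res$location[res$peak_id %in% planted] == "promoter"))
  # null peaks stay mostly unflagged
  expect_lte(mean(res$direction[!res$peak_id %in% planted] != "ns"), 0.08)
})

test_that("peak overlap uses half-open, per-chromosome intersection", {
  a <- tibble::tibble(peak_id = c("a1", "a2", "a3"),
                      chrom = c("chr1", "chr1", "chr2"),
                      start = c(0L, 0L, 0L), end = c(100L, 100L, 100L),
                      score = 1)
  b <- tibble::tibble(peak_id = c("b1", "b2"), chrom = "chr1",
                      start = c(99L, 100L), end = c(200L, 200L), score = 1)
  ov <- overlap_peak_sets(a, b)
  expect_equal(ov$pairs$peak_id_a, c("a1", "a2"))
  expect_true(all(ov$pairs$peak_id_b == "b1"))
  expect_equal(ov$n_a_overlapping, 2)
  expect_equal(ov$n_b_overlapping, 1)
})
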