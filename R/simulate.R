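#' Simulation configuration for the factorial endosperm design
#'
#' Collects the parameters of the synthetic multi-omic generator: an
#' 8-genotype (three biallelic loci: nkd1, nkd2, o2) by multi-timepoint
#' factorial RNA-seq design with planted coexpression modules,
#' negative-binomial noise, TF main and interaction effects, and TF binding
#' peaks placed near target TSSs.
#'
#' @param n_genes Number of genes.
#' @param module_sizes Integer vector of planted module sizes (may be empty
#'   for a null, module-free dataset); their sum must not exceed `n_genes`.
#' @param n_replicates Biological replicates per genotype-timepoint cell.
#' @param timepoints Ordered timepoint labels (days after pollination).
#' @param loci Names of the three mutant loci.
#' @param baseline_log2_mean_range Range of per-gene baseline log2 mean counts.
#' @param main_effects Tibble (`locus`, `module`, `timepoint`, `log2fc`)
#'   of planted main effects; `timepoint = NA` applies to all timepoints.
#' @param interaction_effects Tibble (`locus_a`, `locus_b`, `module`,
#'   `timepoint`, `log2fc`) of planted interaction effects.  A composite
#'   factor is written `"nkd1+nkd2"`.
#' @param loadings_range Range in (0, 1] for module loadings.
#' @param trajectory_sd Standard deviation of the latent per-(genotype,
#'   timepoint) module trajectory draws; 0 disables latent module dynamics.
#' @param dispersion Per-gene NB dispersion alpha (scalar, recycled).
#' @param library_size_range Range of per-sample library size factors
#'   (drawn log-uniform).
#' @param bound_fraction Fraction of genes with a planted binding peak per TF.
#' @param n_chromosomes,chrom_length Genome layout for the synthetic
#'   annotation.
#' @param peak_width Width (bp) of generated peaks.
#' @param decoy_peak_fraction Fraction of peaks placed > 3 kb from any TSS.
#' @param n_accessibility_peaks Number of chromatin-accessibility peaks.
#' @param accessibility_effects Tibble (`locus`, `n_peaks`, `log2fc`,
#'   `location`) of planted accessibility shifts (`location` is `"promoter"`
#'   or `"distal"`).
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_genes = 2000,
                       module_sizes = c(400, 300, 250, 200, 150),
                       n_replicates = 4,
                       timepoints = c(8, 12, 16),
                       loci = c("nkd1", "nkd2", "o2"),
                       baseline_log2_mean_range = c(3, 9),
                       main_effects = NULL,
                       interaction_effects = NULL,
                       loadings_range = c(0.7, 0.95),
                       trajectory_sd = 1,
                       dispersion = 0.05,
                       library_size_range = c(0.7, 1.4),
                       bound_fraction = 0.1,
                       n_chromosomes = 10,
                       chrom_length = 1e6,
                       peak_width = 200,
                       decoy_peak_fraction = 0.2,
                       n_accessibility_peaks = 200,
                       accessibility_effects = NULL) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    module_sizes = as.integer(module_sizes),
    n_replicates = as.integer(n_replicates),
    timepoints = timepoints,
    loci = loci,
    baseline_log2_mean_range = baseline_log2_mean_range,
    main_effects = main_effects %||%
      tibble(locus = character(), module = integer(),
             timepoint = double(), log2fc = double()),
    interaction_effects = interaction_effects %||%
      tibble(locus_a = character(), locus_b = character(),
             module = integer(), timepoint = double(), log2fc = double()),
    loadings_range = loadings_range,
    trajectory_sd = trajectory_sd,
    dispersion = dispersion,
    library_size_range = library_size_range,
    bound_fraction = bound_fraction,
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    peak_width = as.integer(peak_width),
    decoy_peak_fraction = decoy_peak_fraction,
    n_accessibility_peaks = as.integer(n_accessibility_peaks),
    accessibility_effects = accessibility_effects %||%
      tibble(locus = character(), n_peaks = integer(),
             log2fc = double(), location = character())
  )
  if (sum(cfg$module_sizes) > cfg$n_genes) {
    abort("sum(module_sizes) must not exceed n_genes")
  }
  fr <- c(cfg$bound_fraction, cfg$decoy_peak_fraction)
  if (any(fr < 0 | fr > 1)) abort("fractions must lie in [0, 1]")
  if (any(cfg$dispersion < 0)) abort("dispersion must be >= 0")
  if (is.unsorted(cfg$timepoints, strictly = TRUE)) {
    abort("timepoints must be strictly ordered")
  }
  if (any(cfg$loadings_range <= 0 | cfg$loadings_range > 1)) {
    abort("loadings_range must lie in (0, 1]")
  }
  structure(cfg, class = c("sim_config", "list"))
}

#' Generate the fully crossed factorial sample design
#'
#' All 2^3 = 8 genotypes of the three loci at every timepoint, with an equal
#' number of replicates per cell (e.g. 8 genotypes x 3 timepoints x 4
#' replicates = 96 samples).
#'
#' @param n_replicates Replicates per genotype-timepoint cell (>= 2; with a
#'   single replicate per cell the residual variance is inestimable).
#' @param timepoints Ordered timepoint labels.
#' @return Tibble with `sample_id`, the three 0/1 mutant indicators `nkd1`,
#'   `nkd2`, `o2` (0 = wild-type allele), `genotype` label, `timepoint`,
#'   `replicate`.
#' @export
generate_design <- function(n_replicates = 4, timepoints = c(8, 12, 16)) {
  if (n_replicates < 2) {
    abort("n_replicates must be >= 2 (variance inestimable otherwise)")
  }
  design <- crossing(
    nkd1 = 0:1, nkd2 = 0:1, o2 = 0:1,
    timepoint = timepoints, replicate = seq_len(n_replicates)
  )
  design <- mutate(design,
    genotype = genotype_label(.data$nkd1, .data$nkd2, .data$o2),
    sample_id = paste0(gsub(" ", "_", .data$genotype), "_t", .data$timepoint,
                       "_r", .data$replicate)
  )
  select(design, "sample_id", "nkd1", "nkd2", "o2", "genotype",
         "timepoint", "replicate")
}

#' Generate a synthetic gene annotation and genome
#'
#' Places non-overlapping genes (lengths uniform in 500-5000 bp, random
#' strand) on the configured chromosomes and generates random nucleotide
#' sequences. Consensus binding sites can be planted later by the peak
#' generator; the genome here is i.i.d. ACGT.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List with `annotation` (tibble: `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `tss`, `length`; 1-based inclusive) and `genome`
#'   (named `Biostrings::DNAStringSet`).
#' @export
generate_annotation <- function(config, seed = 1) {
  set.seed(split_seed(seed, "annotation"))
  n <- config$n_genes
  lens <- as.integer(round(runif(n, 500, 5000)))
  per_chrom <- ceiling(n / config$n_chromosomes)
  chrom_of <- rep(seq_len(config$n_chromosomes), each = per_chrom)[seq_len(n)]
  ann <- vector("list", config$n_chromosomes)
  for (ch in seq_len(config$n_chromosomes)) {
    idx <- which(chrom_of == ch)
    if (length(idx) == 0) next
    gap_total <- config$chrom_length - sum(lens[idx])
    if (gap_total < length(idx) + 1) {
      abort("genome too small to place genes without overlap")
    }
    gaps <- as.vector(stats::rmultinom(1, gap_total - (length(idx) + 1),
                                       rep(1, length(idx) + 1))) + 1L
    starts <- cumsum(gaps[seq_along(idx)]) +
      cumsum(c(0L, lens[idx][-length(idx)])) + 1L
    ann[[ch]] <- tibble(
      gene_id = sprintf("gene_%04d", idx),
      chrom = paste0("chr", ch),
      start = as.integer(starts),
      end = as.integer(starts + lens[idx] - 1L),
      strand = sample(c("+", "-"), length(idx), replace = TRUE)
    )
  }
  annotation <- bind_rows(ann)
  annotation <- mutate(annotation,
    tss = as.integer(ifelse(.data$strand == "+", .data$start, .data$end)),
    length = as.integer(.data$end - .data$start + 1L)
  )
  genome <- Biostrings::DNAStringSet(vapply(
    seq_len(config$n_chromosomes),
    function(i) paste(sample(c("A", "C", "G", "T"), config$chrom_length,
                             replace = TRUE), collapse = ""),
    character(1)
  ))
  names(genome) <- paste0("chr", seq_len(config$n_chromosomes))
  list(annotation = annotation, genome = genome)
}

# Planted log2 effect matrix (gene x sample) from the config's effect maps
# plus latent module trajectories. Returns list(log2fc = matrix, truth pieces).
build_signal <- function(config, design, module_of, loadings) {
  n <- config$n_genes
  s <- nrow(design)
  eff <- matrix(0, n, s)
  x <- as.matrix(design[, config$loci])

  apply_rows <- function(genes, xvec, tp, lfc) {
    sel <- if (is.na(tp)) rep(TRUE, s) else design$timepoint == tp
    eff[genes, sel] <<- eff[genes, sel] +
      outer(rep(lfc, length(genes)), xvec[sel])
  }
  truth_fc <- list()
  me <- config$main_effects
  for (i in seq_len(nrow(me))) {
    if (!me$locus[i] %in% config$loci) abort("main effect on unknown locus")
    genes <- which(module_of == me$module[i])
    if (length(genes) == 0) abort("main effect on unknown/empty module")
    apply_rows(genes, x[, me$locus[i]], me$timepoint[i], me$log2fc[i])
    truth_fc[[length(truth_fc) + 1]] <- tibble(
      gene_id = sprintf("gene_%04d", genes),
      contrast = me$locus[i], timepoint = me$timepoint[i],
      log2fc = me$log2fc[i], kind = "main"
    )
  }
  ie <- config$interaction_effects
  interaction_affected <- list()
  for (i in seq_len(nrow(ie))) {
    xa <- composite_indicator(design, ie$locus_a[i], config$loci)
    xb <- composite_indicator(design, ie$locus_b[i], config$loci)
    genes <- which(module_of == ie$module[i])
    if (length(genes) == 0) abort("interaction effect on unknown/empty module")
    apply_rows(genes, xa * xb, ie$timepoint[i], ie$log2fc[i])
    truth_fc[[length(truth_fc) + 1]] <- tibble(
      gene_id = sprintf("gene_%04d", genes),
      contrast = paste0(ie$locus_a[i], ":", ie$locus_b[i]),
      timepoint = ie$timepoint[i], log2fc = ie$log2fc[i], kind = "interaction"
    )
    interaction_affected[[paste0(ie$locus_a[i], ":", ie$locus_b[i], "@",
                                 ie$timepoint[i])]] <-
      sprintf("gene_%04d", genes)
  }

  n_mod <- length(config$module_sizes)
  if (n_mod > 0 && config$trajectory_sd > 0) {
    cells <- distinct(design, .data$genotype, .data$timepoint)
    traj <- matrix(rnorm(n_mod * nrow(cells), sd = config$trajectory_sd),
                   n_mod, nrow(cells))
    cell_of <- match(paste(design$genotype, design$timepoint),
                     paste(cells$genotype, cells$timepoint))
    for (m in seq_len(n_mod)) {
      genes <- which(module_of == m)
      eff[genes, ] <- eff[genes, ] +
        outer(loadings[genes], traj[m, cell_of])
    }
  }
  list(log2fc = eff,
       true_log2fc = bind_rows(truth_fc),
       interaction_affected = interaction_affected)
}

# 0/1 indicator for a (possibly composite, "nkd1+nkd2") factor.
composite_indicator <- function(design, factor, loci) {
  parts <- strsplit(factor, "+", fixed = TRUE)[[1]]
  if (!all(parts %in% loci)) abort(paste0("unknown locus in factor ", factor))
  ind <- rep(1, nrow(design))
  for (p in parts) ind <- ind * design[[p]]
  ind
}

#' Generate a factorial count matrix with ground truth
#'
#' Samples gene-level counts `c_gs ~ NB(mean = L_s * 2^(b_g + planted
#' effects + loading_g * trajectory), dispersion alpha_g)` where `L_s` is a
#' log-uniform library factor, `b_g` a uniform baseline log2 mean, planted
#' effects come from the config's main/interaction effect maps, and each
#' planted module has a latent per-(genotype, timepoint) trajectory shared by
#' its genes (scaled by per-gene loadings).
#'
#' @param config A [sim_config()].
#' @param design Design from [generate_design()].
#' @param seed Integer seed.
#' @return List with `counts` (tibble, `gene_id` + one column per sample) and
#'   `truth` (list: `module_of` tibble, `true_log2fc`,
#'   `interaction_affected`, `library_factors`, `baseline_log2`,
#'   `loadings`).
#' @export
generate_counts <- function(config, design, seed = 1) {
  check_design(design)
  set.seed(split_seed(seed, "counts"))
  n <- config$n_genes
  s <- nrow(design)
  gene_ids <- sprintf("gene_%04d", seq_len(n))

  module_of <- integer(n)
  if (length(config$module_sizes) > 0) {
    pool <- sample.int(n)
    off <- 0L
    for (m in seq_along(config$module_sizes)) {
      module_of[pool[(off + 1):(off + config$module_sizes[m])]] <- m
      off <- off + config$module_sizes[m]
    }
  }
  loadings <- ifelse(module_of > 0,
                     runif(n, config$loadings_range[1],
                           config$loadings_range[2]), 0)
  b <- runif(n, config$baseline_log2_mean_range[1],
             config$baseline_log2_mean_range[2])
  lsr <- log(config$library_size_range)
  lib <- exp(runif(s, lsr[1], lsr[2]))

  sig <- build_signal(config, design, module_of, loadings)
  mu <- sweep(2^(b + sig$log2fc), 2, lib, `*`)
  alpha <- rep(config$dispersion, length.out = n)
  counts <- matrix(0, n, s)
  for (g in seq_len(n)) {
    counts[g, ] <- if (alpha[g] < 1e-12) rpois(s, mu[g, ]) else
      rnbinom(s, mu = mu[g, ], size = 1 / alpha[g])
  }
  dimnames(counts) <- list(gene_ids, design$sample_id)

  truth <- list(
    module_of = tibble(gene_id = gene_ids, module = module_of,
                       loading = loadings),
    true_log2fc = sig$true_log2fc,
    interaction_affected = sig$interaction_affected,
    library_factors = setNames(lib, design$sample_id),
    baseline_log2 = setNames(b, gene_ids)
  )
  list(counts = matrix_to_tibble(counts), truth = truth)
}

#' Generate TF binding peaks and accessibility peaks
#'
#' For each locus TF, a `bound_fraction` of genes is drawn as planted targets
#' and each target receives one peak whose midpoint lies within 3 kb of its
#' TSS; a `decoy_peak_fraction` of each TF's peaks is placed with midpoints
#' more than 3 kb from every TSS. Accessibility peaks carry per-sample counts
#' (8 genotypes x `n_acc_replicates`) with planted genotype-dependent shifts.
#'
#' @param config A [sim_config()].
#' @param annotation Annotation tibble from [generate_annotation()].
#' @param seed Integer seed.
#' @param n_acc_replicates Accessibility replicates per genotype.
#' @return List with `dap` (named list of peak tibbles per TF), `atac`
#'   (peak tibble with per-sample count columns), `atac_design`,
#'   `tf_targets` (named list of gene-id vectors), `peak_links` (tibble
#'   peak_id, tf, gene_id, distance) and `atac_truth` (tibble of planted
#'   differential peaks).
#' @export
generate_peaks <- function(config, annotation, seed = 1,
                           n_acc_replicates = 2) {
  set.seed(split_seed(seed, "peaks"))
  if (config$peak_width > config$chrom_length) {
    abort("peak_width exceeds chrom_length")
  }
  half <- config$peak_width %/% 2
  window <- 3000L

  decoy_positions <- function(k) {
    # rejection-sample midpoints > 3 kb from every TSS
    out <- tibble(chrom = character(), mid = integer())
    while (nrow(out) < k) {
      chrom <- paste0("chr", sample.int(config$n_chromosomes, 2 * k + 10,
                                        replace = TRUE))
      mid <- as.integer(round(runif(2 * k + 10, half + 1,
                                    config$chrom_length - half - 1)))
      cand <- tibble(chrom = chrom, mid = mid)
      ok <- vapply(seq_len(nrow(cand)), function(i) {
        tss <- annotation$tss[annotation$chrom == cand$chrom[i]]
        length(tss) == 0 || min(abs(cand$mid[i] - tss)) > window
      }, logical(1))
      out <- bind_rows(out, cand[ok, ])
    }
    out[seq_len(k), ]
  }

  dap <- list()
  tf_targets <- list()
  links <- list()
  for (tf in config$loci) {
    n_tgt <- round(config$bound_fraction * config$n_genes)
    targets <- sort(sample.int(config$n_genes, n_tgt))
    tgt_ann <- annotation[match(sprintf("gene_%04d", targets),
                                annotation$gene_id), ]
    if (config$decoy_peak_fraction >= 1) {
      dec <- decoy_positions(max(n_tgt, 1))
      peaks <- tibble(
        peak_id = paste0(tf, "_decoy_", seq_len(nrow(dec))),
        chrom = dec$chrom,
        start = as.integer(dec$mid - half),
        end = as.integer(dec$mid + half),
        score = runif(nrow(dec), 10, 100)
      )
      dap[[tf]] <- peaks
      tf_targets[[tf]] <- character(0)
      next
    }
    if (n_tgt > 0) {
      # place each peak within the target's TSS window, resampling so it
      # avoids every other gene's window; unavoidable neighbours become
      # targets too, keeping the recovered set equal to the truth
      mid <- integer(n_tgt)
      extra <- list()
      for (i in seq_len(n_tgt)) {
        tss0 <- tgt_ann$tss[i] - 1L
        ann_ch <- annotation[annotation$chrom == tgt_ann$chrom[i] &
                               annotation$gene_id != tgt_ann$gene_id[i], ]
        other <- ann_ch$tss - 1L
        for (try in 1:100) {
          cand <- tss0 + as.integer(round(runif(1, -(window - half - 1),
                                                window - half - 1)))
          cand <- min(max(cand, half + 1L), config$chrom_length - half - 1L)
          if (abs(cand - tss0) <= window &&
              (length(other) == 0 || min(abs(cand - other)) > window)) break
        }
        mid[i] <- cand
        hit <- which(abs(cand - other) <= window)
        if (length(hit) > 0) {
          extra[[length(extra) + 1]] <- tibble(
            peak_id = paste0(tf, "_peak_", i),
            chrom = tgt_ann$chrom[i],
            gene_id = ann_ch$gene_id[hit],
            distance = as.integer(cand - other[hit])
          )
        }
      }
      planted <- tibble(
        peak_id = paste0(tf, "_peak_", seq_len(n_tgt)),
        chrom = tgt_ann$chrom,
        start = as.integer(mid - half),
        end = as.integer(mid + half),
        score = runif(n_tgt, 10, 100)
      )
      links[[tf]] <- bind_rows(
        tibble(peak_id = planted$peak_id, tf = tf,
               gene_id = tgt_ann$gene_id,
               distance = as.integer(mid - (tgt_ann$tss - 1L))),
        if (length(extra) > 0) {
          mutate(bind_rows(extra), tf = tf)[, c("peak_id", "tf", "gene_id",
                                                "distance")]
        }
      )
    } else {
      planted <- tibble(peak_id = character(), chrom = character(),
                        start = integer(), end = integer(), score = double())
    }
    f <- config$decoy_peak_fraction
    n_decoy <- if (f > 0 && n_tgt > 0) round(f / (1 - f) * n_tgt) else 0
    if (n_decoy > 0) {
      dec <- decoy_positions(n_decoy)
      planted <- bind_rows(planted, tibble(
        peak_id = paste0(tf, "_decoy_", seq_len(n_decoy)),
        chrom = dec$chrom,
        start = as.integer(dec$mid - half),
        end = as.integer(dec$mid + half),
        score = runif(n_decoy, 10, 100)
      ))
    }
    dap[[tf]] <- planted
    tf_targets[[tf]] <- unique(links[[tf]]$gene_id)
  }

  # accessibility peaks: half promoter-anchored, half distal decoys
  n_acc <- config$n_accessibility_peaks
  acc_design <- crossing(nkd1 = 0:1, nkd2 = 0:1, o2 = 0:1,
                         replicate = seq_len(n_acc_replicates))
  acc_design <- mutate(acc_design,
    genotype = genotype_label(.data$nkd1, .data$nkd2, .data$o2),
    sample_id = paste0("atac_", gsub(" ", "_", .data$genotype), "_r",
                       .data$replicate))
  acc_design <- select(acc_design, "sample_id", "nkd1", "nkd2", "o2",
                       "genotype", "replicate")
  n_prom <- n_acc %/% 2
  prom_genes <- sample.int(nrow(annotation), n_prom, replace = n_prom >
                             nrow(annotation))
  prom_mid <- pmin(pmax(annotation$tss[prom_genes] - 1L +
                          as.integer(round(runif(n_prom, -1500, 1500))),
                        half + 1L), config$chrom_length - half - 1L)
  dec <- decoy_positions(n_acc - n_prom)
  atac <- tibble(
    peak_id = paste0("acc_", seq_len(n_acc)),
    chrom = c(annotation$chrom[prom_genes], dec$chrom),
    start = as.integer(c(prom_mid, dec$mid) - half),
    end = as.integer(c(prom_mid, dec$mid) + half),
    score = runif(n_acc, 10, 100)
  )
  base <- runif(n_acc, 4, 8)  # log2 baseline accessibility
  eff <- matrix(0, n_acc, nrow(acc_design))
  ae <- config$accessibility_effects
  atac_truth <- list()
  prom_pool <- seq_len(n_prom)
  dist_pool <- seq(n_prom + 1, n_acc)
  for (i in seq_len(nrow(ae))) {
    pool <- if (ae$location[i] == "promoter") prom_pool else dist_pool
    pick <- pool[seq_len(min(ae$n_peaks[i], length(pool)))]
    pool_rest <- setdiff(pool, pick)
    if (ae$location[i] == "promoter") prom_pool <- pool_rest else
      dist_pool <- pool_rest
    xv <- composite_indicator(acc_design, ae$locus[i], config$loci)
    eff[pick, ] <- eff[pick, ] + outer(rep(ae$log2fc[i], length(pick)), xv)
    atac_truth[[i]] <- tibble(peak_id = atac$peak_id[pick],
                              locus = ae$locus[i], log2fc = ae$log2fc[i],
                              location = ae$location[i])
  }
  mu <- 2^(base + eff)
  acc_counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / 0.05),
                       nrow(mu), ncol(mu))
  colnames(acc_counts) <- acc_design$sample_id
  atac <- bind_cols(atac, as_tibble(acc_counts))

  list(dap = dap, atac = atac, atac_design = acc_design,
       tf_targets = tf_targets,
       peak_links = bind_rows(links),
       atac_truth = bind_rows(atac_truth))
}

#' Generate a complete synthetic experiment
#'
#' Convenience wrapper running [generate_design()], [generate_annotation()],
#' [generate_counts()] and [generate_peaks()] under one seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List with `design`, `annotation`, `genome`, `counts`, `truth`,
#'   `peaks`.
#' @export
simulate_experiment <- function(config = sim_config(), seed = 1) {
  design <- generate_design(config$n_replicates, config$timepoints)
  ann <- generate_annotation(config, seed)
  cnt <- generate_counts(config, design, seed)
  peaks <- generate_peaks(config, ann$annotation, seed)
  list(design = design, annotation = ann$annotation, genome = ann$genome,
       counts = cnt$counts, truth = cnt$truth, peaks = peaks)
}

#' Write a simulated experiment to disk
#'
#' Writes counts TSV, design TSV, gene-only GFF3, BED6 per DAP peak set,
#' accessibility BED with count columns, FASTA genome, and ground-truth JSON.
#'
#' @param experiment Result of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(experiment$counts, experiment$design,
               file.path(dir, "counts.tsv"), file.path(dir, "design.tsv"))
  write_gff3_annotation(experiment$annotation, file.path(dir, "genes.gff3"))
  for (tf in names(experiment$peaks$dap)) {
    write_bed_peaks(experiment$peaks$dap[[tf]],
                    file.path(dir, paste0("dap_", tf, ".bed")))
  }
  acc_cols <- experiment$peaks$atac_design$sample_id
  write_bed_peaks(experiment$peaks$atac, file.path(dir, "atac.bed"),
                  count_cols = acc_cols)
  readr::write_tsv(experiment$peaks$atac_design,
                   file.path(dir, "atac_design.tsv"), progress = FALSE)
  Biostrings::writeXStringSet(experiment$genome,
                              file.path(dir, "genome.fasta"))
  truth <- experiment$truth
  truth$library_factors <- as.list(truth$library_factors)
  truth$baseline_log2 <- as.list(truth$baseline_log2)
  jsonlite::write_json(
    list(module_of = truth$module_of, true_log2fc = truth$true_log2fc,
         interaction_affected = truth$interaction_affected,
         tf_targets = experiment$peaks$tf_targets,
         peak_links = experiment$peaks$peak_links),
    file.path(dir, "ground_truth.json"))
  invisible(dir)
}
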