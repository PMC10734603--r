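test_that("median-of-ratios size factors match closed forms", {
  m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  sf <- size_factors_median_ratio(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))

  ident <- cbind(s1 = c(5, 8, 2), s2 = c(5, 8, 2), s3 = c(5, 8, 2))
  rownames(ident) <- paste0("g", 1:3)
  expect_equal(unname(size_factors_median_ratio(ident)), rep(1, 3))

  zero <- cbind(s1 = c(0, 0), s2 = c(1, 1))
  rownames(zero) <- c("g1", "g2")
  expect_error(size_factors_median_ratio(zero), "all-zero")
})

test_that("TPM follows the definition and handles degenerate input", {
  m <- matrix(c(10, 20), ncol = 1, dimnames = list(c("g1", "g2"), "s1"))
  tpm <- compute_tpm(m, c(g1 = 1000, g2 = 2000))
  expect_equal(tpm$s1, c(5e5, 5e5))

  single <- matrix(7, 1, 1, dimnames = list("g1", "s1"))
  expect_equal(compute_tpm(single, c(g1 = 100))$s1, 1e6)

  zero <- matrix(c(5, 0, 5, 0), 2, 2,
                 dimnames = list(c("g1", "g2"), c("s1", "s2")))
  zero[, 2] <- 0
  out <- compute_tpm(zero, c(g1 = 100, g2 = 100))
  expect_equal(out$s2, c(0, 0))
  expect_error(compute_tpm(m, c(g1 = 0, g2 = 2000)), "positive")

  # columns sum to 1e6
  set.seed(2)
  big <- matrix(rpois(200, 60), 20, 10,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  lens <- setNames(sample(500:5000, 20), rownames(big))
  tot <- colSums(as.matrix(compute_tpm(big, lens)[, -1]))
  expect_equal(unname(tot), rep(1e6, 10), tolerance = 1e-9)
})

test_that("dispersion estimation recovers known alpha and shrinks to trend", {
  set.seed(31)
  n <- 400
  groups <- rep(1:8, each = 6)  # 48 samples
  mu <- 100
  pois <- matrix(rpois(n * 48, mu), n, 48,
                 dimnames = list(paste0("g", 1:n), paste0("s", 1:48)))
  dp <- estimate_dispersions(pois, groups)
  expect_lte(median(dp$shrunken), 0.02)

  nb <- matrix(rnbinom(n * 48, mu = mu, size = 5), n, 48,
               dimnames = dimnames(pois))
  dn <- estimate_dispersions(nb, groups)
  expect_gte(median(dn$shrunken), 0.1)
  expect_lte(median(dn$shrunken), 0.3)

  # shrunken lies between raw and trend
  between <- (dn$shrunken >= pmin(dn$raw, dn$trend) - 1e-12) &
    (dn$shrunken <= pmax(dn$raw, dn$trend) + 1e-12)
  expect_true(all(between))

  const <- matrix(5, 3, 8, dimnames = list(paste0("g", 1:3),
                                           paste0("s", 1:8)))
  dc <- estimate_dispersions(const, rep(1:2, each = 4),
                             size_factors = rep(1, 8))
  expect_equal(dc$raw, rep(0, 3))

  expect_error(estimate_dispersions(pois[, 1:4], 1:4), "replicates")
})

test_that("NB GLM matches the Poisson closed form and flags degeneracy", {
  y <- c(rep(10, 4), rep(40, 4))
  X <- cbind(intercept = 1, group = rep(0:1, each = 4))
  f <- fit_nb_glm(y, X, alpha = 0)
  expect_equal(f$log2fc[f$term == "group"], 2, tolerance = 1e-6)

  f0 <- fit_nb_glm(rep(15, 8), X, alpha = 0.1)
  expect_equal(f0$log2fc[f0$term == "group"], 0, tolerance = 1e-6)
  expect_gte(f0$p[f0$term == "group"], 0.99)

  fi <- fit_nb_glm(c(3, 5, 7, 9), cbind(intercept = rep(1, 4)), alpha = 0)
  expect_equal(2^fi$log2fc, mean(c(3, 5, 7, 9)), tolerance = 1e-6)

  # Poisson limit: alpha -> 0 converges to the Poisson fit
  set.seed(8)
  y2 <- rpois(8, lambda = rep(c(20, 55), each = 4))
  fa <- fit_nb_glm(y2, X, alpha = 1e-10)
  fb <- fit_nb_glm(y2, X, alpha = 0)
  expect_lt(max(abs(fa$log2fc - fb$log2fc)), 0.01)

  # separation: one cell all zero
  fs <- fit_nb_glm(c(0, 0, 0, 0, 9, 11, 10, 12), X, alpha = 0.05)
  expect_true(fs$flagged[fs$term == "group"])

  expect_error(fit_nb_glm(y, cbind(1, c(1, 1, 1, 1, 1, 1, 1, 1))),
               "full rank")
})

test_that("BH adjustment matches the step-up formula and propagates NA", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.05), 0.05)
  p20 <- c(0.05, rep(1, 19))
  expect_equal(bh_adjust(p20)[1], 1)

  p <- c(0.01, NA, 0.04, 0.5)
  adj <- bh_adjust(p)
  expect_true(is.na(adj[2]))
  expect_equal(adj[-2], bh_adjust(p[-2]))

  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("DEG rule uses strict thresholds in both directions", {
  tab <- tibble::tibble(
    gene_id = paste0("g", 1:5),
    log2fc = c(1.2, 0.9, -3, 1.0, 2),
    fdr = c(0.01, 1e-10, 0.049, 0.001, 0.05)
  )
  out <- call_degs(tab)
  expect_equal(out$status, c("up", "ns", "down", "ns", "ns"))
})

test_that("planted main effects are recovered by the DE stage", {
  cfg <- sim_config(
    n_genes = 600, module_sizes = c(60), timepoints = 8,
    dispersion = 0.05, trajectory_sd = 0,
    main_effects = tibble::tibble(locus = "o2", module = 1,
                                  timepoint = 8, log2fc = 2))
  ex <- simulate_experiment(cfg, seed = 19)
  deg <- de_timepoint(ex$counts, ex$design, "o2", 8)
  planted <- ex$truth$module_of$gene_id[ex$truth$module_of$module == 1]
  est <- deg$log2fc[deg$gene_id %in% planted]
  expect_lt(abs(median(est) - 2), 0.3)
  expect_gte(mean(deg$status[deg$gene_id %in% planted] == "up"), 0.9)
  expect_equal(glance(deg)$n_genes, 600)
  expect_s3_class(tidy(deg), "tbl_df")
})

test_that("two-group NB fits agree with DESeq2 on the same data", {
  cfg <- sim_config(n_genes = 200, module_sizes = c(40), timepoints = 8,
                    dispersion = 0.1, trajectory_sd = 0,
                    main_effects = tibble::tibble(
                      locus = "nkd1", module = 1, timepoint = 8, log2fc = 1.5))
  ex <- simulate_experiment(cfg, seed = 23)
  d <- ex$design
  sel <- d$genotype %in% c("WT", "nkd1")
  cnt <- as.matrix(ex$counts[, -1])[, d$sample_id[sel]]
  rownames(cnt) <- ex$counts$gene_id
  storage.mode(cnt) <- "integer"

  ours <- de_two_group(cnt, as.integer(d$genotype[sel] == "nkd1"))

  suppressMessages({
    coldata <- data.frame(group = factor(
      ifelse(d$genotype[sel] == "nkd1", "mut", "wt"), c("wt", "mut")))
    dds <- DESeq2::DESeqDataSetFromMatrix(cnt, coldata, ~group)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref <- as.data.frame(DESeq2::results(dds))
  })
  cc <- cor(ours$log2fc, ref$log2FoldChange, use = "complete.obs")
  expect_gte(cc, 0.95)
  expect_lt(median(abs(ours$log2fc - ref$log2FoldChange), na.rm = TRUE), 0.2)
})
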