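test_that("signed adjacency matches closed forms", {
  s <- seq_len(8)
  z1 <- scale(c(1, 2, 3, 4, 5, 6, 7, 8))[, 1]
  z2 <- scale(c(2, 1, 4, 3, 6, 5, 8, 7))[, 1]
  orth <- stats::residuals(stats::lm(z2 ~ z1))
  expr <- rbind(a = z1, b = 2 * z1 + 1, c = -z1, d = orth)
  colnames(expr) <- paste0("s", s)
  adj <- signed_adjacency(expr, beta = 10)
  expect_equal(adj["a", "b"], 1)                    # cor = 1
  expect_equal(adj["a", "c"], 0)                    # cor = -1
  expect_equal(adj["a", "d"], 2^-10, tolerance = 1e-12)  # cor = 0

  bad <- rbind(a = z1, e = rep(1, 8))
  colnames(bad) <- paste0("s", s)
  expect_error(signed_adjacency(bad, 10), "zero-variance")
})

test_that("topological overlap matches formula and brute-force oracle", {
  ones <- matrix(1, 3, 3)
  expect_equal(topological_overlap(ones), matrix(1, 3, 3))

  zeros <- diag(3)
  tom0 <- topological_overlap(zeros)
  expect_equal(tom0[upper.tri(tom0)], rep(0, 3))

  set.seed(14)
  a <- matrix(runif(400), 20, 20)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  expect_lt(max(abs(topological_overlap(a) - tom_oracle(a))), 1e-12)

  a2 <- a
  a2[1, 2] <- a2[1, 2] + 0.1
  expect_error(topological_overlap(a2), "symmetric")
})

test_that("planted blocks are recovered as modules, invariant to gene order", {
  bl <- block_expression(c(100, 100), n_noise = 0, n_samples = 60,
                         loading = 0.95, seed = 33)
  tom <- topological_overlap(signed_adjacency(bl$expr, 10))
  part <- cluster_modules(tom, min_size = 60)
  expect_equal(as.vector(sort(table(part$module))), c(100, 100))
  expect_equal(ari(part$module, bl$modules), 1)

  # permuted gene order gives the same partition up to relabeling
  perm <- sample(nrow(bl$expr))
  tom_p <- topological_overlap(signed_adjacency(bl$expr[perm, ], 10))
  part_p <- cluster_modules(tom_p, min_size = 60)
  reord <- part_p$module[match(part$gene_id, part_p$gene_id)]
  expect_equal(ari(part$module, reord), 1)

  expect_warning(tiny <- cluster_modules(tom, min_size = 1000),
                 "unassigned")
  expect_true(all(tiny$module == 0))
})

test_that("eigengenes follow the SVD definition with sign alignment", {
  v <- scale(rnorm(20, sd = 2) + seq_len(20))[, 1]
  expr <- rbind(g1 = v, g2 = 3 * v + 5, g3 = 0.5 * v - 1)
  colnames(expr) <- paste0("s", 1:20)
  part <- tibble::tibble(gene_id = rownames(expr), module = 1L)
  me <- compute_eigengenes(expr, part)
  expect_equal(unname(me$var_explained), 1)
  expect_equal(sum(me$eigengenes[1, ]^2), 1)        # unit norm
  expect_gt(cor(me$eigengenes[1, ], v), 0.999)      # sign aligned

  # 2-gene closed form: standardized pair with correlation r has singular
  # values prop. to sqrt(1 + r), sqrt(1 - r), so PC1 explains (1 + |r|) / 2
  anti <- rbind(g1 = v, g2 = -v + rnorm(20, sd = 1e-8))
  colnames(anti) <- paste0("s", 1:20)
  me2 <- compute_eigengenes(anti, tibble::tibble(
    gene_id = c("g1", "g2"), module = 1L))
  expect_equal(unname(me2$var_explained), 1, tolerance = 1e-6)

  orth2 <- stats::residuals(stats::lm(rnorm(20) ~ v))
  orth2 <- orth2 / stats::sd(orth2)
  half <- rbind(g1 = v, g2 = 0.5 * v / stats::sd(v) +
                  sqrt(1 - 0.25) * orth2)
  colnames(half) <- paste0("s", 1:20)
  me_h <- compute_eigengenes(half, tibble::tibble(
    gene_id = c("g1", "g2"), module = 1L))
  expect_equal(unname(me_h$var_explained), (1 + 0.5) / 2, tolerance = 1e-9)

  # sample permutation equivariance
  pm <- sample(20)
  me3 <- compute_eigengenes(expr[, pm], part)
  expect_equal(unname(me3$eigengenes[1, ]), unname(me$eigengenes[1, pm]),
               tolerance = 1e-9)

  # reversing gene order never flips the eigengene sign
  me4 <- compute_eigengenes(expr[rev(seq_len(3)), ], part)
  expect_gt(cor(me4$eigengenes[1, ], me$eigengenes[1, ]), 0.999)
})

test_that("eigengene merging joins duplicates and respects anticorrelation", {
  v <- scale(seq_len(30) + rnorm(30))[, 1]
  w <- stats::residuals(stats::lm(rnorm(30) ~ v))
  expr <- rbind(
    matrix(rep(v, 5), 5, byrow = TRUE) + matrix(rnorm(150, sd = .05), 5),
    matrix(rep(v, 5), 5, byrow = TRUE) + matrix(rnorm(150, sd = .05), 5),
    matrix(rep(-v, 5), 5, byrow = TRUE) + matrix(rnorm(150, sd = .05), 5),
    matrix(rep(w, 5), 5, byrow = TRUE) + matrix(rnorm(150, sd = .05), 5)
  )
  rownames(expr) <- paste0("g", 1:20)
  colnames(expr) <- paste0("s", 1:30)
  part <- tibble::tibble(gene_id = rownames(expr),
                         module = rep(1:4, each = 5))
  merged <- merge_close_modules(expr, part, merge_threshold = 0.1)
  # modules 1 and 2 (identical eigengenes) merge; 3 (anti) and 4 (orthogonal)
  # stay separate
  expect_equal(length(setdiff(unique(merged$module), 0)), 3)
  m12 <- merged$module[match(c("g1", "g6"), merged$gene_id)]
  expect_equal(m12[1], m12[2])
  m3 <- merged$module[merged$gene_id == "g11"]
  expect_false(m3 == m12[1])

  un <- merge_close_modules(expr, part, merge_threshold = 0)
  expect_equal(length(setdiff(unique(un$module), 0)), 4)
})

test_that("kME membership and the strict hub rule", {
  set.seed(9)
  e <- matrix(rnorm(40), 2, 20,
              dimnames = list(c("M1", "M2"), paste0("s", 1:20)))
  e <- t(apply(e, 1, function(x) x / sqrt(sum(x^2))))
  z1 <- e[1, ] / stats::sd(e[1, ])
  orth <- stats::residuals(stats::lm(rnorm(20) ~ e[1, ]))
  orth <- orth / stats::sd(orth)
  expr <- rbind(
    hub = e[1, ],                                   # cor 1 with M1
    below = 0.79 * z1 + sqrt(1 - 0.79^2) * orth,    # cor 0.79 < threshold
    above = 0.81 * z1 + sqrt(1 - 0.81^2) * orth,    # cor 0.81 > threshold
    far = orth                                      # cor 0
  )
  colnames(expr) <- paste0("s", 1:20)
  part <- tibble::tibble(gene_id = c("hub", "below", "above", "far"),
                         module = c(1L, 1L, 1L, 0L))
  mm <- module_membership(expr, e, part)
  expect_equal(mm$kme_own[mm$gene_id == "hub"], 1, tolerance = 1e-9)
  expect_true(mm$hub[mm$gene_id == "hub"])
  expect_equal(mm$kme_own[mm$gene_id == "below"], 0.79, tolerance = 1e-9)
  expect_false(mm$hub[mm$gene_id == "below"])
  expect_true(mm$hub[mm$gene_id == "above"])
  # the threshold is a strict inequality
  expect_equal(mm$hub, mm$kme_own > 0.8 & mm$module > 0 &
                 !is.na(mm$kme_own))
  expect_false(mm$hub[mm$gene_id == "far"])         # unassigned, never hub
})

test_that("membership refinement adopts stranded genes, releases weak ones", {
  bl <- block_expression(c(80, 80), n_noise = 60, n_samples = 50,
                         loading = 0.9, seed = 55)
  # corrupt the partition: strand 20 module genes, adopt 10 noise genes
  truth <- bl$modules
  part <- tibble::tibble(gene_id = rownames(bl$expr), module = truth)
  part$module[which(truth == 1)[1:20]] <- 0L
  part$module[which(truth == 0)[1:10]] <- 2L
  refined <- refine_membership(bl$expr, part, min_kme = 0.5, min_size = 10)
  expect_equal(ari(refined$module, truth), 1)
})

test_that("module-TF correlation matches the t-distribution", {
  n <- 20
  set.seed(3)
  z <- scale(rnorm(n))[, 1]
  orth <- stats::residuals(stats::lm(rnorm(n) ~ z))
  orth <- scale(orth)[, 1]
  me <- rbind(M1 = z, M2 = 0.6 * z + sqrt(1 - 0.36) * orth)
  colnames(me) <- paste0("s", 1:n)
  tf <- rbind(nkd1 = z)
  colnames(tf) <- paste0("s", 1:n)
  out <- module_tf_correlation(me, tf)
  r1 <- out[out$module == "M1", ]
  expect_equal(r1$r, 1, tolerance = 1e-9)
  r2 <- out[out$module == "M2", ]
  expect_equal(r2$r, 0.6, tolerance = 1e-9)
  tstat <- 0.6 * sqrt(n - 2) / sqrt(1 - 0.36)
  expect_equal(r2$p, 2 * pt(-tstat, n - 2), tolerance = 1e-9)
  expect_equal(r2$stars, "**")

  zero <- module_tf_correlation(rbind(M1 = z), rbind(tf = orth))
  expect_equal(zero$p, 1, tolerance = 1e-6)

  expect_error(module_tf_correlation(me[, 1:2, drop = FALSE],
                                     tf[, 1:2, drop = FALSE]), "samples")
})
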