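# endonet

Factorial transcription-factor interaction analysis and dynamic
coexpression networks for cereal endosperm multi-omics.

## What it is for

Maize endosperm between 8 and 16 days after pollination (DAP) transitions
from cellular development to grain filling, and three transcription factors
— NKD1, NKD2 and OPAQUE2 (O2) — jointly regulate that transition. Studying
them properly takes a factorial mutant design: all 2³ = 8 genotypes of the
three loci, profiled by RNA-seq across timepoints with replication, plus
TF-binding peaks (DAP-seq) and chromatin accessibility (ATAC-seq).

`endonet` is an R package for analysts working with such designs. It
implements the full chain — differential expression, coexpression modules,
factorial interaction testing, peak-to-gene integration, and regulatory
network assembly — as tidyverse-style functions (tibbles in, tibbles out),
driven by a synthetic multi-omic generator with recorded ground truth so
that every statistical property is testable offline.

## The statistics at the core

* **Differential expression.** Per-gene negative-binomial GLM with log link
  and median-of-ratios offsets: counts `c_gs ~ NB(mu_gs, alpha_g)` with
  `log mu = log s_s + X beta`. Dispersions are method-of-moments estimates
  shrunk toward a mean-dispersion trend (`w = df/(df + prior_df)`,
  `prior_df = 10`); Wald tests, BH FDR, and the DEG rule |log2FC| > 1 and
  FDR < 0.05 (strict).
* **Factorial interactions.** For loci A and B, the model
  `~ x_A + x_B + x_A:x_B`; the interaction coefficient (log2) is the log2FC
  of the A mutation in the B-mutant background minus in the B-wild-type
  background. The composite contrast `nkd1+nkd2 : o2` uses the clean 2×2 of
  {WT, nkd1 nkd2, o2, nkd1 nkd2 o2}. Module-level epistasis is classified
  as additive / enhancement / suppression from genotype deltas in z-units.
* **Coexpression.** Signed adjacency `a_ij = ((1 + cor)/2)^beta` (beta = 10
  pooled; 7/9/7 per timepoint), unsigned TOM, average-linkage clustering
  with a static cut plus eigengene-membership refinement, module merging at
  eigengene dissimilarity 0.1 (0.3 per timepoint), minimum module size 60,
  module eigengenes (first PC), kME, and hubs at kME > 0.8.
* **Regulatory integration.** Peaks are assigned to every gene whose TSS is
  within 3 kb of the peak midpoint (inclusive); locations are classified
  promoter1k / promoter3k / genic / distal-intergenic / other; the
  degenerate consensus TTTGTC[CT]T is scanned on both strands; direct
  targets are bound ∩ differentially expressed genes (hypergeometric
  p < 1e-6); differential accessibility reuses the NB engine on peak
  counts.
* **Network dynamics.** Module flow between timepoints (fractions
  normalized by the later module), split/merge detection, hypergeometric
  term enrichment over local annotation maps, and a tiered
  TF → target-hub → member network with heavy (binding) and light
  (coexpression) edges.

## Worked example

```r
library(endonet)

cfg <- sim_config(n_genes = 800, module_sizes = c(200, 150, 120))
ex  <- simulate_experiment(cfg, seed = 42)

# mutant-vs-WT differential expression at 12 DAP
deg <- de_timepoint(ex$counts, ex$design, "o2", 12)
glance(deg)
#>   genotype timepoint n_genes  n_up n_down
#> 1 o2              12     800    98     16

# pooled coexpression network
lens <- setNames(ex$annotation$length, ex$annotation$gene_id)
expr <- compute_tpm(ex$counts, lens, log2 = TRUE)
fit  <- coexpression_network(expr, beta = 10, min_size = 60,
                             merge_threshold = 0.1)
fit
#> Coexpression network: 800 genes, 3 modules (beta = 10, min size = 60)

# tiered regulatory network from binding evidence + hubs
net <- build_hierarchical_network(c("nkd1", "nkd2", "o2"),
                                  ex$peaks$tf_targets,
                                  fit$membership, fit$partition)
net
#> Regulatory network: 473 nodes (3 TFs, 102 target hubs, 368 members),
#> 13322 edges (114 heavy)

# module flow between two partitions
trace_module_flow(fit$partition, fit$partition, "M12-", "M16-")
#>   from  to    shared to_size fraction
#> 1 M12-1 M16-1    200     200        1
#> 2 M12-2 M16-2    150     150        1
#> 3 M12-3 M16-3    120     120        1
```

The 98 up / 16 down genes reflect the latent module dynamics the generator
plants for the o2-mutant genotypes; the three planted modules are recovered
exactly (adjusted Rand index 1.0 against the generator's ground truth in
this run), and the 114 heavy edges are the planted TF-target links that are
also module hubs.

`plot_eigengenes()`, `plot_module_flow()` and `autoplot()` on a
`coexpression_fit` give the standard ggplot2 views of module dynamics,
flows and module-TF correlations.

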