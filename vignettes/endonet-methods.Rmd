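---
title: "Methods: factorial TF interactions and dynamic coexpression networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: factorial TF interactions and dynamic coexpression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis problem

Maize endosperm between 8 and 16 days after pollination transitions from
cellular development to storage-compound accumulation, and three
transcription factors — NKD1, NKD2 and O2 — jointly steer that transition.
`endonet` implements the full analysis chain for a factorial mutant design
built on three biallelic loci: all 2^3 = 8 genotypes (wild type; single,
double and triple mutants) profiled by RNA-seq over three timepoints with
replication, together with TF-binding peaks (DAP-seq-like) and chromatin
accessibility peaks (ATAC-seq-like). The chain is:

1. per-gene negative-binomial (NB) GLM differential expression with the DEG
   rule |log2FC| > 1 and FDR < 0.05;
2. signed weighted coexpression networks with topological overlap, module
   detection, eigengenes, module merging, kME/hub calling and module-TF
   correlation;
3. factorial interaction testing between locus pairs (including the
   composite nkd1·nkd2 versus o2 comparison) and module-level epistasis
   classification (additive / enhancement / suppression);
4. peak-to-gene target assignment in a 3 kb TSS window, peak location
   categories, degenerate consensus-motif scanning, direct-target calling,
   and differential accessibility;
5. module flow tracing across timepoints and assembly of a tiered
   TF → target-hub → module-member regulatory network.

Every stage is driven by a synthetic-data generator with recorded ground
truth, so all statistical behaviour (calibration, effect recovery, module
recovery, integration) is testable without any external download.

## The synthetic-data generator

`sim_config()` + `simulate_experiment()` emulate the study design:
8 genotypes × 3 timepoints (8, 12, 16 DAP) × 4 replicates = 96 samples.
Counts follow

$$c_{gs} \sim \mathrm{NB}\!\left(\mu_{gs} = L_s \cdot 2^{\,b_g + \sum_\ell
x_{\ell s}\beta_{\ell g t} + x_{As}x_{Bs}\beta_{ABgt} + \lambda_g
E_{m(g)}(\text{genotype}_s, t_s)},\ \alpha_g\right)$$

* $L_s$ — per-sample library factor, log-uniform in `library_size_range`
  (default 0.7–1.4), so normalization is genuinely exercised;
* $b_g$ — baseline log2 mean, uniform in `baseline_log2_mean_range`
  (default 3–9, spanning low- to high-expression genes);
* $\beta$ — planted main/interaction effects in log2 units, addressed by
  (locus, module, timepoint); composite factors such as `"nkd1+nkd2"`
  multiply the constituent indicators;
* $E_m$ — a latent module trajectory drawn per (genotype, timepoint) from
  $N(0, \texttt{trajectory\_sd}^2)$, scaled per gene by a loading
  $\lambda_g$ uniform in `loadings_range` (default 0.7–0.95). This creates
  eigengene-genotype separation without prescribing any specific biology;
* $\alpha_g$ — NB dispersion (default 0.05, a typical replicate-level value
  for well-powered bulk RNA-seq).

Gene lengths are uniform in 500–5,000 bp (needed for TPM); genes are placed
without overlap on a configurable synthetic genome (default 10 × 1 Mb) with
i.i.d. nucleotide sequence. Binding peaks are planted so each target gene
has a peak midpoint within 3 kb of its TSS while avoiding every other
gene's window where possible (unavoidable neighbours are absorbed into the
ground truth, keeping "recovered = planted" well-defined); decoy peaks are
rejection-sampled to lie > 3 kb from every TSS. Accessibility peaks carry
per-sample NB counts with planted genotype-dependent log2 shifts.

Two deliberate design points:

* **`trajectory_sd` and effect recovery.** A latent trajectory is a
  genotype-level random shift shared by a module's genes; in an
  effect-recovery experiment it would be confounded with the planted
  log2FC (the estimate would be `2 + loading × ΔE` with `ΔE` a random
  draw). Recovery studies therefore plant effects on a labelled gene set
  with `trajectory_sd = 0`, while module-recovery studies use
  `trajectory_sd = 1` — each condition isolates the property it measures.
* **Seed handling.** One user seed is split per sub-generator by fixed
  labels, so regenerating one artifact (say, peaks) never perturbs another.

What the generator does **not** emulate: read-level sampling (FASTQ),
sequence composition and mappability, isoforms, batch effects, and
correlated module trajectories driven by a developmental program. Passing
tests therefore demonstrate correctness of the statistical machinery under
the stated model, not performance on any real dataset.

## Differential expression

Normalization is median-of-ratios against a geometric-mean pseudo-reference
(genes with any zero excluded from the reference), rescaled to geometric
mean 1. TPM is computed from counts and gene lengths; an all-zero sample is
defined as all-zero TPM; the log unit is log2(TPM + 1) with pseudocount 1.

Dispersions are genewise method-of-moments estimates
$\hat\alpha_g = \max(0, (s^2_g - \bar\mu_g)/\bar\mu_g^2)$ on normalized
counts with variances pooled across design cells, shrunk toward a lowess
trend of $\hat\alpha$ versus log mean with weight
$w = \mathrm{df}/(\mathrm{df} + \mathrm{prior\_df})$, `prior_df = 10`
(moderate empirical-Bayes-style shrinkage). The per-gene NB GLM uses the
log link with log-size-factor offsets, IRLS to a deviance tolerance of
1e-8 (at most 100 iterations), Wald z-tests with normal reference, and
coefficients reported in log2 units. Fits with a separated cell are clamped
at |log2FC| = 20/log 2 and flagged; non-converged fits get `p = NA`. The BH
step-up adjustment is applied per (timepoint, contrast) family, and DEG
status uses strict inequalities in both thresholds.

A practical caveat the tests make visible: when a large, one-directional
fraction of the analysed panel is differentially expressed (≳ 25%),
median-of-ratios factors absorb part of the signal and log2FC estimates
shrink by ≈ 0.3; at the ~10% DE fractions of the recovery conditions the
bias is below 0.15. This is a property of reference-based normalization,
not of the implementation.

## Coexpression networks

The signed adjacency is $a_{ij} = ((1 + r_{ij})/2)^\beta$ with Pearson
$r$; β defaults to 10 for pooled-timepoint networks and 7/9/7 for the
8/12/16-DAP single-timepoint networks. Topological overlap is the unsigned
TOM on this signed adjacency:
$\mathrm{TOM}_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) / (\min(k_i,k_j) + 1 -
a_{ij})$.

Module detection clusters `1 - TOM` by average linkage. The tree is cut
statically at a quantile of the merge heights (default 0.7); clusters
smaller than `min_size = 60` dissolve to the unassigned label 0. Modules
whose eigengenes are closer than the merge threshold (0.1 pooled, 0.3
per-timepoint) are merged iteratively, recomputing eigengenes after every
merge. Finally `refine_membership()` reassigns every gene to its
highest-kME module when that kME is at least 0.5 (the eigengene then
explains ≥ 25% of the gene's variance), over two passes.

The refinement step is the package's answer to a genuine weakness of any
single static cut: within-module merges occupy the lower part of the
dendrogram and attachments of uncorrelated genes the top, but the boundary
between the two regimes moves with the fraction of unstructured genes. A
cut high enough to keep every module intact admits loosely attached
background genes; a cut low enough to exclude them fragments modules. The
membership pass (the same role as the PAM stage of dynamic hybrid cutting)
repairs both directions and makes the result insensitive to the cut
quantile across 0.6–0.8 in simulation.

Eigengenes are the first right singular vector of the module's per-gene
standardized expression, sign-aligned to correlate non-negatively with the
module's mean standardized expression (this makes reported signs
independent of gene order). Variance explained is $d_1^2/\sum d^2$; for a
standardized two-gene module with correlation $r$ this is $(1 + |r|)/2$.
Hubs are genes with kME to their own module strictly above 0.8. Module-TF
correlation uses Pearson r with the exact t-reference
($t = r\sqrt{n-2}/\sqrt{1-r^2}$) and stars at 0.05/0.01/0.001; the TF
profiles are the regulator genes' log2(TPM + 1) rows.

## Interaction testing and epistasis

For a locus pair (A, B) at one timepoint the per-gene model is
`~ x_A + x_B + x_A:x_B` with offsets, fitted by the same NB machinery; the
interaction coefficient in log2 units is exactly "the log2FC of the A
mutation in the B-mutant background minus in the B-wild-type background".
The composite factor `"nkd1+nkd2"` maps samples to all-constituent-mutant
versus otherwise and restricts the design to the four genotypes where the
constituents are jointly wild-type or jointly mutant — a clean 2×2 against
o2. BH runs across the tested gene set (in the study design, the union of
DEGs at that timepoint); `affected` means FDR < 0.05.

Module-level genotype profiles z-score each gene across a timepoint's
samples and average replicates per genotype; genotypes are compared by
pairwise t-tests paired by gene (unadjusted, as is conventional for
compact-letter displays) and summarized as significance letters at
p < 0.05. Epistasis classification computes per-gene deltas to wild type
($d_A$, $d_B$, $d_{AB}$) and tests, at 0.05 with paired t-tests over
genes: **suppression** when one single-mutant effect is significant but
vanishes in the other mutant background ($d_{AB} - d_A$ not significant
while $d_B$ is, or symmetrically); **enhancement** when
$d_{AB} - d_A - d_B$ is significant with $|d_{AB}| > |d_A + d_B|$ and the
same sign; **additive** when the interaction contrast is not significant;
otherwise inconclusive. Precedence is suppression > enhancement >
additive. The rules are one formalization of letter-style figure logic;
they are invariant to adding a constant to all genotype means.

## Regulatory integration

Peak anchors are midpoints, `floor((start + end)/2)` in 0-based half-open
coordinates; the 1-based TSS is converted at the boundary and signed
distances are oriented by gene strand. Assignment uses an inclusive 3 kb
window (a distance of exactly 3,000 bp is in; 3,001 is out). Location
categories are tested in order: promoter1k (≤ 1 kb of a TSS), promoter3k
(≤ 3 kb), genic (midpoint in a gene body), distal intergenic (> 3 kb
upstream and > 300 bp downstream of every gene, strand-relative), other —
each peak receives exactly one. Consensus scanning matches the degenerate
8-mer TTTGTC[CT]T exactly on both strands (the reverse complement is
scanned for minus-strand sites), reporting all overlapping matches.
Direct-target calling intersects bound genes with DEG sets and flags
hypergeometric p < 1e-6. Differential accessibility reuses the NB engine
on peak counts with up = more open at FDR < 0.05 (strict), cross-tabulated
by the 3 kb promoter definition. Peak-set overlap requires ≥ 1 shared bp
(half-open) with no reciprocal-fraction rule.

## Network dynamics

Module flow between timepoints counts shared genes per (earlier, later)
module pair and normalizes by the later module's size — matching the
convention "x% of the genes in the later module were shared". Splits and
merges require at least `min_fraction = 0.1` flowing to (or from) two or
more partners. The hierarchical network places the three TFs in tier 1,
genes that are both direct targets and hubs in tier 2, and the remaining
members of tier-2 modules in tier 3; heavy edges carry binding evidence
(TF → tier-2, TF → TF), light edges connect tier-2 hubs to coexpressed
members. Edges only run from lower to equal-or-higher tiers, so the graph
is acyclic across tiers. Term enrichment against a user-supplied
annotation map (term → gene set) replaces any web-service dependency with
the same hypergeometric + BH statistic.

## Problem sizes, tolerances and degenerate inputs

The simulation studies shipped with the package use 2,000-gene panels with
96 samples (module recovery, calibration) or one timepoint (32 samples;
effect recovery), matching the factorial scale while keeping a full run in
minutes on one CPU. Numerical choices: IRLS tolerance 1e-8; dispersion
floor 0; TOM and hypergeometric routines are checked against brute-force
oracles to 1e-12; zero-variance genes are excluded from networks with a
logged list and dropped from module eigengenes with a warning; an all-zero
TPM sample is defined as zero; NA p-values propagate through BH without
affecting other genes' ranks; ties in the argmax-kME reassignment break to
the first (lowest-label) module.

## Known limitations

* The NB Wald test with normal reference is mildly anti-conservative at
  n = 4 replicates (observed null rejection ≈ 0.055 at nominal 0.05);
  shrinkage with `prior_df = 10` keeps this within the tested band.
* The static-cut + refinement module detector assumes modules are
  represented by a coherent core of at least `min_size` genes below the
  cut; two planted modules whose latent trajectories are strongly
  correlated by chance can merge irrecoverably, as they would for any
  correlation-based method.
* Consensus scanning is exact-match only (no position weight matrices), by
  scope.
* Module flow counts strict co-membership of genes present in both
  partitions; genes expressed at both timepoints but unassigned in one are
  not counted, which is one of two defensible readings of chord-diagram
  conventions.
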