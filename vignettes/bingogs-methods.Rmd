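---
title: "Marker subset selection with GO priors and bin-based combinatorial optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker subset selection with GO priors and bin-based combinatorial optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Genomic prediction (GBLUP and relatives) regresses a quantitative phenotype
on genome-wide SNP dosages. With modern resequencing panels (millions of
SNPs for a few hundred accessions) most markers are non-causal and merely
dilute the signal, inflate compute, and block the design of cheap
low-density genotyping panels. `bingogs` selects a compact marker subset
that predicts at least as well as the full panel by combining two sources
of information:

* a **biological prior** — quantitative traits are typically driven by many
  minor-effect genes that cluster in Gene Ontology pathways, so candidate
  markers are restricted to those inside genes of sufficiently covered GO
  terms; and
* a **statistical stratification** — mixed-model GWAS p-values computed on
  the training partition split the candidates into strong-effect markers
  (Subset I) and p-value bins of progressively weaker markers, from which a
  chain-wise rolling optimizer accumulates the weak-effect complement
  (Subset II).

## Model

The prediction core is standard GBLUP. For phenotypes $y$ over $n$ samples,

$$ y = 1\mu + g + e, \qquad g \sim N(0,\, G\sigma_g^2), \quad
   e \sim N(0,\, I\sigma_e^2), $$

with $G$ the VanRaden method-1 genomic relationship matrix
$G = WW^\top / (2\sum_j p_j(1-p_j))$, $W$ the dosage matrix centered by
$2p_j$. Variance components are estimated by restricted maximum likelihood,
profiled over $\delta = \sigma_e^2/\sigma_g^2$ after a spectral
decomposition of $G$ (a grid on $\log_{10}\delta$ in $[-6, 6]$ refined by
golden-section search; deterministic). Heritability is
$h^2 = \sigma_g^2/(\sigma_g^2+\sigma_e^2) = 1/(1+\delta)$, which assumes
the diagonal of $G$ is near 1. Among numerically tied profile values the
largest $\delta$ wins, so an uninformative kinship ($G = I$, where the two
components are not separately identifiable) resolves to $\sigma_g^2 \to 0$
rather than an arbitrary split. Held-out samples are predicted as
$\hat\mu + G_{te,tr}(G_{tr,tr} + \lambda I)^{-1}(y_{tr} - \hat\mu)$ with
$\lambda = \hat\sigma_e^2/\hat\sigma_g^2$ re-estimated on every training
partition, never on test data. This is algebraically identical to
ridge-regression BLUP on the markers with penalty $c\lambda$
($c$ the GRM denominator), which the test suite asserts.

The association scan is the EMMAX approximation: the null model
$y = X\beta + g + e$ (intercept + 3 genotype principal components, kinship
from the full marker panel) is fitted once by REML; each marker is then
scored by a generalized-least-squares Wald t-test in the eigen-rotated,
whitened space with $\delta$ fixed at its null estimate. With $K = I$ and
no covariates this reduces exactly to per-marker OLS. P-values are used
only as stratification keys downstream, so no multiplicity correction is
applied.

## The selection procedure

1. **QC** (order: MAF, then Hardy-Weinberg, then LD pruning). Defaults
   follow common practice for inbred-line panels: MAF $\ge$ 0.01,
   HWE p $\ge 10^{-6}$, windowed pruning with 50-SNP windows, step 5,
   $r^2 \le 0.95$. The pruning victim rule (drop the lower-MAF member,
   ties to the later position) is our own deterministic choice; PLINK's
   exact behaviour is not replicated.
2. **GO pool**. GO terms (already propagated through subordinate terms) map
   to genes, genes to the SNPs falling in $[\mathrm{start}-f,
   \mathrm{end}+f)$ (0-based half-open; flank $f$ defaults to 0). Terms
   with strictly more than `min_snps` markers (200 at full scale) are
   "effective"; their union, deduplicated and coordinate-sorted, is the
   candidate pool. Trait-relevance curation of terms is not algorithmic;
   an include/exclude list is exposed instead and defaults to no curation.
3. **Budget**. Random subsets of increasing size are drawn from the pool
   (50 replicates per size), scored by cross-validated GBLUP $r^2$ on the
   training samples, and the mean curve is smoothed with a trailing moving
   average ($\mathrm{MA}_t$, window 3 or 5). With
   $\mathrm{Slope}_t = \mathrm{MA}_t - \mathrm{MA}_{t-1}$, the budget is
   the grid size at the left end of the first interval where either
   $|\mathrm{Slope}_t|$ stays below `near_zero_eps` (default 0.1) times the
   maximum slope for three consecutive intervals, or the slope falls more
   than `drop_frac` (default 20%) below the running mean of all earlier
   slopes. "Near zero" has no absolute definition in accuracy units, hence
   the relative tolerance; the "prior average" is the running mean of all
   earlier slopes by default (`drop_ref = "window"` switches to the mean of
   the previous `ma_window` slopes). If no rule fires the largest grid size
   is returned with a
   warning. Cross-validation (5-fold, training data only) is used for the
   curve because scoring on held-out data during selection would leak.
4. **Subset I**: markers with GWAS $p <$ `p_strong` (default 0.01, strict),
   LD-pruned.
5. **Bins and groups**: remaining pool markers with $p \ge$ `p_strong` go
   into $B$ bins tiling $[0.01, 1]$ — $[0.01, 0.1), [0.1, 0.2), \dots,
   [0.9, 1.0]$ for $B = 10$ — each split into $G$ equal-width sub-interval
   groups. A literal 0.01-wide sliding window cannot give 10 groups in the
   0.09-wide first bin, so group width is `bin_width / G` (0.009 in bin 1,
   0.01 elsewhere). Markers pruned out of Subset I are not re-binned.
   Empty groups contribute nothing and are skipped (no borrowing from
   later bins).
6. **Chain-wise rolling rounds**. Round 1 enumerates exactly $B \times G$
   combinations: starting with every bin at group 1, the leading bin moves
   to the tail with its group index incremented (wrapping), so each
   (bin, group) pair leads exactly once. Each combination is merged with
   Subset I, LD-pruned (accumulated markers protected), and scored by
   $F$-fold cross-validated GBLUP $r^2$ with a fold assignment fixed
   within the round — $B \times G \times F$ model fits in round 1. The
   winner's merged set becomes the accumulated set; its leading group is
   retired everywhere; survivors keep their round-1 membership and roll
   again (full-bin coverage no longer required) until the accumulated set
   reaches the budget or candidates run out. Ties go to the earliest
   combination in enumeration order. The round that crosses the budget is
   kept whole; no partial-group truncation. Subset II is the final set
   minus Subset I (disjoint by construction).
7. **Evaluation**: 75/25 train/test splits, 15 replicates, identical
   splits for every compared marker set (full panel, equal-size random
   subsets, Subset I, Subset II, final), accuracy as squared Pearson
   correlation between observed and predicted test phenotypes (the
   `1 - SSE/SST` form is available via `method = "rss"`), one-tailed
   paired t-tests for the hypothesized improvements. Selection is
   recomputed per replicate on the training partition; a fast mode reuses
   one budget across replicates at desk scale.

## Synthetic data: what it emulates and what it does not

`sim_config()` defines the stated desk-scale world: 300 samples, 5,000
markers on 5 chromosomes, LD blocks of 25 markers with lag-1 latent
correlation 0.9 (haplotypes are thresholded autoregressive Gaussians, so
allele frequencies land in the configured 0.05-0.5 range and adjacent
markers are correlated while blocks are independent), 50 non-overlapping
genes, 12 GO terms, 30 QTNs with standard-normal effects of which 80% sit
inside GO-annotated genes, and $h^2 = 0.7$ enforced exactly in-sample by
orthogonalizing and rescaling the noise. These generators produce the
tagging structure the optimizer exploits and write standard formats
(VCF/GFF3/TSV), but they are not a population-genetic simulation: no
demography, no selection, no population-structure gradients, no
inbreeding (real Arabidopsis accessions are homozygous lines; the
generator draws random-mating genotypes so the Hardy-Weinberg filter is
exercised meaningfully). A green test therefore establishes algorithmic
correctness and the relative ordering of marker sets under a controlled
architecture — not absolute accuracy levels of any real dataset, which
depend on panel density and LD far beyond desk scale.

Two deliberate fixture choices in the acceptance suite: the
subset-ordering criterion (Subset II outperforming Subset I) uses a
strongly polygenic world (400 samples, 3,000 markers, 300 QTNs) because
with 30 large-effect QTNs Subset I alone already captures most of the
signal and the ordering reported for highly polygenic traits cannot be
expected — matching the motivation that weak-effect markers matter most
when effects are many and small. And the plateau criterion checks the
near-zero-slope rule against its analytic crossing with the drop rule
disabled, because on any exponentially saturating curve the relative-drop
rule fires much earlier by design (geometric slope decay); both rules stay
active by default.

## Numerical choices and degenerate inputs

* Missing dosages are kept at I/O and mean-imputed per marker only inside
  numeric kernels (GRM, LD, GWAS, PCA); they are never written back.
* Constant marker vectors: `ld_r2()` returns `NA` (treated as 0 by the
  pruner, so constant markers are never pruned for LD); monomorphic
  markers score $p = 1$ in the GWAS and contribute nothing to the GRM.
* Singular GBLUP systems get a logged $10^{-8}$ ridge jitter; a
  non-positive-semidefinite GRM beyond $-10^{-6}$ errors with advice.
* The optimizer's merge-time pruning uses a precomputed neighbour-LD cache
  ($r^2$ of each marker with its `window - 1` right neighbours; pairs
  further apart in the full panel are treated as unlinked, which the
  windowed contract already implies). The exported `ld_prune()` is the
  exact windowed algorithm and is what QC, Subset I construction and all
  oracle checks use.
* Ties: pruning resolves the highest-$r^2$ pair first (then lower MAF,
  then later position); the optimizer breaks equal accuracies by
  enumeration order; PCA signs are fixed by the largest-magnitude loading.
  All randomness flows through explicit seeds; repeated runs are
  byte-identical.

## Known limitations

Single-trait, single-variance-component analysis only (no multi-kernel
partitions, dominance or epistasis); biallelic SNPs only; no imputation or
phasing; the Bayesian and deep-learning comparison models of the wider
evaluation literature are out of scope, as is exact replication of PLINK
or GEMMA outputs. The per-trait heritabilities and subset sizes reported
for full-scale Arabidopsis panels depend on millions of markers and are
not reproducible at desk scale; the test suite checks the qualitative
claims (dominance over random subsets, Subset ordering, enumeration
identities) instead.
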