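---
title: "Methods and design choices in bivalint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in bivalint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind each module, the
defaults and their rationale, the scope of the synthetic-data generator,
and the numerical conventions that determine behavior at boundaries. It is
the reference for *why* the package behaves as it does; the README shows
*how* to use it.

## 1. The factorial count model

Counts are modeled per gene as negative binomial,

$$K_{gj} \sim \mathrm{NB}(\mu_{gj} = s_j \, q_{gj}, \ \alpha_g),$$

with sample size factor $s_j$ and gene dispersion $\alpha_g$
(variance $\mu + \alpha\mu^2$). The mean follows a 2×2 factorial design
with interaction, `~ e2 * kd`, fitted by `stats::glm.fit` with the
`MASS::negative.binomial` family and `log(s_j)` offsets. Natural-log
coefficients and their covariance are converted to log2. Five named
contrasts are exposed: the two marginal effects (`e2_vs_ctrl`,
`kd_vs_ctrl`, each measured in the other factor's control background), the
two conditional estrogen effects (`kd+e2_vs_kd`, `kd+e2_vs_e2`), and the
`interaction`. Significance is a two-sided Wald normal test.

**Size factors** are the median-of-ratios estimator (each sample's median
ratio to the geometric-mean reference gene-wise profile), rescaled so
their geometric mean is 1. When many genes are planted in one direction
this estimator absorbs a small composition bias (about 0.1 log2 units when
10% of genes are up-regulated); this is the standard, accepted behavior of
the estimator, and the effect-recovery tolerance (±0.25 log2) accounts
for it.

**Dispersions** are estimated per gene by the within-cell method of
moments, $(v - m)/m^2$ averaged over the four design cells (so planted
effects do not inflate them), then shrunk 50/50 toward a mean–dispersion
trend $\alpha(\mu) = a_0 + a_1/\mu$ fitted by least squares with
coefficients clamped to be non-negative ($a_0 \ge 10^{-8}$). Estimates are
floored at $10^{-8}$ and capped at 10. With only three replicates per
cell, per-gene estimates are very noisy; sharing information through the
trend is what keeps the Wald test's type-I error calibrated (empirically
0.05–0.06 at $\alpha = 0.05$ on a 2,000-gene null).

**Multiple testing** uses a covariate-weighted Benjamini–Hochberg scheme:
genes are binned into `n_bins = 5` quantile bins of base mean, candidate
weight vectors are drawn from the grid $\{0, 0.5, 1, 1.5, 2\}^5$ filtered
to mean exactly 1, and the vector maximizing rejections at the target
alpha is selected; final q-values are BH on $\min(p/w, 1)$. The uniform
weight vector is always the first candidate, so the procedure never
rejects fewer tests than plain BH, and `n_bins = 1` reduces to plain BH
exactly. This is a deterministic approximation to independent hypothesis
weighting chosen for transparency and zero extra dependencies.

**Low-count filtering** keeps genes with `rowSums(counts) >= min_mean * n`
(inclusive boundary: a gene whose mean is exactly the threshold is kept).
The variance-stabilizing transform for clustering/PCA is
`log2(count/sf + 4)`; the pseudocount 4 maps zeros to exactly 2 and damps
low-count variance without flattening mid-range fold changes.
`select_variable_genes` takes exactly one of `min_variance` (strict `>`:
a gene exactly at the threshold is excluded) or `top_n`.

## 2. Joint regulatory classification

At significance level `alpha` (strict `<` on q-values; default 1e-4), a
gene doubly significant with opposite log2-fold-change signs is
*cooperative* (estrogen and the intact remodeler push the same
transcriptional program, so losing the remodeler opposes the estrogen
direction), and with shared signs *antagonistic*. A log2 fold change of
exactly 0 has no direction: such a gene is "ns" and — even if doubly
significant — stays "neither", because "e2-only"/"kd-only" are reserved
for genes non-significant in the other contrast. Cooperative and
antagonistic fractions are reported over doubly-significant genes and sum
to 1.

*Remodeler-dependent induction* has two modes. The default,
`interaction`, requires significant estrogen up-regulation plus a
significant negative interaction — the cleanest statistical statement of
"induced, but less so after knockdown". The `delta` mode instead requires
the knockdown-context induction (`kd+e2_vs_kd`) to be significant and
smaller than the estrogen effect, matching how such genes are displayed as
paired effect sizes.

**A power caveat worth stating plainly:** with three replicates per cell,
the interaction coefficient sums the variance of four cell means, giving a
standard-error floor of about $2\sqrt{\alpha_g/3}$ natural-log units
(≈ 0.43 log2 at the fitted-dispersion floor). At the strict default alpha
of 1e-4, sensitivity for interaction effects of 1–2 log2 units is
therefore near zero regardless of sequencing depth — a property of the
design, not of the implementation. The acceptance script reports
dependent-induction sensitivity at both the default alpha and 0.05 so this
is visible rather than hidden.

## 3. Intervals, promoters, and chromatin states

All genomic intervals are 0-based half-open throughout (BED convention);
an interval's length is `end - start`, and a peak starting exactly at a
promoter's end does not overlap it. Interval arithmetic is delegated to
GenomicRanges (converting to 1-based closed internally and back).

Promoter windows are symmetric `width = 3000` bp windows centered on the
TSS regardless of strand, clipped at 0 — a deliberately simple convention
for mark/binding calls at promoters. The cross-sample promoter test uses a
wider `window = 6000` (±3 kb), reflecting the broader windows used when
binarizing reference epigenomes.

Replicate-consensus peaks emit, for every replicate-1 peak overlapping a
replicate-2 peak by ≥ 1 bp, the union interval of the pair, then merge
overlapping unions; the consensus signal is the mean over replicates of
the summed member signals. Replicate-only peaks (decoys) never survive.
The four-state promoter classification (bivalent / K4-only / K27-only /
neither) is a strict partition of the supplied universe.

Association statistics are exact where exactness is cheap: hypergeometric
upper tails via `phyper`, two-sided Fisher p-values via `fisher.test`
(probability-mass summation), with the odds ratio computed from the table
directly and a 0.5 Haldane correction applied — and flagged — only when a
cell is zero. Group expression comparisons use two-sided Wilcoxon
rank-sum tests with normal approximation (`exact = FALSE`), returning `NA`
with a warning when a group has fewer than 3 genes.

## 4. Super-enhancers

Active enhancer peaks (H3K27ac consensus restricted to ATAC-accessible
regions, keeping the H3K27ac coordinates) are stitched within
`stitch_dist = 12500` bp (gap exactly 12,500 merges; 12,501 does not);
peaks fully contained in a promoter window are excluded first. Regions
are ranked by summed member signal; the cutoff sorts signals ascending,
scales rank and signal to [0, 1], and takes the last minimum of
(scaled signal − scaled rank) with a $10^{-12}$ tie tolerance — the
tangent point where the curve's slope reaches 1. Regions strictly above
the cutoff signal are super-enhancers; an exact linear ramp therefore
yields none, and a single dominant region yields exactly one. Gene
association has three modes: promoter overlap (`inside`), nearest-gap
≤ 50 kb (`within50kb`, inclusive), and curated links with score strictly
greater than 1 (`linked`).

## 5. Gene-set enrichment

The enrichment score is the classic weighted running sum: descending by
the chosen statistic (ties broken by gene symbol, so rankings are fully
deterministic), members increment by $|s|^p / N_R$ ($p = 1$ default) and
non-members decrement by $1/(N-k)$; the score is the signed maximum
deviation, positive winning exact ties. A fast $O(k)$ evaluation from hit
indices exploits the piecewise-linear walk (extrema only at or just
before hits); tests verify it against a full re-walk and an independent
implementation.

Nulls are **gene-set permutations** (random same-size sets, shared across
sets of equal size). Phenotype permutation is the textbook choice but a
2×2 design with three replicates admits only 20 distinct relabelings —
far too few. NES divides the observed score by the mean magnitude of
sign-matched null scores; p-values are sign-matched tail fractions with
the +1 continuity correction (hence floored at roughly `1/n_perm`), and
q-values are BH across sets. With ~20 sets under BH, detecting a true
positive at q < 0.05 needs on the order of 1,000 permutations.

## 6. The synthetic-data generator

The generator exists so that every downstream claim is checkable against
planted truth; it is a test instrument, not a biological simulator.

* **Truth table**: effect classes are allocated in exact rounded
  proportions (defaults: 5% cooperative-up, 5% cooperative-down, 3.2%
  antagonistic-up, 2.4% antagonistic-down, 3% dependent-induction);
  effect magnitudes are uniform on [1, 2] log2 with class-consistent
  signs. Chromatin states (5% bivalent, 55% K4-only, 8% K27-only),
  binding (20%) and super-enhancer modes (2% inside, 3% within-50kb, 5%
  linked) are planted per gene. Base means are log-normal(5, 1.5);
  dispersions follow $\min(0.4,\ 0.05 + 10/\mu)$.
* **Genome layout**: genes are laid out on four synthetic chromosomes
  with TSSs 150 kb apart, so promoter windows never collide and planted
  enhancer clusters stay unambiguous.
* **Counts**: NB draws with the planted means/dispersions; library-size
  factors multiply means through an offset, exactly matching the
  estimator's model.
* **Peaks**: promoter-mark peaks are planted in both replicates for
  marked genes; decoys (default 10%) appear in a single replicate only
  and must be removed by consensus. Super-enhancer clusters are four
  1 kb peaks of signal 50; a low-signal background enhancer stratum
  (signal ≈ 2 at 30% of unmarked genes) provides the hockey-stick
  baseline without which the tangent cutoff is undefined.
* **Cross-sample panel**: 56 samples, 20 with the promoter mark and
  expression scaled by 0.2 around log-normal(log 20, 0.75) — small
  enough to be detected by a rank test in ≥ 95% of seeded runs, large
  enough not to be trivial.
* **Scope and limits**: no read-level realism, no strand-specific
  promoters, no correlated gene–gene structure, no batch effects, and
  dispersion is constant across cells. Problem sizes (2,000 genes, 3
  replicates, 2 peak replicates) are this package's own choice of a
  desk-scale regime where every stage finishes in seconds.

All seeded functions call `set.seed` internally on their `seed` argument,
so results are independent of call order; `run_all` derives all stage
seeds from the single config seed and writes provenance headers (package
version, seed, config MD5) but never timestamps, making report bundles
byte-identical across reruns.
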