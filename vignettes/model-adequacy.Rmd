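---
title: "Methods: model fit and adequacy for comparative gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model fit and adequacy for comparative gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adexpr)
```

## The question the package answers

Given a rooted, time-calibrated phylogeny and one expression value per gene
per species (a mean over replicates, with a standard error), which of three
simple models of continuous trait evolution best describes each gene — and,
separately, does that best model describe the gene *adequately*? The first
question is relative (AIC among BM, OU, EB); the second is absolute, and is
answered per gene by a parametric bootstrap of five summary statistics of
the phylogenetic independent contrasts on a model-rescaled "unit tree".

## Models and likelihood

All three models imply a multivariate normal distribution of tip values with
mean `z0` (the root state) and a covariance determined by the tree:

- **BM**: `Cov(i, j) = sigsq * t_ij`, the shared time `t_ij` from the root
  to the MRCA of tips `i` and `j`.
- **OU** (single optimum): pull `alpha` toward `theta`; on an ultrametric
  tree with tip data only, `theta` and `z0` cannot be separated, so the
  package constrains `theta = z0` — the standard single-regime fit. The
  model accumulates variance `sigsq/(2 alpha) * (e^(-2 alpha (T - t2)) -
  e^(-2 alpha (T - t1)))` along a branch spanning depths `[t1, t2]` on a
  tree of height `T`.
- **EB**: BM with rate `sigsq * e^(-r t)`; branch variance
  `sigsq * (e^(-r t1) - e^(-r t2)) / r`, with the `r -> 0` limit reducing
  exactly to BM.

Measurement error is a fixed additive variance: tip `i` contributes `se_i^2`
to its own variance and nothing to covariances. It is *not* estimated —
doing so needs replicate-level modeling that one mean and one SE per species
cannot support.

The likelihood is evaluated by rescaling the tree so each branch carries the
model variance it accumulates, adding `se^2` to terminal branches, and
running the contrasts (pruning) recursion, which yields the exact Gaussian
log-density in `O(n)`; the root state is profiled analytically (its ML value
is the GLS mean the recursion delivers at the root). The test suite checks
this against a dense matrix computation of the same density on a thousand
random small trees.

Parameter counts for AIC include the root state: BM `k = 2` (`sigsq`, `z0`),
OU and EB `k = 3`. Whether published analyses counted the OU optimum as a
separate parameter is rarely stated; with `theta = z0` constrained there is
only one location parameter, so `k = 3` is the defensible count and is used
throughout. Akaike weights are `exp(-dAIC/2)` normalised; exact AIC ties go
to the model with fewer parameters, then to the fixed order BM, EB, OU.

## Optimization

`sigsq` is searched on the log scale in `[1e-8, 1e4]`; `alpha` in
`[1e-8/T, 50/T]` and `r` in `[0, ln(1e5)/T]`, scaled to tree height so the
exponentials stay in range on any time calibration. BM with all `se = 0`
has the closed form `sigsq_hat = sum(pic_raw^2 / v) / n`; otherwise BM is a
one-dimensional bounded search and OU/EB are bounded quasi-Newton searches
from one deterministic start (the BM rate, mild `alpha` or `r`) plus two
seeded random starts (three total by default). Estimates landing within
1e-6 of a bound set a `boundary` flag; a constant trait drives `sigsq` to
the lower bound and is flagged rather than erroring at the fit level (the
pipeline skips such genes upstream with reason `zero_variance`).

## The unit tree and the five statistics

Rescaling with the *fitted* parameters produces a tree on which, were the
model true, the data are BM with `sigma = 1`, so the contrasts are i.i.d.
N(0, 1). Three numerical choices matter here:

- depths in the OU/EB transforms are measured on the **original** tree;
  all adequacy quantities (contrasts, ancestral estimates, node heights)
  are then computed on the **unit** tree. Node heights on the unit tree are
  what make the large-`alpha` degeneracy visible: a strong pull leaves
  almost all root-to-tip variance on the terminal branches, node heights
  collapse, and the node-height slope `s.hgt` is undefined;
- `se^2` is added after model rescaling because measurement variance lives
  on the data scale, not the time scale;
- unit-tree branch lengths below `1e-12` are floored there before the PIC
  division, so degenerate transforms cannot produce 0/0.

The slope statistics share one OLS kernel that returns `NA` when the
predictor variance falls below `1e-12 * max(1, mean(x)^2)` per point —
this is the `s.hgt` `NA` mechanism, and it applies identically to observed
and simulated data. `c.var` is `NA` when all contrasts are zero.

## Bootstrap and p-values

`n_sim` datasets (default 1000) are simulated as BM(`sigma = 1`) from root
state 0 on the unit tree and reduced to the five statistics by the same
kernel as the observed data — the kernel is shared code, vectorised across
replicates, so no code-path bias is possible. With `n` valid (non-`NA`)
null draws, the two-tailed p-value is
`2 * min(1 + #(null <= obs), 1 + #(null >= obs)) / (n + 1)`, capped at 1.
The add-one convention keeps p strictly positive; the two-tailed form is
used for all five statistics, including `d.cdf`, treating a statistic
surprisingly deep in *either* tail as evidence against the model. A gene is
"adequate" when every non-`NA` p-value is at least the cutoff (0.05 by
default); `NA` statistics are excluded from the verdict rather than
counted either way, mirroring how `s.hgt` `NA`s are excluded from
downstream summaries. No multiple-testing correction is applied across
genes: each gene tests one hypothesis (its own fitted model with its own
estimates generated its data).

## Pipeline conventions

Species missing a gene's data are excised from the tree for that gene
(path lengths among the remaining tips are preserved exactly). Genes with
fewer than `min_tips = 4` species are skipped — below four tips the OU and
EB fits are effectively unidentifiable; the threshold is configurable and
recorded in the run metadata. Polytomies are resolved to zero-length
bifurcations (seed-deterministic, covariance-preserving) because the
contrast recursion requires a binary tree. Per-gene seeds derive from a
stable hash of the gene id combined with the master seed, so results are
identical regardless of gene order, column order, or which other genes are
present, and repeated runs are byte-identical.

Replicates are collapsed to species means on the log scale with
`se = sd / sqrt(n)`; the default transform is `log2(x + 1)`, the dominant
convention for expression matrices and safe at zero — the base and offset
are configurable and nothing downstream depends on the choice beyond a
scale factor. CPM, RPKM, and TPM normalizations are provided; with equal
gene lengths CPM and RPKM coincide, and in general the cross-species
pattern per gene is nearly unchanged between them, so normalization choice
has little qualitative effect on model fit.

## The synthetic-data generator

The generator stands in for real multi-species RNA-seq compendia. It
emulates: an ultrametric time tree (pure birth, rate 1, rescaled to exact
height — topology realism is irrelevant to calibration, so no birth–death
machinery); per-gene trait evolution under BM, OU, or EB, plus two
misspecification variants — `BM-2rate` (rate multiplied by 8 on a marked
clade, chosen deterministically as the clade closest to a third of the
tips) and `OU-shift` (optimum displaced by 2 on that clade); and replicate
observation noise, Gaussian on the log scale (default sd 0.1, three
replicates per species), which is where real SEs come from. Defaults are
`n_tips = 20`, tree height 1, `sigsq = 1`, `alpha = 1`, plausible values
for moderately sized comparative expression studies.

What it does *not* emulate: count-level sequencing noise (simulation
starts at normalized log expression), gene-tree/species-tree discordance,
missing-data structure, correlated genes, or multi-optimum regimes beyond
the single shifted clade. Passing calibration tests therefore shows the
machinery is correct and calibrated under its own assumptions — not that
real data satisfy them; the adequacy test itself is the tool for that
second question.

## Problem sizes used in the checks

The package's calibration checks run at sizes chosen to make Monte-Carlo
error small relative to the tolerances: type-I calibration uses 1,000 BM
genes on a 20-tip tree with 500 bootstrap draws per gene (per-statistic
rejection at 0.05 must land in the exact binomial 95% interval around 5%,
[3.7%, 6.4%]); unit-tree calibration pools 200 × 19 contrasts (variance in
[0.9, 1.1], mean in [±0.05]); parameter recovery uses 100 replicates on a
200-tip tree (BM rate within 10% in median; OU pull within a factor of 2
at `alpha * T = 2` — `alpha` is genuinely hard to estimate and a factor-2
median is the realistic bar); misspecification power uses 200 two-rate
genes (c.var rejection at least 3x nominal).

## Known limitations

- Single-regime models only; no multi-optimum or multi-rate OU fits (the
  adequacy machinery would apply to them unchanged, since they satisfy the
  same three-point covariance structure, but regime assignment is a
  modeling decision out of scope here).
- OU/EB require ultrametric trees; non-ultrametric input is a hard error
  rather than a silent approximation.
- The within-species SE is plugged in as known, not jointly estimated.
- A sixth adequacy statistic (the rate coefficient `m.sig`) exists in the
  literature; the five implemented here are the set this analysis is built
  around.
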