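---
title: "First-passage statistics of amino-acid sequences: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{First-passage statistics of amino-acid sequences: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

For an ordered amino-acid pair (x, y), the first-passage distribution is the
probability that, starting from an occurrence of x (the *anchor*), the first
occurrence of y lies exactly L residues away in a chosen scan direction —
toward the carboxyl terminus (C) or the amino terminus (N) — with no y at any
smaller separation. Adjacent residues have L = 1; the anchor itself never
counts as the target, so self-pairs (x = y) are well defined. Passages are
confined to a single protein chain: an anchor whose chain ends before any y
is found is recorded as *censored*, never silently dropped.

If residues were independent and identically distributed, the first passage
to an amino acid with genome-wide frequency $f_y$ would be geometric,

$$P(L) = f_y\,(1 - f_y)^{\,L-1},$$

an exponential in L with decay constant $\lambda_{geo} = -\ln(1 - f_y)$ per
residue, independent of the anchor. Across real proteomes the observed
distributions are indeed close to exponential for most pairs, with a decay
constant set by the target and not the anchor. This motivates the working
model: fit an empirical exponential *background* to each pair's log counts,
and treat localized departures from it as evidence of a correlation between
the two amino acids at that specific separation.

The amplitude of a departure at separation L is summarized by

$$q = \ln\frac{\text{observed count}(L)}{\text{expected count}(L)},
\qquad z = q / \hat\sigma,$$

where the expectation comes from the fitted background
$\exp(a - \lambda L)$ and $\hat\sigma$ is the residual standard deviation of
the log counts within the fit window. A bin is called significant when
$|z| \ge 3$ — three standard deviations from the background. Because q is a
ratio of counts it is invariant under rescaling (raw counts and normalized
probabilities give identical amplitudes), and it reads directly as a
log signal-to-noise ratio.

At the study level, a (pair, L) combination is reported when it is
significant in at least `min_genomes` organisms (default 25), and the
dependence of its amplitude on optimal growth temperature (OGT) is
quantified by the Pearson correlation (two-sided Student-t p-value) and the
Spearman correlation (two-sided permutation p-value) of q against OGT
across organisms.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `l_min`, `l_max` | 2, 49 | residues | the exponential regime sets in after a couple of residues and separations beyond ~50 are dominated by finite gene size; the lower bound keeps the strong nearest-neighbor structure out of the background |
| `clip_sigma` | 3 | residual SDs | one sigma-clipping pass so that genuine peaks (e.g. a strong cysteine pair at L = 3) do not bias the background slope they are judged against |
| `z_thresh` | 3 | background SDs | the classic three-sigma rule for calling a peak within one organism |
| `min_genomes` | 25 | organisms | cross-organism prevalence filter for reported pairs |
| `directions` | N and C | — | both scan directions are counted; a peak of (x, y) in one direction appears for (y, x) in the other |
| `policy` | `split` | — | nonstandard residues cut chains into sub-chains (below) |
| `n_perm` | 1e5 | permutations | Spearman p-value resolution ~1e-5; exact enumeration replaces sampling automatically for n ≤ 8 |
| `sd_mode` | `resid` | — | noise scale for z; a Poisson-approximate alternative (`1/sqrt(count)`) is exposed for low-count regimes |
| `qbar_scope` | `all` | — | the cross-organism mean amplitude averages over every organism with a defined q at the (pair, L), not only those where it is significant |

## Numerical choices

**Fit on raw log counts.** The background is fitted by ordinary least
squares of ln(count) on L over nonzero bins in the window. Normalizing to
probabilities would shift only the intercept, never the slope or residuals,
so raw counts are used directly. Zero-count bins are excluded rather than
pseudocounted: ln 0 is undefined, and under the exponential model at
moderate counts exclusion is unbiased. A pair with fewer than three usable
bins is flagged invalid and skipped downstream instead of raising an error.

**One clipping pass.** After the first fit, bins with absolute residual
above `clip_sigma` times the residual SD are removed and the fit is redone
once. A single pass is enough to protect the slope from isolated peaks
while keeping the procedure deterministic and cheap; iterating to
convergence would couple the background to the peak calls it serves.

**Natural logarithm throughout.** Fits, amplitudes and p-value transforms
all use ln; the Bonferroni threshold $-\ln(0.05/30400) = 13.318$ for a
76-organism, 400-pair family of linearity tests is on this scale.

**Residual SD.** $\hat\sigma$ is the standard OLS residual SD with the
n − 2 denominator, recomputed on the retained bins after clipping.

**Peaks below the fit window** (L = 1 with the default window) are scored
against the extrapolated fitted line — peaks at separations 2 and 3 must be
judged against a background fitted over larger separations if they are not
to bias it.

**Mean first passage.** The mean separation implied by a fitted background
uses the discrete geometric closed form $\langle L\rangle = 1/(1 -
e^{-\lambda})$, not the continuous $1/\lambda$, because separations are
integer-valued. The two agree for small $\lambda$ (abundant targets) and
diverge for rare ones.

**Nonstandard residues.** The model is defined over the 20-letter standard
alphabet. Under the default `split` policy every character outside it (X,
B, Z, U, `*`, gaps) cuts the chain, so an ambiguous residue never anchors
nor terminates a passage and never contributes to a separation — avoiding
phantom long passages across masked regions. Selenocysteine is treated as
nonstandard for the same reason. A `drop_chain` policy (discard any
sequence containing a nonstandard character) is available since published
proteomes differ in how they encode ambiguity.

**Permutation Spearman.** Spearman's rho is the Pearson correlation of
mid-ranks (average ranks on ties, deterministic). The two-sided permutation
p-value uses the add-one estimator $(1 + \#\{|\rho^*| \ge |\rho|\})/(1 +
n_{perm})$ under a caller-supplied seed; for n ≤ 8 all n! permutations are
enumerated and the p-value is exact.

**Tie-breaks.** When one pair is retained at several separations, the
reported (modal) L is the one significant in most organisms, ties broken
toward the smaller separation.

## The synthetic generator

`synthetic_spec()`/`generate_proteome()`/`generate_study()` emulate exactly
the statistical structure the analysis targets, and nothing more:

* chains drawn iid from a typical proteome composition (configurable),
  with lengths geometric around a mean of 350 residues (minimum 30), so
  end-of-chain censoring is exercised at a realistic protein scale;
* optional linear OGT trends on the composition, anchored at a 37 °C
  mesophile reference and renormalized;
* optional planted lag correlations: scanning each chain left to right,
  every occurrence of x overwrites, with probability ε, the residue Δ
  positions downstream with y. Overwrite-based planting (rather than a
  Markov chain) localizes the correlation at exactly lag Δ, giving a clean
  single-peak ground truth; when y = x a planted residue can itself become
  an anchor, and later overwrites win.

What the generator does **not** emulate: protein families and repeats,
phylogenetic covariance between organisms, codon-level structure,
secondary-structure periodicity, or any real thermal-adaptation chemistry.
Tests passing on these synthetic studies therefore validate the statistical
machinery — calibration of the null, recovery of planted effects and
trends — not biological conclusions about real proteomes.

A deliberate subtlety: planting at lag Δ conditionally *depletes* first
passages at separations beyond Δ (a planted y intercepts them), so the
fitted background under a strong planted effect sits slightly below the
iid expectation. Validation therefore compares measured amplitudes against
a brute-force recount of the planted peak relative to its local geometric
neighborhood, not against the global iid law.

## Problem sizes used in the checks

The package's own validation uses sizes chosen to make each property
measurable without waste: closed-form decay-constant recovery uses one
10⁶-residue proteome in 10,000-residue chains (long chains make
end-of-chain censoring negligible, isolating the closed form — with
realistic 350-residue chains the apparent decay gains an extra ~1/chain
length per residue, which is part of what the empirical background absorbs
in real data); null calibration and trend recovery use 40-organism studies
of 100 proteins each over 20 seeded replicates; planted-peak ranking uses
1,000-protein organisms, where the planted cysteine peak dominates every
spurious low-count tail bin. Real proteomes are one to two orders of
magnitude larger, which only tightens every statistic involved.

## Known limitations

* The z-score uses a single pooled residual SD per pair, while log-count
  noise is Poisson-heteroskedastic: bins with very low counts (large L,
  rare pairs) are over-called relative to a 3-sigma nominal rate. The
  cross-organism prevalence filter absorbs this (spurious calls do not
  recur at the same (pair, L) across organisms), and `sd_mode = "poisson"`
  is available when per-bin noise is preferred.
* Background fits on small proteomes with rare amino acids (notably
  cysteine and tryptophan) can fail the three-bin minimum; such pairs are
  flagged and skipped, mirroring the large observed fluctuations of rare
  residues in small genomes.
* Cross-organism correlations are not corrected for phylogenetic
  relatedness; organisms are treated as independent samples.
* The exponential background is a first-order model; systematic curvature
  (e.g. stretched-exponential decay from pooling genes of different
  lengths) is absorbed into the residual SD rather than modeled.

## A minimal session

```{r, eval = FALSE}
library(fpscan)
library(dplyr)

study <- generate_study(
  n_organisms = 40, ogt_range = c(5, 100), seed = 17,
  planted_effects = list(list(x = "C", y = "C", lag = 3,
                              strength = function(ogt) 0.02 + 0.003 * ogt)))

res <- run_scan(study$metadata, config = run_config(), proteomes = study$proteomes)
tidy(res)      # retained pairs with OGT correlations
glance(res)    # study-level counts
autoplot(res)  # OGT vs amplitude for the top pair
```
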