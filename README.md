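# fpscan

First-passage statistics of amino-acid sequences across proteomes.

## The problem

Protein primary sequences are, to a first approximation, strings of
independently drawn amino acids — but not entirely. Some residue pairs
prefer to sit a fixed number of positions apart (cysteines three residues
apart, an arginine followed two residues later by a glutamic acid, ...),
and the strength of these preferences tracks the environment the organism
lives in, most visibly its optimal growth temperature (OGT). `fpscan`
detects such discontiguous correlations with **first-passage statistics**:
for every occurrence of an amino acid x, how far away is the *first*
occurrence of amino acid y?

For independent residues the first passage to y is geometric,

    P(L) = f_y (1 − f_y)^(L−1),    λ_geo = −ln(1 − f_y),

an exponential in the separation L whose decay depends only on the
frequency of the target y. Observed distributions are close to exponential
for almost every ordered pair, so the package fits an empirical exponential
background to each pair's log counts and scores localized departures:

    q = ln(observed / expected),    z = q / σ_resid,

calling a (pair, L) a peak when |z| ≥ 3 within an organism. Across a study
set, pairs significant in many organisms are retained and the dependence of
their amplitude q on OGT is quantified by Pearson (Student-t p) and
Spearman (permutation p) correlations.

The package is for computational biologists who want to scan proteome
FASTA files (or fully synthetic study sets) for separation-specific
amino-acid correlations and their environmental dependence. It includes:

* `count_first_passages()` / `count_all_pairs()` — censoring-aware
  first-passage counting for all 400 ordered pairs, both scan directions,
  in one pass per direction;
* `fit_backgrounds()` — sigma-clipped log-linear background fits, with
  `geometric_null()` and `mean_first_passage()` for the iid comparison;
* `score_deviations()` / `call_peaks()` — amplitude and z-score per
  (pair, separation), peak calls;
* `summarize_pairs()`, `ogt_dependence()`, `mean_length_ogt()`,
  `kruskal_grouping()`, `bonferroni_cutoff()` — cross-organism aggregation
  and the statistical machinery;
* `synthetic_spec()` / `generate_proteome()` / `generate_study()` — a
  synthetic proteome generator with controlled composition, OGT trends and
  planted lag correlations;
* `run_scan()` — the whole pipeline over a metadata table, with TSV
  outputs, plus `tidy()`, `glance()`, `autoplot()` and plotting helpers.

## Worked example

A 30-organism synthetic study in which cysteine pairs three residues apart
are enriched with a strength that grows linearly with pseudo-OGT:

```r
library(fpscan)

study <- generate_study(
  n_organisms = 30, ogt_range = c(5, 100), n_proteins = 150, seed = 17,
  planted_effects = list(list(x = "C", y = "C", lag = 3,
                              strength = function(ogt) 0.02 + 0.003 * ogt)))

res <- run_scan(study$metadata,
                config = run_config(directions = "N", min_genomes = 25),
                proteomes = study$proteomes)
res
#> First-passage scan of 30 organism(s)
#>   directions: N  fit window: [ 2 , 49 ]  z threshold: 3
#>   organisms analyzed: 30  failed: 0
#>   retained (pair, L) combinations (>= 25 genomes): 1
#> # A tibble: 1 × 8
#>   x     y     direction sign      L n_genomes q_bar is_modal
#>   <chr> <chr> <chr>     <chr> <int>     <int> <dbl> <lgl>
#> 1 C     C     N         over      3        28  2.70 TRUE
```

The only retained signal is the planted one: cysteine→cysteine at
separation 3, significant in 28 of 30 organisms, with a mean log-amplitude
q̄ = 2.70 (the observed count at L = 3 is e^2.7 ≈ 15 times the background
expectation). `tidy()` adds its OGT dependence:

```r
tidy(res)
#>   x y direction sign L n_genomes    q_bar is_modal pearson_r    pearson_p spearman_rho spearman_p
#> 1 C C         N over 3        28 2.702576     TRUE 0.9515005 7.245231e-16    0.9719689 9.9999e-06
```

The amplitude rises with OGT (Pearson r = 0.95, Spearman ρ = 0.97; the
Spearman p-value is the permutation floor at 10⁵ permutations). An iid
study with no planted effects retains nothing at the same thresholds.

## Command line

A thin CLI over the same functions lives in `inst/scripts/fpscan.R`
(`synth`, `scan`, `plot` subcommands); see its header for usage. The
methods vignette (`vignettes/first-passage-methods.Rmd`) documents the
model, parameter defaults, numerical choices and limitations.
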