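# igsa

Individual gene-set analysis for bulk and single-cell transcriptomics:
per-sample gene-set expression scores, sign-based enrichment, and an
accumulating clustering that orders disease samples from mild to severe.

Classical enrichment tools summarize each gene by one case-vs-control
contrast, discarding the heterogeneity between patients. `igsa` keeps every
sample: each gene set receives one expression score per sample, pathways
are called significant from how those scores' *signs* split between cases
and controls, and the case samples are then ordered by how far their
pathway profile has drifted from the control profile — a severity ordering
that can be segmented into classes. It is aimed at analysts working with a
gene × sample expression matrix, a GMT pathway collection, and a
control/case phenotype table, who want pathway calls *and* a per-patient
view of them.

## The method in brief

With `g_ij ≥ 0` the log-scale expression of gene `i` in sample `j` and `N`
samples:

1. **Normalize** each gene to its deviation from the average per-sample
   share: `Expr(g_ij) = g_ij / Σ_j g_ij − 1/N`. Positive = above that
   gene's average level; each gene's row sums to exactly 0.
2. **Score** gene set `Q_i` in sample `j` as the mean normalized value over
   `Q_i ∩ S_j` (the members present in the matrix).
3. **Enrich**: per set, count samples scoring `> 0` vs `≤ 0` in cases and
   controls, test the 2×2 table with the two-sided Fisher's exact test,
   adjust by Benjamini–Hochberg. Significant sets are SUPs (case
   up-fraction higher than control) or SDPs (lower).
4. **Cluster**: similarity between two samples over the significant sets is
   the sign-concordance measure SMIC, `L(θ) = N_cgs·θ + N_dgs·(1−θ)` with
   `θ ∈ [0.5, 1]`, profiled to its closed-form maximum
   `max(N_cgs, (N_cgs+N_dgs)/2)`. Starting from the control-mean profile,
   the clustering greedily absorbs the candidate with the highest average
   similarity to all current seeds; absorption rank reads mild → severe.
5. **Segment**: a loess fit to the similarity trace is cut at its flex
   points (curvature sign changes) into severity classes.

## Worked example

A synthetic cohort with known answers: 2,000 genes, 20 controls, 20 cases,
50 gene sets of which 5 are planted up-regulated and 5 down-regulated, with
a linear per-case severity gradient.

```r
library(igsa)

sim <- simulate_cohort(simulation_spec(seed = 42))
enr <- run_enrichment(sim$expression, sim$sets, sim$phenotypes,
                      fdr_threshold = 0.05)
head(enr, 10)
#> # A tibble: 10 × 8
#>    set    n_case_up n_case_down n_ctrl_up n_ctrl_down        p     fdr direction
#>  1 set_04        16           4         0          20  1.54e-7 3.85e-6 SUP
#>  2 set_05        16           4         0          20  1.54e-7 3.85e-6 SUP
#>  3 set_01        15           5         0          20  7.71e-7 3.85e-6 SUP
#>  4 set_02        15           5         0          20  7.71e-7 3.85e-6 SUP
#>  5 set_03        15           5         0          20  7.71e-7 3.85e-6 SUP
#>  6 set_06         5          15        20           0  7.71e-7 3.85e-6 SDP
#>  7 set_07         5          15        20           0  7.71e-7 3.85e-6 SDP
#>  8 set_08         5          15        20           0  7.71e-7 3.85e-6 SDP
#>  9 set_09         5          15        20           0  7.71e-7 3.85e-6 SDP
#> 10 set_10         5          15        20           0  7.71e-7 3.85e-6 SDP
```

The ten planted sets are exactly the ten significant calls: for `set_04`,
16 of 20 cases but 0 of 20 controls score above average (the mildest cases
have barely drifted yet — severity scales the planted shift). Clustering on
the significant sets orders the cases and cuts the similarity trace:

```r
sig <- enr$set[enr$direction != "none"]
cl  <- cluster_samples(attr(enr, "scores"), sim$phenotypes,
                       significant = sig)
cl
#> Accumulating clustering (smic_mle), 20 candidates
#> classes: 5 / 3 / 12 (boundaries at flex points 5, 8 )
#> order: case_01 > case_02 > case_03 > case_04 > case_05 > case_06 > ...
head(tidy(cl), 5)
#> # A tibble: 5 × 4
#>    rank sample_id avg_similarity class
#> 1     1 case_01               10     1
#> 2     2 case_02               10     1
#> 3     3 case_03               10     1
#> 4     4 case_04               10     1
#> 5     5 case_05                7     1
```

The absorption order reproduces the planted severity order exactly
(`case_01` mildest, `case_20` most severe). The first four cases are fully
concordant with the control profile on all 10 significant sets (similarity
10 of a possible 10); from `case_05` on, planted sets start flipping sign
and the average similarity falls, with flex points after ranks 5 and 8
separating a control-like class, a transitional class, and a severe class.
`autoplot(cl)` draws the trace, loess curve and class boundaries;
`plot_markers(double_cluster(...))` shows which pathway is on in which
patient, both axes in clustering order. `igsa_run()` writes all stages as
TSV; `inst/cli/igsa.R` is the shell front end with subcommands `simulate`,
`enrich`, `cluster`, `segment`, `run`, `validate`.

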