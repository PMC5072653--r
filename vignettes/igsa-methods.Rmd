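---
title: "Individual gene-set analysis: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual gene-set analysis: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igsa)
```

## The problem

Classical gene-set enrichment compares one summary of expression change
between cases and controls per gene (a fold change, a t statistic) and asks
whether a pathway's genes are over-represented among the changed ones. That
collapses the cohort's heterogeneity: two patients can activate the same
pathway through different genes, and a pathway can drift progressively with
disease severity in a way a single case-vs-control contrast cannot show.

`igsa` works sample by sample instead. Every gene set gets one expression
score per sample; significance comes from how the *signs* of those scores
split between cases and controls; and case samples are then ordered by how
far their significant-set profile has drifted from the control profile,
yielding a mild-to-severe ordering that can be cut into severity classes.

## Per-sample scoring

Let \(g_{ij} \ge 0\) be the log-scale expression of gene \(i\) in sample
\(j\), with \(N\) samples. The normalized value is the gene's share of its
own total across samples, centred at the average share:

\[
\mathrm{Expr}(g_{ij}) \;=\; \frac{g_{ij}}{\sum_{j'} g_{ij'}} - \frac{1}{N}.
\]

Positive means the gene sits above its cross-sample average in that sample,
negative below; every retained gene's normalized row sums to zero exactly.
Two consequences drive everything downstream: (a) the natural reference for
"up" vs "down" is 0, for genes and for any average of genes; (b) the
transform is invariant to per-gene scale, so genes contribute comparably to
set averages regardless of their absolute intensity.

Genes whose row sum is zero (unexpressed everywhere) have no defined
proportion and carry no between-sample signal; `normalize_expression()`
drops them with a warning rather than imputing. Inputs are expected already
log-transformed; the package validates nonnegativity and offers a
`log2p1` convenience flag for linear-scale matrices, but deliberately does
not guess the user's transform.

The score of gene set \(Q_i\) in sample \(j\) is the arithmetic mean of the
normalized values over \(Q_i \cap S_j\), the set members present in the
matrix after normalization (`score_gene_sets()`). Since the matrix is
dense, the intersection is the same for every sample. Sets intersecting the
matrix in fewer than `min_support` genes are excluded: a set represented by
a single gene merely relays that gene's noise. The default `min_support =
1` keeps the scoring maximally faithful to the plain definition; raising it
is advisable for collections with poor identifier overlap.

## Sign-based enrichment

For each set, count the samples whose score is strictly above 0 versus at
or below 0, separately in cases and controls, and test the resulting 2x2
table with the two-sided Fisher's exact test (minimum-likelihood
convention, via `stats::fisher.test`; degenerate margins give \(p = 1\)).
P-values are adjusted by Benjamini–Hochberg step-up (`stats::p.adjust`;
Benjamini–Yekutieli available for arbitrary dependence). A set significant
at `fdr_threshold` is labelled **SUP** (significantly up-regulated pathway)
when the case up-fraction exceeds the control up-fraction, **SDP** when it
is lower.

Numerical conventions worth stating:

* **Zero scores count as "not above average".** The table must partition
  all samples; exact zeros are measure-zero for continuous data and are
  logged when they occur (they arise routinely for the all-zero start seed,
  see below, but not in contingency tables).
* **Direction comes from the count fractions**, not from mean scores, for
  consistency with the count-based test that confers the significance.
  Tied fractions on a significant set are left unclassified with a warning.
* **Default `fdr_threshold = 0.01`**, a strict choice appropriate for
  collections of a few hundred pathways; 0.05 is the usual alternative for
  smaller collections or exploratory runs and is what the bundled
  simulations use.

Because the test conditions on discrete counts, its p-values are
*super-uniform* (conservative) under the null rather than uniform: they
have large atoms, including one near \(p = 1\) at the modal table. Checks
of null behaviour in the test-suite therefore assert one-sided type-I-error
control at a grid of thresholds, which is the property a valid conservative
test must have, rather than closeness of the p-value distribution to
U(0,1), which discreteness rules out for any correct implementation.

## The SMIC similarity

Two samples are compared through the signs of their scores over the
significant sets. A position is a **CGS** (co-expressed gene set) when both
scores lie on the same side of 0, a **DGS** when on opposite sides; exact
zeros are neither (zero has no direction — this also prevents the all-zero
start seed in gene-set mode from spuriously agreeing with everything). With
counts \(N_{cgs}\) and \(N_{dgs}\) and a weight
\(\theta \in [0.5, 1]\) — the probability that an observed concordance is
not a random coincidence — the similarity is the linear likelihood form

\[
L(\theta) = N_{cgs}\,\theta + N_{dgs}\,(1 - \theta).
\]

`smic(method = "smic_fixed")` evaluates \(L\) at a chosen \(\theta\);
`smic_mle` profiles \(\theta\) out by maximizing over the interval. \(L\)
is linear in \(\theta\), so the maximum sits at an endpoint and has the
closed form \(\max(N_{cgs}, (N_{cgs}+N_{dgs})/2)\): when concordances
dominate, they are all trusted (\(\theta^* = 1\)); when discordances
dominate, the best reading is that signs are uninformative
(\(\theta^* = 0.5\)) and half of all directed positions count. The measure
is symmetric, bounded by the vector length, attains the bound only for
fully concordant vectors, and never decreases when a discordant position
becomes concordant — properties the test-suite checks against a dense
\(\theta\)-grid maximization.

Euclidean distance (negated, so that higher always means more similar),
Pearson and Spearman correlations are available as baselines through the
same interface.

## Accumulating clustering

`cluster_samples()` orders the case samples greedily. The start seed is the
control-mean score vector over the significant sets — the typical healthy
profile. At each step, every remaining candidate's *average* similarity to
all current seeds (start seed included, on equal footing) is computed, and
the candidate with the highest average is absorbed; its average at
selection time is recorded in the trace. Samples that still resemble the
control profile are absorbed early; samples whose profile has drifted
furthest come last, so absorption rank reads as mild-to-severe.

Ties are real: SMIC takes at most \(m + 1\) distinct values on \(m\) sets,
so with few significant sets several candidates often share the maximum,
especially in early steps. Ties are broken by lexicographic candidate id,
logged, making the procedure fully deterministic and invariant to the
input order of candidates. Gene sets can be clustered the same way
(`double_cluster()`): candidates are the significant sets, vectors span all
samples, and the start seed is the zero vector, since no set is tagged
healthy or diseased.

## Flex-point segmentation

The trace of selection-time similarities typically falls in arcs: a
plateau of control-like samples, a slide through intermediates, sometimes a
re-tightening among the uniformly severe. `segment_trace()` fits a loess
curve (degree 2, `span = 0.5` by default — wide enough that only
trace-scale arcs survive on cohorts of tens of samples) to the trace
against rank and places class boundaries at the **flex points**, the ranks
where the fitted curve's second difference changes sign.

Two guards keep this honest on finite data:

* **A curvature floor.** Residual loess wiggle on an essentially straight
  trace produces sign flips of negligible magnitude. Second differences
  smaller than `curvature_tol` count as flat; the default floor,
  \(2\,\mathrm{range}(\hat f)/n^2\) (the curvature of a whole-trace arc of
  about a quarter of the fitted range), passes genuine arcs and rejects
  noise, with an absolute floor of `sqrt(.Machine$double.eps)` so a
  constant trace is one class.
* **`min_class_size`** (default 3): boundaries creating a smaller class
  are merged away, smallest class first. A severity class of one or two
  samples is not interpretable.

A trace too short to fit, or with no qualifying flex point, yields a
single class rather than an error.

## The synthetic cohort generator

`simulate_cohort()` is the package's instrument for studying its own
operating characteristics; its defaults are the study conditions used by
the test-suite and the acceptance script. Per gene, a baseline log2
intensity is drawn from Normal(7, 1) — the magnitude and spread typical of
normalized microarray intensities — floored at 0; each cell adds
Normal(0, 0.3) noise. The default cohort has 2,000 genes, 20 controls and
20 cases, and 50 disjoint sets of 30 genes, 5 planted up and 5 planted
down. Case \(j\) of \(n\) carries severity \(j/n\); planted-up genes gain
`effect * severity` (default maximum shift 1.5 log2 units — a moderate,
clearly biological effect), planted-down genes lose it, all floored at 0.
Severity is linear so that ordering recovery is a well-posed question with
a strictly monotone ground truth.

The generator reproduces bit-for-bit from one integer seed and leaves the
caller's RNG stream untouched. `simulate_trace()` provides the
segmentation fixtures: a noisy straight line (no curvature change — one
class) and two opposite-curvature arcs joined at a known junction.

What the generator does *not* emulate — batch effects, probe saturation,
correlated noise across genes, overlapping pathways, heavy-tailed
intensities — bounds what passing simulations show: they demonstrate that
the implementation recovers planted structure under clean Gaussian
conditions at realistic effect sizes, not that the method is robust to
every artifact of real platforms. Disjoint sets are the default precisely
so that "planted" and "null" are unambiguous when counting false
positives; `overlap = TRUE` relaxes this at the cost of that clarity.

With the default conditions the package's own checks observe: planted-set
recovery of at least 9 of 10 with at most one false positive at FDR 0.05
in ≥ 90% of seeds; a null significant fraction indistinguishable from 0;
and median Spearman correlation 1.0 between absorption rank and planted
severity. The severity recovery deserves a caveat: beyond mid-severity all
cases have fully concordant sign profiles, so their relative order rests
on the deterministic tie-break rather than on signal — sign-based
similarity orders *regimes* sharply but is intentionally coarse within
them.

## Pipeline defaults and scope

`igsa_run()` writes every stage as TSV plus a parameter-echoing log, and
is byte-deterministic given inputs and configuration. Clustering consumes
**SUP-only** scores by default: in practice down-regulated calls are the
less reliable direction (low-expression genes are noisier on the
proportion scale), and a contaminated significant list degrades the
ordering. `direction_filter = "both"` is the right choice when both
directions are trusted — the bundled simulations use it, since their SDPs
are genuinely planted. In-memory use via `run_enrichment()` /
`cluster_samples()` and the thin command-line front end
(`inst/cli/igsa.R`, subcommands `simulate`, `enrich`, `cluster`,
`segment`, `run`, `validate`) expose the same functions and defaults.

Problem sizes throughout the bundled simulations (20-seed batches of the
default cohort; 200-set null cohorts of 3,000 genes) were chosen as the
smallest at which the binary pass/fail questions above are answered with
comfortable Monte-Carlo margins.

Known limitations, beyond the generator's idealizations: cohorts with very
few controls weaken both the start seed and the contingency tables; with
one case and one control the sign test degenerates entirely. Identifier
namespaces are the user's responsibility (`igsa_validate()` reports
per-set overlap before any computation). Probe-level input, normalization
of raw intensities, and survival analysis of the resulting classes are out
of scope.
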