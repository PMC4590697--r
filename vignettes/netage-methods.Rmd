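---
title: "Methods: how netage measures the network integration of new genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how netage measures the network integration of new genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netage)
```

## The question and the data model

New genes arise continually along a lineage — mostly by DNA- or RNA-level
duplication, occasionally de novo — and must work their way into the
pre-existing gene–gene interaction (GGI) network to acquire function.
`netage` quantifies that integration process from three tabular inputs:

* a **scored edge list** (gene A, gene B, confidence in [0, 1]), the form in
  which integrative protein-interaction databases export their evidence;
* a **gene age table** assigning each gene to a phylogenetic branch, plus a
  branch table giving each branch's origination interval in millions of
  years (myr); and
* optional annotation tables: a genes × tissues expression matrix,
  parent→child duplicate pairs, essential-gene lists, category labels.

Networks are undirected simple graphs (igraph objects): self-interactions
are dropped, duplicate records collapsed (keeping the maximum score for a
pair, i.e. the strongest evidence), and only genes participating in a
retained interaction become nodes — the age-stratified statistics describe
network members, not the genome.

## Thresholds and their conventions

Two thresholding conventions are used deliberately and exposed as options:

* PPI networks retain scores **no smaller than** the cutoff
  (`score >= min_score`), with 0.68 — the median of the HIPPIE-style score
  distribution — as the medium-confidence default and 0.77 as the stringent
  reanalysis value.
* Co-expression networks link genes whose Pearson correlation across
  tissues is **strictly greater than** the cutoff (default 0.4). Genes
  constant across tissues carry no correlation signal and are removed
  first; fewer than three tissues is an error because the correlation is
  then meaningless. An optional `log2(x + 1)` transform is available; the
  default correlates raw values.
* An expression **call** is `value > 1.0` (FPKM-like), strictly; binary
  protein-level calls work with `threshold = 0`.
* **Hubs** are genes with degree ≥ 6, the conventional medium connectivity
  of genome-scale PPI networks; `hub_at_median = TRUE` derives the cutoff
  from the network at hand instead.

## Ages

Each branch's numeric age is its interval midpoint. The oldest branch
(branch 0) is unbounded above, so it receives a sentinel age — 500 myr by
default — which is a plotting/regression convention, not a biological
estimate; it is configurable and all conclusions that matter are driven by
the dated branches 1–12. The packaged human and mouse branch tables are
approximate transcriptions of published divergence-time trees (the sources
present them graphically); supply your own branch table when absolute times
matter. "Young" genes default to branches 8–12, the primate-specific
period of the human table.

## Topology metrics

Degree and betweenness come from igraph. Betweenness is reported
unnormalized, matching the classical definition
B(v) = Σ_{i≠j≠v} K(ivj)/K(ij) summed over unordered pairs, where K(ij)
counts shortest i–j paths and K(ivj) those through v; a normalized variant
(dividing by (n−1)(n−2)/2) is available for cross-network comparison. The
test suite checks igraph's values against an independent breadth-first
enumeration oracle on hundreds of small random graphs.

Core/periphery **layers** rank genes by degree (descending, ties broken by
gene id so results are reproducible) and slice the ranking into five
near-equal shells; layer 1 (top 20% of degrees) is the core. When sizes
cannot divide evenly the extra genes go to the top layers.

The **degree-distribution exponent** can be fit two ways. The default is
least squares on the log10 frequency versus log10 degree histogram — the
historical method in the PPI literature, and the one that produces the
small exponents (< 2) typically reported for protein networks. The
statistically preferred alternative is the discrete maximum-likelihood
(Clauset-style) estimator via `igraph::fit_power_law`, with the lower
cutoff `x_min` either KS-selected or fixed. The two estimators answer
slightly different questions (whole-distribution slope versus tail
exponent) and can differ substantially on the same network; both are kept
because published exponents rarely state their method. For validating the
simulator against the closed-form preferential-attachment exponent of 3 we
use the MLE with `x_min = 10`: the pure growth model's degree law only
approaches its asymptotic power law in the tail, and small `x_min` values
absorb the curved low-degree regime into the fit.

## Age-stratified profiles

`age_centrality_profile()` summarizes centralities per branch over
network-member genes, with standard errors of the mean. Betweenness is
summarized as `log10(mean(B) + 1)` by default; averaging `log10(B + 1)`
per gene is available because published "average betweenness (log10)" axes
rarely state which convention they used, and the two differ for skewed
distributions.

Profile regressions default to a **quadratic** polynomial in age: the
age–centrality trends are curvilinear (fast early rise, saturation), and
the quadratic is the lowest-order curve that captures that; the degree is
exposed (`poly_degree`) and a sensitivity check simply refits at other
degrees. Regressions are unweighted across branches. The
interaction-**acquisition rate** is defined as mean degree divided by
branch age — cumulative interactions amortized over the gene group's
lifetime — because the "interactions per myr" quantity has no standard
formula; an incremental variant (difference in mean degree between
adjacent branches over the time gap) is provided. The rate–age trend is
fit as a power law, i.e. ordinary least squares of log10(rate) on
log10(age).

## Duplicate pairs: inheritance and its null

For a parent→child duplicate pair, the **shared-partner fraction** is
|N(p) ∩ N(c) \ {p, c}| over the child's partner count (excluding the
parent): the fraction of the child's partners attributable to inheritance.
Two alternative denominators are available — the parent's partner count
(the natural exposure when estimating a per-edge retention probability)
and the union (Jaccard). A child whose only partner is the parent is
flagged degenerate and contributes 0.

The null model re-draws the same number of uniform random ordered gene
pairs from the network `reps` times (default 1000, minimum 100) and
records each replicate's mean fraction; reported are the null mean, the
observed/null fold, and a one-sided empirical p-value. The whole procedure
is reproducible bit-for-bit from its seed.

## Preferential attachment of novel links

After removing a young gene's interactions shared with its parent, its
remaining **novel** partners are classified into high/moderate/low
centrality terciles — network-wide, equal gene counts per tercile, ranked
by degree or betweenness — and the observed tercile counts are tested by a
chi-square goodness-of-fit against expectation proportional to tercile
sizes. Age preference is tested analogously: observed old/young partner
counts versus a seeded uniform draw of the same number of partners per
young gene, compared in a 2×2 two-sided Fisher exact test (no continuity
adjustments; the exact test handles empty cells).

One design point deserves emphasis. On observational data the terciles are
computed from the analyzed network itself, as published analyses do. When
*calibrating* the test on the growth simulator, however, the centrality
table is computed on the network with the tested novel links removed
(`remove_novel_links()`). The reason is a selection bias: each counted
link raises its own target's final degree, so conditioning on being chosen
inflates the high tercile even when targets are drawn uniformly. In our
calibration runs the bias is dramatic — evaluated against final-network
terciles a uniform kernel is "detected" in nearly all runs, while against
pre-attachment terciles the test holds its nominal size (≤ 5–10% false
positives) and still detects the rich-get-richer kernel essentially
always.

## The growth simulator and what it does (not) emulate

`grow_network()` implements duplication–divergence with optional
preferential attachment: from a small seed clique, each new node either
duplicates a uniformly chosen extant node — inheriting each parental edge
independently with probability `retention_q` — or is born de novo; it then
draws `n_new_links` novel targets, uniformly or with probability
proportional to degree. Nodes map onto the 13 branches of the configured
branch table in birth order, so every downstream operation (age tables,
profiles, young/old splits, pair manifests) runs end to end on simulated
data. Defaults: `p_duplication = 0.95` (duplication dominates recent gene
birth), `retention_q = 0.3`, `n_new_links = 2`, degree-linear kernel.
`simulate_expression()` adds an age-coupled tissue-breadth structure
(default slope 0.04 tissues/myr over a 27-tissue panel, log-normal
expressed values straddling an FPKM-like call threshold of 1), and
`simulate_annotations()` assigns essentiality with probability logistic in
degree.

The simulator reproduces the *statistical couplings* the analysis assumes
— older nodes with higher degree and broader expression, duplicates
sharing parental partners, novel links biased toward high-degree old nodes
— but not the biology it abstracts from: no edge loss over time, no
expression-level constraint on who can interact with whom, no modular or
complex structure, uniform parent choice. Green tests on simulated data
therefore validate the estimators and the plumbing, not any claim about
real interactomes.

**Recovering `retention_q`.** The child-denominator fraction is *not* an
estimator of `q`: immediately after duplication it equals 1 by
construction (every child partner is inherited) and only drifts toward `q`
through later contamination. The package's recovery estimator
(`estimate_retention()`) instead restricts both the parent's partner set
and the shared count to genes born before the child. Because every edge
forms at the birth of its younger endpoint, those are exactly the
parent's partners at the child's birth, each inherited independently with
probability `q` — making the per-pair fraction binomial and the mean
unbiased, whatever happens to either copy afterwards. Simulations at
q ∈ {0.1, 0.3, 0.5, 0.8} (20 replicate 400-node networks each) recover the
generating value within sampling error.

## Numerical and degenerate-input choices

* Ranking ties (layers, terciles) break by gene id after degree, making
  every partition deterministic.
* A constant response gives R² = 0 (not NaN) in profile regressions; the
  power model requires strictly positive values and says so.
* Layer occupancy rows sum to 100 to within 1e-9.
* Chi-square expectations are tercile-size-proportional (sizes can differ
  by one gene); an all-counts-at-expectation table yields statistic 0 and
  p = 1.
* All Monte Carlo operations (random-pair null, uniform partner draws,
  simulator) restore the caller's RNG state and are bit-for-bit
  reproducible from their seed arguments; `run_all()` writes byte-identical
  output bundles for identical configuration and seed.

## Problem sizes used in validation

The shipped validation suite works at sizes chosen to make sampling error
small relative to the tested effects while keeping the suite quick to run:
5,000-node networks (three replicates, averaged) for the
preferential-attachment exponent; 400-node networks × 20 replicates per
retention value for parameter recovery; 500-node networks × 50 replicates
per kernel for detection calibration; 200 random ≤ 12-node graphs for the
betweenness oracle; and exhaustive plus randomized 2×2 tables with margins
up to 30 for the Fisher oracle.

## Known limitations

* Branch time tables are approximate; treat absolute myr values (and the
  branch-0 sentinel especially) as display conventions.
* The degree-exponent least-squares default inherits the well-known biases
  of histogram regression; use the MLE for quantitative claims.
* The acquisition rate divides present-day degree by age and therefore
  conflates acquisition and loss; the simulator has no edge loss, so this
  is exact there but an approximation on real data.
* `mechanism_composition()` treats unannotated genes as their own class
  rather than imputing; fractions are over annotated young genes only.
* Both random expectations (the pair null and the age-preference draw)
  sample uniformly over network genes. A degree-preserving variant would
  isolate age effects from degree effects; it is deliberately not
  implemented, and conclusions about age preference should be read with
  the degree–age coupling in mind.
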