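---
title: "Methods: differential co-expression networks, local partial correlation, and key-driver topology"
author: "diffcoexpr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffcoexpr)
```

# The problem

When a biological system moves between two states — a gene knockout versus
its control, or tumor versus normal tissue — some gene pairs change how
strongly their expression co-varies, even when neither gene changes much in
mean. Differential co-expression analysis looks for these pairs. The working
hypothesis behind this package is that genes which *gain* correlations
during a state transition are disproportionately close, in network terms,
to the genes that cause the transition (the *key drivers*): in a B-cell
knockout the immunoglobulin genes lose their common driver and co-vanish;
in a heterogeneous cancer the drivers sit upstream of the rewired modules.
The package provides the full chain needed to examine that hypothesis:
differential expression, per-condition network inference, differential
correlation, local partial correlation for under-sampled designs, and
topological statistics relative to a key-driver set — plus a synthetic-data
generator with planted truth, so that every stage can be validated without
access to any particular microarray repository.

# The meta-analytic funnel

All three inferential stages (differentially expressed genes, co-expression
edges, differentially correlated pairs) share one funnel across the $m$
parallel datasets:

1. **Per-dataset statistic.** A paired or Welch $t$ (genes), a Pearson
   correlation with the $t$-tail p-value on $n-2$ df (edges), or the Fisher
   $z$ difference test
   $Z = (z_1 - z_2)/\sqrt{1/(n_1-3) + 1/(n_2-3)}$, $z = \mathrm{atanh}\, r$
   (pair differences).
2. **Direction filter.** The signed effect must point the same way in at
   least $k$ of $m$ datasets (2 of 2 in the two-dataset preset, 3 of 5 in
   the five-dataset preset). Zero effects count toward neither direction.
   An optional veto removes units where a dissenting dataset is itself
   nominally significant; it is off by default because the published form
   of the funnel requires only the $k$-of-$m$ agreement.
3. **Per-dataset screen.** At least $k$ of the agreeing datasets must be
   individually significant at the stage's nominal level (0.05 for genes,
   0.20 for correlations, 0.10 for correlation differences in the default
   preset).
4. **Fisher combination.** Two-sided p-values of the agreeing datasets are
   combined by $X = -2\sum \log p_i \sim \chi^2_{2m'}$.
5. **FDR.** Benjamini–Hochberg adjustment of the combined p-values over the
   units that survived steps 2–3 (a sequential funnel: the screen defines
   the family), thresholded at the stage's q (0.10 genes, 0.025 edges,
   0.02 pair differences).
6. **PUC.** Edges must have a correlation sign concordant with the product
   of the two genes' differential-expression directions (positive for
   UP/UP and DN/DN, negative otherwise). Discordant — "unexpected" —
   correlations are discarded. The concordance rule is our reconstruction
   of this filter; it matches the observation that same-direction pairs in
   the motivating analyses all carry positive partial correlations, and it
   is prominently switchable (`puc = FALSE`).

**Why two-sided p-values in step 4.** Combining one-sided p-values taken
toward the observed consensus looks more powerful, but those p-values are
Uniform(0, ½) under the null once the direction has been selected from the
data, which destroys the calibration of step 5: the null distribution of
the combined statistic is no longer uniform and the BH guarantee fails.
Directionality is therefore enforced solely by the filter in step 2, and
the combination stays two-sided and calibrated. This choice costs power —
see *Operating characteristics* below — and we consider the trade
deliberate: a differential-correlation list with an honest FDR is worth
more than a longer list without one.

A differentially correlated pair (DCP) must additionally be an edge of
exactly one condition network: a **gain** when the edge exists only in the
perturbed/tumor network, a **loss** when only in the control network.
Pairs significant in the difference test but edges in both networks (or
neither) are excluded; candidate pairs are those nominally correlated
(p < `p_screen`) in at least one condition.

# Local partial correlation

With hundreds of DEG nodes and a few dozen samples the global precision
matrix is not estimable, so partial correlations are computed *locally*:
for each screened pair, only the correlation sub-matrix over the pair plus
its first-order neighborhood (genes significantly correlated with either
pair member; genes correlated only with the neighbors are excluded) is
inverted, and only the pair's entry
$-\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}$ is kept, with a two-sided
$t$ p-value on $n - k - 2$ df, $k$ the conditioning-set size. When the
neighborhood outgrows the per-condition sample count $n$, the
$\lfloor n/2 \rfloor$ neighbors with the largest
$\max(|r_{\cdot i}|, |r_{\cdot j}|)$ are retained (the trigger compares to
$n$ and the cap is $n/2$, read literally from the method's description;
the ranking aggregator is switchable to the mean). Ties at the cut break
lexicographically, singular sub-matrices receive a $10^{-8}$ diagonal
ridge with a warning, and datasets with fewer than 6 samples in a
condition are skipped. Two exact reduction points anchor the
implementation and its tests: with an empty conditioning set the LPC and
its p-value equal the Pearson quantities, and when the conditioning set
saturates the variable set the LPC equals the global precision-matrix
partial correlation.

# Topology relative to key drivers

Two measures locate a gene relative to an externally supplied key-driver
set in the (tumor/perturbed) network:

* **Minimum shortest path (MSP):** the smallest unweighted BFS distance to
  any driver; 0 for drivers themselves, undefined (and excluded from group
  comparisons, with counts logged) when no driver is reachable.
* **Bipartite betweenness centrality (BBC):** Brandes-style fractional
  betweenness restricted to ordered pairs (driver, peripheral gene), where
  peripheral genes are the degree-1 nodes. Interior vertices of the
  shortest paths accumulate $\sigma_{st}(v)/\sigma_{st}$; endpoints get no
  credit. Fractional counting is used because raw path counting is
  ambiguous under path multiplicity; the two coincide when shortest paths
  are unique, and a raw-count mode is available (`bbc_mode = "count"`).

DC genes are compared against the remaining eligible genes (non-driver,
non-peripheral) by the Mann–Whitney rank-sum test (normal approximation
with tie correction) and by a label-permutation test of the mean BBC
difference with $p = (1 + \#\{|T^\pi| \ge |T|\})/(B + 1)$, seeded and
reproducible, $B = 10{,}000$ by default. The exact permutation scheme is
underdetermined in the motivating work; permuting the DC label over the
eligible genes is our documented choice.

# The synthetic generator

`generateTruth()` + `sampleDatasets()` emulate the study designs the
pipeline targets: $m$ parallel datasets, two conditions, planted mean-shift
DEGs, planted per-condition correlation structure with gain and loss pairs,
causal hub genes whose correlations are gained in condition B, optional
pairing, optional inter-sample heterogeneity. Defaults (chosen once, as the
reference study conditions):

* 300 genes, 60 DEGs at ±1.5 SD (units of total per-sample SD), two
  datasets of 12 + 12 samples, paired.
* 5 causal hubs × 4 partners: hub–partner correlations 0 → 0.8 in
  condition B (20 primary gain pairs). Blocks are one-factor (the hub
  drives the partners), so partner–partner pairs carry induced secondary
  gains of about $0.8^2/(1-\mathrm{ICC})$; they are recorded in the truth
  as non-primary and count as true positives in recovery metrics, while
  sensitivity statements refer to the primary pairs.
* 10 loss pairs (0.8 → 0) and 5 shared pairs (0.8 in both conditions —
  edges of both networks, hence never DCPs; they exercise the
  exactly-one-network exclusion and the null calibration of the
  difference test).
* Gains and losses are planted between same-direction DEGs with positive
  correlation, the biologically natural case (co-regulated genes moving
  together) and the one the PUC filter retains.
* **Pairing.** The reference design is littermate-paired, so the default
  is a paired draw with a per-gene, per-pair random intercept of variance
  ICC = 0.15 (total variance 1). Litter/pair effects of 10–30% are
  typical for inbred designs; the value must also satisfy
  $1-\mathrm{ICC} > r_{\text{planted}}$ for a planted observed
  correlation of 0.8 to be representable at all (the intercept is shared
  across conditions and cannot carry a condition-specific correlation),
  which bounds the ICC below 0.2. The residual correlation is scaled up
  by $1/(1-\mathrm{ICC})$ so that the *observed* within-condition
  correlation matches the planted target — verified empirically in the
  tests (planted 0.8 recovered within ±0.1 at $n = 200$).
* **Heterogeneity** $h$: each condition-B sample activates each hub block
  with probability $1-h$; inactive blocks revert to the baseline
  structure for that sample, emulating tumors with heterogeneous causal
  factors.
* Matrices are repaired to the nearest PSD matrix by eigenvalue clipping
  with re-normalised unit diagonal; planted entries are asserted to stay
  within 0.02 of target. All randomness flows from explicit seeds.

What the generator does **not** model: probe-level artifacts, saturation,
batch effects, non-Gaussian noise, and mean–variance coupling. Passing the
recovery suites therefore shows that the inferential chain is correct and
calibrated under its own assumptions, not that any particular microarray
result will reproduce.

# Operating characteristics at the reference conditions

The recovery suite (200 seeded replicates of the default design) measures:
DEG sensitivity for 1.5 SD shifts; sensitivity and empirical FDR for the
primary gain pairs; and the gain/loss confusion among detected pairs. DEG
sensitivity sits at the edge of 0.90: with $n = 12$ pairs per dataset the
paired $t$ has per-dataset power ≈ 0.95 at 1.5 SD, and the funnel requires
nominal significance in both datasets. Gain-DCP sensitivity is
structurally lower, around 0.5: the difference statistic for $r: 0 \to
0.8$ at $n = 12$ has mean $Z = \mathrm{atanh}(0.8)/\sqrt{2/9} \approx
2.33$ per dataset, and even before any multiplicity adjustment the
probability that the two-sided Fisher combination of two such tests clears
the 0.02 FDR stage is at most ≈ 0.7; requiring both DEG endpoints to be
recovered compounds it. This ceiling is a property of the design
(two datasets of 12 + 12 at these thresholds), not of the implementation;
the same chain reaches high sensitivity with more samples or datasets.
Empirical DCP FDR stays near 0.02, well under control, and detected pairs
essentially never cross the gain/loss classification (the host-network
rule makes the classes structurally disjoint). Null calibration — no
planted effects for DEGs, identical correlation structure in both
conditions for DCPs — keeps discovery rates below the nominal q levels.

Problem sizes used by the validation suites (chosen to make the Monte
Carlo error small relative to the margins checked): 200 replicates for
recovery, 100 for null calibration and the Gaussian-chain LPC check, 30
pooled replicates for the causal-enrichment analogue, 200 random graphs
(≤ 8 nodes) for exhaustive path-enumeration cross-checks, and 1,000
random vectors for the meta-statistics oracles.

# Numerical and degenerate-input conventions

* Zero-variance $t$ tests return $p = 0$ when the mean difference is
  nonzero (unbounded evidence), $p = 1$ otherwise; they then survive or
  fail the FDR step like any other unit.
* Constant vectors make a correlation *untestable* (NA), not an error;
  untestable units are excluded from the funnel and a gene untestable in
  too many datasets to reach $k$ is excluded and logged.
* $|r| = 1$ returns $p = 0$; Fisher $z$ inputs are clipped away from ±1
  by $10^{-12}$ before the difference test.
* Pairwise statistics use complete cases for that pair.
* Equal opposing support in the direction filter (possible when
  $k \le m/2$) yields no consensus and the unit fails — a deterministic
  tie rule.
* All expression values are assumed log-scale; median normalization
  subtracts each array's median over non-missing genes and is idempotent.

# Known limitations

* The moderated (random-variance) $t$ used by some array suites is
  replaced by the classical paired/Welch $t$; with ≥ 10 samples per group
  the difference is small, but very small designs will differ.
* The PUC filter is a reconstruction (sign concordance); if the original
  filter differed, edge sets near the threshold may differ.
* The per-dataset screen and the FDR family are defined sequentially;
  computing BH over all pairs instead would be more conservative. Both
  interpretations are defensible; the sequential one mirrors the funnel's
  published description and is what the calibration suite validates.
* LPC neighborhoods come from each dataset's own screened graph, so LPC
  edge sets are not nested across datasets; only the final meta-analysed
  network is reported.
* The permutation test and the BBC raw-count mode are provided for
  completeness but are not part of the calibrated funnel.

# A minimal run

```{r example, eval = FALSE}
res <- runPipeline(
  config = dcConfig("bcko"),
  simulate = list(truth_config = truthConfig()),
  seed = 1, output_dir = "dc-run")
rr <- recoveryReport(res, res$truth)
res$log          # the funnel: pairs screened -> direction -> FDR -> PUC
rr$deg_sensitivity
rr$dcp_gain_sensitivity_primary
```
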