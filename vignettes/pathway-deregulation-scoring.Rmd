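---
title: "Per-sample pathway deregulation scoring: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-sample pathway deregulation scoring: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathdereg)
```

## The problem

In many case–control expression studies the biological group effect is
small compared to the variation between individuals. Gene-level testing
then finds few or no differentially expressed genes, and group-level
pathway enrichment — which typically consumes such gene lists — finds
nothing either. Two things help: aggregating weak, distributed signals
over the genes of a pathway, and scoring each *sample* rather than each
group, so the result can feed per-patient prediction. This package
scores every pathway in every sample by its *deviation from the normal
(control-typical) state*: low = normal, high = deregulated.

## The model

### Step 1 — expression preprocessing

Input is a non-negative expression matrix on linear scale (log2 data is
exponentiated on load), with probe rows mapped to Entrez genes and
collapsed by arithmetic mean. Two transforms follow:

* **Noise floor.** All values below the global nearest-rank
  `q`-quantile of the matrix (default `q = 0.05`) are raised to that
  threshold. Unexpressed genes fluctuate around a platform detection
  limit; without flooring, that fluctuation would later masquerade as
  deviation. A single global threshold treats noise as a property of
  the platform, not of individual genes, and flooring (rather than row
  removal) keeps the matrix shape stable.
* **Per-gene min–max scaling** to $[0,1]$ over *all* samples. This puts
  genes with very different dynamic ranges on one scale and bounds
  everything downstream. A zero-range gene carries no information and
  maps to 0.5 everywhere; its deviations are then zero because the
  reference is also 0.5.

### Step 2 — pathway graphs

KGML entries become nodes — `gene` (one or more Entrez members),
`group` (a complex; members are the union of its components), and
`compound` — and relations become signed directed edges
(inhibition/repression $\to -1$; activation/expression $\to +1$; other
subtypes $\to 0$; inhibition wins when subtypes conflict, because a
missed inhibition is the costlier error). `map` entries are links to
other pathways with no measurable content and are dropped. Compound
nodes are parsed but excluded from scoring: they are not measured by an
expression array, and keeping them would only dilute node values with
zeros.

### Step 3 — node values

For gene $g$, the reference $r_g$ is the median of its scaled values
over control samples. Sample $s$'s deviation is $|x_{gs} - r_g|$, and a
node's value is the mean deviation of its measured member genes.
Deviation — not signed activity — is used deliberately: a sizeable
share of pathway relations is inhibiting (about 12% on average, more
than half in some pathways), so "all nodes highly expressed" does not
characterize an active pathway, and any signed activity score inherits
that ambiguity. Deviation from normal is well defined regardless.

**Jackknife-matched reference.** A control sample must not be compared
against a median it helped form: its deviation would be biased low and
the case-vs-control test would be sharply anti-conservative (we measured
a type-I rate of 0.18 at $\alpha = 0.05$ on null data with 11 controls).
Each control is therefore compared against the median of the *other*
controls. That alone leaves a second asymmetry — cases would face a
median of $n$ controls while controls face $n-1$, estimators with
different sampling variance — so each case sample likewise omits one
control, assigned by deterministic rotation over name-sorted samples.
Every sample then faces a median of $n_{ctrl}-1$ control values it did
not contribute to, and scores are invariant to column order.

### Step 4 — pathway scores

Topology enters as a *rough* importance weight rather than a detailed
propagation model: methods that consume curated structure in fine
detail tend to inherit its errors. A node's downstream reach $r_i$ (how
many distinct nodes it can influence along directed relations,
sign-agnostic, self excluded) is normalized to give
$w_i = 1 + r_i / \max_j r_j \in [1, 2]$ — hubs with wide feedback count
up to twice as much as leaves, never more. The score is the weighted
mean of node values, hence bounded in $[0,1]$, exactly 0 for a sample
sitting on the reference, and independent of the weights whenever node
values are uniform.

Pathways with fewer than `min_nodes = 5` measured nodes are skipped:
one- or two-gene "pathways" produce noise-driven scores and would
dominate rankings by chance.

## Evaluation framework

* **Group testing.** Per pathway, a two-sided Wilcoxon rank-sum test of
  case vs control scores: exact when both groups have $\le 25$ samples
  and scores are tie-free, tie-corrected normal approximation
  otherwise. P-values become Benjamini–Hochberg FDRs; their mean over
  pathways ($\overline{FDR}$) summarizes the comparison.
* **FDR ratio.** $-\log_2$ of real-data $\overline{FDR}$ over the mean
  $\overline{FDR}$ of 10 mock datasets, each a random split of the
  pooled samples into two (near-)equal artificial groups. The first
  artificial group takes the control-reference role, and the reference
  is recomputed per mock — the mock arm must pay the same reference
  estimation cost as the real arm, otherwise the comparison flatters
  the real data. Base 2 is the package-wide convention; it is also the
  unique base under which the published benchmark table of
  (FDR, M\_FDR, ratio) triples is internally consistent.
* **Sample-size curves.** One group is repeatedly subsampled to each
  size with the other intact; a parallel mock arm draws both artificial
  groups from the control pool only, showing how much *apparent*
  separation a given group size produces with no real difference. The
  varied mock group matches the tested size and the remaining controls
  form its counterpart — a choice made because the control pool is
  finite; it keeps the mock arm's total sample count comparable to the
  real arm's.
* **Structural uncertainty.** A target pathway is degraded by removing
  a fraction (5–50%) of nodes or relations uniformly at random
  (`floor(fraction * N)` items; node removal takes incident relations
  with it), rescored within the full collection, and checked against
  the top-`k` (default 25) of the median-difference ranking. Scores of
  unperturbed competitors are computed once and reused — perturbing one
  pathway cannot change them.

## The synthetic generator

`simulate_expression()` builds
$x_{gs} = \exp(\beta_g + \phi_s + \varepsilon_{gs}) \cdot e^{\mathbb 1[s \in case,\ g \in effect]\,\log\theta}$:

| parameter | default | meaning |
|---|---|---|
| `gene_sd` | 1.0 | SD of per-gene log baselines $\beta_g$ (spans the usual intensity range) |
| `individual_sd` | 0.1 | SD of the global per-sample factor $\phi_s$ (residual array effect after normalization) |
| `residual_sd` | 0.5 | SD of per-gene, per-sample variation $\varepsilon_{gs}$ — the individual biological variation that masks group effects |
| `effect_size` | 1.5 | multiplicative effect $\theta$ on effect-pathway genes in cases |
| `inhibition_fraction` | 0.12 | target share of inhibiting relations |
| `n_pathways` | 250 | so a top-25 window is ~10% of the collection |
| `p_shared` | 0.1 | chance a pathway gene is reused from another pathway |

With these defaults the log effect ($\log 1.5 = 0.41$) is smaller than
the per-gene individual variation (0.5) — single genes are barely
detectable and only aggregation over a pathway's nodes recovers the
signal, which is precisely the regime the method targets. The effect is
applied *after* all random draws, so sweeping `effect_size` under one
seed changes only the effect genes' case columns; effect-size sweeps
are paired by construction. `simulate_study()` designates as the effect
pathway the one whose node count is closest to the collection median —
perturbation experiments should act on a typical pathway, not an
extreme one.

What the generator does **not** emulate: platform-specific probe
effects, batch structure, count-based (RNA-seq) noise, correlated gene
modules beyond pathway membership, and partial responsiveness (every
gene of an effect pathway responds, where real pathways deregulate
heterogeneously). Passing tests on this generator therefore demonstrate
internal correctness and the intended statistical behavior, not
performance on any particular real dataset.

## Numerical choices and degenerate inputs

* Nearest-rank (type 1) quantile for the noise floor; `q = 0` is a
  no-op and the filter is idempotent.
* Constant genes scale to 0.5; unscorable pathways (no measured nodes,
  or fewer than `min_nodes`) are flagged and skipped, never silently
  scored.
* Ranking ties break lexicographically by pathway id, making rankings
  deterministic.
* All experiment replicates derive their seed from a single master seed
  via a fixed affine map modulo the largest 32-bit prime, so results
  are reproducible and independent of evaluation order.
* A fully tied score vector gives p = 1 (no evidence), avoiding the
  rank-sum test's degenerate case.

## Problem sizes used in the shipped experiments

The test suite exercises the full standard study (250 pathways,
13 + 11 samples) for null calibration (20 studies × 10 mocks),
parameter recovery (10 studies), and structural robustness (3 studies ×
100 perturbations per fraction and mode, the full removal grid). The
dose–response check uses a 40-pathway collection with 6 effect pathways
and 12 + 12 samples, where the collection-wide mean FDR is responsive
to the effect: with a single effect pathway among 250, even a perfectly
detected effect moves the mean FDR by well under 1%, which is a
property of the metric, not of the scoring. Sample-size curves are
demonstrated at reduced grids; the functions accept the full 5–30 range.

## Known limitations

* **Mild anti-conservatism with small control pools.** Even with the
  jackknife-matched reference, all case samples share essentially one
  realized reference; conditional on that reference landing off-center,
  their deviations move together, which inflates the rank-sum test's
  variance beyond its nominal null. On null data with 11 controls we
  measure a per-pathway type-I rate of ~0.06 at $\alpha = 0.05$; it
  decays only slowly with more controls. This is intrinsic to
  deviation-from-estimated-reference scoring and is the reason at least
  15 control samples are recommended. The FDR-ratio framework is the
  antidote: mock relabellings inherit the same inflation, so the ratio
  is calibrated around zero under the null.
* Scores are unsigned: a pathway suppressed in cases and one activated
  in cases are both simply "deregulated".
* Relation signs inform parsing and quality control but not score
  direction, by design; the importance weights use topology only
  coarsely.
* Cross-dataset comparison of absolute scores is not supported; scores
  are relative to each dataset's own controls and scaling.
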