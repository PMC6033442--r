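# pathdereg

Per-sample pathway deregulation scores from gene expression and KEGG
pathway topology, with a full evaluation framework for testing how well
such scores separate case and control groups when the group effect is
modest compared to natural individual variation.

## Who this is for

Transcriptomics studies of subtle phenotypes — pre-clinical disease
stages, early seroconversion, mild asthma — often show almost no
differentially expressed genes: the group effect is drowned by
individual variation. Group-level pathway tools then return nothing, and
per-gene analyses do not transfer to individual patients. `pathdereg`
computes a *deregulation* score for every pathway in every sample: low
means the pathway behaves like a typical control sample, high means it
deviates from normal. Per-sample scores can feed phenotype prediction,
patient stratification, or simple case-vs-control group testing.

## The method

For an expression matrix $X$ (genes × samples, linear scale) with
case/control labels and a collection of KEGG pathways in KGML format:

1. **Preprocess expression.** Map probes to Entrez genes (collapsing by
   mean), floor values below a global nearest-rank quantile threshold
   (default $q = 0.05$, a detection-limit proxy), and min–max scale each
   gene over all samples to $[0, 1]$.
2. **Parse pathways.** Each KGML file becomes a signed directed graph:
   gene, group (complex) and compound nodes joined by relations whose
   subtypes give a sign (inhibition $\Rightarrow -1$, activation
   $\Rightarrow +1$, else 0).
3. **Node values.** For gene $g$ the control reference $r_g$ is the
   median scaled value over control samples (jackknife-matched: each
   sample is compared against a median of control values it did not
   contribute to). A node's value for sample $s$ is the mean of
   $|x_{gs} - r_g|$ over its measured member genes — a deviation in
   $[0, 1]$, deliberately sign-agnostic because inhibiting relations
   make "high expression = active" scoring invalid.
4. **Pathway scores.** Node importance is $w_i = 1 + r_i / \max_j r_j$
   where $r_i$ is the node's downstream reach (distinct nodes reachable
   along relation directions), so topology modulates but never
   dominates. The pathway score is the importance-weighted mean of node
   values:
   $\mathrm{score}_s = \sum_i w_i v_{is} / \sum_i w_i \in [0, 1]$.

Pathways are ranked by $|\mathrm{median}_{case} - \mathrm{median}_{ctrl}|$
of their scores. The evaluation framework tests scores with two-sided
Wilcoxon rank-sum tests per pathway, converts p-values to
Benjamini–Hochberg FDRs, and summarizes separation as the **FDR ratio**

$$\mathrm{FDRratio} = -\log_2\!\left(\frac{\overline{FDR}(\mathrm{real})}{\tfrac1{10}\sum_{i=1}^{10}\overline{FDR}(\mathrm{mock}_i)}\right),$$

where each mock dataset randomly splits the pooled samples into two
equally sized artificial groups. Higher is better; zero means the real
labels do no better than chance. Additional experiments measure the
effect of sample size and the robustness of detection when 5–50% of a
pathway's nodes or relations are randomly removed.

A seeded synthetic-data generator (`simulate_study()`,
`simulate_pathways()`, `simulate_expression()`) produces toy KGML
collections and expression matrices with log-normal baselines, global
per-sample factors, per-cell individual variation, and a multiplicative
group effect restricted to designated pathways — so the whole package
installs, tests and demonstrates itself without any download.

## Worked example

```r
library(pathdereg)

study <- simulate_study(seed = 2, effect_size = 1.5)   # 13 cases, 11 controls
s <- scale_genes(filter_noise(study$expression, q = 0.05))
scores <- score_pathways(s, study$pathways)
scores
#> <pathway_scores> 250 pathways x 24 samples (13 case, 11 control)
head(rank_pathways(scores), 3)
#> # A tibble: 3 x 6
#>   pathway_id name                  median_case median_control median_diff  rank
#> 1 syn0030    Synthetic pathway 30        0.224          0.110      0.114      1
#> 2 syn0123    Synthetic pathway 123       0.260          0.154      0.107      2
#> 3 syn0232    Synthetic pathway 232       0.168          0.254      0.0859     3
study$effect_pathway
#> [1] "syn0030"
```

The deregulated pathway (`syn0030`, a 1.5-fold effect hidden under
individual variation of comparable size) is recovered at rank 1; its
case samples score a median 0.224 versus 0.110 in controls.

Pathway information concentrates the signal relative to a gene-level
analysis of the same scaled values. On a smaller collection in which 6
of 40 pathways carry a 2-fold effect:

```r
cfg <- sim_config(n_pathways = 40, nodes_per_pathway = c(6, 14),
                  n_genes_background = 200, n_case = 12, n_control = 12,
                  effect_pathways = sprintf("syn%04d", 1:6),
                  effect_size = 2, seed = 7)
pws <- simulate_pathways(cfg)
s <- scale_genes(filter_noise(simulate_expression(cfg, pws)))
glance(fdr_ratio_experiment(s, pws, arm = "pathway", n_mock = 10, seed = 7))
#>   arm     fdr_real fdr_mock_mean fdr_ratio n_mock
#> 1 pathway    0.584         0.834     0.515     10
glance(fdr_ratio_experiment(s, arm = "gene", n_mock = 10, seed = 7))
#>   arm   fdr_real fdr_mock_mean fdr_ratio n_mock
#> 1 gene     0.716         0.975     0.445     10
```

The pathway arm separates real labels from mock relabellings more
strongly (ratio 0.52) than the gene arm (0.44).

A command-line wrapper with `score`, `evaluate`, `perturb` and
`simulate` commands is installed at
`system.file("cli", "pathdereg.R", package = "pathdereg")`:

```sh
Rscript inst/cli/pathdereg.R simulate --out demo --seed 1
Rscript inst/cli/pathdereg.R score --expr demo/expression.tsv \
  --mapping demo/mapping.tsv --labels demo/labels.tsv \
  --kgml-dir demo/kgml --out demo/results
```

## Vignette

`vignettes/pathway-deregulation-scoring.Rmd` documents the model, every
tunable parameter, the design decisions behind the reconstruction, what
the synthetic generator does and does not emulate, and known
limitations.
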