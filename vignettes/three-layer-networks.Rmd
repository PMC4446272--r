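---
title: "Methods: three-layered gene-set networks from transcriptomics and physiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-layered gene-set networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`trilayer` integrates a two-group expression experiment (high-fat vs low-fat
diet, profiled per timepoint in adipose tissue or any comparable design) with
per-animal physiology into a single multilayer network. Every node in the
network is backed by a set of genes:

* **process** nodes — biological-process gene sets that are enriched in the
  ranked differential-expression signal, backed by their members among the
  tested genes;
* **regulator** nodes — transcription factors whose target genes (regulons)
  are over-represented among differentially expressed genes, backed by their
  differentially expressed targets;
* **physiology** nodes — measured parameters (body mass gain, tissue weights,
  energy intake, ...) backed by the genes whose expression tracks them across
  individual animals.

Edges encode gene-set overlap between node pairs, quantified by the overlap
coefficient $|A \cap B| / \min(|A|, |B|)$. Because the three layers are
derived from the same gene universe, shared genes are a direct, mechanistic
currency: an edge between a regulator and a physiological parameter means
the same genes that respond to the regulator also track the phenotype.

## Stage by stage

**Differential expression.** A pooled-variance two-sample t per gene, with
the gene-wise variance shrunk towards a common prior:
$\tilde{s}^2_g = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$, $t$ referred to
$t_{d_0 + d_g}$. The prior degrees of freedom $d_0$ are fixed and
user-settable (default 4) with $s_0^2$ the mean pooled variance. This is a
deliberate simplification of empirical-Bayes moderation: it shrinks in the
same direction with the same limiting behaviour ($d_0 = 0$ recovers the
ordinary pooled t exactly; $d_0 \to \infty$ uses the common variance for all
genes) while remaining a two-line formula whose calibration we can verify
directly — under a constant-variance null the p-values are
Kolmogorov–Smirnov-uniform at $10^4$ genes (checked in the test suite).
FDR control is Benjamini–Hochberg.

**Preranked enrichment.** Genes are ranked by descending t (ties broken
lexically by gene id for reproducibility). For a set $S$, walking the ranked
list adds $|s_i|^p / N_R$ at members and subtracts $1/(N - N_H)$ elsewhere;
the enrichment score is the running sum's maximal absolute deviation
(signed, first extremum on exact ties). The weighting exponent defaults to
$p = 1$. Sets with effective size (members in the universe) outside
[15, 500] are excluded. Significance comes from a seeded permutation null of
random same-size gene sets — with only a ranked list as input, sample-label
permutation is not available, and gene-set sampling is the standard
preranked null. The p-value is the same-sign exceedance fraction with
$(+1)/(n+1)$ smoothing so $-\log_{10} p$ is always finite; NES divides ES by
the mean same-sign null ES; the FDR q follows the usual pooled
null-vs-observed NES tail ratio, made monotone and capped at 1.

**Direction ("up", "down", "both").** Enrichment is run twice: on the
forward ranking and on the negated, reversed ranking. Reversing and negating
a ranking exactly negates every enrichment score, so "significant positive
ES in both runs" can never hold if significance is judged on the max-abs
statistic; a workable definition must look at the positive running-sum
deviation of each run separately. Each run therefore also reports a
one-sided p for its positive deviation (`p_pos`); a set is *up* when only
the forward run's positive deviation is significant, *down* when only the
reversed run's is, and *both* when both are — which happens exactly when
members crowd both extremes of the ranking. The node score is
$-\log_{10}(\min p)$, negative for *down*.

**Regulators.** For each regulon, a one-sided hypergeometric test of the
overlap between its targets and the FDR < 0.05 gene list over the tested
universe, plus the activation z-score
$z = (n_{up} - n_{down})/\sqrt{n_{up} + n_{down}}$ over the differentially
expressed targets, and the activation score $-\log_{10}(p)\,\mathrm{sign}(z)$.
This is a transparent stand-in for proprietary curated-knowledge-base
scoring: same inputs, same outputs, published formulas. Regulators with
identical differentially-expressed target sets carry no independent
information at the network level and are clustered; the smallest-p member
(ties lexical) represents the cluster. Identity of the DE-restricted target
sets is the default key — the full-target alternative is exposed — because
the DE targets are what back the network nodes. A side effect is that all
regulators with *empty* DE target sets share one (vacuous) cluster; they
can never become nodes, which require a nonempty backing set.

**Physiology.** Spearman's rho per (parameter, gene) across all animals of
both diet groups within the timepoint, with a two-sided p from the
t-approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$. Pooling the diet groups
maximises n and spans the induced phenotype range; a per-group option
exists. A gene joins a parameter's set when $|\rho| > 0.8$ and $p < 0.05$ —
the dual cutoff is applied as stated, with no multiple-testing correction
across the gene-by-parameter grid; at $n \approx 20$–24 animals the
$|\rho| > 0.8$ requirement is by far the stronger filter (the null
probability of passing it is orders of magnitude below 0.05).

**Network assembly.** Nodes: processes and regulator representatives with
enrichment p < 0.05 and physiological parameters with nonempty gene sets.
Edges: all allowed layer pairs with overlap ≥ 1 gene and coefficient at or
above the cutoff — 0.3 for physiology–process pairs (their backing sets are
small, and the published practice relaxes this pair), 0.5 for everything
else; both boundaries inclusive. Process–process edges are kept (the
process layer is an enrichment map); regulator–regulator and
physiology–physiology edges are excluded by default. Topology statistics
(degree, unnormalised shortest-path betweenness, local clustering
coefficient, density) come from igraph, validated in the tests against a
brute-force path-counting oracle.

## The synthetic-study generator

The generator emulates the study design the pipeline assumes: two diets at
two timepoints with independent cohorts (10/diet early, 12/diet late),
log2 expression as Gaussian noise (sd 0.5) around gene baselines
$\mathcal{N}(8, 1.5)$, and three kinds of planted structure recorded in a
truth manifest:

* **regulons** — planted regulons get pairwise-disjoint target sets whose
  expression is shifted by $\pm$`effect_size` (default 1.5 log2 units, a
  strong but realistic diet effect) in HFD samples only;
* **processes** — each planted regulon seeds one process built from its
  targets plus random fill, and a third of the remaining processes borrow
  half their members from a random regulon, so cross-layer overlap exists by
  construction;
* **physiology** — each linked parameter is a latent standard-normal animal
  factor added to a 50-gene module with the slope chosen from the closed
  bivariate-normal relation $\rho_S = (6/\pi)\arcsin(\rho_P/2)$ so the
  population Spearman correlation hits `link_rho_target` (default 0.9); the
  calibration is verified empirically in the tests (mean attained $|\rho|$
  within $\pm 0.1$ of target across 20 seeds).

What the generator deliberately does **not** model: probe-level artifacts,
normalisation residue, batch effects, gene–gene correlation beyond the
planted structure, heavy-tailed noise, or longitudinal correlation between
timepoints (cohorts are distinct animals). Passing recovery and calibration
tests on this generator therefore demonstrates that the statistical
machinery is correct and calibrated under its stated assumptions — not that
real microarray data satisfy those assumptions.

## Numerical choices and degenerate inputs

* Ranking ties broken lexically by gene id; the enrichment-score extremum
  takes the first position on exact ties (exact ties between the positive
  and negative deviation make the ES sign rule-dependent; the magnitude
  never is).
* Permutation p-values smoothed as $(k+1)/(n+1)$; $n_{perm}$ defaults to
  1000 (p resolution $10^{-3}$), seeded, with the caller's RNG state
  restored.
* Genes with missing values are dropped from that timepoint's test; genes
  with zero posterior variance (possible only at $d_0 = 0$) yield NA with a
  warning rather than an error for the whole matrix.
* $|\rho| = 1$ reports the smallest representable positive p so
  $-\log_{10} p$ stays finite; fewer than 4 complete pairs is an error.
* A regulon with no targets in the universe gets p = 1 and a warning; an
  empty-overlap regulon has z reported as 0 with `z_defined = FALSE`.
* Networks with empty layers are legal (an early-timepoint physiology layer
  with one or two nodes is expected); a fully empty network warns.
* All outputs are timestamp-free and keyed to the seed, so a rerun is
  byte-identical — the run manifest (parameters, seed, input and output
  checksums) suffices to verify a reproduction.

## Problem sizes in the test suite

The deep checks run at sizes chosen to make their statistical tolerances
meaningful while keeping the suite quick: null calibration uses $10^4$ genes
for the KS test and 1000 gene sets with a 1000-draw permutation null
(binomial sd of the 0.05 rate ≈ 0.007 against a ±0.02 band); recovery runs
20 independent studies of 2000 genes at the early-timepoint design
(n = 10/diet); oracle equivalences use 100 random ranked lists (N ≤ 50),
exhaustive hypergeometric enumeration on universes ≤ 15, 1000 random BH and
Spearman instances, 30-node networks against an all-pairs edge oracle and
≤ 20-node graphs against a path-counting betweenness oracle.

## Limitations

* The moderation prior is fixed, not estimated; rank-based downstream
  stages (enrichment consumes ranks, regulon enrichment consumes FDR flags)
  are insensitive to moderate misspecification, but the t magnitudes
  themselves are not empirical-Bayes posteriors.
* The gene-sampling permutation null ignores inter-gene correlation, as
  preranked enrichment generally does; real-data p-values are optimistic to
  an unknowable degree.
* The "both" direction rule is one defensible operationalisation of a
  category that has no canonical computational definition.
* Published overlap-coefficient tables in this field are not always
  invertible to integer set sizes, so no attempt is made to treat any
  specific published edge coefficient as an exact oracle; the similarity
  method (overlap, Jaccard, or a combined blend) is a configuration choice.

## A minimal run

```{r example}
library(trilayer)

study_dir <- tempfile()
write_study(generate_study(synth_config(seed = 1)), study_dir)

cfg <- pipeline_config(
  expression = file.path(study_dir, "expression.tsv"),
  samples = file.path(study_dir, "samples.tsv"),
  process_gmt = file.path(study_dir, "processes.gmt"),
  regulon_gmt = file.path(study_dir, "regulons.gmt"),
  physiology = file.path(study_dir, "physiology.tsv"),
  out_dir = tempfile(), seed = 42)

res <- run_pipeline(cfg)
res[["12w"]]$network
topology_stats(res[["12w"]]$network)$nodes
autoplot(res[["12w"]]$network)
```
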