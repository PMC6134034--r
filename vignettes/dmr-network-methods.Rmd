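---
title: "DMR co-methylation networks: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DMR co-methylation networks: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmrnet)
```

## The problem

Single differentially methylated CpG sites are noisy markers of disease.
Differentially methylated regions (DMRs) — runs of multiple consecutive
CpGs that shift together between groups — are more robust, and sets of
DMRs whose methylation co-varies across individuals ("DMR networks")
suggest coordinated epigenetic regulation, for example by shared drivers
such as age or glycemia in progressive liver disease. `dmrnet` implements
the full discovery path: probe-level quality filtering, region calling,
weighted co-methylation network construction over the DMR CpGs,
aggregation of CpG-level interconnectedness to DMR pairs, thresholded
network extraction, cross-cohort replication, and correlation of network
methylation with clinical traits and gene expression.

## The network model

For CpG probes $i, j$ with methylation fractions ($\beta$-values) across
samples, the unsigned weighted adjacency is

$$ a_{ij} = |\mathrm{PCC}_{ij}|^{\beta}, $$

the absolute Pearson correlation raised to a soft-threshold power
$\beta$. The power is chosen as the smallest integer at which the network
looks scale-free: connectivity $k_i = \sum_j a_{ij}$ is binned (10
equal-width bins over the observed range), and $\log_{10}$ bin frequency
is regressed on $\log_{10}$ bin mean connectivity. The fit index is the
*signed* $-\operatorname{sign}(\text{slope}) \cdot R^2$, so only fits in
which frequency decreases with connectivity count as scale-free; a power
qualifies when the index exceeds 0.70. Two numerical guards matter here:

* **Mean-connectivity floor.** At extreme powers any adjacency —
  including pure noise — collapses to a near-empty graph whose few
  surviving edges mimic a scale-free tail. A candidate power therefore
  also needs mean connectivity $\bar k \ge$ `min_mean_k` (default 1).
  Without this guard, i.i.d. noise at small sample sizes "qualifies" at
  powers where the network has essentially no edges.
* **Fallback.** When no candidate qualifies, `pick_soft_threshold()`
  returns the scan with a warning and the pipeline falls back to a fixed
  default power (6), recorded in the run manifest.

Topological overlap between probes combines direct adjacency with shared
neighbourhood:

$$ \mathrm{TOM}_{ij} = \frac{\sum_u a_{iu}a_{uj} + a_{ij}}
   {\min(k_i, k_j) + 1 - a_{ij}}, $$

with unit diagonal by convention and 0 for fully isolated pairs. The
DMR-level statistic is the arithmetic mean of $\mathrm{TOM}_{ij}$ over
all cross pairs $i \in A$, $j \in B$ of two *distinct* DMRs; within-DMR
pairs never contribute (they are trivially high because member CpGs are
co-differential by construction). DMR pairs whose average TOM reaches the
cutoff (default 0.15, inclusive) become edges, and **DMR networks are the
connected components** of that graph with at least two nodes, ordered by
node count (ties: summed edge weight, then smallest member id). Defining
networks as connected components is a deliberate formalization of what is
usually done by visual inspection in a graph viewer; it is the minimal
rule that is deterministic and testable.

## Module detection

CpG modules are found by average-linkage hierarchical clustering on
$1 - \mathrm{TOM}$ with a *static* cut at `cut_height` (default 0.99);
clusters below `min_module_size` (default 10) are labeled grey, the rest
take the conventional size-ordered colour palette (turquoise, blue,
brown, yellow, ...). A static cut was chosen over dynamic hybrid tree
cutting because it has one transparent parameter and is exactly
reproducible; this is a documented divergence from common WGCNA
defaults, and module labels should be read as cluster identifiers, not
matched against any particular published figure. Average linkage can
produce tiny height inversions under tied dissimilarities; heights are
passed through a monotone (cumulative-maximum) envelope so the cut is
always well defined.

## Region calling

Probe-level differential methylation uses Welch's t-test on
$\beta$-values (the pipeline operates on $\beta$ throughout; M-value
modeling is out of scope). BH-significant probes (default
$\alpha = 0.05$) are chained along each chromosome while neighbour gaps
stay within a single lasso radius (default 1,000 bp); chains with at
least `min_probes` (default 3) members are candidate DMRs. Member
p-values are combined with Stouffer's method, signed by each probe's
effect direction so that coherent regions gain and incoherent ones lose
significance; combined p-values are BH-adjusted across candidates. The
published region caller this emulates varies its radius by genomic
feature class; a single configurable radius is a declared
simplification. Cross-cohort consensus keeps regions where every cohort
called an overlapping DMR (≥ 1 bp, transitively merged to the union
interval with unioned probe sets).

## Trait and expression association

CpG–trait association is pairwise-complete Pearson correlation with
t-distributed two-sided p-values, BH-adjusted within each trait.
Cross-cohort pooling uses the fixed-effect Fisher-z model: $z =
\operatorname{atanh}(r)$ with variance $1/(n-3)$, inverse-variance
weighting, Cochran's Q for heterogeneity; a DerSimonian–Laird
random-effects estimate is available but not the default. For
methylation–expression correlation a DMR is summarized as the unweighted
mean $\beta$ of its member probes. Clinical two-group comparisons use
Welch t-tests for numeric traits and Fisher's exact test for 2×2
categorical traits.

## The synthetic-data generator

`simulate_cohorts()` emulates the structure of a multi-cohort 450K-style
study: two disease cohorts split into mild/advanced groups (default 30
each), an optional control cohort, a background of independent CpGs, and
**two planted DMR networks** (default 10 DMRs × 3–5 CpGs each). Signal
is composed on the logit scale and inverse-logit transformed, which
keeps $\beta \in (0,1)$ without clipping artifacts; `dmr_effect_delta`
and `noise_sd` are specified on the $\beta$ scale and converted with the
local logit slope at each probe's baseline.

Each planted probe follows

$$ \beta_{ps} = \sigma\!\left( \mathrm{logit}(b_p) +
   d_D\,\Delta_p\,\mathbf{1}[\text{advanced}_s] +
   d_D\,\lambda\, f_{w(D),s}\,c_p + \varepsilon_{ps} \right), $$

where $b_p$ is the probe baseline, $d_D \in \{+1,-1\}$ the DMR's
direction, $\lambda$ the network loading, and $f_w$ the network's latent
factor. The direction multiplies **both** the group effect and the
factor loading: hypomethylated DMRs move opposite to hypermethylated
ones along the shared regulatory axis, which is what coordinated
regulation means, and the unsigned $|\mathrm{PCC}|^\beta$ network is
direction-blind. (If the direction touched only the group effect, the
direction-signed group variance would decorrelate opposite-direction
DMRs of the same network and no threshold could recover the planted
structure.)

Latent factors are group-independent. Fibrosis stage is an ordinal
discretization of factor 2 *within* each group — mild samples get stages
0–2 by factor-2 tertiles, advanced samples 3–4 by median split — so
stage tracks both disease group and the network-2 driver without
contaminating the planted group effect. Age and fasting glucose are
linear in the factors plus Gaussian noise per `trait_couplings`
(defaults: age loads 0.5/0.5, glucose 0.2/0.6, scaled to years and
mg/dL). The control cohort has zero group effect and its network-2
loading attenuated ×0.2, so network 2 should replicate only weakly
there. Optionally a gene–expression matrix is emitted with expression
anti-correlated to each planted DMR's mean methylation.

Default effect sizes (`dmr_effect_delta` 0.2, `network_loading` 0.9,
`noise_sd` 0.02, factor scale 0.15 on the $\beta$ scale) are chosen as
realistic-but-strong values for a testable ground truth; no published
effect-size distribution was available to calibrate against, and the
defaults are not revisited per test. What the generator does **not**
emulate: IDAT-level intensities and detection-p chemistry, type-I/II
probe design differences, SNP artifacts, batch effects, and realistic
genome-wide correlation background. Passing tests therefore demonstrate
algorithmic correctness and recovery under the stated generative model,
not performance on real arrays.

## Problem sizes and determinism

The test suite and the acceptance script run the full pipeline on 2
cohorts + control × 60–150 samples × ~260 probes (two planted networks
of 10 DMRs × 3 CpGs over a 200-probe background), null calibrations on
2,000 probes × 50 replicates, and oracle comparisons on matrices of 5–30
nodes; these sizes give stable statistics while keeping a full run in
tens of seconds. All randomness flows from a single integer seed;
everything downstream of the generator is deterministic, so identical
configurations reproduce artifacts byte-for-byte.

## Known limitations

* The region caller uses one global lasso radius and a single
  probe-level test; feature-aware radii and covariate adjustment are out
  of scope.
* Network extraction depends on the chosen soft threshold; on data
  without scale-free structure the documented fallback power is used and
  should be reviewed via the scan table.
* Cross-cohort network matching maximizes node overlap (exhaustively for
  up to 7 networks per cohort, greedily beyond); with many similar-sized
  networks the greedy path may be suboptimal.
* BMIQ/ComBat-style normalization is not implemented; the pipeline
  expects pre-normalized $\beta$-values, with full quantile
  normalization available as a light-weight stand-in.
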