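# dmrnet

Discovery of **differentially methylated region (DMR) networks** from
beta-value methylation matrices (Illumina 450K-style data).

Single CpG sites are noisy disease markers; DMRs — runs of consecutive
CpGs shifting together between groups — are more robust, and groups of
DMRs whose methylation co-varies across individuals point to coordinated
epigenetic regulation (e.g. by age or glycemia in progressive liver
disease). `dmrnet` provides the full analysis path for finding and
replicating such DMR networks, plus a synthetic-data generator with
planted ground truth so every stage can be validated end to end.

## Method

For CpG probes *i*, *j*, the unsigned weighted co-methylation adjacency
is

&nbsp;&nbsp;&nbsp;&nbsp;*a<sub>ij</sub>* = |PCC<sub>ij</sub>|<sup>β</sup>,

with the soft threshold β selected as the smallest integer whose network
is scale-free (signed log–log fit index −sign(slope)·R² > 0.70, mean
connectivity ≥ 1). Topological overlap

&nbsp;&nbsp;&nbsp;&nbsp;TOM<sub>ij</sub> = (Σ<sub>u</sub> a<sub>iu</sub>a<sub>uj</sub> + a<sub>ij</sub>) / (min(k<sub>i</sub>, k<sub>j</sub>) + 1 − a<sub>ij</sub>)

measures interconnectedness; the DMR-pair statistic is the **mean TOM
over all cross-DMR CpG pairs** of two distinct DMRs (within-DMR pairs
excluded). DMR pairs with average TOM ≥ 0.15 become edges, and DMR
networks are the connected components of that graph. Regions themselves
are called by chaining BH-significant Welch-test probes within a lasso
radius (default 1,000 bp, ≥ 3 probes) with signed Stouffer-combined,
BH-adjusted region significance; replication uses reciprocal interval
overlap across cohorts and correlation pooling uses fixed-effect
Fisher-z meta-analysis (z = atanh r, var 1/(n−3)).

## Worked example

```r
library(dmrnet)

# two disease cohorts + control, two planted DMR networks of 10 DMRs x 3 CpGs
cfg <- simulation_config(seed = 7, n_dmrs_per_network = 10,
                         probes_per_dmr = c(3L, 3L), n_probes_background = 200)
sim <- simulate_cohorts(cfg)

res <- run_all(pipeline_config(output_dir = "dmrnet_demo", seed = 7),
               dataset = sim)
print(res$results$network$cohort1$graph)
#> DMR network graph: 20 DMRs, 90 edges at avg-TOM >= 0.15
#>   network1: 10 DMRs
#>   network2: 10 DMRs
#>   isolated: 0
```

All 20 planted DMRs are recovered as consensus regions across the two
disease cohorts, and thresholding the average-TOM matrix at 0.15 splits
them into exactly the two planted networks. TOM percentiles within a
network summarize its interconnectedness:

```r
tom_percentiles(res$results$network$cohort1$tom, network1_cpgs,
                dmr_map = probe_to_dmr)
#>   p25   p50   p75
#> 0.886 0.900 0.905
```

Correlation pooling across cohorts:

```r
mc <- meta_correlation(r = c(0.3, 0.5), n = c(35, 33))
#> pooled r = 0.4016 (p = 8.06e-04, Q = 0.890)
```

The pooled estimate is the inverse-variance Fisher-z average of the two
cohort correlations; Q near its degrees of freedom indicates no
meaningful heterogeneity. The run directory additionally receives
`dmrs.bed`/`dmrs.tsv`, per-cohort edge lists and GraphML files (with
degree, component, and cross-cohort presence attributes for
Cytoscape-compatible viewers), the cross-cohort comparison JSON, the
pooled trait correlations, and a JSON run manifest recording every
parameter and per-stage count.

A thin command-line wrapper with per-stage subcommands
(`simulate`, `filter`, `call-dmrs`, `network`, `dmr-network`, `traits`,
`run-all`) is installed at `inst/cli/dmrnet.R`.

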