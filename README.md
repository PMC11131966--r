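# frnet

Microbial genomes encode far more functions than a community actually uses:
metagenomics measures what taxa *could* do, metaproteomics what they *are
doing*. `frnet` pairs the two views to decide, for each protein family,
whether it is a **specialist** function (carried by few taxa), a **niche**
function (widely encoded but selectively expressed under ecological
competition), or an **essential** function (widely encoded *and* widely
expressed because growth is impossible without it). It is aimed at microbiome
researchers with paired taxon-by-function tables — a gene content network
(GCN) from metagenomes and a protein content network (PCN) from
metaproteomes — plus a taxonomic relative-abundance profile.

## The statistic

For one function and a community with relative abundances
`p = (p_1, …, p_N)`, the gene-level functional redundancy is

```
FR_g = Σ_i Σ_{j≠i} (1 − d_ij^GCN) p_i p_j
```

with the binary pair distance `d_ij^GCN = 0` iff both taxa carry the gene
(and `FR_p` analogously on the PCN): the probability that two individuals
drawn from different taxa both carry (or both express) the function. `FR` is
bounded by the Simpson-type taxonomic diversity `TD = 1 − Σ p_i²`, giving the
normalized `nFR = FR/TD ∈ [0, 1]`. The three function types occupy distinct
regions of the `(FR_g, FR_p)` plane — specialist: low/low; niche: high/≈0;
essential: high/high — and a three-component Gaussian mixture fitted on
simulated communities (with k-means and QDA alternatives) assigns each family
a type.

The package also ships a consumer-resource community-assembly simulator that
plants the three function types in 10,000 synthetic genomes, sub-samples
expression, and integrates chemostat dynamics to steady state — producing
GCN/PCN/profile triples with ground-truth labels used to calibrate and
validate the classifier — plus detection-depth sensitivity sweeps
(abundance-percentile thresholds) and metaproteomic fold-change statistics.

## Worked example

The canonical two-species, three-protein toy: both taxa encode the *red*
protein but only one expresses it (niche); both encode and express *green*
(essential); only one encodes *blue* (specialist). With equal abundances:

```r
library(frnet)
fx <- two_species_example()          # p = (0.5, 0.5)
function_metrics(fx$paired)
#>   function_id k_gcn k_pcn fr_g fr_p nfr_g nfr_p flag_frp_gt_frg
#> 1        blue     1     1  0.0  0.0     0     0           FALSE
#> 2       green     2     2  0.5  0.5     1     1           FALSE
#> 3         red     2     1  0.5  0.0     1     0           FALSE
```

The niche protein shows the diagnostic signature: its degree drops from
`k_GCN = 2` to `k_PCN = 1` and its protein-level redundancy collapses to 0
while `FR_g = 2 p_1 p_2 = 0.5`; the essential protein keeps `FR_p = FR_g`;
the specialist is zero at both levels.

At full scale, assemble a community from 10,000 species, compute redundancies
for the survivors, and fit the mixture classifier:

```r
res <- assemble_community(crm_params(seed = 1))
res
#> Consumer-resource assembly: 39 survivors of 10000 species (steady at t = 31702)

nets    <- crm_networks(res)
metrics <- function_metrics(nets$paired)
fit     <- fr_classify(metrics, labels = unname(nets$labels), seed = 1)
fit
#> Function-type classifier (GMM, redundancy features)
#>     fr_g   fr_p       type
#> 1 0.0250 0.0002 specialist
#> 2 0.4920 0.1095  essential
#> 3 0.3025 0.0003      niche

pred <- predict(fit, metrics)
table(truth = nets$labels[pred$function_id], assigned = pred$assigned_type)
#>             assigned
#> truth        essential niche specialist
#>   essential         20     0          0
#>   niche              0    20          0
#>   specialist        0     0         20
```

All 60 planted functions are recovered: the assembled community separates the
three types in the `(FR_g, FR_p)` plane, while the same species drawn at
random without assembly do not (see `random_control_networks()`).

A thin command-line wrapper (`inst/cli/frnet.R`) exposes the same pipeline as
`simulate`, `fr`, `classify`, `sensitivity`, `foldchange` and `fixtures`
subcommands; `vignettes/functional-redundancy.Rmd` documents the model and
its assumptions.

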