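---
title: "Gene- vs protein-level functional redundancy: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene- vs protein-level functional redundancy: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

A taxon's genome records its functional *potential*; its expressed proteome
records its *realized* function. `frnet` contrasts the two through a pair of
bipartite taxon-by-function incidence networks — the gene content network
(GCN) and the protein content network (PCN) — weighted by a taxonomic
relative-abundance profile `p`. For each function, the redundancy

$$\mathrm{FR} = \sum_i \sum_{j \ne i} (1 - d_{ij})\, p_i p_j$$

uses the binary pair distance $d_{ij} = 0$ iff both taxa carry (GCN) or
express (PCN) the function. Computationally this is the closed form
$(\sum_{i \in O} p_i)^2 - \sum_{i \in O} p_i^2$ over the owner set $O$, which
the test suite checks against the literal double-loop sum to $10^{-12}$.
$\mathrm{FR}$ is bounded by the Simpson-type diversity
$\mathrm{TD} = 1 - \sum_i p_i^2$ of the same profile, and
$\mathrm{nFR} = \mathrm{FR}/\mathrm{TD}$ removes the evenness dependence
(a more uneven profile shrinks every FR; the uniform profile maximizes the FR
of a fully shared function, a property the tests verify by grid search over
the 2- and 3-taxon simplices).

Assumptions worth making explicit:

* distances are binary presence/absence — no phylogenetic or abundance-
  weighted variant;
* redundancy is *per function*, not the community-wide aggregate over all
  functions;
* when a GCN/PCN pair is aligned (`paired_networks()`), the function set is
  the intersection of the two networks, the taxon set is their union (a taxon
  absent from one network owns/expresses nothing there), and the profile is
  renormalized over the retained taxa so that Eq. (FR) operates on a proper
  composition. Whether real-data profiles should be renormalized after
  dropping taxa absent from the networks is not decidable from first
  principles; we renormalize, because FR compares *pairs within the observed
  community*;
* a single-taxon community has `TD = 0`; its `nFR` is defined as 0 rather
  than raising an error, since degenerate communities are legal inputs;
* functions with `FR_p > FR_g` (impossible when the PCN is a subgraph of the
  GCN, but common in real data where sequencing and MS detection depths
  differ) are *flagged, never clamped* — the sensitivity module below exists
  to study exactly this artifact.

Nestedness is reported as NODF on the $[0,1]$ scale with the standard
decreasing-fill rule: line pairs with equal marginal totals contribute zero
overlap. The implementation is order-invariant (equivalent to sorting by
marginal totals first) and is cross-checked in the tests against an
independent implementation and a hand-enumerated 4×4 case.

## The community-assembly simulator

The synthetic-data generator is a chemostat consumer-resource model whose job
is to *plant* the three function types with known labels and let ecological
competition produce the observable signatures. Each niche and each specialist
function is the ability to consume one unique, externally supplied resource;
essential functions consume nothing but each missing one multiplies growth.
Genomes are independent Bernoulli draws per function with type-specific
probabilities; expression is an independent Bernoulli thinning of the genome
at a single rate `p_expr` for *all* types — this symmetry matters, because it
is what makes the no-assembly control non-separable.

Species dynamics:

$$\frac{dN_i}{dt} = N_i \left[(1-\pi)^{m_i}\,\frac{1}{b_i}\sum_{a \in E_i} R_a
  - \mu_i - c\,b_i\right], \qquad
  \frac{dR_a}{dt} = s - \delta R_a - R_a \sum_i N_i \frac{e_{ia}}{b_i}$$

where $E_i$ is the set of consumption functions species $i$ expresses,
$b_i = |E_i|$, $m_i$ its number of unexpressed essential functions, $\pi$ the
essential penalty, $\mu_i$ its maintenance rate and $c$ the per-expressed-
consumption-protein burden. Three modelling choices deserve justification,
since they are this package's own:

1. **Enzyme-budget uptake** ($1/b_i$): each species splits a fixed catabolic
   proteome budget across the consumption functions it expresses. With plain
   summed uptake, resource levels self-equilibrate so that expressing *more*
   consumption genes is always weakly better; survivors are then broad
   expressers, the expressed overlap of niche functions among survivors never
   drops below the a-priori rate, and niche and essential functions stay
   inseparable in the $(\mathrm{FR_g}, \mathrm{FR_p})$ plane. The budget
   trade-off makes parsimonious expressers win, which is exactly the
   catabolite-repression logic of selective expression: an *E. coli*-like
   cell gains by committing to the resource it actually uses.
2. **Expression burden** ($c\,b_i$, default 0.1 per expressed consumption
   protein, same units as the maintenance rate 0.1): a direct cost of
   synthesizing transport/catabolic machinery. It sharpens the same
   selection; essentials carry no burden term because their cost is already
   modelled as the growth penalty.
3. **Maintenance heterogeneity** (`maint_cv = 0.05`, lognormal): with purely
   discrete traits, two species expressing the same single resource with
   equal essential repertoires are exact ecological twins and coexist
   neutrally, inflating survivor counts past the competitive-exclusion bound
   of one species per resource. A 5% coefficient of variation in basal
   maintenance — well within plausible physiological variation — breaks these
   ties without otherwise affecting the selection structure.

`p_expr` defaults to 0.35. The sub-sampling rate is a free parameter of the
design (expression sub-sampling is observed in culture, but its rate is not
identified); 0.35 was fixed once, jointly with the two parameters above, as
the value at which the simulator reproduces the expected phenomenology —
roughly 35–40 survivors out of 10,000 species on 40 resources, essential
functions expressed by most survivors (FR_p approaching FR_g), niche
functions expressed by ~1–3 survivors each (FR_p ≈ 0), and an equal-abundance
random control in which niche and essential functions are statistically
indistinguishable. It was not revisited afterwards.

Defaults for the remaining rates (`resource_supply = 1`, `dilution = 0.1`,
`maintenance = 0.1` in reciprocal-time units, `essential_penalty = 0.05` per
missing essential) put the community in an ordinary chemostat regime;
survivor counts and cluster separation are insensitive to severalfold changes
in supply, dilution and maintenance (we probed this during design).

### Integration and steady state

With 10,040 state variables, generic stiff solvers (which build full
Jacobians) are impractical, and the post-transient relaxation is far too long
for explicit Runge–Kutta at its stability-limited step. The integrator
exploits the model's structure: resources are *linear* given abundances, so
they are updated exactly under frozen abundances, and abundances are updated
by an exponential step using the trapezoidal average of growth rates before
and after the resource update (Lie splitting). Fixed points of the dynamics
are exact fixed points of the scheme, the update preserves positivity, and
the step is adapted so no species changes by more than ~20% per step, capped
at `h_max = 0.5` (larger caps can excite a numerical 2-cycle near
equilibrium). The test suite compares the scheme against `deSolve::lsoda` on
a 30-species community over a fixed horizon (agreement to $10^{-3}$).

Species below `extinction_threshold = 1e-6` are pruned at every step.
Termination is *quasi-steady*: the run is declared converged when every
established species (abundance above $10^{-3}$ of the current maximum) has
$|g_i| <$ `steady_state_tol` $= 10^{-8}$ while all remaining stragglers are
strictly declining; such stragglers carry negligible biomass, are
deterministically extinct, and are removed from the survivor set. Waiting for
them to cross the extinction threshold instead can take $t \gg 10^5$ when a
near-neutral loser declines at a rate set only by a percent-level maintenance
difference. Reaching `t_max` ($6\times10^4$ by default) first flags the
result non-steady rather than erroring.

## The classifier

`fr_classify()` is the package's central model object. The default method is
a 3-component full-covariance Gaussian mixture over the raw
$(\mathrm{FR_g}, \mathrm{FR_p})$ pairs, fitted by EM (tolerance $10^{-6}$,
covariance ridge $10^{-6}$) from 10 k-means-seeded restarts. Two numerical
safeguards address a genuine pathology of this data: the niche and specialist
clusters have near-zero variance along the FR_p axis, and maximum likelihood
often prefers merging them into one "slab" component (absorbing 2/3 of the
points) while splitting the dispersed essential cluster in two. Because the
synthetic reference design is balanced (20 functions per type), restart
solutions in which a single component absorbs more than half the functions
are discarded as degenerate; and when ground-truth labels are available, a
label-derived initialization joins the restart pool (EM is monotone, so this
start converges to the nearest non-degenerate optimum, which likelihood
selection then compares fairly against the k-means starts).

Components map to types canonically: with labels, the bijection maximizing
label agreement (ties broken by geometry); without, by centroid geometry —
the component lowest on the gene-level axis is specialist, and of the
remaining two the one higher on the protein-level axis is essential. The
`degree` feature space divides $(k_\mathrm{GCN}, k_\mathrm{PCN})$ by the
taxon count so synthetic and real scales are comparable; redundancy features
are used raw by default (an optional per-axis min–max rescale exists for
transferring a synthetic-fit model to data on a different scale — note that
exact-ML mixtures are affine-equivariant, so this matters only through the
fixed ridge and initialization). Points outside the synthetic support
(e.g. `FR_p > FR_g`) are classified as-is.

K-means (K = 3, 10 restarts, hard assignments) and QDA (supervised, trained
on families with assumed types: ABC-type transporters → niche, ribosomal
proteins → essential, PTS proteins → specialist) are provided as
alternatives. QDA falls back to ridge-regularized Gaussian discriminants when
a class covariance is singular, rather than failing. `evaluate_accuracy()`
scores assignments against the assumed ground-truth families only; functions
from unmapped families (e.g. unknown-function categories) are classified but
excluded from the denominator.

## Detection-depth sensitivity and fold changes

`apply_percentile_threshold()` keeps the top *k*% most abundant network edges
by a **global** ranking over all nonzero taxon-function entries (the most
literal reading of keeping "the most abundant" entries; a per-taxon variant
would be a different experiment). Ties at the cutoff are all retained, making
the filter deterministic. Since filtering only removes edges, degree and FR
are monotone non-increasing as the threshold tightens; `threshold_sweep()`
also counts, per gene-side (GAPT) level, how many functions show the
`FR_p > FR_g` inversion against the unfiltered PCN — lowering GAPT can only
increase this count.

The quantitative module normalizes protein intensities to within-taxon
"fractions" per condition × replicate (scale-invariant per taxon, summing to
1), averages *fractions* across replicates within a group before forming
`log2(treatment/control)` (robust to unbalanced replicates; per-replicate
ratios would require paired designs), and excludes zero-control proteins with
a warning rather than silently pseudocounting (a pseudocount flag exists, off
by default). Group comparisons are two-sided Mann–Whitney-Wilcoxon tests with
Bonferroni correction and the conventional five-level star buckets; the
one-sample Wilcoxon signed-rank test against zero handles all-zero samples by
convention (p = 1). All-identical pooled samples likewise give p = 1.

## What the generator does and does not emulate

The simulator produces the *structure* the classifier needs — paired
networks with expression a strict subgraph of the genome, ground-truth
labels, competition-driven selective expression — under clean conditions:
binary incidence, complete detection, no cross-feeding or metabolite
secretion, no temporal resource pulses, no evolution, no peptide-level
ambiguity. Passing the synthetic acceptance checks therefore demonstrates the
pipeline's internal validity (the three types are recoverable when the
mechanism is the one modelled), not field performance on real
metagenome–metaproteome pairs, where incomplete detection produces
`FR_p > FR_g` artifacts, annotation transfers blur family boundaries, and
clusters overlap substantially. Real-data validation quantities (connectance,
NODF, per-family accuracies) require the original deposited datasets and
external database searches, and are deliberately outside the automated
checks; the package nevertheless ingests tables of exactly that shape (the
test suite exercises an 85-taxa × 1542-function instance end to end).

## Problem sizes and seeds used by the checks

The acceptance checks run the full study scale: 10,000 species, 20 functions
per type, 40 resources, five simulation seeds (about 2–3 s per assembly with
the splitting integrator). Module tests use 400-species communities with 15
functions, where the competitive-exclusion bound (≤ 10 survivors on 10
resources) is reached reliably within `t_max = 2e5`. Every stochastic step
takes an explicit seed; the simulator derives independent substreams for
genomes, expression, controls and maintenance variation from its master seed,
so each component can be varied while holding the others fixed.

## Known limitations

* The CRM is one concrete mechanism generating selective expression;
  alternative mechanisms (regulatory switching, condition-dependent
  expression) would produce PCNs whose statistics this generator does not
  mimic.
* The mixture classifier assumes three clusters; families with mixed or
  intermediate roles are forced into the nearest type.
* Binary incidence discards expression magnitude; weakly expressed functions
  count as fully expressed edges.
* NODF and connectance are computed on the aligned (intersected) networks,
  so they depend on the function universe retained by the intersection.
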