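---
title: "Detecting and comparing spatial clusters in areal prevalence data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and comparing spatial clusters in areal prevalence data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arealscan)
```

## The problem

County-level surveillance data arrive as one count per areal unit: a
population denominator $N_i$, a case count $c_i$, a centroid, and often
region-level covariates (percent hypertensive, percent diabetic, ...).
The question is whether prevalence is geographically uniform and, if
not, *where* the excess sits. `arealscan` implements the two standard
scan-statistic answers under a discrete Poisson model — circular windows
of variable radius, and irregularly shaped (flexible) windows — together
with the machinery needed to compare their answers formally and to ask
whether detected hotspots are explained by known risk factors.

## The Poisson scan model

Conditional on the total case count $C = \sum_i c_i$, the null model
says cases fall into regions with probabilities $N_i/N$. A candidate
cluster (a *zone* $z$, a set of regions) has expected count
$e_z = C \, N_z / N$. The scan statistic is the maximum over all zones
of the log-likelihood ratio comparing distinct Poisson rates inside and
outside the zone against a single common rate:

$$
\mathrm{LLR}(z) \;=\; c_z \log\frac{c_z}{e_z}
 + (C - c_z)\log\frac{C - c_z}{C - e_z},
\qquad c_z > e_z,
$$

and 0 otherwise (only excess-risk zones are of interest; $0\log 0 := 0$,
so the statistic is finite even when one side is empty). `poisson_llr()`
implements this; a property test checks it against a direct evaluation
of the two Poisson log-likelihoods on a thousand random triples.

Two risk-ratio conventions attach to a zone and both are computed
everywhere: the inside/outside relative risk
$(c_z/e_z) \big/ \left((C-c_z)/(C-e_z)\right)$, which circular-scan
reports conventionally print as the "prevalence ratio", and the plain
observed/expected ratio $c_z/e_z$, which flexible-scan reports print.
The `pr_definition` field of `scan_config()` selects which one feeds the
reporting filter, defaulting to the convention of each scan type. This
duality matters when checking published tables: the bundled Florida
cluster tables (`florida_fixtures()`) round to the printed values only
under the correct convention for each method.

## Window families

**Circular** (`enumerate_circular()`): for each region as a centre, the
nested zones formed by adding other regions in order of ascending
centroid distance, truncated when the cumulative population would pass
`max_window` (default 13%) of the study total. The cap is on
*population*, not on region count: it simultaneously guarantees the
largest unit can be a cluster by itself and forbids windows so large
they stop being "local". Duplicated member sets reached from different
centres are emitted once. Distance ties are broken lexicographically by
region id, which makes the family — and therefore the whole scan —
invariant to the row order of the input table.

**Flexible** (`enumerate_flexible()`): all *connected* subsets of at
most $K$ regions (default 10) lying inside each centre's
$(K-1)$-nearest neighbourhood. Connectivity comes from explicit
adjacency pairs when polygon contiguity is available, else from a
symmetrised $K$-nearest-neighbour graph; both are accepted as inputs
since areal data sometimes ship without geometry. Enumeration grows
subsets incrementally with a forbidden-set rule so each connected subset
appears exactly once; an exhaustive bitmask oracle verifies equality on
every test graph up to 14 nodes. The family size explodes
combinatorially with $K$ and the graph degree, so a `zone_budget`
(default $5\times10^6$) aborts clearly rather than thrash; exhaustive
flexible scanning is a small-to-moderate-cluster tool by construction.

**Restriction.** The flexible scan scores zones with the *restricted*
LLR: the LLR multiplied by the indicator that every member region is
individually hot, i.e. has one-tailed mid-p
$P(X > c_i) + \tfrac12 P(X = c_i) < \alpha_1$ under
$X \sim \mathrm{Poisson}(e_i)$. The default $\alpha_1 = 0.2$ is the
established default for the restricted statistic (the source analysis
does not state its value, so the default is exposed as configuration).
Mid-p rather than the plain tail is the default, matching the reference
implementation lineage; `mid_p = FALSE` switches. The restriction keeps
low-risk regions from riding inside an irregular cluster purely as
connective tissue — the L-shaped-hotspot tests show exactly this
failure mode in the unrestricted circular scan.

## Monte Carlo inference

Inference conditions on $C$: each replicate redistributes all $C$ cases
over regions as a multinomial with probabilities $N_i/N$ (or adjusted
weights, below), the maximum statistic over the *same* zone family is
recorded, and a zone's p-value is its rank among the replicate maxima,
$p = (1 + \#\{\text{rep max} \ge \mathrm{obs}\})/(R + 1)$. With the
default $R = 999$ the smallest attainable p-value is 0.001. Conditional
multinomial replicates (rather than unconditional Poisson) are what make
the maximum exchangeable between observed and replicate data; a test
spies on the replicate stream to confirm every replicate carries exactly
$C$ cases. For the flexible scan the restriction is recomputed on every
replicate, so observed and null statistics are the same functional.

Secondary clusters are selected greedily: descending statistic, keep a
zone only if it shares no region with an already-kept zone, then drop
anything with $p > \alpha$ (default 0.05) or prevalence ratio $\le$
`pr_min` (default 1.2). The reporting filters are *reporting* rules;
the hypothesis test proper is the p-value of the most likely zone, and
that is what the size simulations measure.

## Covariate adjustment

Adjustment is the two-step indirect standardisation used with scan
software that cannot take continuous covariates directly:

1. `fit_poisson_offset()` fits
   $\log E[c_i] = \beta_0 + x_i^\top\beta + \log N_i$ by IRLS
   (`stats::glm`, tolerance $10^{-8}$, max 100 iterations). Covariates
   enter untransformed on the log-rate scale as percentages. With an
   intercept the fitted values satisfy $\sum \hat e_i = C$.
2. `adjusted_scan()` reruns a scan with $\hat e_i$ playing the role of
   population everywhere: zone expecteds
   $e_z = C \sum_{i\in z}\hat e_i / \sum_i \hat e_i$, multinomial
   replicate probabilities $\hat e_i/\sum \hat e$, and (circular) window
   cap on the $\hat e_i$. With an intercept-only model this reduces
   exactly — replicate for replicate under a shared seed — to the
   unadjusted scan, which is tested.

Constant covariates are aliased with the intercept; they are dropped
with a warning (leaving every fitted value unchanged) rather than
treated as an error, while any other rank deficiency halts. No
overdispersion correction is applied: the model is pure Poisson, and
quasi-likelihood variants are out of scope. Adjustment is wired for both
scan variants although the flexible path is an extension beyond the
standard circular use.

## Comparing two solutions

`compare_scans()` reduces each solution to a binary region-membership
vector ("in any reported cluster") and computes: the 2×2 contingency;
the exact McNemar test on the discordant cells
($p = \min(1,\, 2P(X \le \min(b,c)))$, $X\sim\mathrm{Bin}(b+c,\tfrac12)$);
Cohen's kappa with the Fleiss large-sample CI and a null test; PABAK
($2P_o - 1$) with a CI obtained by transforming the exact
Clopper–Pearson interval of $P_o$ — this transformed-exact choice
reproduces a published PABAK interval to four decimals, which a
normal-approximation interval does not; Landis–Koch labels; two-sample
continuity-corrected proportion tests (via `stats::prop.test`) on the
case and population shares; and the Cluster Information Criterion

$$\mathrm{CLIC} = -2\sum \mathrm{LLR} + \log(p)\, n$$

with natural log, $p$ the population in cluster regions and $n$ the
number of significant clusters. The natural-log reading is not
arbitrary: recomputing the criterion from the bundled circular-scan
table matches the published magnitude to 0.002% under $\ln$ and fails
badly under $\log_{10}$. The formula yields a *negative* value whenever
the likelihood term dominates, yet published comparisons print positive
numbers; `clic()` therefore returns both the signed value (ground
truth) and the magnitude (the printed convention), and the lower-
magnitude solution is read as the better fit. The flexible solution's
published criterion cannot be recomputed desk-side because restricted
LLRs are not printed; it is covered by property tests on the formula
(strictly decreasing in $\sum$LLR, increasing in $n$ and $p$) instead.

## The synthetic generator

`generate_region_data()` draws from a `simulation_scenario()`: region
rate $\lambda_i = \pi_0 \cdot RR(\text{zone}) \cdot
\exp\left(\sum_k \beta_k (x_{ik} - \bar x_k)\right)$, counts
$c_i \sim \mathrm{Poisson}(\lambda_i N_i)$ truncated at $N_i$ with a
warning. Covariates are centred at their realised means before effects
apply, so $\pi_0$ stays the marginal prevalence. Seeds live in the
scenario or the call — there is no hidden global state.

The fixed `scenario_suite()` encodes the study conditions the package
is tested under: 10×10 lattices with 5,000 people per cell and baseline
prevalence 3.7% (so a cell expects ~185 cases — informative but not
overwhelming counts); embedded zones at relative risk 2.0 for the power
benchmarks, bracketing published cluster ratios of 1.2–2.5; a
covariate-driven scenario whose 5-cell hotspot carries its entire
relative risk of 1.6 through a hypertension-like covariate (10-point
in-zone shift, $\beta = \log(1.6)/10$); and a 67-region irregular
lattice with log-uniform populations ($10^4$–$2.5\times10^6$) whose
largest region is pinned at 13% of the total — mirroring a setting in
which the window cap was chosen so the largest county could itself be a
cluster.

What the generator does *not* emulate: survey weighting and its design
effects (the real prevalence estimates behind such county tables come
from weighted telephone surveys), spatially autocorrelated covariate
fields beyond the zone structure, and non-Poisson overdispersion.
Passing tests therefore demonstrate correctness of the statistical
machinery under its own model, not robustness to those features of real
surveillance data.

## Numerical and design choices

* Distance ties and duplicate windows are resolved lexicographically by
  region id; two runs with identical seed and inputs produce
  byte-identical serialized reports, and shuffling input rows changes
  nothing.
* Spherical (haversine, sphere radius 6371 km) and planar distances are
  both supported; lon/lat input defaults to spherical since county
  centroid files are typically geographic. Which projection the
  original analyses used is generally unstated, so neither mode is
  privileged.
* `p_from_repmax` counts replicate ties *against* the observed
  statistic, keeping the test valid (conservative) under discreteness.
* Jenks class breaks use Fisher's exact dynamic programme rather than
  the common heuristic — inputs are at most a few hundred regions, so
  exactness is free.
* Degenerate inputs fail loudly and early: duplicate ids, cases above
  population, windows excluding every region, rank-deficient designs,
  zone budgets exceeded.

## Simulation scale and what the checks show

The acceptance-grade simulations use 200 null datasets and 100 hotspot
datasets per claim at 199 Monte Carlo replicates per scan, and the
flexible engine runs at $K = 5$–6 on the 10×10 lattices (the
Florida-style $K = 10$ neighbourhood on a rook lattice inflates the
connected-subset family without changing what the benchmark measures).
These sizes give the binomial bands quoted in the tests: e.g. 200 null
runs bound the empirical size of a 5% test between 1.5% and 9% at 99%
confidence. Observed behaviour: both engines sit near nominal size;
the circular scan localises a compact RR-2 hotspot essentially
perfectly; on an L-shaped hotspot the flexible scan's overlap with
truth is strictly better (mean Jaccard ≈ 0.8 vs ≈ 0.56 in the bundled
benchmark script); and the covariate-driven hotspot is detected
unadjusted but vanishes after adjustment.

## Known limitations

Exhaustive flexible enumeration is exponential in $K$ on dense graphs;
use the budget, a sparser adjacency, or a smaller $K$. p-values are
purely Monte Carlo (no Gumbel approximation), so very small p-values
need large $R$. Only the high-risk (hot-spot) alternative is scanned;
low-risk clusters, space–time scanning, and non-Poisson models
(Bernoulli, ordinal) are out of scope, as are survey-weighted
prevalence estimation and cartographic rendering beyond GeoJSON export.
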