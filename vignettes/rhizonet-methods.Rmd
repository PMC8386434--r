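---
title: "Methods: co-occurrence structure, compositional statistics and yield prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence structure, compositional statistics and yield prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

rhizonet analyzes replicated field-trial microbiome studies: 16S (bacterial)
and ITS (fungal) OTU count tables over locations, treatment arms, blocks and
time points, with a per-block crop yield. This vignette explains the models
and the numerical choices; it states no empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## Pairwise co-occurrence model

Presence/absence is defined on raw counts (`count > 0`), before any zero
handling. For two OTUs observed in $N_1$ and $N_2$ of $N$ samples, the null
model places the two occupancy sets independently and uniformly; the number
of shared samples is then hypergeometric,
$$P(X = j) = \binom{N_1}{j}\binom{N-N_1}{N_2-j}\Big/\binom{N}{N_2},$$
with expectation $N_1 N_2 / N$. `veech_pair_test()` evaluates both inclusive
tails in log space (via `phyper`), so the identity
$P(X \le j) + P(X \ge j) - P(X = j) = 1$ holds to machine precision and the
smallest attainable p-value is exact rather than a permutation floor.

A pair becomes a **co-occurrence** edge when $P(X \ge j_{obs}) < \alpha$ *and*
$j_{obs}$ exceeds its expectation, a **co-exclusion** edge in the mirrored
case; requiring the correct side of the expectation keeps degenerate pairs
from being classified both ways. Default $\alpha = 0.05$ per tail with no
multiple-testing correction, matching the convention of the incidence-based
co-occurrence literature; both the level and an optional BH switch are
config-exposed because the convention is a choice, not a law.

Before testing, OTUs are filtered by prevalence — at least 30% of all
samples for bacteria and 10% for fungi (the fungal table has proportionally
fewer, more prevalent OTUs) — with a hard cap of 4,000 nodes and $10^7$
pairs; ties at the cap break by prevalence, then total count, then OTU id,
so the filter is deterministic.

**Local networks.** Each sample's network is the induced subgraph of the
metacommunity network on the OTUs detected in that sample. Six statistics
summarize it: for each edge type, the edge *proportion* (local edges over
$\binom{S}{2}$, where $S$ counts **all** OTUs detected in the sample, not
only network nodes), the global *transitivity* (3 × triangles / connected
triples; defined 0 when no triple exists), and the *modularity* of a greedy
modularity-maximizing partition (igraph's fast-greedy agglomeration, which
is deterministic; 0 for edgeless graphs). Modularity needs a partition and
the partition algorithm is in principle pluggable; greedy maximization was
chosen because it is fast, deterministic, and standard.

## Compositional statistics

Zero counts are replaced under a Dirichlet prior with per-part means
$\alpha_j$ and total mass $s$: a zero part of a sample with depth $n$
receives $\alpha_j s/(n+s)$, and the nonzero parts are multiplicatively
rescaled, preserving their ratios exactly. Defaults are
$\alpha_j = 1/D$, $s = D/2$ — a Jeffreys-style pseudo-count of 0.5 per part.
The literature the analysis builds on says only "a Dirichlet prior", so the
least-informative symmetric choice is the default and both parameters are
exposed. If an imputed value reaches the smallest observed proportion of its
sample the function warns, since the prior is then not "small" relative to
the data.

CLR, Aitchison distance, PCoA and PERMANOVA follow the standard
compositional pipeline. PCoA is implemented as classical scaling of the
Gower-centered squared distances; on Aitchison distances its eigenvalues
equal those of a PCA of the centered CLR matrix, and the test suite checks
this duality to 1e-8 on every fixture. (The original analysis mentions NMDS
once but presents PCoA ordinations; only PCoA is implemented — PCoA is what
the duality argument and the downstream projection need.)

PERMANOVA uses sequential (Type I) sums of squares in the user-given term
order via projection matrices on the Gower-centered inner-product matrix,
pseudo-F statistics, and unrestricted permutation of sample identities with
the $(1+\#\{F^* \ge F\})/(1+n_{perm})$ estimator, so p-values never reach 0.
Aliased terms (including single-level factors) are reported with 0 df rather
than erroring. Whether the original analysis used sequential or marginal SS
is unstated; sequential-in-stated-order is the explicit, reproducible
choice, and the term order is part of the configuration.

## Treatment effects

The treatment effect is always a *difference of changes*: within one
location and one interval (T0→T1, T0→T2, T0→T3), the change over time in
the treated arm minus the change in the control arm, i.e. the interaction
coefficient of `value ~ treatment * time` by OLS. Applied to CLR abundances
this is a log-ratio fold-change contrast; applied to the local network
properties it is the same contrast in property units. The original analysis
used edgeR's negative-binomial machinery for the abundance version; this
package deliberately substitutes the CLR-scale OLS contrast so that the
estimator is self-contained, exactly testable against analytic oracles
(noise-free cell means are recovered exactly; type-I error is nominal), and
consistent between the abundance and the network-property analyses. Effect
direction and log-scale units are preserved. FDR control is
Benjamini–Hochberg within each (marker, location, interval) family, matching
how per-location significant sets are reported.

Degenerate designs are flagged, not dropped: an empty treatment×time cell
yields `"untestable"`, a zero-variance response yields `"degenerate"` with
p = 1 when the estimate is 0.

## Yield model

Block yields are bimodal in the emulated trial; the two-way categorization
threshold is placed at the deepest KDE minimum (Gaussian kernel, Silverman's
`nrd0` bandwidth) between the two highest modes, on **block-level** yields
(yield is constant within a block). KDE bumps under 5% of the peak density
are ignored when counting modes — tail wiggles of a kernel estimate are not
modes. Boundary values belong to the lower category (`<=30` style labels).
Sensitivity schemes split at (26, 35) and (20, 26, 35) t/ha.

Features per sample (T0–T2 with known yield): 70 joint principal components
of the column-centered concatenation of both CLR matrices (no unit-variance
scaling; a single projection over all included samples, as in the emulated
analysis — the train/test leakage this implies is documented here and a
stricter train-only projection can be obtained by projecting manually), the
12 local network properties, a treatment indicator, a bulk/rhizosphere
indicator, and one integer-coded `geo_variety` factor collapsing location
and seed variety (the two are confounded in the emulated design).

The classifier is a probability forest: CART trees on bootstrap samples
(Gini splits, `mtry = floor(sqrt(p))`, minimum node size 5), whose terminal
node class frequencies are averaged over trees; the predicted label is the
arg-max probability. No random-forest package is assumed: the forest is
implemented in compiled code inside this package, drawing all randomness
from R's RNG so a seed makes fits bit-reproducible. Importance is mean
decrease in Gini impurity, so constant features score exactly 0. The split
is stratified at 25% held out (the emulated analysis held out 26 of 104).
Defaults of 500 trees and stratified splitting are package choices (the
original states neither).

`transitivity_yield_regression()` aggregates fungal co-occurrence
transitivity to the block mean over T0–T2 samples and regresses block yield
on it by OLS. The block is the unit because yield is block-constant;
sample-level regression is available via a flag but pseudo-replicates.

## The synthetic world

`generate_study()` produces the full factorial design: 3 locations × 2 arms
× 10 blocks × 4 time points = 240 samples, 500 bacterial and 200 fungal
OTUs, multinomial counts at uniform 8,000–60,000 reads/sample. Its defaults
*are* the stated world of the emulated trial; they were fixed once and are
not tuned to tests.

* **Incidence first.** Presence/absence is generated before abundance,
  because the co-occurrence engine is incidence-based. Each marker has 6
  latent binary habitat factors. A *block habitat quality* $q_b \sim
  \mathrm{Beta}$ is drawn per block and shared by all factors (block-level
  community structure is the signal the yield model is meant to recover;
  six independent factors would average it away); each sample activates
  each factor with probability $q_b$. A factor's main group (10 bacterial /
  6 fungal OTUs) is present with probability 0.9 when the factor is active
  and 0.2 otherwise; an anti-coupled group (4/3 OTUs) has the two
  probabilities swapped. Within-group pairs are the planted co-occurrences,
  main×anti pairs the planted co-exclusions. Background OTUs get a
  Beta(1.2, 1.2) baseline prevalence with location- and rhizosphere-specific
  logit shifts (sd 1.2 and 0.8), so location dominates beta-diversity and
  bulk vs rhizosphere is compositionally visible, and a multiplicative
  richness dip (×0.85) in rhizosphere samples.
* **Abundance.** Conditional on presence: log-normal relative abundances
  with per-OTU location effects (sd 0.9), rhizosphere effects (sd 0.7) and
  sample noise (sd 0.4); counts are multinomial at the drawn depth.
* **Treatment.** 20 bacterial (10 fungal) differential OTUs per affected
  location, with a ±2 log2 interaction effect at T1/T2 in treated samples —
  planted in only 2 of 3 locations, the two low-yield ones, mirroring the
  trial in which the inoculant raised yield in two locations only. T3
  returns to baseline: no persistent legacy.
* **Yield.** The generating fungal co-occurrence network is the planted
  cliques embedded in a sparse (p = 0.03) unstructured background — without
  the background, any induced subgraph of disjoint cliques has transitivity
  exactly 1 and the planted driver would be degenerate. Block yield =
  location intercept (23, 26, 38 t/ha; the 20–45 t/ha scale straddles the
  30 t/ha convention, the per-block values being unpublished) + 3 t/ha
  treatment gain in the two affected locations + slope × (block-mean
  generating transitivity − 0.2) + N(0, 1.5²) noise. Fungal (not bacterial)
  factor activation is location-graded, so fungal community structure — and
  only fungal — carries the yield signal, reproducing the asymmetry the
  emulated study reports. The default slope is 30 t/ha per transitivity
  unit (the generator's transitivity spans roughly 0.1–0.3, so the term
  contributes a few t/ha, comparable to the treatment effect); the
  `yield-linked` fixture raises it to 45 with noise 1.0 and halves the
  Beta concentration of block quality to widen block-to-block structural
  spread.

**What a green test does and does not establish.** The generator emulates
the design factors, compositionality, planted incidence structure and the
block-structure→yield pathway. It does not emulate sequencing error,
chimeras, taxonomy misassignment, phylogenetic correlation, overdispersion
beyond the log-normal-multinomial, spatial autocorrelation within fields, or
year effects. Green recovery tests establish that the *pipeline* detects
what it claims to detect in a world where the truth is known — not that the
emulated study's biological conclusions are correct.

## Numerical and interface choices

* Exact tails come from `phyper`; the N ≤ 8 acceptance oracle enumerates
  all incidence placements combinatorially and agrees to 1e-12.
* TSV (UTF-8, tab, `.` decimal) is the canonical on-disk dialect; network
  edge lists print probabilities with 12 significant decimals (`%.12e`), so
  write→read→write is byte-stable. Missing yield is an empty field and
  stays `NA`, never 0 (T3 and yield-missing samples are excluded from the
  yield model by contract).
* The pipeline configuration (`run_config()`) requires an explicit seed for
  every stochastic stage (simulation, PERMANOVA permutations, forest) and
  the manifest records md5 digests of every stage output; identical configs
  reproduce identical digests. On-disk configs are JSON (no YAML parser is
  assumed in the environment; the schema is unchanged).
* The default end-to-end test study is the full 240-sample factorial; unit
  and acceptance tests scale ensemble sizes (e.g. 200-tree forests inside
  50-seed loops) to stay within time budgets, and say so where they do.

## Known limitations

Single-threaded; pair testing is all-pairs dense (fine for ≤ 4,000 nodes by
construction); no correlation-based network inference, no strata-restricted
permutations, no rarefaction, no hyperparameter search; the joint PCA leaks
test-set composition into the training features exactly as the emulated
analysis's single projection does (documented above, strict alternative
available).
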