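# rhizonet

Soil and rhizosphere microbiome analysis for replicated field trials:
co-occurrence network structure, compositional statistics, treatment-effect
contrasts, and yield prediction.

## The problem

Field trials of microbial inoculants collect 16S (bacterial) and ITS
(fungal) OTU count tables from bulk soil (before planting, after harvest)
and rhizosphere (during growth) across locations, treated/control blocks and
time points, together with a per-block crop yield in t/ha. Three questions
recur: *Did the treatment shift community composition or structure, where
and when?* *Which community features carry information about yield?* *Can a
sample tell us whether its block will be high- or low-yielding?*

rhizonet implements that analysis as a tested, reusable pipeline:

- **Exact pairwise co-occurrence**: for OTUs present in $N_1$ and $N_2$ of
  $N$ samples, the number of shared samples under independent placement is
  hypergeometric; both inclusive tails are computed exactly. Pairs with
  $P(X \ge j) < \alpha$ (and $j$ above the expectation $N_1N_2/N$) form the
  co-occurrence network, the mirrored pairs the co-exclusion network. OTUs
  are prevalence-filtered first (30% bacteria / 10% fungi, ≤ 4,000 nodes).
- **Local network properties**: per sample, the induced subgraph of each
  metacommunity network on the detected OTUs, summarized by modularity,
  transitivity, and edge proportion relative to all $\binom{S}{2}$ OTU
  pairs in the sample — six statistics per marker.
- **Compositional statistics**: Bayesian-multiplicative zero replacement
  (Dirichlet prior), CLR transform, Aitchison distances, PCoA, and
  sequential-SS PERMANOVA with permutation p-values.
- **Treatment effects**: per location and time interval, the
  difference-of-changes (treatment × time interaction) OLS contrast, applied
  to CLR abundances (with Benjamini–Hochberg FDR per location/interval
  family) and to the local network properties.
- **Yield model**: block yields categorized at the density minimum of their
  bimodal distribution (≤30 / >30 t/ha convention; 3- and 4-way sensitivity
  schemes at 26/35 and 20/26/35), a probability forest (implemented in
  compiled code in this package: bootstrap CART trees, averaged
  terminal-node class frequencies, Gini importances, stratified 25%
  hold-out), and a block-level transitivity–yield regression.
- **Synthetic studies with planted truth** (`generate_study()`): latent
  habitat factors plant co-occurring/co-excluding OTU groups, block-level
  habitat quality drives fungal network transitivity which drives a bimodal
  block yield, and treatment effects are planted in two of three locations —
  so every stage of the pipeline can be validated against known ground
  truth without any sequencing data.

## Worked example

```r
library(rhizonet)

study <- generate_study(synthetic_config(seed = 1))
study
#> synthetic_study: 240 samples, 500 bacterial + 200 fungal OTUs, 60 blocks

inc <- incidence_matrix(study$fungi)
net <- build_metacommunity(
  inc, filter_otus(inc, 0.10, total_counts = colSums(study$fungi$counts)),
  marker = "ITS", counts = study$fungi$counts, min_prevalence = 0.10)
net
#> metacommunity_network [ITS]: 189 nodes, 2509 cooccurrence + 1968 coexclusion edges
```

189 of 200 fungal OTUs pass the 10% prevalence filter, capturing 98.8% of
the fungal reads; edges are OTU pairs whose shared-sample count is
significantly above (co-occurrence) or below (co-exclusion) the
hypergeometric expectation at α = 0.05.

```r
clr16 <- clr_transform(replace_zeros(study$bacteria))
permanova(aitchison_distance(clr16), study$metadata,
          c("location", "time_point", "treatment"), n_perm = 999, seed = 1)
#>         term  df     ss     r2      f     p
#> 1   location   2  73131 0.1356 19.003 0.001
#> 2 time_point   3  16276 0.0302  2.820 0.001
#> 3  treatment   1   1618 0.0030  0.841 0.889
#> 4   Residual 233 448329 0.8312     NA    NA
#> 5      Total 239 539354 1.0000     NA    NA
```

Location and sampling time structure bacterial beta-diversity (p = 0.001);
this synthetic seed plants no global treatment shift, and the treatment row
is correctly null (R² = 0.003). R² is the fraction of Aitchison sum of
squares explained by each (sequential) term.

The yield model on the `yield-linked` fixture (stronger planted
structure→yield slope):

```r
st <- generate_study(synthetic_config(yield_transitivity_slope = 45,
                                      yield_noise_sd = 1.0,
                                      activation_concentration = 0.5,
                                      seed = 1))
# ... networks and properties_table() as above, then:
thr <- find_density_split(st$truth$blocks$yield)   # 33.1 t/ha
feats <- assemble_features(joint_projection(clr16, clrIT, 70), props,
                           st$metadata, thr)
fit_probability_forest(feats, seed = 1)
#> probability forest: 135 train / 45 test, accuracy 1.000
#> top importances:
#>                           PC1                   geo_variety
#>                        0.1019                        0.0948
#>   fun_cooccurrence_modularity fun_cooccurrence_transitivity
#>                        0.0343                        0.0340
#>   fun_cooccurrence_proportion                           PC2
#>                        0.0220                        0.0209

transitivity_yield_regression(props, st$metadata)
#> slope 86.2, R2 = 0.59, p = 7.5e-13 (n = 60 blocks)
```

Held-out classification is perfect on this planted world, and — as in the
field study this package emulates — the *fungal* co-occurrence structure
(modularity, transitivity, proportion) outranks every bacterial property,
with block-mean fungal transitivity positively predicting block yield.

## Pipeline and CLI

`run_all(run_config(...), out_dir)` executes
transform → diversity → networks → local properties → effects → yield model,
writes TSV/JSON outputs plus a manifest of md5 digests, and is
byte-reproducible for a fixed config (every stochastic stage requires an
explicit seed). A thin CLI wraps the same calls:

```sh
exec/rhizonet simulate --name tiny --seed 7 --out fixtures/
exec/rhizonet validate --otu fixtures/tiny_16S.tsv --marker 16S \
                       --meta fixtures/tiny_metadata.tsv
exec/rhizonet run --seed 1 --out run1/
```

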