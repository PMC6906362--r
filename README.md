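# psychcooccur

Bayesian analysis of how **co-occurring psychological characteristics** —
expressed by children and their guardians — associate with the outcome of a
pediatric nutritional intervention.

Univariate screens of psychological traits against intervention outcomes
are often inconclusive because traits do not act alone: a trait that leans
one way at baseline can lean the opposite way once a second trait
co-occurs with it. This package implements a full pipeline for detecting
such interactions in cohorts of children with binary characteristic
vectors and entry/exit BMI-for-age z-scores, plus a synthetic-cohort
simulator with known ground truth (the motivating clinical data are
private, so every stage is testable without any download).

## The method

**Outcome labeling.** Improvement is Δz = z-entry − z-exit of the
BMI-for-age z-score. The improvement threshold is anchored in biology
rather than chosen by hand: among children with first/last measurements of
insulin, triglycerides and HOMA-IR, those whose three biomarkers all moved
strictly toward the healthy range are compared with the rest by a
two-sided Mann–Whitney U test, and the threshold is the mean Δz of the
improved-lab group. Children with Δz ≥ threshold are labeled IMPV
(improved); the rest MC (minimal change).

**Baseline prevalence comparison.** For characteristic *c* with counts
k₁/n₁ (IMPV) and k₂/n₂ (MC), the group prevalences get conjugate
posteriors θ₁ ~ Beta(k₁+a₀, n₁−k₁+b₀), θ₂ ~ Beta(k₂+a₀, n₂−k₂+b₀), and the
baseline tendency is

P(θ₁ > θ₂) = ∫₀¹ f₁(x) F₂(x) dx

by adaptive quadrature (≤ 1e−6 absolute error). Values ≥ 0.9 flag an IMPV
lean; ≤ 0.1 flag an MC lean (conservation of probability). Each comparison
also reports the 2×2-table odds ratio, absolute risk reduction and
population attributable risk %, with a Haldane–Anscombe +0.5 correction at
zero cells.

**Stay/Swap interaction screen.** Characteristics beyond the 90% rule act
as *seeds*. Each (seed, partner) dyad — and (seed, partner, partner) triad
— is treated as one entity (expressed only when all members are), and its
P(θ₁ > θ₂) is computed the same way. Entities occurring ≤ 5 times across
both groups are discarded as rare; otherwise the designation is **Stay**
when the entity leans the same way as its seed at ≥ 90%, **Swap** when it
reaches ≥ 90% in the opposite direction, and Discarded (indeterminate) in
between.

**Co-occurrence networks.** Per outcome group, nodes are the
characteristics expressed in *both* groups; an edge joins characteristics
co-occurring within at least one child, weighted by the proportion of the
group's children expressing both. Sixteen node-level structural metrics
(degree/closeness/betweenness centralities, clique counts, triangles,
clustering coefficients, connectivity, vitality, Burt's effective size and
constraint, edge load and weight, …) are computed per node or per edge.

**BEST with gamma priors.** Each metric's two distributions are compared
with a two-group Bayesian estimation model (Student-t likelihood per
group; gamma priors on locations and scales because structural metrics are
non-negative, anchored at pooled sample statistics with CV = 2; ν−1 ~
Exponential, prior mean 30). A hand-written adaptive
Metropolis-within-Gibbs sampler (1,000 burn-in / 10,000 draws,
deterministic given a seed) yields the posterior of the IMPV − MC location
difference and its 90% highest-density interval; an HDI spanning 0 is
itself an informative negative control.

## Worked example

```r
library(psychcooccur)

scenario <- default_scenario(rng_seed = 20L)   # 128 IMPV / 372 MC, 77 traits
gen <- generate_cohort(scenario)
coh <- gen$cohort

filt <- sex_association_filter(coh, alpha = 0.05)  # sex-confound control
coh <- restrict_catalog(coh, filt$retained)

lab <- label_cohort(coh)                       # lab-anchored threshold
print(lab$threshold)
#> delta-z improvement threshold: 0.885
#>   lab-complete children: 70 (improved 17 / not improved 53)
#>   Mann-Whitney U = 708.0, two-sided p = 0.000432
#>   group means: improved 0.885, not improved 0.212
coh <- lab$cohort

base  <- baseline_scan(coh)                    # Beta posteriors + epi stats
seeds <- select_seeds(base)
head(seeds, 3)
#>    id direction baseline_prob
#> 1 c01      IMPV     1.0000000
#> 2 c03      IMPV     0.9953554
#> 3 c05      IMPV     0.9358871

dy <- dyad_scan(coh, base)                     # Stay/Swap screening
dy[dy$seed == "c01" & dy$designation %in% c("Stay", "Swap"), ][1:3, ]
#>   members p_higher_impv designation odds_ratio
#> 1 c01+c03      0.000792        Swap      0.093
#> 2 c01+c04      0.999907        Stay      6.825
#> 3 c01+c05      0.999835        Stay      3.948
```

The planted swap dyad of the default scenario is recovered: `c01` alone
leans IMPV with probability 1.00, but joined by `c03` the pair flips to a
99.9% MC lean (`Swap`, odds ratio 0.09). Continuing to the network stage:

```r
shared <- shared_characteristics(coh)          # expressed in both groups
nets <- lapply(c(IMPV = "IMPV", MC = "MC"),
               function(g) build_network(coh, g, shared))
metrics <- lapply(nets, compute_all_metrics)   # the 16 structural metrics
cmp <- compare_all_metrics(metrics$IMPV, metrics$MC,
                           best_config(rng_seed = 20L))
cmp[cmp$metric == "clustering",
    c("metric", "mean_impv", "mean_mc", "hdi_low", "hdi_high")]
#>       metric mean_impv mean_mc  hdi_low  hdi_high
#>   clustering     0.952   0.976 -0.02961  -0.01848
```

The 90% HDI of the clustering difference excludes 0: per-node clustering
is credibly higher in the MC network of this synthetic cohort. A
one-call version of all of the above, with CSV/JSON/GraphML outputs and a
reproducibility manifest, is:

```r
res <- run_pipeline(pipeline_config(scenario = default_scenario(),
                                    out_dir = "run1", rng_seed = 42L))
```

## Acceptance script

`scripts/acceptance.R` re-runs the entire pipeline from scratch on the
default synthetic scenario — simulation, sex filter, lab-anchored
labeling, baseline scan, dyad/triad screening, networks, sixteen metrics
and the BEST comparison — at the supplied seed, and writes the results
JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/methods.Rmd`) documents the model
assumptions, every tunable parameter with its default and rationale, what
the synthetic generator does and does not emulate, numerical conventions
(quadrature bracketing, tie rules, disconnected-graph conventions) and
known limitations.
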