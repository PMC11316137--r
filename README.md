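# mycogrowth

Tools for asking whether trees that grow faster along a soil nitrogen
gradient also host richer, different arbuscular mycorrhizal fungal
(AMF) communities.  The package takes the analysis from raw tree-core
ring widths and ASV count tables to the three results that matter:

1. **Growth vs. nitrogen** — annual basal area increment
   (BAI, cm² yr⁻¹), reconstructed from ring widths anchored at the
   field-measured DBH, is modelled per species with a Bayesian
   hierarchical log-normal model:

   BAIᵢ,ᵧ ~ logNormal(Dᵢ,ᵧ, σ²ᵢ,ᵧ),
   Dᵢ,ᵧ = α + β₁·Nminᵢ + β₂·BAIᵢ,ᵧ₋₁ + β₃·lnDBHᵢ,ᵧ₋₁ +
   β₄·MayMinTempᵧ + SEREᵢ,

   with size-dependent variance σ² = a + b·lnDBH and spatially
   explicit random effects (SERE) under an exponential distance-decay
   kernel, fitted by an adaptive Metropolis-within-Gibbs sampler with
   elliptical slice updates for the random effects (DIC, split R-hat,
   posterior prediction included).

2. **Richness vs. growth and nitrogen** — Chao1 richness of the ASV
   community shared between the two host species, regressed on
   per-tree mean BAI and on net N mineralization (F statistic with
   (1, n−2) df, adjusted R²).

3. **Community turnover** — a from-scratch threshold indicator taxa
   analysis: per-taxon change points on a continuous gradient via
   indicator-value permutation z-scores, with bootstrap **purity** and
   **reliability** (significant when both ≥ 0.95), at ASV and
   virtual-taxon level, on Hellinger-transformed abundances.

A synthetic-data generator (`simulate_study()`) emulates the full study
— a 12-stand N-mineralization gradient spanning ~0.22–1.87 μg N g⁻¹
day⁻¹, growth series drawn from the model above, and communities with a
planted richness trend and planted threshold responders — so every
stage is testable without field or sequence data.

## Worked example

```r
library(mycogrowth)

cfg   <- sim_config(seed = 1)          # 12 sites x 5 trees x 40 years
study <- simulate_study(cfg)

# ring widths -> DBH -> BAI for one tree (measured DBH 25.5 cm in 2021)
rw  <- subset(study$growth$rings, tree_id == "T001")
dbh <- reconstruct_dbh(rw, measured_dbh_cm = 25.5, final_year = 2021)
bai <- compute_bai(dbh)

# growth model for all trees (3 chains x 3000 iterations)
des <- build_design(study$growth$bai, study$growth$diameters,
                    study$trees, study$growth$temps)
fit <- summarize_fit(run_mcmc(des, n_iter = 3000, seed = 2), des,
                     allow_unconverged = TRUE)
print(fit)
```

```
Hierarchical growth model fit: 2340 tree-years, 60 trees
    parameter     mean      sd    q2.5   q97.5 rhat significant
1       alpha  1.79145 0.02905  1.7332 1.84679 1.00       FALSE
2       beta1  0.60229 0.03113  0.5420 0.66587 1.00        TRUE
3       beta2  0.03758 0.01269  0.0129 0.06394 1.00        TRUE
4       beta3  0.08073 0.00762  0.0662 0.09519 1.00        TRUE
5       beta4  0.08977 0.00432  0.0814 0.09837 1.00        TRUE
6           a  0.04316 0.00129  0.0407 0.04583 1.01       FALSE
7           b  0.00518 0.00115  0.0028 0.00734 1.01        TRUE
8       theta -0.03220 0.98812 -1.7923 2.12407 1.00       FALSE
9 sigma2_sere  0.04837 0.01007  0.0322 0.07078 1.01       FALSE
R2 (log scale) = 0.923, R2 (natural scale) = 0.891
DIC = 7713.4 (pD = 66.0)
```

The nitrogen coefficient `beta1` (per standard deviation of N
mineralization, on log-BAI) is positive with a 95% credible interval
excluding zero: faster growth at higher nitrogen, after accounting for
tree size, last year's growth, spring temperature and within-site
spatial dependence.  The generating value here was 0.6.

Downstream, on the same synthetic study:

```r
sp     <- study$trees$species[match(rownames(study$community$counts),
                                    study$trees$tree_id)]
shared <- filter_shared(study$community$counts, sp)
rich   <- chao1_per_sample(shared)
regress_diversity(rich, study$trees$nmin)[c("F", "df2", "p", "adj_r2")]
#> $F      293.06...
#> $df2    58
#> $p      2.4e-24
#> $adj_r2 0.832

titan <- classify_community(shared, study$trees$nmin,
                            titan_config(n_bootstrap = 250, seed = 3))
print(titan)
#> Threshold indicator taxa analysis: 40 taxa tested
#>   significant increasers: 12
#>   significant decreasers: 2
```

`run_pipeline(pipeline_config(synthetic = cfg, out_dir = "out"))` runs
everything — dendro, two species-level model fits, richness
regressions, four threshold-taxa tables — and writes a `manifest.json`
of MD5 hashes so reruns can be verified bit-identical.

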