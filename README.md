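# soilniche

Tools for modelling soil bacterial relative abundances from environmental
drivers, describing the niche space those models imply, and projecting how
communities may shift as the drivers change.

Continental soil surveys (16S rRNA amplicon tables over ~10^3 sites) record
each taxon's relative abundance together with climate (mean annual
temperature, humidity, precipitation), vegetation (C3 macrothermal, C3
mesothermal and C4 megathermal coverages) and soil chemistry (organic
carbon, conductivity, pH). `soilniche` treats these nine drivers and one
taxon as an observed-variable structural equation model (path analysis): a
recursive causal network

> climate → vegetation → soil → taxon

in which each endogenous variable *y* obeys a linear equation
*y = α + Σ βᵢ·parentᵢ + ζ*, the implied covariance
Σ̂ = f(B, Γ, Ψ, Φ) is compared with the sample covariance *S* through the ML
discrepancy *F = ln|Σ̂| − ln|S| + tr(SΣ̂⁻¹) − p*, and fit is judged by χ²,
CFI, RMSEA and SRMR. Standardized path coefficients (β·sd(parent)/sd(child))
are then used three ways:

* as **response-trait indicators** arranged taxa × 9 drivers, Ward-clustered
  into response groups and mapped to ternary soil/vegetation/climate
  coordinates (each axis = 100·Σ|family coefficients| / Σ|all nine|);
* as **traits on a phylogeny**, tested for global signal with Abouheif's
  Cmean (a Moran-type statistic on the topology-only Abouheif proximity)
  and for local signal with per-tip local Moran's I (LIPA);
* as **prediction machinery**, pushing future driver scenarios through the
  fitted equations to get future relative abundances, ln-fold changes (with
  the half-minimum zero replacement), Bray–Curtis/PCoA community
  displacement and inverse-distance-gridded maps.

Niche shape along single gradients is described independently with the
seven Huisman–Olff–Fresco (HOF) response models (flat, monotone, plateau,
symmetric and skewed unimodal, bimodal), selected by AICc with bootstrap
stabilisation; the optimum is the interior maximum of the chosen curve and
the niche edges are its inflection points.

A first-class synthetic-data generator (`generate_dataset()`,
`generate_hof_gradient()`, `generate_tree_and_trait()`,
`multinomial_counts()`) draws data with known causal, unimodal and
phylogenetic ground truth so that every stage is testable without any
external download. Preprocessing utilities cover rarefaction (default
22,500 reads/sample), 16S gene-copy-number correction, taxonomic rank
aggregation and the log10 environment transform.

## Worked example

```r
library(soilniche)

## a 1,381-sample world drawn from the packaged causal network
cfg <- default_generator_config(n_samples = 1381, seed = 42)
ds  <- generate_dataset(cfg)
d   <- dplyr::bind_cols(ds$env, taxon = as.numeric(abund_matrix(ds$abundances)))

fit <- fit_sem(d, default_sem_spec())
fit
#> <sem_fit> n = 1381
#>   chi2 = 5.934 (df = 12, p = 0.919), CFI = 1.000, RMSEA = 0.000, SRMR = 0.0065
#>   R2[taxon] = 0.294

holdout_validate(d, default_sem_spec(), n_train = 1000, seed = 7)$metrics
#> # A tibble: 1 × 4
#>   n_train n_test pearson_r r_squared
#> 1    1000    381     0.536     0.277

## niche shape along one gradient
g  <- generate_hof_gradient("IV", c(M = 4, a = -2, b = 6, c = 1.6), 300,
                            noise_sd = 0.02, seed = 3)
fit_hof(g, gradient, abundance, seed = 9)
#> <hof_fit> chosen type V (AICc choice V; bootstrap: V,V,V,V,V )
#>   optimum 0.299, edges [0.0785, 0.5205]

## phylogenetic signal of a Brownian trait
tt <- generate_tree_and_trait(64, brownian_sd = 1, seed = 11)
cmean_test(tt$trait, abouheif_proximity(tt$tree), n_perm = 999, seed = 13)
#> Abouheif's Cmean = 0.7424 (one-sided p = 0.001, 999 permutations, 64 tips)
```

The model fits its own generating topology (χ² p = 0.92, CFI = 1), explains
about 30% of taxon variance as configured, predicts the 381 hold-out
samples, recovers the planted type-IV/V optimum at 0.30 (skewed type V is
an acceptable twin of the symmetric truth at this noise level), and detects
the Brownian trait's conservation (Cmean ≫ 0, p = 0.001).

Every fitted object has `tidy()`/`glance()` methods and the result types
have `autoplot()`/`plot_*()` companions (`plot_ternary()`,
`plot_grid_map()`).

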