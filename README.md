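# wetlanddiv

Statistical analysis of tree diversity and composition in collated wetland
forest inventories — the situation where a few hundred sites, surveyed by
many teams with different methods, span several biomes and a wide climatic
gradient, and the questions are: how does composition turn over among
regions, how complete is the sampling of each region's flora, and how does
site-level diversity respond to climate across its *whole* conditional
distribution, not just its mean?

The package is written for community ecologists and biogeographers working
with incidence/abundance compilations (the same machinery applies to any
site-by-taxon data with partial sampling, e.g. microbiome surveys).

## What it computes

* **Compositional dissimilarity** on presence–absence: the modified Forbes
  coefficient, robust to partial sampling —
  `F' = a(n+√n) / [a(n+√n) + (3/2)bc]` with `a` shared species, `b`, `c`
  unique and `n = a+b+c`; used throughout as the dissimilarity `1 − F'` —
  plus Simpson turnover `βsim = min(b,c)/(a+min(b,c))` and lower-triangle
  matrix correlation.
* **Structure**: Ward clustering (`ward.D2`/`ward.D`) with cluster-to-label
  matching and adjusted-Rand cut-size selection; PCoA with explicit
  negative-eigenvalue reporting; seeded multi-start stress-1 NMDS rotated
  rigidly onto the first PCoA axis; permutation-tested climate vectors
  after an |r| > 0.7 collinearity filter.
* **Regional diversity**: random species-accumulation curves with an
  individuals-axis rescaling, and coverage-based rarefaction/extrapolation
  from incidence frequencies, with sample coverage
  `Ĉ = 1 − (Q1/U)·(T−1)Q1/[(T−1)Q1 + 2Q2]` and Chao-type asymptotic
  bounds; biome-occupancy tables of widespread versus restricted species.
* **Local diversity**: Fisher's alpha from `S = α ln(1 + N/α)` per site;
  *exact* single-covariate quantile regression (pinball loss, vertex
  enumeration, compiled) with xy-pair bootstrap intervals, full coefficient
  paths β(τ), and conditional densities obtained by monotone rearrangement
  and differencing of the fitted quantile process; ANOVA + Tukey–Kramer
  with compact letters on log alpha; a paired-t utility for
  diameter-cutoff sensitivity checks.
* **A synthetic metacommunity generator** whose defaults emulate a
  five-biome, 196-site national compilation: biome species pools with
  controlled pairwise overlap, log-series site communities (so Fisher's
  alpha is the true site parameter), per-biome Gaussian climate, and a
  right-skewed diversity law whose *upper* quantiles respond to
  temperature while the lower tail is climate-flat.

See `vignettes/wetland-diversity-methods.Rmd` for assumptions, defaults
and numerical details, and `analysis/01_simulate.R` … `04_local_diversity.R`
for the end-to-end narrative drivers (they write their tables under
`results/`).

## A worked example

```r
library(wetlanddiv)

cfg <- metacommunity_config(seed = 42)   # default five-biome conditions
mc  <- generate_dataset(cfg)
print(mc)
#> Synthetic metacommunity: 196 sites, 4999 species, 5 biomes (seed 42)

ar  <- alpha_records(mc$inventory)       # Fisher's alpha per site
lab <- mc$metadata$biome[match(ar$site_id, mc$metadata$site_id)]
round(tapply(ar$alpha, lab, mean, na.rm = TRUE), 1)
#>  Amazon Atlantic Forest Caatinga Cerrado Pampas
#>    18.4            12.8     19.0    19.0   12.3

D    <- dissimilarity_matrix(mc$community, "forbes")
tree <- ward_cluster(D)
sel  <- select_k(tree, setNames(mc$metadata$biome, mc$metadata$site_id))
sel$best_k        # 5  (adjusted Rand 0.98: clusters recover the biomes)

x  <- mc$metadata$mat                    # mean annual temperature, deg C
quantile_fit(ar$alpha, x, 0.9)$coefficients["b1"]   #  2.20
quantile_fit(ar$alpha, x, 0.1)$coefficients["b1"]   #  0.10
true_quantile_slope(cfg, 0.9)                       #  2.4
```

The last three numbers are the point of the design: diversity–temperature
slopes are strong at the 90th percentile (2.20 per °C, generating value
2.4) and essentially zero at the 10th (0.10) — the generator plants a
climate signal only in the upper quantiles, and the exact quantile
regression finds it. Warm biomes (Amazon, Caatinga, Cerrado) end up with
the higher mean alphas because the default law couples diversity to
temperature alone.

A full config-driven run (ingest → dissimilarity → clustering/ordination
→ rarefaction/occupancy → alpha/quantile models, all artifacts written to
an output directory) is one call:

```r
run_pipeline(validate_config("my_run.yaml"))
```

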