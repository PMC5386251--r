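---
title: "Methods: diversity and composition analysis of wetland tree metacommunities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity and composition analysis of wetland tree metacommunities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical machinery in `wetlanddiv`, the
assumptions behind each stage, the defaults and why they were chosen, and
what the synthetic metacommunity generator does and does not emulate.

## The analysis problem

The package targets compilations of forest-inventory data of the kind
assembled for national-scale wetland tree syntheses: a few hundred sites
across several biomes, each contributed by a different survey with its own
plot size, diameter cutoff and sampling effort, reduced to a common
three-column form (site, species, abundance) plus per-site climate
covariates. Three features of such data drive every methodological choice
here:

1. **Sampling is partial and heterogeneous.** Any statistic that is
   sensitive to effort will confound ecology with methodology.
2. **Only (S, N) is reliably available per site** — species richness and
   total stems — because many sources do not publish full abundance
   tables.
3. **Diversity–climate relationships need not be homogeneous across the
   conditional distribution**: hidden hydro-edaphic constraints can keep
   most sites well below the diversity ceiling their climate allows.

## Compositional dissimilarity

Pairwise dissimilarity uses presence–absence only. The primary metric is a
modified Forbes coefficient: with `a` shared species, `b` and `c` unique to
each site and `n = a + b + c`,

    F' = a (n + sqrt(n)) / [ a (n + sqrt(n)) + (3/2) b c ]

and the package standardizes on the *dissimilarity* `1 − F'` everywhere
(clustering and ordination accept dissimilarities; working on one scale
avoids sign errors). F' is derived under the assumption that both samples
are incomplete draws from their communities, which is exactly the situation
in a multi-survey compilation. The Simpson turnover index
`min(b, c) / (a + min(b, c))` is provided as the conventional
biogeographic alternative; on realistic metacommunities the two are nearly
collinear (Pearson r ≈ 0.98 on the default generator), which is the
package's built-in sanity check that the Forbes implementation behaves
like a turnover measure. Matrix comparison uses plain lower-triangle
Pearson correlation; a Mantel permutation p-value is available but not the
default, since the correlation itself (not its significance) is the
quantity of interest.

Both metrics are undefined when both sets are empty and the package treats
an empty site as an error rather than a zero: an inventory with no valid
species indicates an upstream data problem.

## Clustering and ordination

Ward clustering runs on the dissimilarity matrix via the `ward.D2`
criterion by default (the variant whose objective uses squared
dissimilarities, the convention of most modern implementations); `ward.D`
is exposed because compilations analysed with older software may have used
it, and the analysis drivers report both. Cluster–biome agreement is
summarized two ways: a cut of the tree is matched to reference labels by
assigning each cluster its modal label (a site is "mismatched" when its
cluster's modal label is not its own), and the cut size is chosen by
maximizing the adjusted Rand index against the labels. ARI was chosen as
the selection criterion because it is chance-corrected and standard; ties
go to the smallest k.

PCoA applies Gower double-centering to `−½ D∘D` and reports *all*
eigenvalues. Presence–absence dissimilarities are generally non-Euclidean,
so negative eigenvalues occur; by default no Cailliez/Lingoes correction is
applied and the proportion of variation uses positive eigenvalues only,
with the "divide by total absolute eigenvalue mass" convention reported
alongside, so both common conventions are visible.

NMDS minimizes Kruskal stress-1 in two dimensions through
`vegan::monoMDS`, wrapped with 20 seeded random starts plus one
PCoA-seeded start (tolerance 1e−7 on the stress ratio, 500 iterations);
the best-stress solution is returned with a convergence flag, and
non-convergence warns rather than errs because a slightly unconverged
configuration is still interpretable. The NMDS is then rigidly rotated so
its first dimension maximally correlates with the first PCoA axis — a pure
rotation (plus a sign convention), verified by the tests to preserve
inter-point distances to 1e−10 — so the two ordinations can be read side
by side.

Climate vectors are fitted by least-squares regression of each centered,
unit-scaled variable on the ordination coordinates; the arrow is the
normalized coefficient vector and significance comes from a permutation
test of r² (999 permutations by default, exact enumeration available for
tiny n, used by the test suite at n = 6). Before fitting, a greedy
collinearity filter walks the variables in priority order and drops any
with |r| > 0.7 against an already-retained variable — high collinearity
makes fitted directions unstable and redundant.

## Regional diversity

Accumulation curves resample site order without replacement (ten random
orderings by default, exhaustive enumeration for small regions) and report
the per-effort mean and range. Because stem density differs systematically
among biomes, the effort axis can be rescaled from sites to individuals by
each biome's mean stems per site; the richness values are untouched, so
the operation is trivially invertible.

Coverage-based rarefaction/extrapolation works from incidence frequencies
(T sampling units, per-species incidence counts Y, uniques Q1, duplicates
Q2). Interpolated richness uses the exact hypergeometric expectation;
estimated coverage at the observed effort is

    C = 1 − (Q1/U) · (T−1)Q1 / [ (T−1)Q1 + 2Q2 ]

and extrapolation is governed by the Chao-type estimate of undetected
species `Q0 = ((T−1)/T) Q1² / (2 Q2)` (falling back to `Q1(Q1−1)/2` with a
warning when Q2 = 0), which bounds the extrapolated curve at
`S_obs + Q0`. Rather than trusting transcribed formulas, the test suite
validates interpolation against exhaustive subset enumeration on small
regions and against a Monte-Carlo subsampling oracle (agreement within two
Monte-Carlo standard errors) on larger ones. Extrapolation defaults to at
most twice the observed number of sampling units, beyond which the
estimator is known to be unreliable.

## Local diversity

Fisher's alpha is the implicit solution of `S = α ln(1 + N/α)`. The solver
brackets the root in [1e−8, 1e8] with expansion, bisects via `uniroot`,
then polishes with Newton steps until the recovered S is within 1e−12;
round-trip accuracy (α → S → α) is tested at 1e−6 relative error. Sites
where every individual is a distinct species (S = N) admit no finite root:
they are flagged undefined, excluded from alpha-based models with a logged
count, and the exclusion is configurable. Non-integer abundance totals
(importance values) are rounded half-to-even with a warning before use as
N, since the log-series is defined on counts.

Quantile regression of alpha on each climate covariate (one covariate at a
time, by design — multivariable fits are out of scope) is solved
*exactly*: an optimal solution of the pinball-loss problem interpolates at
least two data points, so the compiled solver enumerates all O(n²)
candidate lines. The positive and negative residual sums of a candidate do
not depend on τ, so a whole coefficient path over the default grid
τ = 0.01…0.99 costs little more than one fit. Inference is by xy-pair
bootstrap (B = 1000, seeded) with percentile intervals; pair resampling
was chosen over residual resampling because the scientific question is
precisely about heteroskedastic, quantile-dependent structure. Headline
fits use τ ∈ {0.1, 0.3, 0.5, 0.7, 0.9}.

Conditional densities are obtained by inverting the fitted quantile
process at a covariate value: evaluate `Q(τ|x₀)` on the grid, sort if any
crossing is detected (monotone rearrangement — it repairs validity without
changing any fitted marginal quantile, and the result is flagged), and
differentiate `Δτ/ΔQ` at grid midpoints. The estimate integrates to the
grid's τ-mass (0.98) by construction; tests require the trapezoid
integral in [0.95, 1.05] and agreement with the Normal closed form within
5% over the central 80% when the process comes from Gaussian quantiles.

Biome comparisons of mean diversity use one-way ANOVA on natural-log alpha
(raw alpha is strongly right-skewed) with Tukey–Kramer all-pairs
comparisons, valid for unequal group sizes, summarized by a compact letter
display computed by insert-and-absorb over the significant-pair list. A
classical paired t-test utility is included for sensitivity analyses such
as comparing site diversity under two diameter cutoffs.

No multiple-testing correction is applied across the four climate
covariates: the fits are reported per variable, and readers should treat
the per-variable p-values accordingly.

## The synthetic metacommunity generator

The generator produces data with exactly the statistical structure the
pipeline assumes, so that every stage can be tested against known truth:

* **Biome-structured pools with controlled overlap.** Pools are assembled
  from pairwise-exclusive shared blocks (`round(overlap · min(pool
  sizes))` species shared by exactly that pair) plus exclusive species, so
  realized pairwise intersections match the request to within one species.
  The construction deliberately contains no higher-order (3+ biome) shared
  blocks; a species occurring in three or more biomes therefore never
  arises, which is the main structural simplification relative to real
  occupancy tables.
* **Log-series site communities.** A site with diversity parameter α and N
  individuals is drawn by a sequential urn in which individual i founds a
  new species with probability α/(α+i−1); this yields a log-series
  abundance distribution with `E[S] = α(ψ(α+N) − ψ(α)) ≈ α ln(1+N/α)`, so
  Fisher's alpha is the *true* parameter and estimator recovery is a
  meaningful test (relative bias under 5% at N ≥ 5000 is asserted in the
  suite). The log-series, not the lognormal, is the law under which alpha
  is the natural parameter — descriptions of the index sometimes invoke
  the lognormal's "few common, many rare" shape, but the generator is
  deliberately log-series so that truth is well-defined.
* **A right-skewed, upper-quantile-coupled diversity law.** Site alpha is
  drawn as `α = A(U) + g(U)·Σ βⱼ(xⱼ − refⱼ)` with U uniform,
  `A(τ) = exp(μ + σ Φ⁻¹(τ))` a lognormal base, and
  `g(τ) = max(0, (τ − q₀)/(1 − q₀))` a hinge at q₀ = 0.5. The generating
  τ-quantile slope on covariate j is exactly `βⱼ·g(τ)`: zero at and below
  the median, rising linearly above it. Coupling is additive on the raw
  covariate scale with a reference origin below the covariate's observed
  range, which keeps alpha positive and the quantile function monotone
  without constraining β. By default only mean annual temperature carries
  a nonzero slope (β = 3 alpha-units per °C at τ = 1, reference 15 °C), so
  a single-covariate quantile regression has a single well-defined
  generating value; the other covariates acquire only the indirect,
  between-biome correlation structure.
* **Defaults are the emulated study conditions.** Five biomes with 196
  sites split 63/58/50/12/13; per-biome climate Gaussian with the
  compilation's published biome means and standard deviations (dry months,
  annual precipitation, precipitation seasonality CV, mean annual
  temperature, temperature seasonality); stems per site lognormal with
  biome means near 1330/1590/1170/680/1440. Species pools are set to
  roughly twice each biome's documented richness: the observed union of a
  partially sampled region understates its true pool, and a pool as small
  as the observed union can be exhausted by the log-series upper tail. The
  base alpha law (median 7, σ = 0.55) places site alpha in the 5–30 range
  typical of such compilations. A consequence worth knowing: because the
  climate coupling is hinge-shaped, biome differences in *mean* log alpha
  are modest on the default generator even though upper-quantile
  differences are strong — the conditional-median structure is nearly
  climate-flat by construction.
* **Seeding.** One master seed; per-component substreams (climate, alpha,
  stems, communities) are derived from it so any stage can be regenerated
  in isolation and every dataset is bit-reproducible.

What the generator does **not** emulate: spatial autocorrelation,
dispersal or flood-pulse mechanics, taxonomic error, within-site habitat
structure, or importance-value abundances. Tests passing on synthetic data
therefore certify the statistical machinery, not the ecological
faithfulness of any particular real compilation.

## Numerical choices and degenerate inputs

* Fisher solver: bracket expansion plus Newton polish; S = N flagged, S > N
  is a domain error.
* Quantile fits: ties in the candidate-line loss break deterministically
  to the first pair in index order; constant covariates are an error;
  degenerate bootstrap resamples (constant covariate) are redrawn and
  counted.
* Forbes with a = 0 returns dissimilarity 1 even when the product `b·c`
  vanishes (one empty difference set), avoiding 0/0.
* PCoA eigenvalues below `max(λ)·1e−9` are treated as non-positive; axes
  are only returned for positive eigenvalues.
* Compact letters: insert-and-absorb; with no significant pairs all groups
  share one letter.
* The k-selection ARI of a degenerate reference partition (all labels
  equal) is 0 for every k ≥ 2, so the tie rule returns the smallest k.

## Problem sizes used by the tests and the acceptance script

The test suite runs entirely on generated data: small 3-biome
metacommunities (15–45 sites, pools of a few hundred species) for
structural checks, 120 deep sites (N ≈ 9000) for estimator bias, 200
replicates for bootstrap-coverage and type-I-error simulations, and 50
seeded replicates at roughly half the default site count for
upper-quantile slope recovery. The acceptance script runs the full default
conditions (196 sites, ~250k individuals) once per seed. These sizes were
chosen to make the Monte-Carlo assertions statistically stable while
keeping a full run in the minutes range on one core.

## Known limitations

* The overlap construction supports pairwise sharing only; occupancy
  tables from the generator have empty 3+-biome classes.
* The exact quantile-regression solver is O(n²) in memory for candidates
  and O(n³) per bootstrap resample; it is comfortable to n of a few
  hundred (its design point) but is not meant for thousands of sites.
* Coverage extrapolation inherits the usual caveat that Chao-type lower
  bounds become speculative far beyond the observed effort; the default
  caps extrapolation at 2T.
* The XLSX reader ingests the first sheet with a detected header; heavily
  formatted workbooks should be exported to CSV instead.
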