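# Local and regional diversity: Fisher's log-series alpha, size-based
# accumulation with individual rescaling, coverage-based rarefaction /
# extrapolation of incidence data, and biome-occupancy tabulation.

#' Fisher's alpha from species and individual counts
#'
#' Solves `S = alpha * log(1 + N / alpha)` for the unique positive root by
#' bracketed bisection (bracket `[1e-8, 1e8]`, expanded if needed) followed
#' by Newton polishing to `|S - alpha log(1 + N/alpha)| < 1e-12`. When
#' `S = N` (every individual its own species) no finite root exists and
#' `NA` is returned. Alpha is increasing in S at fixed N.
#'
#' @param S species count (>= 1).
#' @param N individual count (>= S); non-integer N (importance values) are
#'   accepted as-is here.
#' @return alpha, or `NA_real_` when S = N.
#' @examples
#' fishers_alpha(100, 1000)
#' @export
fishers_alpha <- function(S, N) {
  if (length(S) > 1 || length(N) > 1)
    return(mapply(fishers_alpha, S, N))
  if (S < 1) stop("S must be >= 1")
  if (S > N) stop("S cannot exceed N")
  if (S == N) return(NA_real_)
  f <- function(a) a * log1p(N / a) - S
  lo <- 1e-8; hi <- 1e8
  while (f(hi) < 0) hi <- hi * 10  # expansion; f is increasing in alpha
  while (f(lo) > 0) lo <- lo / 10
  a <- uniroot(f, c(lo, hi), tol = 1e-12)$root
  for (i in 1:8) {  # Newton polish
    fa <- f(a)
    if (abs(fa) < 1e-12) break
    a <- a - fa / (log1p(N / a) - N / (a + N))
  }
  a
}

#' Per-site alpha records from an inventory summary
#'
#' Computes Fisher's alpha for each site from (S, N). Non-integer N is
#' rounded half-to-even with a warning; sites with S = N get `NA` alpha
#' (no finite log-series fit) and are counted.
#'
#' @param inventory data.frame with `site_id`, `n_individuals`,
#'   `n_species` (as produced by [inventory_summary()]).
#' @return data.frame of class `alpha_records`: site_id, S, N, alpha;
#'   attribute `n_undefined` counts S = N sites.
#' @export
alpha_records <- function(inventory) {
  need <- c("site_id", "n_individuals", "n_species")
  stopifnot(all(need %in% names(inventory)))
  N <- inventory$n_individuals
  if (any(N != round(N))) {
    warning(sum(N != round(N)),
            " non-integer individual totals rounded half-to-even")
    N <- round(N)
  }
  S <- inventory$n_species
  alpha <- fishers_alpha(S, N)
  structure(data.frame(site_id = inventory$site_id, S = S, N = N,
                       alpha = alpha, stringsAsFactors = FALSE),
            class = c("alpha_records", "data.frame"),
            n_undefined = sum(is.na(alpha)))
}

site_species_sets <- function(table) {
  lapply(split(table$species_name, table$site_id), unique)
}

#' Random species-accumulation curves per biome
#'
#' For each biome, `n_curves` random orderings of its sites are drawn
#' without replacement and cumulative distinct-species counts recorded;
#' the per-effort mean and range across orderings are returned, plus a
#' pooled all-sites curve. With `exhaustive = TRUE` all orderings are
#' enumerated (small regions only), making the mean exact.
#'
#' @param table a `community_table`.
#' @param metadata a `site_metadata` with biome labels.
#' @param n_curves number of random site orderings.
#' @param seed RNG seed (required unless exhaustive).
#' @param exhaustive enumerate all orderings instead of sampling.
#' @return named list of data.frames (one per biome plus `"All sites"`):
#'   effort_sites, richness_mean, richness_min, richness_max, mode.
#' @export
accumulation_curves <- function(table, metadata, n_curves = 10, seed = NULL,
                                exhaustive = FALSE) {
  sets <- site_species_sets(table)
  lab <- biome_of(names(sets), metadata)
  groups <- c(split(sets, lab), list(`All sites` = sets))
  if (!exhaustive) {
    if (is.null(seed)) stop("seed required for random accumulation curves")
    set.seed(seed)
  }
  lapply(groups, function(g) {
    ns <- length(g)
    orders <- if (exhaustive) {
      p <- all_permutations(ns)
      lapply(seq_len(nrow(p)), function(i) p[i, ])
    } else replicate(n_curves, sample.int(ns), simplify = FALSE)
    rich <- vapply(orders, function(o) {
      seen <- character(0)
      vapply(g[o], function(sp) {
        seen <<- union(seen, sp)
        length(seen)
      }, 0L)
    }, integer(ns))
    rich <- matrix(rich, nrow = ns)
    data.frame(effort_sites = seq_len(ns),
               richness_mean = rowMeans(rich),
               richness_min = apply(rich, 1, min),
               richness_max = apply(rich, 1, max),
               mode = "size")
  })
}

#' Rescale an accumulation curve's effort axis to individuals
#'
#' Multiplies the site-based effort axis by the region's mean stems per
#' site, so biomes with different stem densities are compared on a common
#' individuals axis. Richness values are unchanged and the operation is
#' invertible.
#'
#' @param curve a curve data.frame from [accumulation_curves()].
#' @param mean_stems mean number of individuals per site (> 0).
#' @export
rescale_to_individuals <- function(curve, mean_stems) {
  stopifnot(mean_stems > 0)
  curve$effort_individuals <- curve$effort_sites * mean_stems
  curve
}

#' Incidence frequency summary of a region
#'
#' @param table a `community_table`.
#' @param sites optional character vector restricting the region.
#' @return list of class `incidence_summary`: `T` (sampling units), `Y`
#'   (per-species incidence counts), `U = sum(Y)`, `Q1`, `Q2` (uniques and
#'   duplicates), `S_obs`.
#' @export
incidence_frequencies <- function(table, sites = NULL) {
  stopifnot(inherits(table, "community_table"))
  if (!is.null(sites)) {
    table <- table[table$site_id %in% sites, , drop = FALSE]
    if (nrow(table) == 0) stop("no records for the requested sites")
  }
  sets <- site_species_sets(table)
  Y <- table(unlist(sets))
  Y <- stats::setNames(as.integer(Y), names(Y))
  structure(list(T = length(sets), Y = Y, U = sum(Y),
                 Q1 = sum(Y == 1L), Q2 = sum(Y == 2L),
                 S_obs = length(Y)),
            class = "incidence_summary")
}

#' Estimated sample coverage of incidence data
#'
#' `C_hat = 1 - (Q1/U) * (T-1)Q1 / ((T-1)Q1 + 2Q2)`: the estimated
#' proportion of incidences in the assemblage belonging to species already
#' detected. The coverage deficit `1 - C_hat` is the chance that a new
#' incidence belongs to a previously unsampled species.
#'
#' @param inc an `incidence_summary` with `T >= 2`.
#' @return list with `coverage` and `deficit`.
#' @export
sample_coverage <- function(inc) {
  if (inc$T < 2) stop("coverage estimator undefined for T < 2")
  if (inc$U < 1) stop("no incidences")
  C <- if (inc$Q1 == 0) 1 else
    1 - (inc$Q1 / inc$U) *
      ((inc$T - 1) * inc$Q1 / ((inc$T - 1) * inc$Q1 + 2 * inc$Q2))
  list(coverage = C, deficit = 1 - C)
}

#' Coverage-based rarefaction and extrapolation curve (incidence data)
#'
#' Expected species richness and estimated coverage as functions of the
#' number of sampling units t. Interpolation (t < T) uses the hypergeometric
#' expectations `S(t) = S_obs - sum_i C(T - Y_i, t) / C(T, t)` and
#' `C(t) = 1 - sum_i (Y_i / U) C(T - Y_i, t) / C(T - 1, t)`; the observed
#' point t = T uses the [sample_coverage()] estimator; extrapolation
#' (t > T, bounded by `t_max`) uses the Chao2-type estimate of undetected
#' species `Q0_hat = ((T-1)/T) Q1^2 / (2 Q2)` (or `((T-1)/T) Q1(Q1-1)/2`
#' with a warning when Q2 = 0), so extrapolated richness is non-decreasing
#' and asymptotically bounded by `S_obs + Q0_hat`.
#'
#' @param inc an `incidence_summary`.
#' @param t_grid sampling-unit grid (default `1..t_max`).
#' @param t_max extrapolation bound (default `2 * T`).
#' @return data.frame of class `coverage_curve`: t, richness, coverage,
#'   type (interpolated / observed / extrapolated).
#' @export
coverage_curve <- function(inc, t_grid = NULL, t_max = 2L * inc$T) {
  T <- inc$T; Y <- inc$Y; U <- inc$U; Q1 <- inc$Q1; Q2 <- inc$Q2
  if (is.null(t_grid)) t_grid <- seq_len(t_max)
  if (any(t_grid < 1)) stop("t grid must be positive")
  if (any(t_grid > t_max)) stop("t grid exceeds extrapolation bound t_max")
  Q0_hat <- if (Q2 > 0) (T - 1) / T * Q1^2 / (2 * Q2) else {
    if (Q1 > 1) warning("Q2 = 0: falling back to Q1(Q1-1)/2 convention")
    (T - 1) / T * Q1 * (Q1 - 1) / 2
  }
  rich <- cov_t <- numeric(length(t_grid))
  for (k in seq_along(t_grid)) {
    t <- t_grid[k]
    if (t < T) {
      rich[k] <- inc$S_obs - sum(exp(lchoose(T - Y, t) - lchoose(T, t)))
      cov_t[k] <- 1 - sum((Y / U) * exp(lchoose(T - Y, t) -
                                          lchoose(T - 1, t)))
    } else if (t == T) {
      rich[k] <- inc$S_obs
      cov_t[k] <- sample_coverage(inc)$coverage
    } else {
      tstar <- t - T
      rich[k] <- inc$S_obs + if (Q0_hat > 0 && Q1 > 0)
        Q0_hat * (1 - (1 - Q1 / (Q1 + T * Q0_hat))^tstar) else 0
      cov_t[k] <- 1 - (Q1 / U) *
        ((T - 1) * Q1 / ((T - 1) * Q1 + 2 * Q2))^(tstar + 1)
    }
  }
  structure(data.frame(t = t_grid, richness = rich, coverage = cov_t,
                       type = ifelse(t_grid < T, "interpolated",
                                     ifelse(t_grid == T, "observed",
                                            "extrapolated"))),
            class = c("coverage_curve", "data.frame"),
            Q0_hat = Q0_hat)
}

#' Biome-occupancy table
#'
#' For each species, the number of biomes it occurs in; tabulated per biome
#' (of that biome's species, how many occur in exactly 1..B biomes, with
#' proportions) and overall (exclusive and all-biome species).
#'
#' @param table a `community_table`.
#' @param metadata a `site_metadata`; every site must carry a biome label.
#' @return list of class `occupancy_table`: `counts` (biome x n-biomes
#'   matrix), `proportions`, `totals` (species per biome), `overall`
#'   (n_exclusive, n_all_biomes, all_biome_species).
#' @export
occupancy_table <- function(table, metadata) {
  lab <- biome_of(table$site_id, metadata)
  biomes <- unique(metadata$biome)
  occ <- lapply(split(lab, table$species_name), unique)
  n_occ <- vapply(occ, length, 0L)
  B <- length(biomes)
  counts <- matrix(0L, B, B, dimnames = list(biomes, paste0("in", 1:B)))
  for (b in biomes) {
    sp_b <- names(occ)[vapply(occ, function(x) b %in% x, TRUE)]
    counts[b, ] <- tabulate(n_occ[sp_b], nbins = B)
  }
  totals <- rowSums(counts)
  structure(list(counts = counts, proportions = counts / totals,
                 totals = totals,
                 overall = list(
                   n_species = length(occ),
                   n_exclusive = sum(n_occ == 1L),
                   n_all_biomes = sum(n_occ == B),
                   all_biome_species = names(occ)[n_occ == B])),
            class = "occupancy_table")
}
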