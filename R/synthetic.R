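# Synthetic metacommunity generator: biome-structured species pools with
# controlled pairwise overlap, log-series site communities, right-skewed
# site diversity whose upper quantiles respond to climate, and per-biome
# sampling intensity.

# Default climate means/sds per biome (dry months, mm/yr, CV %, degC,
# sd x 100), site counts and mean stems per site chosen to emulate a
# five-biome national wetland inventory compilation.
default_biomes <- function() {
  list(
    biomes = c("Amazon", "Atlantic Forest", "Cerrado", "Caatinga", "Pampas"),
    site_counts = c(63L, 58L, 50L, 12L, 13L),
    # regional pools from which inventories sample; roughly twice the
    # documented per-biome richness of the emulated compilation, since the
    # observed union of a partially sampled region understates its pool
    pool_sizes = c(2400L, 1800L, 1700L, 450L, 370L),
    climate_means = rbind(
      dry_months    = c(2.0,   5.11,  5.67,  8.44,  1.92),
      map_mm        = c(2557,  1426,  1337,  957,   1440),
      p_seasonality = c(42.8,  56.4,  75.7,  92.8,  13.6),
      mat           = c(26.8,  20.1,  23.6,  26.1,  18.6),
      t_seasonality = c(42.2,  228.4, 139.1, 105.0, 347.0)),
    climate_sds = rbind(
      dry_months    = c(1.5,  2.0,  0.8,  1.9,  1.5),
      map_mm        = c(463,  208,  186,  314,  156),
      p_seasonality = c(15.1, 22.1, 9.6,  16.8, 3.9),
      mat           = c(0.5,  2.1,  2.1,  1.2,  0.8),
      t_seasonality = c(11.4, 35.5, 40.1, 40.3, 26.1)),
    stems_mean = c(1327, 1586, 1169, 679, 1440),
    latlong = rbind(lat = c(-3, -22, -15, -9, -30),
                    lon = c(-63, -45, -47, -40, -53)))
}

#' Configuration of the synthetic metacommunity generator
#'
#' The defaults emulate a five-biome compilation of 196 wetland forest
#' inventories: per-biome species pools with moderate pairwise sharing,
#' per-biome Gaussian climate, log-normal stems-per-site, and a site
#' diversity law that is right-skewed and coupled to climate only in its
#' upper quantiles.
#'
#' The site-level Fisher's alpha is drawn as `alpha = A(U) + g(U) *
#' sum_j beta_j * (x_j - ref_j)` with `U ~ Uniform(0,1)`,
#' `A(tau) = exp(mu_log + sigma_log * qnorm(tau))` a log-normal base, and
#' `g(tau) = max(0, (tau - q0) / (1 - q0))` a hinge that switches the
#' climate effect on only above the quantile threshold `q0`. The generating
#' slope of the conditional tau-quantile on covariate j is therefore
#' exactly `beta_j * g(tau)`: zero at and below `q0`, rising linearly to
#' `beta_j` at tau = 1. By default only mean annual temperature carries a
#' nonzero slope, so a single-covariate quantile regression has a
#' well-defined generating value.
#'
#' @param n_biomes number of biomes (defaults use the first `n_biomes` of
#'   the built-in five).
#' @param biomes,site_counts,pool_sizes per-biome labels, site counts and
#'   species-pool sizes.
#' @param pairwise_overlap symmetric matrix (unit diagonal) of shared
#'   species fractions; a scalar is recycled to all off-diagonal pairs. The
#'   shared fraction of a pair is its intersection size over the smaller
#'   pool.
#' @param climate_means,climate_sds covariate-by-biome matrices.
#' @param alpha_model list with `mu_log`, `sigma_log`, `q0`, `beta` (named
#'   per covariate; units: alpha per covariate unit at tau = 1) and `ref`
#'   (reference origin per covariate so climate contributions stay
#'   non-negative).
#' @param stems_meanlog,stems_sdlog per-biome log-normal law of individuals
#'   per site (`stems_meanlog` defaults to match the built-in per-biome mean
#'   stem counts).
#' @param seed integer master seed; per-component substreams are derived
#'   from it.
#' @return list of class `metacommunity_config`.
#' @export
metacommunity_config <- function(n_biomes = 5L, biomes = NULL,
                                 site_counts = NULL, pool_sizes = NULL,
                                 pairwise_overlap = 0.12,
                                 climate_means = NULL, climate_sds = NULL,
                                 alpha_model = NULL,
                                 stems_meanlog = NULL, stems_sdlog = 0.7,
                                 seed = 1L) {
  d <- default_biomes()
  if (is.null(biomes)) biomes <- rep_len(d$biomes, n_biomes)
  if (is.null(site_counts)) site_counts <- rep_len(d$site_counts, n_biomes)
  if (is.null(pool_sizes)) pool_sizes <- rep_len(d$pool_sizes, n_biomes)
  if (is.null(climate_means))
    climate_means <- d$climate_means[, rep_len(1:5, n_biomes), drop = FALSE]
  if (is.null(climate_sds))
    climate_sds <- d$climate_sds[, rep_len(1:5, n_biomes), drop = FALSE]
  colnames(climate_means) <- colnames(climate_sds) <- biomes
  if (is.null(stems_meanlog))
    stems_meanlog <- log(rep_len(d$stems_mean, n_biomes)) - stems_sdlog^2 / 2
  stems_meanlog <- rep_len(stems_meanlog, n_biomes)
  stems_sdlog <- rep_len(stems_sdlog, n_biomes)
  if (length(pairwise_overlap) == 1L) {
    pairwise_overlap <- matrix(pairwise_overlap, n_biomes, n_biomes)
    diag(pairwise_overlap) <- 1
  }
  covs <- rownames(climate_means)
  if (is.null(alpha_model)) {
    beta <- ref <- stats::setNames(numeric(length(covs)), covs)
    beta["mat"] <- 3
    ref["mat"] <- 15
    alpha_model <- list(mu_log = log(7), sigma_log = 0.55, q0 = 0.5,
                        beta = beta, ref = ref)
  }
  cfg <- list(n_biomes = as.integer(n_biomes), biomes = biomes,
              site_counts = as.integer(site_counts),
              pool_sizes = as.integer(pool_sizes),
              pairwise_overlap = pairwise_overlap,
              climate_means = climate_means, climate_sds = climate_sds,
              alpha_model = alpha_model,
              stems_meanlog = stems_meanlog, stems_sdlog = stems_sdlog,
              latlong = d$latlong[, rep_len(1:5, n_biomes), drop = FALSE],
              seed = as.integer(seed))
  validate_metacommunity_config(cfg)
  structure(cfg, class = "metacommunity_config")
}

validate_metacommunity_config <- function(cfg) {
  B <- cfg$n_biomes
  ov <- cfg$pairwise_overlap
  if (!isTRUE(all.equal(ov, t(ov))) || any(diag(ov) != 1) ||
      any(ov < 0 | ov > 1))
    stop("pairwise_overlap must be symmetric with unit diagonal, in [0,1]")
  if (any(cfg$pool_sizes < 1L)) stop("pool sizes must be >= 1")
  if (any(cfg$climate_sds < 0)) stop("climate sds must be >= 0")
  if (length(cfg$site_counts) != B || length(cfg$pool_sizes) != B ||
      any(dim(ov) != B))
    stop("per-biome fields must have length n_biomes")
  am <- cfg$alpha_model
  if (am$sigma_log < 0 || am$q0 <= 0 || am$q0 >= 1)
    stop("alpha_model: sigma_log >= 0 and q0 in (0,1) required")
  invisible(cfg)
}

# synthetic binomial for global species index i (4 species per genus)
synthetic_binomial <- function(i) {
  sprintf("Genus%04d species%05d", (i - 1L) %/% 4L + 1L, i)
}

#' Build biome species pools with controlled pairwise overlap
#'
#' Pools are assembled from blocks: for each biome pair (i, j) a block of
#' `round(overlap_ij * min(pool_i, pool_j))` species shared by exactly that
#' pair, plus per-biome exclusive species filling each pool to its requested
#' size. Realized pairwise intersections therefore equal the requested
#' shared counts up to rounding (within one species). Overlap systems whose
#' shared blocks exceed a pool size are rejected.
#'
#' @param config a `metacommunity_config`.
#' @return list with `pools` (named list of species-name vectors) and
#'   `shared_counts` (matrix of realized pairwise intersections).
#' @export
build_species_pools <- function(config) {
  B <- config$n_biomes
  n <- config$pool_sizes
  ov <- config$pairwise_overlap
  m <- matrix(0L, B, B)
  for (i in seq_len(B - 1)) for (j in (i + 1):B)
    m[i, j] <- m[j, i] <- as.integer(round(ov[i, j] * min(n[i], n[j])))
  excl <- n - rowSums(m)
  if (any(excl < 0))
    stop("infeasible overlap system: shared species exceed pool size for ",
         paste(config$biomes[excl < 0], collapse = ", "))
  pools <- rep(list(character(0)), B)
  counter <- 0L
  take <- function(k) {
    out <- synthetic_binomial(counter + seq_len(k))
    counter <<- counter + k
    out
  }
  if (B > 1)
    for (i in seq_len(B - 1)) for (j in (i + 1):B) if (m[i, j] > 0) {
      blk <- take(m[i, j])
      pools[[i]] <- c(pools[[i]], blk)
      pools[[j]] <- c(pools[[j]], blk)
    }
  for (i in seq_len(B)) if (excl[i] > 0)
    pools[[i]] <- c(pools[[i]], take(excl[i]))
  names(pools) <- config$biomes
  dimnames(m) <- list(config$biomes, config$biomes)
  list(pools = pools, shared_counts = m)
}

#' Sample one site community from a log-series law
#'
#' Sequential urn scheme in which individual i founds a new species with
#' probability `alpha / (alpha + i - 1)` and otherwise recruits to the
#' species of a uniformly chosen earlier individual. The expected species
#' count is `alpha * (digamma(alpha + N) - digamma(alpha))`, which equals
#' `alpha * log(1 + N / alpha)` up to O(1/N), and the abundance distribution
#' is Fisher's log-series, so `alpha` is the true diversity parameter of the
#' site. Species identities are drawn from `pool` without replacement.
#'
#' @param pool character vector of available species names.
#' @param alpha Fisher's alpha (> 0).
#' @param n_individuals total individuals to draw (>= 1).
#' @return named integer vector of abundances summing to `n_individuals`.
#' @export
sample_site_community <- function(pool, alpha, n_individuals) {
  stopifnot(alpha > 0, n_individuals >= 1)
  counts <- hoppe_urn_sample(alpha, as.integer(n_individuals))
  s <- length(counts)
  if (s > length(pool))
    stop("species pool (", length(pool), ") smaller than realized species ",
         "draw (", s, "); increase the pool size")
  stats::setNames(counts, sample(pool, s))
}

#' Generate a full synthetic metacommunity
#'
#' Composes [build_species_pools()], per-biome Gaussian climate, a
#' right-skewed climate-coupled site diversity law (see
#' [metacommunity_config()]) and [sample_site_community()] into the data
#' model consumed by the rest of the pipeline. All randomness derives from
#' `config$seed` through named substreams, so any component can be
#' regenerated in isolation.
#'
#' @param config a `metacommunity_config`.
#' @return list of class `metacommunity`: `community` (a
#'   `community_table`), `metadata` (a `site_metadata`), `inventory`
#'   (per-site N and S), and `truth` (per-site true alpha/biome/N/latent
#'   quantile, pools, and the generating quantile-slope function values).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "metacommunity_config"))
  B <- config$n_biomes
  set.seed(config$seed)
  sub <- stats::setNames(sample.int(.Machine$integer.max - 1L, 4L),
                         c("climate", "alpha", "stems", "community"))
  pools <- build_species_pools(config)
  covs <- rownames(config$climate_means)
  biome_of_site <- rep(config$biomes, config$site_counts)
  n_sites <- length(biome_of_site)
  site_ids <- sprintf("site%03d", seq_len(n_sites))

  set.seed(sub["climate"])
  clim <- sapply(covs, function(v) {
    rnorm(n_sites,
          mean = config$climate_means[v, biome_of_site],
          sd = config$climate_sds[v, biome_of_site])
  })
  bi <- match(biome_of_site, config$biomes)
  lat <- config$latlong["lat", bi] + runif(n_sites, -3, 3)
  lon <- config$latlong["lon", bi] + runif(n_sites, -3, 3)

  am <- config$alpha_model
  set.seed(sub["alpha"])
  u <- runif(n_sites)
  base <- exp(am$mu_log + am$sigma_log * qnorm(u))
  g <- pmax(0, (u - am$q0) / (1 - am$q0))
  contrib <- as.vector(clim[, covs, drop = FALSE] %*% am$beta[covs]) -
    sum(am$beta[covs] * am$ref[covs])
  alpha_true <- base + g * pmax(contrib, 0)

  set.seed(sub["stems"])
  n_target <- pmax(20L, as.integer(round(rlnorm(n_sites,
    meanlog = config$stems_meanlog[bi], sdlog = config$stems_sdlog[bi]))))

  set.seed(sub["community"])
  recs <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    ab <- sample_site_community(pools$pools[[biome_of_site[i]]],
                                alpha_true[i], n_target[i])
    recs[[i]] <- data.frame(site_id = site_ids[i],
                            species_name = names(ab),
                            abundance = as.numeric(ab),
                            stringsAsFactors = FALSE)
  }
  community <- community_table(do.call(rbind, recs), normalize = FALSE)

  metadata <- site_metadata(data.frame(
    site_id = site_ids, biome = biome_of_site,
    latitude = lat, longitude = lon, clim,
    stringsAsFactors = FALSE), community = community)

  inv <- inventory_summary(community)
  inv <- inv[match(site_ids, inv$site_id), ]
  rownames(inv) <- NULL

  headline <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  truth <- list(
    sites = data.frame(site_id = site_ids, biome = biome_of_site,
                       alpha_true = alpha_true, n_target = n_target,
                       latent_u = u, stringsAsFactors = FALSE),
    pools = pools$pools, shared_counts = pools$shared_counts,
    beta = am$beta, q0 = am$q0,
    slope_at = sapply(headline, function(tau)
      am$beta * pmax(0, (tau - am$q0) / (1 - am$q0))),
    seed = config$seed, substreams = sub)
  colnames(truth$slope_at) <- paste0("tau", headline)

  structure(list(community = community, metadata = metadata,
                 inventory = inv, truth = truth, config = config),
            class = "metacommunity")
}

#' Generating quantile-slope of the synthetic diversity law
#' @param config a `metacommunity_config`.
#' @param tau quantile level(s).
#' @param covariate covariate name (default "mat").
#' @export
true_quantile_slope <- function(config, tau, covariate = "mat") {
  am <- config$alpha_model
  am$beta[[covariate]] * pmax(0, (tau - am$q0) / (1 - am$q0))
}

#' @export
print.metacommunity <- function(x, ...) {
  cat("Synthetic metacommunity:", nrow(x$truth$sites), "sites,",
      length(unique(x$community$species_name)), "species,",
      x$config$n_biomes, "biomes (seed", x$truth$seed, ")\n")
  invisible(x)
}
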