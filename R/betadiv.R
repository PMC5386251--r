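# Presence-absence pairwise dissimilarity: Forbes F' (robust to partial
# sampling) and Simpson (turnover), plus matrix comparison.

#' Shared/unique species counts for a site pair
#'
#' @param x,y character vectors (species present at each site); duplicates
#'   ignored.
#' @return list of class `pair_counts` with `a` (shared), `b` (only in x),
#'   `c` (only in y) and `n = a + b + c`.
#' @export
pair_counts <- function(x, y) {
  x <- unique(as.character(x)); y <- unique(as.character(y))
  a <- length(intersect(x, y))
  structure(list(a = a, b = length(x) - a, c = length(y) - a,
                 n = length(union(x, y))), class = "pair_counts")
}

#' Forbes F' dissimilarity
#'
#' Dissimilarity `1 - F'` with `F' = a(n + sqrt(n)) / (a(n + sqrt(n)) +
#' (3/2) b c)`, `n = a + b + c`. F' assumes sampling of each site is
#' partial, which makes it robust when incidence lists come from surveys of
#' very different effort. Symmetric in (b, c); 0 for identical or nested
#' pairs, 1 when no species are shared.
#'
#' @param pc a `pair_counts` (or list with elements a, b, c).
#' @return dissimilarity in \[0, 1\].
#' @export
forbes_fprime <- function(pc) {
  a <- pc$a; b <- pc$b; cc <- pc$c
  n <- a + b + cc
  if (n < 1) stop("both species sets empty: Forbes F' undefined")
  if (a == 0) return(1)
  num <- a * (n + sqrt(n))
  1 - num / (num + 1.5 * b * cc)
}

#' Simpson (beta-sim) dissimilarity
#'
#' `min(b, c) / (a + min(b, c))`: pure turnover, insensitive to richness
#' differences, 0 on nested pairs.
#'
#' @inheritParams forbes_fprime
#' @export
simpson_dissim <- function(pc) {
  a <- pc$a; m <- min(pc$b, pc$c)
  if (a + m < 1) stop("a + min(b, c) = 0: Simpson dissimilarity undefined")
  m / (a + m)
}

#' Pairwise dissimilarity matrix over all sites
#'
#' Computes all pairwise presence-absence dissimilarities of a community
#' table at once (via the site-by-species incidence matrix, so it scales to
#' hundreds of sites).
#'
#' @param table a `community_table` (>= 2 sites, each with >= 1 species).
#' @param metric "forbes" or "simpson".
#' @return symmetric matrix of class `dissim_matrix` with zero diagonal,
#'   site ids as dimnames and the metric as attribute `metric`. Use
#'   `as.dist()` to feed clustering.
#' @export
dissimilarity_matrix <- function(table, metric = c("forbes", "simpson")) {
  metric <- match.arg(metric)
  stopifnot(inherits(table, "community_table"))
  sites <- unique(table$site_id)
  if (length(sites) < 2) stop("need at least 2 sites")
  M <- unclass(table(factor(table$site_id, levels = sites),
                     table$species_name))
  M <- (M > 0) * 1
  s <- rowSums(M)
  if (any(s == 0)) stop("empty site(s): ",
                        paste(sites[s == 0], collapse = ", "))
  a <- tcrossprod(M)
  b <- s - a            # species only in row site
  cc <- t(b)            # species only in column site
  n <- a + b + cc
  if (metric == "forbes") {
    num <- a * (n + sqrt(n))
    D <- 1 - num / (num + 1.5 * b * cc)
    D[a == 0] <- 1
  } else {
    m <- pmin(b, cc)
    D <- m / (a + m)
  }
  diag(D) <- 0
  dimnames(D) <- list(sites, sites)
  structure(D, class = c("dissim_matrix", "matrix"), metric = metric)
}

#' Correlation between two dissimilarity matrices
#'
#' Pearson (or rank) correlation over the strictly-lower-triangle entries.
#' Optionally a Mantel permutation p-value (permuting site order of the
#' second matrix).
#'
#' @param d1,d2 `dissim_matrix` objects with identical site orders.
#' @param method passed to [stats::cor()].
#' @param n_perm Mantel permutations (0 = none).
#' @param seed RNG seed, required when `n_perm > 0`.
#' @return list with `r` and, when requested, `mantel_p`.
#' @export
matrix_correlation <- function(d1, d2, method = "pearson", n_perm = 0,
                               seed = NULL) {
  if (!identical(rownames(d1), rownames(d2)))
    stop("site orders differ between matrices")
  lt <- lower.tri(d1)
  r <- cor(d1[lt], d2[lt], method = method)
  out <- list(r = r)
  if (n_perm > 0) {
    if (is.null(seed)) stop("seed required for Mantel permutations")
    set.seed(seed)
    n <- nrow(d1)
    rp <- replicate(n_perm, {
      p <- sample.int(n)
      cor(d1[lt], d2[p, p][lt], method = method)
    })
    out$mantel_p <- (1 + sum(rp >= r)) / (1 + n_perm)
  }
  out
}
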