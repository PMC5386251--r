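# Compositional structure: Ward clustering matched against reference biome
# labels, PCoA, multi-start NMDS, rigid rotation to a reference axis,
# collinearity filtering and permutation-tested climate vectors.

as_square_dissim <- function(d) {
  m <- unclass(as.matrix(d))
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-10)))
    stop("dissimilarity matrix is not symmetric")
  m
}

#' Ward hierarchical clustering of a dissimilarity matrix
#'
#' @param d a `dissim_matrix` (or any symmetric dissimilarity matrix /
#'   `dist`).
#' @param variant "D2" (default; Ward criterion on squared dissimilarities,
#'   `hclust` method `ward.D2`) or "D" (`ward.D`).
#' @return an [stats::hclust] tree; merge heights are non-decreasing.
#' @export
ward_cluster <- function(d, variant = c("D2", "D")) {
  variant <- match.arg(variant)
  m <- as_square_dissim(d)
  hclust(as.dist(m), method = if (variant == "D2") "ward.D2" else "ward.D")
}

#' Cut a tree into k groups and match clusters to reference labels
#'
#' Each cluster is mapped to its modal reference label (ties broken
#' alphabetically); a site is mismatched when its cluster's modal label
#' differs from its own.
#'
#' @param tree an `hclust` tree.
#' @param k number of groups (1..n sites).
#' @param labels reference labels, in the tree's site order (named vectors
#'   are reordered by the tree's labels).
#' @return list: `assignments` (site, cluster, label, cluster label,
#'   mismatch flag), `mismatch_rate`, `per_label_rate`, `contingency`.
#' @export
cut_and_match <- function(tree, k, labels) {
  n <- length(tree$labels)
  if (k < 1 || k > n) stop("k must be in [1, ", n, "]")
  if (!is.null(names(labels))) labels <- labels[tree$labels]
  labels <- as.character(labels)
  cl <- cutree(tree, k = k)
  modal <- vapply(split(labels, cl), function(x) {
    tt <- sort(table(x), decreasing = TRUE)
    nm <- names(tt)[tt == tt[1]]
    sort(nm)[1]
  }, character(1))
  cluster_label <- modal[as.character(cl)]
  mis <- cluster_label != labels
  per <- vapply(split(mis, labels), mean, 0)
  list(assignments = data.frame(site_id = tree$labels, cluster = unname(cl),
                                label = labels,
                                cluster_label = unname(cluster_label),
                                mismatch = unname(mis),
                                stringsAsFactors = FALSE),
       mismatch_rate = mean(mis), per_label_rate = per,
       contingency = table(cluster = cl, label = labels))
}

#' Adjusted Rand index between two partitions
#' @param a,b label vectors of equal length.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # degenerate: both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Choose the cut size that best recovers reference labels
#'
#' Scores each candidate k by the adjusted Rand index between the k-group
#' cut and the reference labels; returns the maximizer (ties go to the
#' smallest k).
#'
#' @inheritParams cut_and_match
#' @param k_range integer vector of candidate k.
#' @return list with `best_k` and `scores` (k, adjusted Rand).
#' @export
select_k <- function(tree, labels, k_range = 2:8) {
  n <- length(tree$labels)
  if (any(k_range < 2 | k_range > n)) stop("k_range must lie in [2, ", n, "]")
  if (!is.null(names(labels))) labels <- labels[tree$labels]
  sc <- vapply(k_range, function(k)
    adjusted_rand_index(cutree(tree, k = k), labels), 0)
  list(best_k = k_range[which.max(sc)],
       scores = data.frame(k = k_range, ari = sc))
}

#' Principal coordinates analysis
#'
#' Gower double-centering of `-0.5 * D^2` followed by eigendecomposition.
#' Axes are ordered by eigenvalue; coordinates are returned for axes with
#' positive eigenvalues only, scaled by `sqrt(lambda)`. Negative eigenvalues
#' (possible for non-Euclidean dissimilarities such as Forbes F') are
#' reported, not corrected; the proportion of variation of axis i is
#' `lambda_i / sum(positive lambda)`. `prop_all_eigenvalues` additionally
#' reports the convention that divides by `sum(lambda_pos) +
#' sum(|lambda_neg|)`.
#'
#' @param d dissimilarity matrix.
#' @param n_axes number of axes to return.
#' @return list of class `ordination_result`: `points`, `eigenvalues`,
#'   `prop_explained`, `prop_all_eigenvalues`, `method = "pcoa"`.
#' @export
pcoa <- function(d, n_axes = 2) {
  m <- as_square_dissim(d)
  n <- nrow(m)
  A <- -0.5 * m^2
  B <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  e <- eigen(B, symmetric = TRUE)
  lambda <- e$values
  pos <- lambda > max(lambda) * 1e-9
  n_use <- min(n_axes, sum(pos))
  pts <- e$vectors[, seq_len(n_use), drop = FALSE] %*%
    diag(sqrt(lambda[seq_len(n_use)]), n_use)
  rownames(pts) <- rownames(m)
  colnames(pts) <- paste0("axis", seq_len(n_use))
  structure(list(points = pts, eigenvalues = lambda,
                 prop_explained = lambda[pos] / sum(lambda[pos]),
                 prop_all_eigenvalues = lambda[pos] /
                   (sum(lambda[pos]) + sum(abs(lambda[!pos]))),
                 method = "pcoa"),
            class = "ordination_result")
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Minimizes stress-1 from `n_starts` random configurations plus one
#' PCoA-seeded start, returning the best solution. The underlying engine is
#' `vegan::monoMDS` (global model, primary tie treatment); determinism is
#' guaranteed by the required seed.
#'
#' @param d dissimilarity matrix.
#' @param n_dims embedding dimension.
#' @param n_starts random starts in addition to the metric start.
#' @param max_iter,tol iteration cap and relative stress-change stopping
#'   tolerance.
#' @param seed RNG seed (required).
#' @return `ordination_result` with `points`, `stress`, `converged`,
#'   `method = "nmds"`.
#' @export
nmds <- function(d, n_dims = 2, n_starts = 20, max_iter = 500, tol = 1e-7,
                 seed) {
  if (missing(seed)) stop("seed is required for nmds()")
  m <- as_square_dissim(d)
  n <- nrow(m)
  dd <- as.dist(m)
  set.seed(seed)
  inits <- c(list(pcoa(m, n_axes = n_dims)$points),
             replicate(n_starts,
                       matrix(runif(n * n_dims, -1, 1), n), simplify = FALSE))
  best <- NULL
  for (y0 in inits) {
    if (ncol(y0) < n_dims)  # degenerate PCoA start: pad with noise
      y0 <- cbind(y0, matrix(runif(n * (n_dims - ncol(y0)), -1e-4, 1e-4), n))
    fit <- vegan::monoMDS(dd, y = y0, k = n_dims, model = "global",
                          maxit = max_iter, sratmax = 1 - tol)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  pts <- best$points
  rownames(pts) <- rownames(m)
  colnames(pts) <- paste0("dim", seq_len(n_dims))
  converged <- best$icause %in% c(2L, 3L)  # stress ratio / scale criterion
  if (!converged) warning("NMDS did not converge within max_iter")
  structure(list(points = pts, stress = best$stress, converged = converged,
                 method = "nmds", n_starts = n_starts + 1L),
            class = "ordination_result")
}

#' Rigidly rotate an ordination so axis 1 tracks a reference score
#'
#' Finds the orthogonal rotation whose first rotated dimension has maximal
#' Pearson correlation with `reference` (the rotation taking dimension 1
#' along the regression direction of the reference on the coordinates);
#' inter-point distances are unchanged. Sign convention: positive
#' correlation with the reference.
#'
#' @param ord an `ordination_result`.
#' @param reference numeric vector of reference axis scores (e.g. the first
#'   PCoA axis), in the same site order.
#' @return the rotated `ordination_result`.
#' @export
rotate_to_reference <- function(ord, reference) {
  X <- ord$points
  if (length(reference) != nrow(X))
    stop("reference length does not match number of sites")
  k <- ncol(X)
  if (k == 1L) return(ord)
  S <- cov(X)
  w <- tryCatch(solve(S, cov(X, reference)),
                error = function(e) stop("degenerate configuration: ", e$message))
  w <- w / sqrt(sum(w^2))
  Q <- qr.Q(qr(cbind(w, diag(k))))[, seq_len(k), drop = FALSE]
  if (sum(Q[, 1] * w) < 0) Q[, 1] <- -Q[, 1]
  Y <- X %*% Q
  if (cor(Y[, 1], reference) < 0) {
    Y[, 1] <- -Y[, 1]  # sign convention only
  }
  dimnames(Y) <- dimnames(X)
  ord$points <- Y
  ord$rotated <- TRUE
  ord
}

#' Greedy collinearity filter for climate variables
#'
#' Walks the variables in priority order, retaining one unless its absolute
#' Pearson correlation with an already-retained variable exceeds
#' `threshold`. Constant variables (undefined r) are excluded with a
#' warning.
#'
#' @param climate data.frame / matrix of numeric variables.
#' @param threshold absolute-correlation cutoff.
#' @param priority column-name order in which variables are considered.
#' @return list: `retained`, `dropped` (named by the retained variable that
#'   caused each drop).
#' @export
decorrelate_variables <- function(climate, threshold = 0.7,
                                  priority = colnames(climate)) {
  X <- as.data.frame(climate)[priority]
  const <- vapply(X, function(v) var(v, na.rm = TRUE) == 0 ||
                    !is.finite(var(v, na.rm = TRUE)), TRUE)
  if (any(const)) {
    warning("constant variable(s) excluded: ",
            paste(names(X)[const], collapse = ", "))
    X <- X[!const]
  }
  retained <- character(0)
  dropped <- character(0)
  for (v in names(X)) {
    r_with <- vapply(retained, function(u)
      abs(cor(X[[v]], X[[u]], use = "complete.obs")), 0)
    if (length(r_with) && any(r_with > threshold)) {
      dropped[v] <- retained[which.max(r_with)]
    } else retained <- c(retained, v)
  }
  list(retained = retained, dropped = dropped)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Fit climate vectors onto an ordination
#'
#' For each variable: least-squares regression of the centered, unit-scaled
#' variable on the ordination coordinates; the fitted vector direction is
#' the normalized coefficient vector, r-squared comes from that fit, and
#' the p-value is the permutation tail probability of r-squared under
#' random permutation of the variable across sites (`exact = TRUE`
#' enumerates all n! permutations; feasible for n <= 8).
#'
#' @param ord an `ordination_result`.
#' @param climate data.frame of climate variables, rows in site order of
#'   the ordination. Rows with missing values are dropped with a warning.
#' @param n_perm number of random permutations.
#' @param seed RNG seed (required unless `exact`).
#' @param alpha significance level for the `significant` flag.
#' @param exact use exhaustive permutation enumeration.
#' @return data.frame of class `fitted_vectors`: variable, one direction
#'   cosine per axis, r2, p, significant.
#' @export
fit_climate_vectors <- function(ord, climate, n_perm = 999, seed = NULL,
                                alpha = 0.05, exact = FALSE) {
  X <- ord$points
  climate <- as.data.frame(climate)
  keep <- stats::complete.cases(climate)
  if (!all(keep)) {
    warning(sum(!keep), " site(s) with missing climate dropped")
    climate <- climate[keep, , drop = FALSE]
    X <- X[keep, , drop = FALSE]
  }
  n <- nrow(X); k <- ncol(X)
  if (n < k + 2) stop("need at least dims + 2 complete sites")
  if (!exact && is.null(seed)) stop("seed required for permutation test")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  H <- Xc %*% solve(crossprod(Xc)) %*% t(Xc)  # hat matrix of coordinates
  perms <- if (exact) all_permutations(n) else NULL
  if (!exact) set.seed(seed)
  res <- lapply(names(climate), function(v) {
    y <- as.numeric(scale(climate[[v]]))
    if (!all(is.finite(y))) stop("constant climate variable: ", v)
    r2_of <- function(z) sum((H %*% z)^2) / sum(z^2)
    r2 <- r2_of(y)
    beta <- solve(crossprod(Xc), crossprod(Xc, y))
    dir <- beta / sqrt(sum(beta^2))
    r2p <- if (exact) apply(perms, 1, function(p) r2_of(y[p])) else
      replicate(n_perm, r2_of(y[sample.int(n)]))
    p <- if (exact) mean(r2p >= r2 - 1e-12) else
      (1 + sum(r2p >= r2)) / (1 + n_perm)
    out <- data.frame(variable = v, t(as.numeric(dir)), r2 = r2, p = p)
    names(out)[2:(1 + k)] <- paste0("axis", seq_len(k))
    out
  })
  out <- do.call(rbind, res)
  out$significant <- out$p < alpha
  class(out) <- c("fitted_vectors", "data.frame")
  out
}
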