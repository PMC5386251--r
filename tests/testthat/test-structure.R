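make_labels <- function(md) stats::setNames(md$biome, md$site_id)

test_that("Ward clustering recovers separated blocks and matches a hand
           Lance-Williams recursion", {
  # two clear blocks
  m <- matrix(0.9, 6, 6); m[1:3, 1:3] <- 0.1; m[4:6, 4:6] <- 0.1
  diag(m) <- 0
  dimnames(m) <- list(paste0("s", 1:6), paste0("s", 1:6))
  tree <- ward_cluster(m)
  expect_setequal(split(tree$labels, cutree(tree, 2))[[1]],
                  paste0("s", 1:3))
  expect_true(all(diff(tree$height) >= -1e-12))

  # 4-site hand recursion (ward.D2 update)
  set.seed(4)
  p <- matrix(rnorm(8), 4)
  d0 <- as.matrix(dist(p))
  dimnames(d0) <- list(letters[1:4], letters[1:4])
  tree <- ward_cluster(d0)
  # oracle: explicit Lance-Williams recursion on squared distances
  clusters <- as.list(letters[1:4]); sizes <- rep(1, 4)
  d2 <- d0^2; heights <- numeric(3)
  for (step in 1:3) {
    k <- length(clusters)
    best <- c(Inf, 0, 0)
    for (i in 1:(k - 1)) for (j in (i + 1):k)
      if (d2[i, j] < best[1]) best <- c(d2[i, j], i, j)
    i <- best[2]; j <- best[3]
    heights[step] <- sqrt(best[1])
    ni <- sizes[i]; nj <- sizes[j]
    newd2 <- vapply(seq_len(k)[-c(i, j)], function(l)
      ((ni + sizes[l]) * d2[i, l] + (nj + sizes[l]) * d2[j, l] -
         sizes[l] * d2[i, j]) / (ni + nj + sizes[l]), 0)
    keep <- seq_len(k)[-c(i, j)]
    d2 <- rbind(cbind(d2[keep, keep, drop = FALSE], newd2),
                c(newd2, 0))
    clusters <- c(clusters[keep],
                  list(c(clusters[[i]], clusters[[j]])))
    sizes <- c(sizes[keep], ni + nj)
  }
  expect_equal(tree$height, sort(heights), tolerance = 1e-10)
})

test_that("clustering is invariant to input site order", {
  tab <- random_table(n_sites = 8, n_species = 50, seed = 6)
  D <- dissimilarity_matrix(tab, "forbes")
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  Dp <- structure(unclass(D)[perm, perm], class = class(D))
  labels <- stats::setNames(rep(c("X", "Y"), 4), rownames(D))
  t1 <- ward_cluster(D); t2 <- ward_cluster(Dp)
  expect_equal(sort(t1$height), sort(t2$height), tolerance = 1e-12)
  m1 <- cut_and_match(t1, 3, labels); m2 <- cut_and_match(t2, 3, labels)
  expect_equal(m1$mismatch_rate, m2$mismatch_rate)
})

test_that("cluster-label matching has the right edge behaviour", {
  tab <- random_table(n_sites = 6, n_species = 40, seed = 9)
  D <- dissimilarity_matrix(tab, "forbes")
  tree <- ward_cluster(D)
  labels <- stats::setNames(rep(c("X", "Y", "Z"), 2), rownames(D))
  expect_equal(cut_and_match(tree, 6, labels)$mismatch_rate, 0)
  same <- stats::setNames(rep("X", 6), rownames(D))
  for (k in c(2, 4, 6))
    expect_equal(cut_and_match(tree, k, same)$mismatch_rate, 0)
  expect_error(cut_and_match(tree, 7, labels), "k must")
})

test_that("k selection recovers separable groups and ties to smallest k", {
  mc <- generate_dataset(small_config(seed = 55, overlap = 0.05))
  D <- dissimilarity_matrix(mc$community, "forbes")
  tree <- ward_cluster(D)
  labels <- make_labels(mc$metadata)
  sel <- select_k(tree, labels, k_range = 2:6)
  expect_equal(sel$best_k, 3L)
  expect_true(all(sel$scores$ari[sel$scores$k == sel$best_k] >=
                    sel$scores$ari))
  # low pool overlap: near-perfect biome recovery at k = 3
  expect_lt(cut_and_match(tree, 3, labels)$mismatch_rate, 0.10)
  # uninformative labels: flat score path, smallest k returned
  same <- stats::setNames(rep("X", length(labels)), names(labels))
  sel2 <- select_k(tree, same, k_range = 2:5)
  expect_equal(sel2$best_k, 2L)
  expect_equal(var(sel2$scores$ari), 0)
})

test_that("adjusted Rand matches the independent implementation", {
  skip_if_not_installed("mclust")
  set.seed(3)
  for (i in 1:5) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b))
  }
})

test_that("PCoA recovers Euclidean configurations and hand eigenvalues", {
  set.seed(21)
  pts <- matrix(rnorm(10), 5, 2)
  D <- as.matrix(dist(pts))
  ord <- pcoa(D, n_axes = 4)
  # two positive eigenvalues; distances reproduced to numerical precision
  expect_equal(sum(ord$eigenvalues > 1e-8), 2L)
  expect_lt(max(abs(dist(ord$points[, 1:2]) - dist(pts))), 1e-8)
  expect_equal(sum(ord$prop_explained), 1)

  # 3-point oracle: eigendecomposition of the hand-centered matrix
  m <- matrix(c(0, .4, .7, .4, 0, .5, .7, .5, 0), 3)
  A <- -0.5 * m^2
  J <- diag(3) - 1 / 3
  lambda <- eigen(J %*% A %*% J, symmetric = TRUE)$values
  ord3 <- pcoa(m)
  expect_equal(ord3$eigenvalues, lambda, tolerance = 1e-12)

  # agreement with the classical-scaling reference implementation
  cs <- cmdscale(as.dist(m), k = 2, eig = TRUE)
  expect_equal(abs(ord3$points[, 1]), abs(cs$points[, 1]),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("NMDS reaches near-zero stress on perfect 2-D data and its
           stress matches an independent stress-1 recomputation", {
  set.seed(14)
  pts <- matrix(rnorm(24), 12, 2)
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(paste0("s", 1:12), paste0("s", 1:12))
  ord <- nmds(D, n_dims = 2, n_starts = 5, seed = 3)
  expect_lt(ord$stress, 0.01)

  # noisy non-Euclidean input: recompute stress-1 from the coordinates
  Dn <- D + matrix(runif(144, 0, 0.3), 12)
  Dn <- (Dn + t(Dn)) / 2; diag(Dn) <- 0
  ord2 <- suppressWarnings(nmds(Dn, n_dims = 2, n_starts = 5, seed = 3))
  dd <- as.dist(Dn); cf <- dist(ord2$points)
  o <- order(as.vector(dd))
  fit <- isoreg(as.vector(cf)[o])$yf
  stress1 <- sqrt(sum((as.vector(cf)[o] - fit)^2) / sum(cf^2))
  expect_equal(ord2$stress, stress1, tolerance = 1e-10)

  # determinism under a fixed seed
  ord3 <- suppressWarnings(nmds(Dn, n_dims = 2, n_starts = 5, seed = 3))
  expect_identical(ord2$points, ord3$points)
})

test_that("rotation to a reference axis is rigid and optimal", {
  set.seed(31)
  X <- matrix(rnorm(40), 20, 2)
  ord <- structure(list(points = X, method = "pcoa"),
                   class = "ordination_result")
  # reference = own first axis: nothing changes (up to sign)
  r1 <- rotate_to_reference(ord, X[, 1])
  expect_equal(abs(cor(r1$points[, 1], X[, 1])), 1, tolerance = 1e-10)
  # 90-degree rotated configuration: recovered up to sign
  R90 <- matrix(c(0, -1, 1, 0), 2)
  ordr <- structure(list(points = X %*% R90, method = "pcoa"),
                    class = "ordination_result")
  rec <- rotate_to_reference(ordr, X[, 1])
  expect_gt(abs(cor(rec$points[, 1], X[, 1])), 1 - 1e-10)
  # distances preserved; correlation at least as good as any grid angle
  ref <- rnorm(20)
  rot <- rotate_to_reference(ord, ref)
  expect_lt(max(abs(dist(rot$points) - dist(X))), 1e-10)
  grid_best <- max(vapply(seq(0, 2 * pi, length.out = 720), function(th) {
    cor(X[, 1] * cos(th) + X[, 2] * sin(th), ref)
  }, 0))
  expect_gte(cor(rot$points[, 1], ref) + 1e-6, grid_best)
})

test_that("collinearity filtering is a greedy pairwise-r pass", {
  set.seed(7)
  x1 <- rnorm(30); x2 <- rnorm(30)
  clim <- data.frame(v1 = x1, v2 = x1 + rnorm(30, sd = 0.05),
                     v3 = x2, v4 = 0.8 * x1 + 0.6 * x2)
  res <- decorrelate_variables(clim, threshold = 0.7)
  # brute-force check of the greedy rule
  retained <- character(0)
  for (v in names(clim)) {
    if (!length(retained) ||
        all(abs(cor(clim[[v]], clim[retained])) <= 0.7))
      retained <- c(retained, v)
  }
  expect_equal(res$retained, retained)
  expect_true("v2" %in% names(res$dropped))
  expect_warning(decorrelate_variables(cbind(clim, cst = 1)), "constant")
  # orthogonal variables all retained
  expect_equal(decorrelate_variables(data.frame(a = x1, b = x2))$retained,
               c("a", "b"))
})

test_that("fitted climate vectors: direction, r2, and permutation p", {
  set.seed(2)
  X <- matrix(rnorm(60), 30, 2)
  ord <- structure(list(points = X, method = "pcoa"),
                   class = "ordination_result")
  clim <- data.frame(ax1 = 2 * X[, 1] + 5)
  fv <- fit_climate_vectors(ord, clim, n_perm = 49, seed = 1)
  expect_equal(fv$r2, 1, tolerance = 1e-10)
  expect_equal(abs(fv$axis1), 1, tolerance = 1e-8)
  expect_equal(fv$axis2, 0, tolerance = 1e-6)

  # n = 6: exhaustive permutation p equals explicit enumeration via lm
  X6 <- matrix(rnorm(12), 6, 2)
  ord6 <- structure(list(points = X6, method = "pcoa"),
                    class = "ordination_result")
  y <- rnorm(6)
  fv6 <- fit_climate_vectors(ord6, data.frame(v = y), exact = TRUE)
  perms <- NULL
  for (i in 1:6) for (j in setdiff(1:6, i)) for (k in setdiff(1:6, c(i, j)))
    for (l in setdiff(1:6, c(i, j, k)))
      for (m in setdiff(1:6, c(i, j, k, l)))
        perms <- rbind(perms, c(i, j, k, l, m, setdiff(1:6, c(i, j, k, l, m))))
  r2s <- apply(perms, 1, function(p)
    summary(lm(scale(y[p]) ~ X6))$r.squared)
  r2obs <- summary(lm(scale(y) ~ X6))$r.squared
  expect_equal(fv6$p, mean(r2s >= r2obs - 1e-12))
  expect_equal(fv6$r2, r2obs, tolerance = 1e-10)
})

test_that("permutation test of vectors holds its type-I error", {
  set.seed(77)
  X <- matrix(rnorm(40), 20, 2)
  ord <- structure(list(points = X, method = "pcoa"),
                   class = "ordination_result")
  rej <- vapply(1:200, function(i) {
    fv <- fit_climate_vectors(ord, data.frame(v = rnorm(20)),
                              n_perm = 99, seed = i)
    fv$p < 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.11)
})
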