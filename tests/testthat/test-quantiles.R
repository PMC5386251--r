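test_that("quantile fits are exact on noiseless lines and at vertices", {
  x <- c(1:12); y <- 2 * x
  for (tau in c(0.1, 0.5, 0.9)) {
    f <- quantile_fit(y, x, tau)
    expect_equal(unname(f$coefficients), c(0, 2), tolerance = 1e-12)
    expect_equal(f$loss, 0, tolerance = 1e-12)
  }
  # vertex-enumeration oracle: optimal solutions interpolate >= 2 points
  set.seed(6)
  x <- rnorm(12); y <- 1 + x + rnorm(12)
  for (tau in c(0.25, 0.5, 0.8)) {
    f <- quantile_fit(y, x, tau)
    best <- Inf
    for (i in 1:11) for (j in (i + 1):12) {
      if (x[i] == x[j]) next
      b1 <- (y[j] - y[i]) / (x[j] - x[i]); b0 <- y[i] - b1 * x[i]
      best <- min(best, pinball_loss(y, x, b0, b1, tau))
    }
    expect_equal(f$loss, best, tolerance = 1e-12)
    expect_equal(pinball_loss(y, x, f$coefficients["b0"],
                              f$coefficients["b1"], tau),
                 f$loss, tolerance = 1e-12)
  }
  expect_error(quantile_fit(y, rep(1, 12), 0.5), "constant")
  expect_error(quantile_fit(y[1:5], x[1:5], 0.5), "at least 10")
})

test_that("the median fit agrees with an independent LAD optimizer", {
  set.seed(17)
  x <- rnorm(40); y <- 2 + 3 * x + rt(40, df = 3)
  f <- quantile_fit(y, x, 0.5)
  lad <- function(b) sum(abs(y - b[1] - b[2] * x))
  best <- Inf
  for (start in list(c(0, 0), c(2, 3), coef(lm(y ~ x)))) {
    o <- optim(start, lad, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
    best <- min(best, o$value)
  }
  # the exact fit can never beat the LAD optimum by construction, and the
  # two optimizers agree on the achieved objective
  expect_lte(2 * f$loss, best + 1e-9)               # rho_0.5(u) = |u|/2
  expect_equal(2 * f$loss, best, tolerance = 1e-4)
})

test_that("quantile fits are equivariant under affine changes", {
  set.seed(23)
  x <- rnorm(30); y <- 1 + 2 * x + rnorm(30)
  f <- quantile_fit(y, x, 0.7)
  fx <- quantile_fit(y, 10 * x, 0.7)
  expect_equal(fx$coefficients["b1"], f$coefficients["b1"] / 10,
               tolerance = 1e-10, ignore_attr = TRUE)
  fy <- quantile_fit(y + 5, x, 0.7)
  expect_equal(fy$coefficients["b0"], f$coefficients["b0"] + 5,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fy$coefficients["b1"], f$coefficients["b1"],
               tolerance = 1e-10, ignore_attr = TRUE)
  # pinball contract between quantile levels
  f9 <- quantile_fit(y, x, 0.9); f1 <- quantile_fit(y, x, 0.1)
  expect_lte(f9$loss,
             pinball_loss(y, x, f1$coefficients["b0"],
                          f1$coefficients["b1"], 0.9))
})

test_that("the quantile process composes standalone fits without smoothing", {
  set.seed(31)
  x <- rnorm(40); y <- 1 + 2 * x + rnorm(40)
  taus <- c(0.2, 0.5, 0.8)
  proc <- quantile_process(y, x, taus)
  for (i in seq_along(taus)) {
    f <- quantile_fit(y, x, taus[i])
    expect_equal(proc$b1[i], unname(f$coefficients["b1"]))
    expect_equal(proc$b0[i], unname(f$coefficients["b0"]))
  }
  # location-shift data: slope path flat, every slope within a few
  # bootstrap standard errors of the common generating slope
  set.seed(32)
  x2 <- rnorm(100); y2 <- 1 + 2 * x2 + rnorm(100)
  procb <- quantile_process(y2, x2, taus, B = 300, seed = 9)
  expect_true(all(abs(procb$b1 - 2) <= 4 * procb$b1_se))
})

test_that("bootstrap intervals are seeded and collapse on noiseless data", {
  set.seed(41)
  x <- rnorm(30); y <- 3 + 1.5 * x + rnorm(30)
  b1 <- bootstrap_qr(y, x, 0.5, B = 200, seed = 11)
  b2 <- bootstrap_qr(y, x, 0.5, B = 200, seed = 11)
  expect_identical(b1$ci, b2$ci)
  yline <- 3 + 1.5 * x
  b0 <- bootstrap_qr(yline, x, 0.5, B = 100, seed = 2)
  expect_lt(diff(b0$ci[, "b1"]), 1e-10)
  expect_error(bootstrap_qr(y, x, 0.5, B = 50, seed = 1), "B must")
})

# builds a quantile_process directly from closed-form conditional quantiles
process_from_quantiles <- function(b0_fun, b1, taus = seq(0.01, 0.99, 0.01)) {
  structure(data.frame(tau = taus, b0 = b0_fun(taus), b1 = b1,
                       loss = NA_real_),
            class = c("quantile_process", "data.frame"))
}

test_that("conditional densities recover the Normal closed form", {
  mu <- function(x) 1 + 2 * x
  sigma <- 1.5
  proc <- process_from_quantiles(function(t) 1 + sigma * qnorm(t), b1 = 2)
  for (x0 in c(-1, 0.5)) {
    de <- conditional_density(proc, x0)
    expect_false(attr(de, "rearranged"))
    central <- de$q > mu(x0) + sigma * qnorm(0.1) &
      de$q < mu(x0) + sigma * qnorm(0.9)
    rel_err <- abs(de$density - dnorm(de$q, mu(x0), sigma)) /
      dnorm(de$q, mu(x0), sigma)
    expect_lt(max(rel_err[central]), 0.05)
    # normalization: trapezoid integral close to the grid's tau mass
    integral <- sum(diff(de$q) * (head(de$density, -1) + de$density[-1]) / 2)
    expect_gt(integral, 0.95)
    expect_lt(integral, 1.05)
  }
  # location-shift process: densities at two x0 are horizontal translates
  d1 <- conditional_density(proc, 0)
  d2 <- conditional_density(proc, 1)
  expect_equal(d2$q - 2, d1$q, tolerance = 1e-10)
  expect_equal(d2$density, d1$density, tolerance = 1e-10)
})

test_that("quantile crossing is repaired by monotone rearrangement", {
  taus <- seq(0.01, 0.99, 0.01)
  b0 <- 1 + 1.5 * qnorm(taus)
  b1 <- rep(c(2, 1.9), length.out = length(taus))  # jittered slopes cross
  proc <- structure(data.frame(tau = taus, b0 = b0, b1 = b1,
                               loss = NA_real_),
                    class = c("quantile_process", "data.frame"))
  de <- conditional_density(proc, 10)
  expect_true(attr(de, "rearranged"))
  expect_true(all(de$density >= 0))
  expect_true(all(diff(de$q) > 0))
})

test_that("ANOVA on log alpha matches the two-group t identity and
           separates well-separated groups", {
  set.seed(3)
  alpha <- data.frame(site_id = paste0("s", 1:40),
                      alpha = exp(rnorm(40, rep(c(1, 2), each = 20), 0.5)))
  md <- site_metadata(data.frame(site_id = alpha$site_id,
                                 biome = rep(c("X", "Y"), each = 20)))
  res <- anova_log_alpha(alpha, md)
  tt <- t.test(log(alpha$alpha) ~ md$biome, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$df, c(1, 38))
  # letters: distinct groups get disjoint letters, identical ones share
  expect_false(res$letters["X"] == res$letters["Y"])
  set.seed(4)
  alpha3 <- data.frame(site_id = paste0("s", 1:60),
                       alpha = exp(rnorm(60, rep(c(0, 0, 3), each = 20), 0.4)))
  md3 <- site_metadata(data.frame(site_id = alpha3$site_id,
                                  biome = rep(c("X", "Y", "Z"), each = 20)))
  res3 <- anova_log_alpha(alpha3, md3)
  expect_true(grepl("a", res3$letters["X"]) && grepl("a", res3$letters["Y"]))
  expect_false(grepl(res3$letters["Z"], res3$letters["X"]))
  # undefined alphas are excluded with a count
  alpha$alpha[1] <- NA
  expect_message(res_na <- anova_log_alpha(alpha, md), "excluded")
  expect_equal(res_na$n_used, 39)
  expect_equal(res_na$n_excluded, 1)
})

test_that("the ANOVA holds its size under permuted labels", {
  set.seed(8)
  rej <- vapply(1:200, function(i) {
    alpha <- data.frame(site_id = paste0("s", 1:30),
                        alpha = exp(rnorm(30)))
    md <- site_metadata(data.frame(site_id = alpha$site_id,
                                   biome = sample(rep(c("X", "Y", "Z"), 10))))
    anova_log_alpha(alpha, md)$p < 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.11)
})

test_that("the paired t utility matches the hand formula", {
  a <- c(10, 12, 9, 14, 11); b <- c(8, 11, 9.5, 10, 10)
  res <- paired_t(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$mean_diff, mean(d))
  expect_error(paired_t(a, a), "zero variance")
  expect_error(paired_t(a, b[1:3]), "equal length")
  # shift recovery
  set.seed(5)
  x <- rnorm(60); y <- x + 2 + rnorm(60, sd = 0.3)
  expect_equal(paired_t(y, x)$mean_diff, 2, tolerance = 0.2)
})
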