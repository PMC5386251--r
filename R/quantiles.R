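# Quantile regression of diversity on climate: exact single-covariate fits,
# coefficient paths over the quantile process, xy-pair bootstrap,
# conditional densities by inverting the quantile process, ANOVA/Tukey on
# log alpha, and the paired dbh-sensitivity t-test.

drop_incomplete <- function(y, x) {
  keep <- is.finite(y) & is.finite(x)
  n_drop <- sum(!keep)
  if (n_drop) message(n_drop, " incomplete (y, x) pair(s) dropped")
  list(y = y[keep], x = x[keep], n = sum(keep))
}

#' Exact linear quantile regression (one covariate)
#'
#' Minimizes the pinball loss `sum(rho_tau(y - b0 - b1 x))`,
#' `rho_tau(u) = u (tau - 1[u < 0])`, exactly: an optimal solution
#' interpolates at least two data points, so all candidate lines through
#' point pairs are enumerated and scored (compiled; O(n^2) candidates).
#' Deterministic: among loss ties the first candidate in pair order wins.
#'
#' @param y response vector (n >= 10 after dropping incomplete pairs).
#' @param x covariate vector; must not be constant.
#' @param tau quantile level in (0, 1).
#' @return list of class `quantile_fit`: `tau`, `coefficients` (b0, b1),
#'   `loss`, `n`.
#' @export
quantile_fit <- function(y, x, tau) {
  d <- drop_incomplete(y, x)
  if (d$n < 10) stop("need at least 10 complete observations")
  if (var(d$x) == 0) stop("constant covariate: quantile fit undefined")
  fit <- qr_enumerate(d$y, d$x, tau)
  structure(list(tau = tau,
                 coefficients = c(b0 = unname(fit[1, "b0"]),
                                  b1 = unname(fit[1, "b1"])),
                 loss = unname(fit[1, "loss"]), n = d$n),
            class = "quantile_fit")
}

#' Pinball (check) loss of a candidate line
#' @param y,x data; `b0`, `b1` intercept and slope; `tau` quantile level.
#' @export
pinball_loss <- function(y, x, b0, b1, tau) {
  r <- y - b0 - b1 * x
  sum(r * (tau - (r < 0)))
}

#' Quantile-process coefficient path
#'
#' [quantile_fit()] at every tau on the grid; the tau-independent candidate
#' scoring makes the whole path barely more expensive than a single fit. No
#' smoothing is applied across taus. Optional percentile bootstrap bands
#' resample (y, x) pairs once per replicate and refit the entire path.
#'
#' @inheritParams quantile_fit
#' @param taus strictly increasing grid within (0, 1); default
#'   `seq(0.01, 0.99, by = 0.01)`.
#' @param B bootstrap replicates for bands (0 = none).
#' @param seed RNG seed, required when `B > 0`.
#' @return data.frame of class `quantile_process`: tau, b0, b1, loss, and
#'   when bootstrapped b0_lo/b0_hi/b1_lo/b1_hi (percentile 95% bands) and
#'   b0_se/b1_se.
#' @export
quantile_process <- function(y, x, taus = seq(0.01, 0.99, by = 0.01),
                             B = 0, seed = NULL) {
  if (any(diff(taus) <= 0) || any(taus <= 0 | taus >= 1))
    stop("taus must be strictly increasing within (0, 1)")
  d <- drop_incomplete(y, x)
  if (d$n < 10) stop("need at least 10 complete observations")
  if (var(d$x) == 0) stop("constant covariate")
  fit <- qr_enumerate(d$y, d$x, taus)
  out <- data.frame(tau = taus, b0 = fit[, "b0"], b1 = fit[, "b1"],
                    loss = fit[, "loss"])
  if (B > 0) {
    if (is.null(seed)) stop("seed required for bootstrap bands")
    set.seed(seed)
    b0s <- b1s <- matrix(NA_real_, B, length(taus))
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(d$n, replace = TRUE)
        if (var(d$x[idx]) > 0) break
      }
      fb <- qr_enumerate(d$y[idx], d$x[idx], taus)
      b0s[b, ] <- fb[, "b0"]; b1s[b, ] <- fb[, "b1"]
    }
    out$b0_se <- apply(b0s, 2, sd); out$b1_se <- apply(b1s, 2, sd)
    out$b0_lo <- apply(b0s, 2, quantile, 0.025)
    out$b0_hi <- apply(b0s, 2, quantile, 0.975)
    out$b1_lo <- apply(b1s, 2, quantile, 0.025)
    out$b1_hi <- apply(b1s, 2, quantile, 0.975)
  }
  structure(out, class = c("quantile_process", "data.frame"), n = d$n)
}

#' xy-pair bootstrap of a quantile fit
#'
#' Resamples (y, x) pairs with replacement `B` times, refitting exactly
#' each time (compiled); degenerate resamples with a constant covariate are
#' redrawn and counted. Returns per-coefficient standard deviations and
#' 2.5/97.5 percentile confidence intervals.
#'
#' @inheritParams quantile_fit
#' @param B replicates (>= 100).
#' @param seed RNG seed (required).
#' @param return_draws also return the B x 2 coefficient draws.
#' @return list of class `qr_bootstrap`: `se`, `ci` (2 x 2 matrix), `B`,
#'   `n_redrawn`, optionally `draws`.
#' @export
bootstrap_qr <- function(y, x, tau, B = 1000, seed, return_draws = FALSE) {
  if (missing(seed)) stop("seed is required for bootstrap_qr()")
  if (B < 100) stop("B must be >= 100")
  d <- drop_incomplete(y, x)
  if (var(d$x) == 0) stop("constant covariate")
  set.seed(seed)
  draws <- qr_pair_bootstrap(d$y, d$x, tau, as.integer(B))
  ci <- apply(draws, 2, quantile, c(0.025, 0.975))
  out <- list(se = apply(draws, 2, sd), ci = ci, B = B,
              n_redrawn = attr(draws, "n_redrawn"))
  if (return_draws) out$draws <- draws
  structure(out, class = "qr_bootstrap")
}

#' Conditional density from a quantile process
#'
#' Evaluates the fitted conditional quantile function
#' `Q(tau | x0) = b0(tau) + b1(tau) x0` on the process grid, applies
#' monotone rearrangement (sorting) if quantile crossing is detected, and
#' differentiates: the density at the midpoint of adjacent grid quantiles
#' is `dtau / dQ`. Midpoints with zero dQ are skipped with a warning.
#'
#' @param proc a `quantile_process` (a fine grid, e.g. 0.01..0.99, gives a
#'   usable density).
#' @param x0 covariate value at which to condition.
#' @return data.frame of class `density_estimate`: `q` (response grid
#'   midpoints), `density`; attributes `x0`, `rearranged`.
#' @export
conditional_density <- function(proc, x0) {
  stopifnot(inherits(proc, "quantile_process"))
  Q <- proc$b0 + proc$b1 * x0
  rearranged <- is.unsorted(Q)
  if (rearranged) Q <- sort(Q)
  dQ <- diff(Q)
  dtau <- diff(proc$tau)
  keep <- dQ > 0
  if (any(!keep)) warning(sum(!keep), " zero-width quantile step(s) skipped")
  structure(data.frame(q = ((Q[-length(Q)] + Q[-1]) / 2)[keep],
                       density = (dtau / dQ)[keep]),
            class = c("density_estimate", "data.frame"),
            x0 = x0, rearranged = rearranged)
}

# greedy insert-absorb compact letter display from a logical
# "significantly different" matrix
compact_letters <- function(sig) {
  groups <- rownames(sig)
  sets <- list(groups)
  for (i in seq_along(groups)) for (j in seq_along(groups)) {
    if (j <= i || !sig[i, j]) next
    for (k in rev(seq_along(sets))) {
      s <- sets[[k]]
      if (all(c(groups[i], groups[j]) %in% s)) {
        sets[[k]] <- setdiff(s, groups[i])
        sets <- c(sets, list(setdiff(s, groups[j])))
      }
    }
    # absorb sets contained in another
    keep <- !vapply(seq_along(sets), function(k)
      any(vapply(seq_along(sets), function(l)
        l != k && all(sets[[k]] %in% sets[[l]]), TRUE)), TRUE)
    sets <- sets[keep]
  }
  sets <- sets[order(vapply(sets, function(s) min(match(s, groups)), 0))]
  letters_of <- vapply(groups, function(g)
    paste(letters[which(vapply(sets, function(s) g %in% s, TRUE))],
          collapse = ""), character(1))
  letters_of
}

#' One-way ANOVA with Tukey HSD on (log) Fisher's alpha
#'
#' Compares mean log alpha among biomes: fixed-effects one-way ANOVA,
#' Tukey-Kramer all-pairs comparisons (valid for unequal group sizes), and
#' a compact letter display (groups sharing no letter differ at the
#' family-wise level). Sites with undefined alpha (S = N) are excluded and
#' counted.
#'
#' @param alpha a `alpha_records` data.frame (or any with `site_id` and
#'   `alpha`).
#' @param metadata a `site_metadata` supplying biome labels.
#' @param log_response compare natural-log alpha (default) or raw alpha.
#' @param conf_level family-wise confidence level for Tukey.
#' @return list of class `anova_tukey`: `F`, `df`, `p`, `n_used`,
#'   `n_excluded`, `group_means`, `tukey` (pairwise table), `letters`.
#' @export
anova_log_alpha <- function(alpha, metadata, log_response = TRUE,
                            conf_level = 0.95) {
  lab <- biome_of(alpha$site_id, metadata)
  ok <- is.finite(alpha$alpha)
  n_excl <- sum(!ok)
  if (n_excl) message(n_excl, " site(s) with undefined alpha excluded")
  y <- if (log_response) log(alpha$alpha[ok]) else alpha$alpha[ok]
  g <- factor(lab[ok])
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs n >= 2")
  fit <- aov(y ~ g)
  av <- summary(fit)[[1]]
  tk <- TukeyHSD(fit, conf.level = conf_level)$g
  lev <- levels(g)
  sig <- matrix(FALSE, nlevels(g), nlevels(g), dimnames = list(lev, lev))
  pr <- stats::setNames(tk[, "p adj"], rownames(tk))
  for (nm in rownames(tk)) {
    pair <- strsplit(nm, "-", fixed = TRUE)[[1]]
    sig[pair[1], pair[2]] <- sig[pair[2], pair[1]] <- pr[nm] <
      (1 - conf_level)
  }
  structure(list(F = av[1, "F value"], df = c(av[1, "Df"], av[2, "Df"]),
                 p = av[1, "Pr(>F)"], n_used = length(y),
                 n_excluded = n_excl,
                 group_means = tapply(y, g, mean),
                 tukey = tk, letters = compact_letters(sig)),
            class = "anova_tukey")
}

#' Paired t-test utility
#'
#' Classical paired t on the differences `a - b`; used for sensitivity
#' analyses such as comparing site diversity under two dbh cutoffs.
#'
#' @param a,b paired numeric vectors of equal length (>= 2).
#' @return list: `mean_diff`, `t`, `df`, `p` (two-sided).
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 2) stop("need at least 2 pairs")
  if (var(a - b) == 0) stop("zero variance of differences: t undefined")
  tt <- t.test(a, b, paired = TRUE)
  list(mean_diff = unname(tt$estimate), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value)
}
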