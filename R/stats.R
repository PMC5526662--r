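#' Group-level t and z maps of a paired contrast
#'
#' Per pixel: one-sample t over subjects of the paired differences
#' `A - B`, and `z = probit(1 - p/2) * sign(t)` from the two-sided
#' t p-value -- the z-score whose tail probability matches the t test's.
#' Pixels with zero across-subject variance get a guarded `|z|` of 37
#' and are reported in `degenerate`.
#'
#' @param a,b 3-D `subject x freq x time` arrays (or `subject x pixel`
#'   matrices) on identical grids; `b` may be 0 for an against-zero test.
#' @return list with `t`, `z` (matrices or vectors matching the input
#'   pixel grid), `df` and `degenerate` (logical map).
#' @export
group_z_map <- function(a, b = 0) {
  d <- a - b
  dm <- if (length(dim(d)) == 3)
    matrix(d, nrow = dim(d)[1]) else as.matrix(d)
  n <- nrow(dm)
  if (n < 2) stop("need at least two subjects", call. = FALSE)
  m <- colMeans(dm)
  s <- sqrt(colSums(sweep(dm, 2, m)^2) / (n - 1))
  t_stat <- ifelse(s > 0, m / (s / sqrt(n)),
                   ifelse(m == 0, 0, sign(m) * Inf))
  p_half <- pt(-abs(t_stat), df = n - 1)
  z <- -qnorm(pmax(p_half, 1e-300)) * sign(t_stat)
  z[t_stat == 0] <- 0
  degenerate <- s == 0 & m != 0
  z[degenerate] <- sign(m[degenerate]) * 37
  reshape_like <- function(v) {
    if (length(dim(d)) == 3) matrix(v, dim(d)[2], dim(d)[3]) else v
  }
  list(t = reshape_like(t_stat), z = reshape_like(z), df = n - 1,
       degenerate = reshape_like(degenerate))
}

#' Cluster-based permutation test on subject difference maps
#'
#' Pixels whose |z| exceeds the two-sided pre-cluster threshold form
#' 4-connected clusters (positive and negative separately); each
#' cluster's mass is its summed z. The null distribution collects, per
#' permutation of subject-level sign flips (each pair kept, order of
#' subtraction randomized), the single largest absolute cluster mass;
#' a cluster is significant when its |mass| exceeds the null's
#' `1 - alpha` quantile. `p = (1 + #{null >= |mass|}) / (n_perm + 1)`.
#'
#' @param diffs 3-D `subject x freq x time` array of paired differences.
#' @param n_perm number of permutations (default 2000; < 100 warns).
#' @param threshold_p two-sided pre-cluster threshold (default 0.05).
#' @param alpha cluster significance level (default 0.05).
#' @param seed integer seed for the sign flips.
#' @return object of class `cluster_result`: `clusters` (list of `mask`,
#'   `mass`, `sign`, `p_perm`), `sig_mask`, `z`, `null_max`, plus the
#'   test parameters.
#' @export
cluster_permutation <- function(diffs, n_perm = 2000, threshold_p = 0.05,
                                alpha = 0.05, seed = 1) {
  if (n_perm < 100) warning("n_perm < 100 gives coarse p-values")
  gz <- group_z_map(diffs)
  z <- gz$z
  zthr <- qnorm(1 - threshold_p / 2)
  lab <- cpp_label_clusters(z, zthr)
  n_pos <- length(lab$pos_mass)
  masses <- c(lab$pos_mass, lab$neg_mass)
  signs <- c(rep(1, n_pos), rep(-1, length(lab$neg_mass)))
  dm <- matrix(diffs, nrow = dim(diffs)[1])
  tthr <- stats::qt(1 - threshold_p / 2, df = dim(diffs)[1] - 1)
  set.seed(seed)
  null_max <- cpp_perm_null(dm, nrow(z), ncol(z), zthr, tthr, n_perm)
  clusters <- lapply(seq_along(masses), function(i) {
    list(mask = lab$labels == i, mass = masses[i], sign = signs[i],
         p_perm = (1 + sum(null_max >= abs(masses[i]))) / (n_perm + 1))
  })
  sig_mask <- matrix(FALSE, nrow(z), ncol(z))
  crit <- quantile(null_max, 1 - alpha, names = FALSE)
  for (cl in clusters)
    if (cl$p_perm <= alpha) sig_mask <- sig_mask | cl$mask
  structure(list(clusters = clusters, sig_mask = sig_mask, z = z,
                 t = gz$t, null_max = null_max, null_crit = crit,
                 threshold_p = threshold_p, n_perm = n_perm,
                 alpha = alpha, seed = seed),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  n_sig <- sum(vapply(x$clusters, function(cl) cl$p_perm <= x$alpha,
                      logical(1)))
  cat(sprintf(
    "<cluster_result> %d cluster(s), %d significant at alpha=%.2f (%d permutations)\n",
    length(x$clusters), n_sig, x$alpha, x$n_perm))
  for (cl in x$clusters)
    cat(sprintf("  sign %+d  mass %8.1f  p = %.4f\n", cl$sign, cl$mass,
                cl$p_perm))
  invisible(x)
}

#' Cluster permutation on 1-D band time courses
#'
#' Same procedure as [cluster_permutation()] with 1-D adjacency
#' (neighboring time samples).
#'
#' @param diffs `subject x time` matrix of paired differences.
#' @inheritParams cluster_permutation
#' @return a `cluster_result` whose masks are vectors over time.
#' @export
cluster_permutation_1d <- function(diffs, n_perm = 2000,
                                   threshold_p = 0.05, alpha = 0.05,
                                   seed = 1) {
  arr <- array(diffs, c(nrow(diffs), 1, ncol(diffs)))
  res <- cluster_permutation(arr, n_perm, threshold_p, alpha, seed)
  res$clusters <- lapply(res$clusters, function(cl) {
    cl$mask <- as.vector(cl$mask); cl
  })
  res$sig_mask <- as.vector(res$sig_mask)
  res$z <- as.vector(res$z)
  res
}

#' Spearman correlation with a percentile bootstrap CI
#'
#' Rank correlation (average ranks for ties) with a 95% percentile
#' bootstrap confidence interval over paired resamples.
#'
#' @param x,y paired numeric vectors (n >= 5).
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return list with `rho`, `ci` (length 2) and `n`. Constant `x` or `y`
#'   yields `rho = NA`.
#' @export
spearman_bootstrap <- function(x, y, n_boot = 2000, seed = 1,
                               conf = 0.95) {
  stopifnot(length(x) == length(y))
  if (length(x) < 5) stop("need at least 5 pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, ci = c(NA_real_, NA_real_),
                n = length(x)))
  rho <- cor(x, y, method = "spearman")
  set.seed(seed)
  boots <- cpp_spearman_boot(x, y, n_boot)
  boots <- boots[is.finite(boots)]
  al <- (1 - conf) / 2
  ci <- if (length(boots)) quantile(boots, c(al, 1 - al), names = FALSE)
  else c(NA_real_, NA_real_)
  list(rho = rho, ci = ci, n = length(x))
}

#' Fisher-z group test of per-subject correlations
#'
#' Transforms each subject's rho with `atanh` (variance stabilizing) and
#' runs a two-sided one-sample t-test against zero. Subjects with
#' `|rho| = 1` (infinite z) are excluded with a warning.
#'
#' @param rhos numeric vector of per-subject correlation coefficients.
#' @return list with `t`, `p`, `ci` (CI of the mean Fisher z), `mean_z`
#'   and `n_used`.
#' @export
fisherz_group_test <- function(rhos) {
  keep <- is.finite(rhos) & abs(rhos) < 1
  if (any(!keep, na.rm = TRUE))
    warning(sum(!keep), " subject(s) with |rho| >= 1 or missing excluded")
  z <- atanh(rhos[keep])
  if (length(z) < 2) stop("need at least two usable subjects",
                          call. = FALSE)
  if (sd(z) == 0) {
    t_val <- if (mean(z) == 0) 0 else sign(mean(z)) * Inf
    return(list(t = t_val, p = if (t_val == 0) 1 else 0,
                ci = rep(mean(z), 2), mean_z = mean(z),
                n_used = length(z)))
  }
  tt <- t.test(z)
  list(t = unname(tt$statistic), p = tt$p.value,
       ci = unname(tt$conf.int), mean_z = mean(z), n_used = length(z))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1), delegating to the
#' standard implementation.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Maximum extent-power correlation in a time-frequency window
#'
#' Spearman rho between trial-wise movement extent and power at every
#' pixel inside the band and time window; returns the extremum by |rho|
#' with its location and a bootstrap CI at that pixel (the per-subject
#' search mirrors the idea that optimal frequencies and latencies differ
#' across subjects).
#'
#' @param trial_power 3-D `trial x freq x time` array (attributes
#'   `freqs`, `times` as from [epoch_tf()]).
#' @param extents trial-wise movement extents (percent).
#' @param band frequency search band, Hz (default `c(60, 90)`).
#' @param window time search window, s (default `c(0, 0.156)`).
#' @param n_boot,seed bootstrap settings for the CI.
#' @return list with `rho`, `freq`, `time`, `ci`; `rho = NA` when the
#'   extents are constant.
#' @export
max_corr_search <- function(trial_power, extents, band = c(60, 90),
                            window = c(0, 0.156), n_boot = 2000,
                            seed = 1) {
  if (dim(trial_power)[1] < 5) stop("need at least 5 trials",
                                    call. = FALSE)
  freqs <- attr(trial_power, "freqs")
  times <- attr(trial_power, "times")
  fs <- which(freqs >= band[1] & freqs <= band[2])
  ts <- which(times >= window[1] & times <= window[2])
  if (!length(fs) || !length(ts))
    stop("no pixels inside the search window", call. = FALSE)
  if (sd(extents) == 0)
    return(list(rho = NA_real_, freq = NA_real_, time = NA_real_,
                ci = c(NA_real_, NA_real_)))
  best <- list(rho = 0, freq = NA_real_, time = NA_real_, px = NULL)
  for (f in fs) for (tt in ts) {
    r <- suppressWarnings(cor(extents, trial_power[, f, tt],
                              method = "spearman"))
    if (is.finite(r) && abs(r) >= abs(best$rho))
      best <- list(rho = r, freq = freqs[f], time = times[tt],
                   px = trial_power[, f, tt])
  }
  ci <- spearman_bootstrap(extents, best$px, n_boot = n_boot,
                           seed = seed)$ci
  list(rho = best$rho, freq = best$freq, time = best$time, ci = ci)
}

#' Paired comparison with a normality-guarded test choice
#'
#' Lilliefors test on the paired differences decides between the paired
#' t-test (normality not rejected at 0.05) and the Wilcoxon signed-rank
#' test (exact for n <= 15). All-zero differences return p = 1 with a
#' degenerate flag.
#'
#' @param a,b paired numeric vectors (n >= 5).
#' @return list with `statistic`, `p`, `test_used`
#'   (`"t"`/`"wilcoxon"`/`"degenerate"`) and `normality_p`.
#' @export
paired_test <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 5)
  d <- a - b
  if (all(d == 0))
    return(list(statistic = NA_real_, p = 1, test_used = "degenerate",
                normality_p = NA_real_))
  norm_p <- tryCatch(nortest::lillie.test(d)$p.value,
                     error = function(e) NA_real_)
  if (!is.na(norm_p) && norm_p < 0.05) {
    exact <- length(d) <= 15 && !any(d == 0) &&
      !anyDuplicated(abs(d[d != 0]))
    wt <- wilcox.test(a, b, paired = TRUE, exact = exact)
    list(statistic = unname(wt$statistic), p = wt$p.value,
         test_used = "wilcoxon", normality_p = norm_p)
  } else {
    tt <- t.test(a, b, paired = TRUE)
    list(statistic = unname(tt$statistic), p = tt$p.value,
         test_used = "t", normality_p = norm_p)
  }
}
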