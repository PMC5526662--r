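test_that("group z map matches hand-computed paired t-statistics", {
  # differences {1,2,3}: mean 2, sd 1, t = 2 / (1 / sqrt(3)) = 2*sqrt(3)
  a <- array(0, c(3, 1, 1)); a[, 1, 1] <- c(1, 2, 3)
  gz <- group_z_map(a)
  expect_equal(gz$t[1, 1], 2 * sqrt(3), tolerance = 1e-12)
  p2 <- 2 * pt(-2 * sqrt(3), df = 2)
  expect_equal(gz$z[1, 1], qnorm(1 - p2 / 2), tolerance = 1e-12)
  # A = B: t and z are identically zero
  b <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  gz0 <- group_z_map(b, b)
  expect_true(all(gz0$t == 0) && all(gz0$z == 0))
  # sign flipping negates t and z
  gzn <- group_z_map(-a)
  expect_equal(gzn$t, -gz$t)
  expect_equal(gzn$z, -gz$z)
})

test_that("cluster labeling uses 4-connectivity with signed clusters", {
  z <- matrix(0, 5, 5)
  z[1:2, 1:2] <- 3      # positive block
  z[4:5, 4:5] <- -3     # negative block
  z[1, 5] <- 3          # isolated pixel (diagonal must not connect)
  lab <- cpp_label_clusters(z, qnorm(0.975))
  expect_length(lab$pos_mass, 2)
  expect_length(lab$neg_mass, 1)
  expect_equal(sort(lab$pos_mass), c(3, 12))
  expect_equal(lab$neg_mass, -12)
})

test_that("all-zero differences give an empty cluster result", {
  d <- array(0, c(5, 6, 7))
  res <- cluster_permutation(d, n_perm = 200, seed = 4)
  expect_length(res$clusters, 0)
  expect_false(any(res$sig_mask))
})

test_that("an injected block effect is detected as a positive cluster", {
  set.seed(30)
  found <- 0
  for (rep in 1:5) {
    d <- array(rnorm(9 * 20 * 30), c(9, 20, 30))
    d[, 6:10, 11:20] <- d[, 6:10, 11:20] + 2   # Cohen's d = 2 block
    res <- cluster_permutation(d, n_perm = 500, seed = rep)
    sig_pos <- Filter(function(cl) cl$sign > 0 && cl$p_perm <= 0.05,
                      res$clusters)
    overlap <- any(vapply(sig_pos, function(cl)
      any(cl$mask[6:10, 11:20]), logical(1)))
    if (overlap) found <- found + 1
  }
  expect_gte(found, 4)
})

test_that("permutation p-values respect the finite lower bound and determinism", {
  set.seed(31)
  d <- array(rnorm(6 * 8 * 8), c(6, 8, 8))
  d[, 1:4, 1:4] <- d[, 1:4, 1:4] + 3
  r1 <- cluster_permutation(d, n_perm = 300, seed = 9)
  r2 <- cluster_permutation(d, n_perm = 300, seed = 9)
  expect_identical(r1$null_max, r2$null_max)
  ps <- vapply(r1$clusters, `[[`, numeric(1), "p_perm")
  expect_true(all(ps >= 1 / 301))
  # relabeling (A,B) -> (B,A) flips cluster signs, same masses
  r3 <- cluster_permutation(-d, n_perm = 300, seed = 9)
  expect_equal(sort(abs(vapply(r3$clusters, `[[`, numeric(1), "mass"))),
               sort(abs(vapply(r1$clusters, `[[`, numeric(1), "mass"))))
})

test_that("1-D cluster permutation finds a step effect", {
  set.seed(32)
  d <- matrix(rnorm(9 * 60), 9, 60)
  d[, 31:60] <- d[, 31:60] + 2
  res <- cluster_permutation_1d(d, n_perm = 500, seed = 2)
  sig <- Filter(function(cl) cl$p_perm <= 0.05 && cl$sign > 0,
                res$clusters)
  expect_gte(length(sig), 1)
  span <- which(Reduce(`|`, lapply(sig, `[[`, "mask")))
  expect_gt(mean(span > 30), 0.8)
  empty <- cluster_permutation_1d(matrix(0, 5, 40), n_perm = 100,
                                  seed = 1)
  expect_length(empty$clusters, 0)
})

test_that("permutation p-values are near-uniform under the null", {
  set.seed(33)
  min_ps <- replicate(60, {
    d <- array(rnorm(8 * 10 * 12), c(8, 10, 12))
    res <- cluster_permutation(d, n_perm = 200, seed = sample.int(1e6, 1))
    ps <- vapply(res$clusters, `[[`, numeric(1), "p_perm")
    if (length(ps)) min(ps) else 1
  })
  # family-wise error at alpha = 0.05 should be roughly nominal
  expect_lt(mean(min_ps <= 0.05), 0.18)
})

test_that("spearman bootstrap hits the exact endpoints", {
  x <- 1:10
  r1 <- spearman_bootstrap(x, x^3, n_boot = 200, seed = 1)
  expect_equal(r1$rho, 1)
  expect_equal(r1$ci, c(1, 1))
  r2 <- spearman_bootstrap(x, -x, n_boot = 200, seed = 1)
  expect_equal(r2$rho, -1)
  expect_true(is.na(spearman_bootstrap(rep(1, 10), rnorm(10))$rho))
  expect_error(spearman_bootstrap(1:3, 1:3), "at least 5")
})

test_that("bootstrap resampler is seed-deterministic", {
  x <- rnorm(30); y <- rnorm(30)
  a <- spearman_bootstrap(x, y, n_boot = 500, seed = 7)
  b <- spearman_bootstrap(x, y, n_boot = 500, seed = 7)
  expect_identical(a$ci, b$ci)
})

test_that("Fisher-z group test behaves at its fixed points", {
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  r0 <- fisherz_group_test(rep(0, 6))
  expect_equal(r0$t, 0); expect_equal(r0$p, 1)
  rs <- fisherz_group_test(c(-0.4, 0.4, -0.2, 0.2))
  expect_equal(rs$t, 0, tolerance = 1e-12)
  expect_warning(rp <- fisherz_group_test(c(1, 0.3, 0.4, 0.5)),
                 "excluded")
  expect_equal(rp$n_used, 3)
})

test_that("BH adjustment is monotone and dominates the raw p-values", {
  set.seed(34)
  p <- runif(20)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= -1e-12))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(0.5, 6)), rep(0.5, 6))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("max-correlation search localizes a constructed coupling", {
  set.seed(35)
  n_tr <- 40
  ext <- runif(n_tr, 0, 100)
  arr <- array(rnorm(n_tr * 6 * 10, sd = 0.3), c(n_tr, 6, 10))
  attr(arr, "freqs") <- seq(61, 91, by = 6)
  attr(arr, "times") <- seq(0, 0.18, by = 0.02)
  arr[, 3, 4] <- arr[, 3, 4] - 0.03 * ext   # 73 Hz, 60 ms, negative
  res <- max_corr_search(arr, ext, band = c(60, 90), window = c(0, 0.156))
  expect_lt(res$rho, -0.8)
  expect_equal(res$freq, 73)
  expect_equal(res$time, 0.06)
  expect_true(is.na(max_corr_search(arr, rep(5, n_tr))$rho))
  # single in-window pixel returns that pixel's correlation
  one <- max_corr_search(arr, ext, band = c(72, 74),
                         window = c(0.055, 0.065))
  expect_equal(one$rho, cor(ext, arr[, 3, 4], method = "spearman"))
})

test_that("paired test switches branches on normality", {
  a <- rnorm(12, sd = 1)
  r_eq <- paired_test(a, a)
  expect_equal(r_eq$p, 1)
  expect_identical(r_eq$test_used, "degenerate")
  set.seed(36)
  base <- rnorm(14)
  skew <- base + c(runif(11, 0.005, 0.02), 40, 60, 90)  # heavy-tailed
  r_sk <- paired_test(skew, base)
  expect_identical(r_sk$test_used, "wilcoxon")
  norm_shift <- base + 2 + rnorm(14, sd = 0.5)
  r_n <- paired_test(norm_shift, base)
  expect_identical(r_n$test_used, "t")
  expect_lt(r_n$p, 0.05)
})
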