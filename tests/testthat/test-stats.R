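mk_fc <- function(m, ids = as.character(seq_len(nrow(m)))) {
  diag(m) <- NA
  dimnames(m) <- list(ids, ids)
  structure(m, class = c("fc_matrix", "matrix"), parcel_ids = ids)
}

test_that("delta_fc is elementwise subtraction with parcel checks", {
  set.seed(3)
  a <- matrix(rnorm(16), 4); a <- (a + t(a)) / 2
  b <- matrix(rnorm(16), 4); b <- (b + t(b)) / 2
  d <- delta_fc(mk_fc(a), mk_fc(b))
  expect_equal(unclass(d)[upper.tri(d)], (b - a)[upper.tri(a)])
  expect_true(all(unclass(delta_fc(mk_fc(a), mk_fc(a))) == 0, na.rm = TRUE))
  shifted <- mk_fc(a + 0.3)
  expect_true(all(abs(unclass(delta_fc(mk_fc(a), shifted)) - 0.3) < 1e-12,
                  na.rm = TRUE))
  expect_error(delta_fc(mk_fc(a), mk_fc(b, ids = c("p1", "p2", "p3", "p4"))),
               "parcel mismatch")
})

test_that("BH step-up matches the hand oracle and p.adjust", {
  # spec example at alpha = 0.05
  p <- c(0.001, 0.008, 0.039, 0.041)
  res <- fdr_bh(p, alpha = 0.05)
  expect_identical(fdr_bh(p, 0.05)$q_values < 0.05, oracle_bh_reject(p, 0.05))
  expect_equal(res$q_values, stats::p.adjust(p, "BH"))
  # boundary cases
  expect_true(fdr_bh(0.005, 0.01)$significant)
  all1 <- fdr_bh(rep(1, 10), 0.01)
  expect_true(all(all1$q_values == 1) && !any(all1$significant))
  expect_error(fdr_bh(numeric(0)), "empty")
  expect_error(fdr_bh(c(0.5, 0)), "0, 1")
  # random vectors against the library oracle
  set.seed(7)
  for (i in 1:10) {
    pv <- runif(sample(3:50, 1))
    expect_equal(fdr_bh(pv, 0.05)$q_values, stats::p.adjust(pv, "BH"))
  }
})

test_that("exact enumeration gives the analytic minimum p", {
  # 3 vs 3, maximal separation: only identity and complement reach |T_obs|,
  # so two-tailed p = 2/20 = 1/10
  y <- matrix(c(10, 11, 12, 0, 1, 2), ncol = 1, dimnames = list(NULL, "e"))
  res <- permutation_edge_test(y, factor(rep(c("a", "b"), each = 3),
                                         levels = c("a", "b")),
                               n_perm = 100, exact = TRUE, alpha = 0.05)
  expect_equal(res$p_perm, 0.1)
  expect_equal(res$observed_stat, 10)
  expect_identical(res$direction, "hyper")
})

test_that("group ordering follows factor levels and direction is signed", {
  y <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1, dimnames = list(NULL, "e"))
  g <- factor(rep(c("low", "high"), each = 3), levels = c("high", "low"))
  res <- permutation_edge_test(y[c(4:6, 1:3), , drop = FALSE],
                               factor(rep(c("high", "low"), each = 3),
                                      levels = c("high", "low")),
                               exact = TRUE, n_perm = 100)
  expect_gt(res$observed_stat, 0)
  expect_identical(res$direction, "hyper")
})

test_that("permutation p is reproducible and invariant to subject order", {
  set.seed(10)
  n <- 12
  y <- matrix(rnorm(n * 30), n, dimnames = list(NULL, paste0("e", 1:30)))
  g <- factor(rep(c("a", "b"), each = 6), levels = c("a", "b"))
  r1 <- permutation_edge_test(y, g, n_perm = 500, seed = 9, exact = FALSE)
  r2 <- permutation_edge_test(y, g, n_perm = 500, seed = 9, exact = FALSE)
  expect_identical(r1$p_perm, r2$p_perm)
  expect_true(all(r1$p_perm >= 1 / 501))
  perm <- sample(n)
  r3 <- permutation_edge_test(y[perm, ], g[perm], n_perm = 500, seed = 9,
                              exact = FALSE)
  # same exchangeable null; exact equality holds for the exact mode
  e1 <- permutation_edge_test(y, g, exact = TRUE, n_perm = 100)
  e3 <- permutation_edge_test(y[perm, ], g[perm], exact = TRUE, n_perm = 100)
  expect_equal(e1$p_perm, e3$p_perm)
  expect_equal(e1$observed_stat, e3$observed_stat)
})

test_that("covariate handling: constant dropped, missing rejected, size checks", {
  y <- matrix(rnorm(12 * 3), 12, dimnames = list(NULL, c("a", "b", "c")))
  g <- rep(c("x", "y"), each = 6)
  expect_warning(permutation_edge_test(y, g, covariate = rep(2, 12),
                                       n_perm = 200), "constant covariate")
  expect_error(permutation_edge_test(y, g, covariate = c(NA, rnorm(11)),
                                     n_perm = 200), "missing")
  expect_error(permutation_edge_test(y, rep(c("x", "y"), c(11, 1)),
                                     n_perm = 200), ">= 2")
  expect_error(permutation_edge_test(y, g, n_perm = 50), ">= 100")
})

test_that("null p-values are approximately uniform (KS)", {
  set.seed(30)
  n <- 14
  y <- matrix(rnorm(n * 400), n, dimnames = list(NULL, paste0("e", 1:400)))
  g <- rep(c("a", "b"), each = 7)
  res <- permutation_edge_test(y, g, n_perm = 499, seed = 2, exact = FALSE)
  ks <- suppressWarnings(stats::ks.test(res$p_perm, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("covariate adjustment removes a pure-confound group difference", {
  set.seed(41)
  n1 <- 9; n2 <- 9; m <- 200
  apnea <- c(rnorm(n1, 7.5, 0.8), rnorm(n2, 10.5, 0.8))
  g <- rep(c("veh", "trt"), c(n1, n2))
  y <- 0.4 * apnea + matrix(rnorm((n1 + n2) * m), n1 + n2, m)
  colnames(y) <- paste0("e", 1:m)
  adj <- permutation_edge_test(y, g, covariate = apnea, n_perm = 300,
                               seed = 5, exact = FALSE, alpha = 0.05)
  rate_adj <- mean(adj$p_perm < 0.05)
  expect_lt(abs(rate_adj - 0.05), 0.05)
  # without adjustment the confound drives rejections far above alpha
  raw <- permutation_edge_test(y, g, n_perm = 300, seed = 5, exact = FALSE)
  expect_gt(mean(raw$p_perm < 0.05), 0.5)
})

test_that("volume comparisons: null high p, disjoint supports at the floor", {
  set.seed(12)
  v_null <- rep(c(3, 3, 3, 3, 3), 2) + rep(0, 10)
  res <- volume_group_test(rep(5, 10), rep(c("a", "b"), each = 5))
  expect_gte(res$a_vs_b$p, 0.5)
  v <- c(1:5, 101:105)
  res2 <- volume_group_test(v, rep(c("a", "b"), each = 5))
  expect_equal(res2$a_vs_b$p, 2 / choose(10, 5))
  # power at the generator's persist fractions and n = 8-10 per group
  set.seed(13)
  treated <- rnorm(8, 0.8, 0.2); vehicle <- rnorm(10, 0.1, 0.1)
  res3 <- volume_group_test(c(treated, vehicle),
                            rep(c("t", "v"), c(8, 10)))
  expect_lt(res3$t_vs_v$p, 0.05)
})

test_that("pooled MD-metric correlation behaves at the extremes", {
  set.seed(15)
  md <- runif(60, 0.6, 0.8)
  res <- nodal_md_correlation(md, -md, n_perm = 300, seed = 1)
  expect_equal(res$r, -1)
  expect_lt(res$p, 0.01)
  ind <- nodal_md_correlation(rnorm(1000), rnorm(1000), n_perm = 200, seed = 2)
  expect_lt(abs(ind$r), 0.1)
  expect_error(nodal_md_correlation(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(nodal_md_correlation(1:2, 2:1), ">= 3")
})
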