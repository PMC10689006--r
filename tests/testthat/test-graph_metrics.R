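test_that("proportional threshold keeps the right edges deterministically", {
  # 4 nodes, all-equal positive weights, sparsity 0.5 -> ceil(3) = 3 edges,
  # chosen by the lexicographic tie-break: (1,2), (1,3), (2,3)
  z <- matrix(0.4, 4, 4); diag(z) <- NA
  a1 <- proportional_threshold(z, 0.5)
  a2 <- proportional_threshold(z, 0.5)
  expect_identical(a1, a2)
  expect_equal(sum(a1) / 2, 3)
  # lexicographic (i, j) order under ties: (1,2), (1,3), (1,4)
  expect_equal(a1[1, 2] + a1[1, 3] + a1[1, 4], 3L)

  # sparsity 1.0 with all-positive z -> complete graph
  zc <- matrix(runif(25, 0.1, 1), 5, 5); zc <- (zc + t(zc)) / 2; diag(zc) <- NA
  expect_equal(sum(proportional_threshold(zc, 1)) / 2, 10)

  # distinct weights, sparsity 0.3 on 5 nodes (10 pairs) -> top ceil(3) pairs
  set.seed(6)
  w <- matrix(0, 5, 5)
  w[upper.tri(w)] <- sample(seq(0.1, 1, length.out = 10))
  w <- w + t(w); diag(w) <- NA
  adj <- proportional_threshold(w, 0.3)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  top3 <- ut[order(-w[upper.tri(w)])[1:3], , drop = FALSE]
  expect_equal(sum(adj) / 2, 3)
  expect_true(all(adj[top3] == 1))
})

test_that("negative edges are excluded and shortfalls recorded", {
  z <- matrix(-0.5, 6, 6)
  z[1, 2] <- z[2, 1] <- 0.3
  diag(z) <- NA
  adj <- proportional_threshold(z, 0.45)    # requests ceil(6.75) = 7 edges
  expect_equal(sum(adj) / 2, 1)
  expect_equal(attr(adj, "shortfall"), 6L)
  expect_error(proportional_threshold(z, 0), "sparsity")
})

test_that("clustering coefficient matches hand counts", {
  k3 <- matrix(1, 3, 3); diag(k3) <- 0
  expect_equal(unname(clustering_coefficient(k3)), rep(1, 3))
  star <- matrix(0, 4, 4); star[1, 2:4] <- 1; star <- star + t(star)
  expect_equal(unname(clustering_coefficient(star)), rep(0, 4))
  # edges {AB, AC, BC, CD, DE}: C = (1, 1, 1/3, 0, 0)
  g <- matrix(0, 5, 5)
  g[cbind(c(1, 1, 2, 3, 4), c(2, 3, 3, 4, 5))] <- 1
  g <- g + t(g)
  expect_equal(unname(clustering_coefficient(g)), c(1, 1, 1 / 3, 0, 0))
})

test_that("local efficiency matches definitional cases", {
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  expect_equal(unname(local_efficiency(k4)), rep(1, 4))
  p3 <- matrix(0, 3, 3); p3[1, 2] <- p3[2, 3] <- 1; p3 <- p3 + t(p3)
  expect_equal(unname(local_efficiency(p3)), c(0, 0, 0))
})

test_that("metrics equal the brute-force oracle on all 64 graphs with n = 4", {
  for (i in seq_len(64)) {
    A <- indexed_adjacency(4, i)
    expect_equal(unname(clustering_coefficient(A)), oracle_clustering(A))
    expect_equal(unname(local_efficiency(A)), oracle_local_efficiency(A))
  }
})

test_that("metrics equal the oracle on random graphs up to n = 12", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(5:12, 1)
    A <- random_adjacency(n, runif(1, 0.15, 0.8))
    expect_equal(unname(clustering_coefficient(A)), oracle_clustering(A))
    expect_equal(unname(local_efficiency(A)), oracle_local_efficiency(A))
  }
})

test_that("adjacency validation rejects malformed inputs", {
  bad <- matrix(c(0, 2, 2, 0), 2)
  expect_error(clustering_coefficient(bad), "binary")
  loop <- diag(2)
  expect_error(local_efficiency(loop), "diagonal")
  asym <- matrix(c(0, 1, 0, 0), 2)
  expect_error(clustering_coefficient(asym), "symmetric")
})

test_that("sparsity-summed metrics equal level-by-level recomputation", {
  set.seed(19)
  p <- 10
  z <- matrix(rnorm(p * p, 0.2, 0.4), p, p)
  z <- (z + t(z)) / 2; diag(z) <- NA
  dimnames(z) <- list(as.character(1:p), as.character(1:p))
  zfc <- structure(z, class = c("fc_matrix", "matrix"),
                   parcel_ids = as.character(1:p))
  grid <- sparsity_grid()
  tab <- sparsity_summed_metrics(zfc, grid)
  cc_ref <- le_ref <- numeric(p)
  for (s in as.numeric(grid)) {
    a <- proportional_threshold(z, s)
    cc_ref <- cc_ref + oracle_clustering(a)
    le_ref <- le_ref + oracle_local_efficiency(a)
  }
  expect_equal(tab$cc_sum, cc_ref)
  expect_equal(tab$le_sum, le_ref)
  expect_true(all(tab$cc_sum >= 0 & tab$cc_sum <= length(grid)))
  expect_true(all(tab$le_sum >= 0 & tab$le_sum <= length(grid)))
  # edgeless graphs (all-negative z) give zero sums
  zneg <- -abs(z); diag(zneg) <- NA
  tab0 <- sparsity_summed_metrics(
    structure(zneg, class = c("fc_matrix", "matrix"),
              parcel_ids = as.character(1:p)), grid)
  expect_true(all(tab0$cc_sum == 0 & tab0$le_sum == 0))
})

test_that("sums are monotone under grid refinement", {
  set.seed(20)
  p <- 8
  z <- matrix(rnorm(p * p, 0.3, 0.3), p, p); z <- (z + t(z)) / 2; diag(z) <- NA
  zfc <- structure(z, class = c("fc_matrix", "matrix"),
                   parcel_ids = as.character(1:p))
  coarse <- sparsity_summed_metrics(zfc, sparsity_grid(c(0.1, 0.3)))
  fine <- sparsity_summed_metrics(zfc, sparsity_grid(c(0.1, 0.2, 0.3)))
  expect_true(all(fine$cc_sum >= coarse$cc_sum - 1e-12))
  expect_true(all(fine$le_sum >= coarse$le_sum - 1e-12))
})

test_that("node relabeling permutes metric outputs identically", {
  set.seed(21)
  A <- random_adjacency(9, 0.4)
  perm <- sample(9)
  Ap <- A[perm, perm]
  expect_equal(unname(clustering_coefficient(Ap)),
               unname(clustering_coefficient(A))[perm])
  expect_equal(unname(local_efficiency(Ap)),
               unname(local_efficiency(A))[perm])
})

test_that("sparsity grid validation", {
  expect_error(sparsity_grid(c(0.1, 0.1)), "increasing")
  expect_error(sparsity_grid(c(0, 0.2)), "in \\(0,1\\)")
  expect_equal(length(sparsity_grid()), 8L)
})
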