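# Independent brute-force oracles and small fixtures shared across tests.
# These deliberately use different algorithms from the package code paths.

# triangle counting by explicit triple loop
oracle_clustering <- function(A) {
  n <- nrow(A)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    t <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb)) if (a < b)
      t <- t + A[nb[a], nb[b]]
    cc[i] <- 2 * t / (k * (k - 1))
  }
  cc
}

# Floyd-Warshall all-pairs shortest paths
oracle_apsp <- function(A) {
  n <- nrow(A)
  D <- ifelse(A == 1, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_local_efficiency <- function(A) {
  n <- nrow(A)
  eff <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    D <- oracle_apsp(A[nb, nb, drop = FALSE])
    s <- 0
    for (a in seq_len(k)) for (b in seq_len(k)) if (a != b && is.finite(D[a, b]))
      s <- s + 1 / D[a, b]
    eff[i] <- s / (k * (k - 1))
  }
  eff
}

# literal BH step-up: largest k with p_(k) <= k*alpha/m
oracle_bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ks <- which(p[o] <= seq_len(m) * alpha / m)
  rej <- rep(FALSE, m)
  if (length(ks)) rej[o[seq_len(max(ks))]] <- TRUE
  rej
}

random_adjacency <- function(n, prob = 0.4) {
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1, prob)
  A + t(A)
}

# the i-th of the 2^(n choose 2) labelled graphs on n nodes
indexed_adjacency <- function(n, i) {
  e <- n * (n - 1) / 2
  bits <- as.integer(intToBits(i - 1L))[seq_len(e)]
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- bits
  A + t(A)
}

# tiny hand-built label volume: dims 6x3x4, ipsi x<=3, contra x>=4,
# cortex z in 3:4, subcortical z in 1:2; one parcel per hemisphere/tissue
tiny_labels <- function(space_tag = "toy") {
  lab <- array(0L, c(6, 3, 4))
  for (x in 1:6) for (z in 1:4) {
    hemi <- if (x <= 3) 0L else 2L
    tis <- if (z >= 3) 1L else 2L
    lab[x, , z] <- hemi + tis
  }
  pt <- data.frame(
    label_id = 1:4,
    name = c("ipsi_ctx", "ipsi_sub", "contra_ctx", "contra_sub"),
    hemisphere = c("ipsi", "ipsi", "contra", "contra"),
    tissue = c("cortex", "subcortical", "cortex", "subcortical"),
    stringsAsFactors = FALSE)
  label_volume(lab, pt, voxel_mm = c(0.25, 0.25, 0.25), space_tag = space_tag)
}

# small, fast cohort configuration for pipeline-level tests; nested overrides
# are merged into the fast defaults by name
fast_sim <- function(...) {
  base <- list(
    grid_dims = c(20, 20, 10), n_parcels = 8,
    group_sizes = c(sham = 4, injury_vehicle = 4, injury_treated = 3),
    lesion = list(center = c(6, 10, 7), radii = c(3, 3, 2)),
    timeseries = list(n_timepoints = 150))
  over <- list(...)
  for (nm in names(over)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
      utils::modifyList(base[[nm]], over[[nm]]) else over[[nm]]
  }
  do.call(simulation_config, base)
}

expect_edge_stats <- function(res) {
  expect_s3_class(res, "edge_stats")
  expect_true(all(res$p_perm > 0 & res$p_perm <= 1))
  expect_true(all(res$q_fdr >= res$p_perm - 1e-12))
  expect_setequal(unique(res$direction), intersect(c("hyper", "hypo"), res$direction))
}
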