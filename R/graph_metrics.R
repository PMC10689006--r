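#' Proportional-sparsity grid
#'
#' @param levels Strictly increasing fractions in (0,1); default 10% to 45%
#'   in 5% increments.
#' @return Validated numeric vector of class `sparsity_grid`.
#' @export
sparsity_grid <- function(levels = seq(0.10, 0.45, by = 0.05)) {
  levels <- as.numeric(levels)
  if (any(levels <= 0 | levels >= 1)) stop("sparsity levels must lie in (0,1)")
  if (is.unsorted(levels, strictly = TRUE)) stop("levels must be strictly increasing")
  structure(levels, class = "sparsity_grid")
}

#' Proportional threshold of an FC matrix
#'
#' Binarizes a Fisher-z connectivity matrix by keeping the top
#' `ceiling(sparsity * E)` edges by z among the positive-z edges, where E is
#' the number of node pairs. Negative and zero z edges are excluded before
#' ranking. Ties are broken by a fixed total order (z descending, then
#' parcel-pair lexicographic), so the result is deterministic across
#' platforms. If fewer positive edges exist than requested, all positive
#' edges are kept and the shortfall is recorded in the `shortfall`
#' attribute.
#'
#' @param z An `fc_matrix` (or symmetric numeric matrix, NA diagonal).
#' @param sparsity Fraction in (0,1].
#' @return Binary symmetric adjacency matrix (0/1, zero diagonal) with the
#'   input dimnames.
#' @export
proportional_threshold <- function(z, sparsity) {
  if (!is.numeric(sparsity) || sparsity <= 0 || sparsity > 1)
    stop("sparsity must lie in (0,1]")
  m <- unclass(z)
  p <- nrow(m)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  w <- m[upper.tri(m)]
  E <- nrow(ut)
  k <- ceiling(sparsity * E)
  pos <- which(is.finite(w) & w > 0)
  ord <- pos[order(-w[pos], ut[pos, 1], ut[pos, 2])]
  keep <- ord[seq_len(min(k, length(ord)))]
  adj <- matrix(0L, p, p, dimnames = dimnames(m))
  adj[cbind(ut[keep, 1], ut[keep, 2])] <- 1L
  adj <- adj + t(adj)
  attr(adj, "shortfall") <- max(0L, k - length(pos))
  adj
}

#' Binary clustering coefficient
#'
#' Watts-Strogatz nodal clustering: `C_i = 2 t_i / (k_i (k_i - 1))` with
#' `t_i` the number of triangles through node i; `C_i = 0` for degree < 2.
#'
#' @param adj Binary symmetric adjacency matrix, zero diagonal.
#' @return Numeric vector of per-node coefficients in `[0, 1]`.
#' @export
clustering_coefficient <- function(adj) {
  A <- check_adjacency(adj)
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  cc <- ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
  stats::setNames(cc, rownames(A))
}

#' Binary local efficiency
#'
#' Nodal local efficiency: the global efficiency of the subgraph induced on
#' the neighbors of node i, i.e. the mean over ordered neighbor pairs (j,h)
#' of `1 / d_jh` with distances computed within that subgraph (disconnected
#' pairs contribute 0). Nodes with degree < 2 score 0.
#'
#' @param adj Binary symmetric adjacency matrix, zero diagonal.
#' @return Numeric vector of per-node efficiencies in `[0, 1]`.
#' @export
local_efficiency <- function(adj) {
  A <- check_adjacency(adj)
  n <- nrow(A)
  eff <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    d <- length(nb)
    if (d < 2) next
    sub <- A[nb, nb, drop = FALSE]
    D <- bfs_distances(sub)
    inv <- 1 / D
    inv[!is.finite(inv)] <- 0
    diag(inv) <- 0
    eff[i] <- sum(inv) / (d * (d - 1))
  }
  stats::setNames(eff, rownames(A))
}

# all-pairs shortest path lengths of a small binary graph via BFS level sets
bfs_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    depth <- 0
    visited <- rep(FALSE, n)
    visited[s] <- TRUE
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- which(!visited & colSums(A[frontier, , drop = FALSE]) > 0)
      if (!length(nxt)) break
      D[s, nxt] <- depth
      visited[nxt] <- TRUE
      frontier <- nxt
    }
  }
  D
}

check_adjacency <- function(adj) {
  A <- unclass(as.matrix(adj))
  attr(A, "shortfall") <- NULL
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  if (any(A != 0 & A != 1)) stop("adjacency must be binary")
  if (any(diag(A) != 0)) stop("adjacency must have zero diagonal")
  if (!isTRUE(all.equal(A, t(A)))) stop("adjacency must be symmetric")
  storage.mode(A) <- "double"
  A
}

#' Sparsity-summed nodal graph metrics
#'
#' For each sparsity level: proportionally threshold the FC matrix, compute
#' the nodal clustering coefficient and local efficiency on the binary
#' graph, then sum each metric per node across levels. With the default
#' 8-level grid each sum lies in `[0, 8]`.
#'
#' @param z An `fc_matrix`.
#' @param grid A [sparsity_grid()].
#' @return Data frame with columns `node`, `cc_sum`, `le_sum` plus a
#'   `grid` attribute.
#' @export
sparsity_summed_metrics <- function(z, grid = sparsity_grid()) {
  ids <- attr(z, "parcel_ids") %||% rownames(z) %||% as.character(seq_len(nrow(z)))
  cc <- le <- numeric(nrow(z))
  for (s in grid) {
    adj <- proportional_threshold(z, s)
    cc <- cc + clustering_coefficient(adj)
    le <- le + local_efficiency(adj)
  }
  out <- data.frame(node = ids, cc_sum = unname(cc), le_sum = unname(le),
                    stringsAsFactors = FALSE)
  attr(out, "grid") <- as.numeric(grid)
  out
}
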