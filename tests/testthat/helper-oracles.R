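## Independent brute-force oracles, deliberately written with different
## algorithms than the package implementations.

## Convex hull area by exhaustive edge testing: a directed pair (i, j) is a
## hull edge iff all other points lie on or to the left of it. O(n^3).
oracle_hull_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(0)
  verts <- integer(0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    cross <- (xy[j, 1] - xy[i, 1]) * (xy[, 2] - xy[i, 2]) -
             (xy[j, 2] - xy[i, 2]) * (xy[, 1] - xy[i, 1])
    if (all(cross >= -1e-9)) verts <- c(verts, i, j)
  }
  verts <- unique(verts)
  if (length(verts) < 3) return(0)
  hv <- xy[verts, , drop = FALSE]
  ctr <- colMeans(hv)
  ord <- order(atan2(hv[, 2] - ctr[2], hv[, 1] - ctr[1]))
  hv <- hv[ord, , drop = FALSE]
  x <- hv[, 1]; y <- hv[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

## All-pairs neighbour counting by explicit double loop.
oracle_neighbor_counts <- function(xy, radius) {
  n <- nrow(xy)
  out <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (sqrt(sum((xy[i, ] - xy[j, ])^2)) <= radius) out[i] <- out[i] + 1L
    }
  }
  out
}

## Union-find over hyperedges; returns canonical partition labels
## (first-appearance order over sorted node ids).
oracle_chain_partition <- function(nodes, members) {
  parent <- seq_along(nodes)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (m in members) {
    idx <- match(m, nodes)
    for (k in idx[-1]) {
      ra <- find(idx[1]); rb <- find(k)
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  as.integer(factor(roots, levels = unique(roots[order(nodes)])))
}

## Minimax 1-center by conservative grid refinement plus a Nelder-Mead
## polish (the objective has a flat valley when two points support the
## enclosing circle, so aggressive shrinking loses the optimum).
oracle_minimax_center <- function(xy, tol = 0.02) {
  f <- function(p) max(sqrt((xy[, 1] - p[1])^2 + (xy[, 2] - p[2])^2))
  lo <- apply(xy, 2, min); hi <- apply(xy, 2, max)
  ctr <- (lo + hi) / 2
  span <- max(hi - lo, 1)
  while (span > tol) {
    gx <- seq(ctr[1] - span, ctr[1] + span, length.out = 41)
    gy <- seq(ctr[2] - span, ctr[2] + span, length.out = 41)
    g <- as.matrix(expand.grid(gx, gy))
    obj <- apply(g, 1, f)
    ctr <- g[which.min(obj), ]
    span <- span / 2
  }
  fit <- stats::optim(ctr, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  list(center = unname(fit$par), radius = fit$value)
}

## Exact two-sided rank-sum p-value by direct enumeration over index
## subsets (midranks; doubling rule capped at 1).
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  sums <- apply(utils::combn(n, n1), 2, function(ix) sum(r[ix]))
  min(1, 2 * min(mean(sums <= w + 1e-9), mean(sums >= w - 1e-9)))
}

## Random connector hypergraph for property tests.
random_hypergraph <- function(n_nodes, n_edges, max_k = 4) {
  nodes <- seq_len(n_nodes)
  members <- lapply(seq_len(n_edges), function(i) {
    k <- sample(2:max_k, 1)
    sort(sample(nodes, k))
  })
  list(nodes = nodes, members = members)
}
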