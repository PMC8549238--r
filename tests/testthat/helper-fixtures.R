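# Fixture builders and independent oracles used across the suite.

# Build a pcor_network directly from an edge list (node labels, optional
# partial correlations), bypassing estimation, for graph-level tests.
make_network <- function(edge_pairs, partials = NULL, nodes = NULL) {
  ep <- do.call(rbind, lapply(edge_pairs, function(e) sort(as.character(e))))
  if (is.null(nodes)) nodes <- sort(unique(as.vector(ep)))
  if (is.null(partials)) partials <- rep(0.5, nrow(ep))
  i <- match(ep[, 1], nodes); j <- match(ep[, 2], nodes)
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  ord <- order(i, j)
  i <- i[ord]; j <- j[ord]; partials <- partials[ord]
  rho <- diag(length(nodes))
  for (r in seq_along(i)) rho[i[r], j[r]] <- rho[j[r], i[r]] <- partials[r]
  dimnames(rho) <- list(nodes, nodes)
  edges <- data.frame(
    from = nodes[i], to = nodes[j], i = i, j = j,
    partial_correlation = partials,
    sign = ifelse(partials >= 0, "positive", "negative"),
    strong = abs(partials) >= 0.20,
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, rho = rho, edges = edges,
                 strong_threshold = 0.20),
            class = "pcor_network")
}

# Independent inclusive-neighborhood Jaccard similarity between two edges,
# written with plain set operations (no package internals).
oracle_edge_similarity <- function(edges_ij, e1, e2) {
  nb <- function(v) {
    out <- v
    for (r in seq_len(nrow(edges_ij))) {
      if (edges_ij[r, 1] == v) out <- c(out, edges_ij[r, 2])
      if (edges_ij[r, 2] == v) out <- c(out, edges_ij[r, 1])
    }
    unique(out)
  }
  shared <- intersect(e1, e2)
  if (length(shared) == 0) return(0)
  k <- shared[1]
  a <- setdiff(e1, k); b <- setdiff(e2, k)
  length(intersect(nb(a), nb(b))) / length(union(nb(a), nb(b)))
}

# Direct partition-density formula on a membership vector over edges.
oracle_partition_density <- function(edges_ij, membership) {
  M <- nrow(edges_ij)
  contrib <- 0
  for (cid in unique(membership)) {
    rows <- which(membership == cid)
    m_c <- length(rows)
    n_c <- length(unique(as.vector(edges_ij[rows, , drop = FALSE])))
    if (n_c > 2) contrib <- contrib + m_c * (m_c - n_c + 1) /
        ((n_c - 2) * (n_c - 1))
  }
  2 / M * contrib
}

# Exhaustive oracle for the partition-density maximum over single-linkage
# cuts: at every threshold t, communities are the connected components of
# the edge-graph whose links are edge pairs with similarity >= t.
oracle_max_density <- function(edges_ij) {
  M <- nrow(edges_ij)
  sim <- matrix(0, M, M)
  for (a in seq_len(M - 1)) {
    for (b in (a + 1):M) {
      sim[a, b] <- sim[b, a] <-
        oracle_edge_similarity(edges_ij, edges_ij[a, ], edges_ij[b, ])
    }
  }
  thresholds <- sort(unique(c(sim[upper.tri(sim)], Inf)))
  best <- -Inf
  for (t in thresholds) {
    # union-find over edges joined at similarity >= t
    parent <- seq_len(M)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (a in seq_len(M - 1)) for (b in (a + 1):M) {
      if (sim[a, b] >= t) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[ra] <- rb
      }
    }
    memb <- vapply(seq_len(M), find, integer(1))
    best <- max(best, oracle_partition_density(edges_ij, memb))
  }
  best
}

# Naive single-linkage agglomeration returning sorted merge heights,
# independent of stats::hclust.
oracle_single_linkage_heights <- function(d) {
  m <- nrow(d)
  active <- as.list(seq_len(m))
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- Inf; bi <- bj <- NA
    for (a in seq_len(length(active) - 1)) {
      for (b in (a + 1):length(active)) {
        dd <- min(d[active[[a]], active[[b]]])
        if (dd < best) { best <- dd; bi <- a; bj <- b }
      }
    }
    heights <- c(heights, best)
    active[[bi]] <- c(active[[bi]], active[[bj]])
    active[[bj]] <- NULL
  }
  sort(heights)
}

# Small standardized intake table with known structure for scoring tests.
toy_standardized <- function(n = 200, seed = 42) {
  set.seed(seed)
  f <- rnorm(n)
  z <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    a = f + rnorm(n, sd = 0.4),
    b = f + rnorm(n, sd = 0.4),
    c = f + rnorm(n, sd = 0.4))
  for (v in c("a", "b", "c")) z[[v]] <- as.numeric(scale(z[[v]]))
  z
}

# Random correlation matrix that is comfortably positive definite.
random_correlation <- function(p, seed) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  S <- crossprod(A) + p * diag(p)
  stats::cov2cor(S)
}
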