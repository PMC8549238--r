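# Link-community detection over partial-correlation edges: edges are
# clustered by the similarity of their endpoints' inclusive neighborhoods,
# agglomerated by single linkage, and the dendrogram is cut where the
# partition density is maximal. A food group (node) may belong to several
# communities, which is what lets nested dietary patterns share foods.

inclusive_neighborhoods <- function(edges, nodes) {
  nbr <- lapply(seq_along(nodes), function(v) v)
  for (r in seq_len(nrow(edges))) {
    i <- edges$i[r]; j <- edges$j[r]
    nbr[[i]] <- c(nbr[[i]], j)
    nbr[[j]] <- c(nbr[[j]], i)
  }
  lapply(nbr, function(v) sort(unique(v)))
}

pick_edges <- function(network, edges = c("all", "strong")) {
  edges <- match.arg(edges)
  ed <- network$edges
  if (edges == "strong") ed <- ed[ed$strong, , drop = FALSE]
  rownames(ed) <- NULL
  ed
}

#' Similarity between two edges of a partial-correlation network
#'
#' Edges sharing a node `k` are compared through their non-shared endpoints
#' `i` and `j`: the default (unweighted) similarity is the Jaccard index of
#' the inclusive neighborhoods `n+(i)` and `n+(j)` (each node's neighbor set
#' including itself). The weighted variant is the Tanimoto coefficient of
#' `|rho|`-weighted neighborhood profiles (each node's self-weight set to its
#' mean incident edge weight). Edges with no shared node have similarity 0.
#'
#' @param network a `pcor_network`.
#' @param e1,e2 edges as length-2 vectors of node labels (or indices).
#' @param weighted use the `|rho|`-weighted Tanimoto similarity.
#' @param edges which edge set defines the graph: all nonzero-partial edges
#'   (default) or only strong ones.
#' @return similarity in `[0, 1]`.
#' @export
edge_similarity <- function(network, e1, e2, weighted = FALSE,
                            edges = c("all", "strong")) {
  ed <- pick_edges(network, edges)
  as_idx <- function(e) {
    if (is.character(e)) match(e, network$nodes) else as.integer(e)
  }
  find_edge <- function(e) {
    e <- sort(as_idx(e))
    if (anyNA(e)) stop("edge refers to unknown node")
    r <- which(ed$i == e[1] & ed$j == e[2])
    if (!length(r)) {
      stop("edge (", e[1], ", ", e[2], ") is not in the network")
    }
    r
  }
  r1 <- find_edge(e1); r2 <- find_edge(e2)
  if (r1 == r2) stop("e1 and e2 must be different edges")
  sim <- edge_similarity_matrix(ed, length(network$nodes), weighted)
  sim[r1, r2]
}

edge_similarity_matrix <- function(ed, n_nodes, weighted = FALSE) {
  m <- nrow(ed)
  sim <- matrix(0, m, m)
  if (m < 2) { diag(sim) <- 1; return(sim) }
  nbr <- inclusive_neighborhoods(ed, seq_len(n_nodes))
  if (weighted) {
    w <- matrix(0, n_nodes, n_nodes)
    for (r in seq_len(m)) {
      w[ed$i[r], ed$j[r]] <- w[ed$j[r], ed$i[r]] <- abs(ed$partial_correlation[r])
    }
    a <- matrix(0, n_nodes, n_nodes)  # row v: weighted profile of node v
    for (v in seq_len(n_nodes)) {
      nb <- setdiff(nbr[[v]], v)
      if (length(nb)) {
        a[v, nb] <- w[v, nb]
        a[v, v] <- mean(w[v, nb])
      }
    }
  }
  incident <- vector("list", n_nodes)
  for (r in seq_len(m)) {
    incident[[ed$i[r]]] <- c(incident[[ed$i[r]]], r)
    incident[[ed$j[r]]] <- c(incident[[ed$j[r]]], r)
  }
  other_end <- function(r, k) if (ed$i[r] == k) ed$j[r] else ed$i[r]
  for (k in seq_len(n_nodes)) {
    inc <- incident[[k]]
    if (length(inc) < 2) next
    for (a1 in seq_len(length(inc) - 1)) {
      for (a2 in (a1 + 1):length(inc)) {
        r1 <- inc[a1]; r2 <- inc[a2]
        i <- other_end(r1, k); j <- other_end(r2, k)
        if (weighted) {
          ai <- a[i, ]; aj <- a[j, ]
          s <- sum(ai * aj) /
            (sum(ai^2) + sum(aj^2) - sum(ai * aj))
        } else {
          s <- length(intersect(nbr[[i]], nbr[[j]])) /
            length(union(nbr[[i]], nbr[[j]]))
        }
        sim[r1, r2] <- sim[r2, r1] <- max(sim[r1, r2], s)
      }
    }
  }
  diag(sim) <- 1
  sim
}

#' Single-linkage agglomerative clustering of network edges
#'
#' @param network a `pcor_network`.
#' @param edges cluster all nonzero-partial edges (default) or only strong
#'   ones.
#' @param weighted use the weighted edge similarity.
#' @return Object of class `edge_dendrogram`: the clustered `edges`
#'   data.frame, the similarity matrix, an `hclust` merge tree (NULL when
#'   fewer than 2 edges), and the network's node labels.
#' @export
cluster_edges <- function(network, edges = c("all", "strong"),
                          weighted = FALSE) {
  ed <- pick_edges(network, edges)
  m <- nrow(ed)
  sim <- edge_similarity_matrix(ed, length(network$nodes), weighted)
  hc <- NULL
  if (m >= 2) {
    d <- as.dist(1 - sim)
    hc <- hclust(d, method = "single")
  } else {
    warning("fewer than 2 edges: trivial dendrogram")
  }
  structure(list(edges = ed, similarity = sim, hclust = hc,
                 nodes = network$nodes),
            class = "edge_dendrogram")
}

community_stats <- function(edset) {
  n_c <- length(unique(c(edset$i, edset$j)))
  m_c <- nrow(edset)
  list(m = m_c, n = n_c)
}

#' Partition density of an edge partition
#'
#' `D = (2/M) * sum_c m_c (m_c - n_c + 1) / ((n_c - 2)(n_c - 1))` over
#' communities `c` with `m_c` edges and `n_c` nodes; two-node communities
#' (single edges and their duplicates) contribute 0. A clique community
#' attains the per-community maximum of 1.
#'
#' @param communities list of edge sets (data.frames with columns `i`, `j`).
#' @param M total number of edges partitioned.
#' @return D, a number (in `[0, 1]` for connected communities).
#' @export
partition_density <- function(communities, M) {
  keys <- unlist(lapply(communities, function(e) paste(e$i, e$j)))
  if (anyDuplicated(keys)) stop("communities overlap: edge sets must be disjoint")
  if (length(keys) != M) stop("communities must partition all ", M, " edges")
  contrib <- vapply(communities, function(edset) {
    s <- community_stats(edset)
    if (s$n <= 2) return(0)
    s$m * (s$m - s$n + 1) / ((s$n - 2) * (s$n - 1))
  }, numeric(1))
  2 / M * sum(contrib)
}

#' Cut an edge dendrogram at maximum partition density
#'
#' Evaluates the partition density at the all-singletons cut and at every
#' distinct merge height, and returns the partition maximizing it. Ties go to
#' the higher similarity threshold (more, smaller communities), so the result
#' is deterministic.
#'
#' @param dendrogram an `edge_dendrogram`.
#' @return Object of class `link_communities`: `communities` (list of edge
#'   data.frames), `community_edge_ids`, `node_membership` (per node, the ids
#'   of communities touching it), `cut_similarity`, `partition_density`,
#'   `edges`, `nodes`.
#' @export
cut_at_max_density <- function(dendrogram) {
  stopifnot(inherits(dendrogram, "edge_dendrogram"))
  ed <- dendrogram$edges
  m <- nrow(ed)
  if (m == 0) {
    warning("no edges: empty community set")
    return(new_link_communities(list(), ed, dendrogram$nodes, 1, 0))
  }
  if (m == 1) {
    return(new_link_communities(list(1L), ed, dendrogram$nodes, 1, 0))
  }
  hc <- dendrogram$hclust
  heights <- sort(unique(hc$height))
  # candidate memberships: singletons first (highest similarity threshold),
  # then each distinct merge height in increasing order
  candidates <- c(list(seq_len(m)),
                  lapply(heights, function(h) cutree(hc, h = h + 1e-12)))
  cut_sims <- c(1, 1 - heights)
  best_d <- -Inf; best <- NULL; best_sim <- NA_real_
  for (ci in seq_along(candidates)) {
    memb <- candidates[[ci]]
    comm <- split(seq_len(m), memb)
    d <- partition_density(lapply(comm, function(ids) ed[ids, , drop = FALSE]), m)
    if (d > best_d + 1e-12) {
      best_d <- d; best <- comm; best_sim <- cut_sims[ci]
    }
  }
  new_link_communities(unname(best), ed, dendrogram$nodes, best_sim, best_d)
}

new_link_communities <- function(edge_id_sets, ed, nodes, cut_similarity, D) {
  communities <- lapply(edge_id_sets, function(ids) ed[ids, , drop = FALSE])
  membership <- setNames(vector("list", length(nodes)), nodes)
  for (ci in seq_along(communities)) {
    touched <- unique(c(communities[[ci]]$i, communities[[ci]]$j))
    for (v in touched) {
      membership[[v]] <- c(membership[[v]], ci)
    }
  }
  structure(
    list(communities = communities, community_edge_ids = edge_id_sets,
         node_membership = membership, cut_similarity = cut_similarity,
         partition_density = D, edges = ed, nodes = nodes),
    class = "link_communities")
}

#' @export
print.link_communities <- function(x, ...) {
  cat("Link communities:", length(x$communities), "communities over",
      nrow(x$edges), "edges; partition density",
      format(x$partition_density, digits = 4), "at similarity threshold",
      format(x$cut_similarity, digits = 4), "\n")
  invisible(x)
}

#' Community centrality of a node
#'
#' The number of communities whose edge sets touch the node — the criterion
#' for the central food of a dietary network. Nodes with every incident edge
#' pruned have centrality 0.
#'
#' @param communities a `link_communities` object.
#' @param node node label (or index).
#' @return integer membership count.
#' @export
community_centrality <- function(communities, node) {
  stopifnot(inherits(communities, "link_communities"))
  if (is.character(node)) {
    if (!node %in% communities$nodes) stop("unknown node: ", node)
  } else {
    if (node < 1 || node > length(communities$nodes)) {
      stop("unknown node index: ", node)
    }
    node <- communities$nodes[node]
  }
  length(communities$node_membership[[node]])
}

#' Assemble dietary networks from link communities
#'
#' Dietary networks are the connected components of the union graph of all
#' community edge sets; components with fewer than `min_nodes` food groups
#' (default 3) are dropped. Within each network the central food group(s)
#' maximize community membership, ties broken by the largest sum of `|rho|`
#' over incident edges. Networks are named by node-count rank
#' (`network1` = largest) and can be renamed by the user.
#'
#' @param communities a `link_communities` object.
#' @param min_nodes minimum food groups per network (default 3).
#' @param names optional character vector of names, by size rank.
#' @return list of `dietary_network` objects (class `dietary_network_set`),
#'   each with `name`, `nodes`, `edges`, `communities` (ids), `centrality`
#'   (named counts), `central`, and a `loadings` slot filled by
#'   [pca_loadings()].
#' @export
assemble_networks <- function(communities, min_nodes = 3, names = NULL) {
  stopifnot(inherits(communities, "link_communities"))
  ed <- communities$edges
  if (!length(communities$communities) || nrow(ed) == 0) {
    warning("empty community set: no dietary networks")
    return(structure(list(), class = "dietary_network_set"))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = communities$nodes[ed$i], to = communities$nodes[ed$j]),
    directed = FALSE,
    vertices = data.frame(name = communities$nodes))
  comp <- igraph::components(g)
  nets <- list()
  for (ck in seq_len(comp$no)) {
    members <- communities$nodes[comp$membership == ck]
    in_comp <- communities$nodes[ed$i] %in% members &
      communities$nodes[ed$j] %in% members
    if (!any(in_comp)) next           # isolated nodes
    if (length(members) < min_nodes) next
    sub <- ed[in_comp, , drop = FALSE]
    member_comms <- which(vapply(communities$communities, function(ce) {
      any(communities$nodes[ce$i] %in% members)
    }, logical(1)))
    centrality <- vapply(members, function(v)
      community_centrality(communities, v), integer(1))
    top <- members[centrality == max(centrality)]
    if (length(top) > 1) {
      strength <- vapply(top, function(v) {
        vi <- match(v, communities$nodes)
        sum(abs(sub$partial_correlation[sub$i == vi | sub$j == vi]))
      }, numeric(1))
      central <- top[which.max(strength)]
    } else central <- top
    node_comms <- lapply(members, function(v)
      communities$node_membership[[v]])
    names(node_comms) <- members
    nets[[length(nets) + 1]] <- structure(
      list(name = NA_character_, nodes = members, edges = sub,
           communities = member_comms,
           node_communities = node_comms,
           centrality = setNames(centrality, members),
           central = central, loadings = NULL),
      class = "dietary_network")
  }
  if (!length(nets)) {
    warning("no component with >= ", min_nodes, " nodes")
    return(structure(list(), class = "dietary_network_set"))
  }
  ord <- order(-vapply(nets, function(nw) length(nw$nodes), integer(1)))
  nets <- nets[ord]
  if (is.null(names)) names <- sprintf("network%d", seq_along(nets))
  for (i in seq_along(nets)) nets[[i]]$name <- names[i]
  names(nets) <- names
  structure(nets, class = "dietary_network_set")
}

#' @export
print.dietary_network <- function(x, ...) {
  cat("Dietary network '", x$name, "': ", length(x$nodes), " food groups, ",
      nrow(x$edges), " edges, central food: ", x$central,
      " (in ", x$centrality[[x$central]], " communities)\n", sep = "")
  invisible(x)
}

#' @export
print.dietary_network_set <- function(x, ...) {
  cat(length(x), "dietary network(s)\n")
  for (nw in x) print(nw)
  invisible(x)
}

#' Detect link communities in one call
#'
#' Convenience wrapper: [cluster_edges()] then [cut_at_max_density()].
#'
#' @inheritParams cluster_edges
#' @return a `link_communities` object.
#' @export
detect_link_communities <- function(network, edges = c("all", "strong"),
                                    weighted = FALSE) {
  cut_at_max_density(cluster_edges(network, edges, weighted))
}
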