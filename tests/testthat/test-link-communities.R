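test_that("edge similarity follows the inclusive-neighborhood Jaccard", {
  tri <- make_network(list(c("a", "b"), c("a", "c"), c("b", "c")))
  expect_equal(edge_similarity(tri, c("a", "b"), c("a", "c")), 1.0)
  # path a-b-c-d: edges (a,b),(b,c) share b; n+(a)={a,b}, n+(c)={b,c,d}
  path <- make_network(list(c("a", "b"), c("b", "c"), c("c", "d")))
  expect_equal(edge_similarity(path, c("a", "b"), c("b", "c")), 0.25)
  # disjoint edges
  dis <- make_network(list(c("a", "b"), c("c", "d")))
  expect_equal(edge_similarity(dis, c("a", "b"), c("c", "d")), 0)
  expect_error(edge_similarity(dis, c("a", "b"), c("a", "c")), "not in the network")
  expect_error(edge_similarity(dis, c("a", "b"), c("b", "a")), "different edges")
})

test_that("edge similarity is symmetric, bounded, and matches the oracle", {
  set.seed(5)
  nodes <- letters[1:8]
  pairs <- t(combn(nodes, 2))
  keep <- sample(nrow(pairs), 12)
  net <- make_network(lapply(keep, function(r) pairs[r, ]))
  ed <- net$edges
  for (a in 1:(nrow(ed) - 1)) {
    for (b in (a + 1):nrow(ed)) {
      s1 <- edge_similarity(net, c(ed$from[a], ed$to[a]),
                            c(ed$from[b], ed$to[b]))
      s2 <- edge_similarity(net, c(ed$from[b], ed$to[b]),
                            c(ed$from[a], ed$to[a]))
      expect_identical(s1, s2)
      expect_gte(s1, 0); expect_lte(s1, 1)
      expect_equal(s1, oracle_edge_similarity(cbind(ed$i, ed$j),
                                              c(ed$i[a], ed$j[a]),
                                              c(ed$i[b], ed$j[b])))
    }
  }
})

test_that("single-linkage merge heights equal a brute-force recomputation", {
  set.seed(8)
  nodes <- letters[1:8]
  pairs <- t(combn(nodes, 2))
  keep <- sample(nrow(pairs), 11)
  net <- make_network(lapply(keep, function(r) pairs[r, ]))
  dend <- cluster_edges(net)
  d <- 1 - dend$similarity
  expect_equal(sort(dend$hclust$height),
               oracle_single_linkage_heights(d), tolerance = 1e-12)
})

test_that("triangle edges merge at similarity 1; disjoint triangles split", {
  tri <- make_network(list(c("a", "b"), c("a", "c"), c("b", "c")))
  dend <- cluster_edges(tri)
  expect_equal(max(dend$hclust$height), 0, tolerance = 1e-12)
  two <- make_network(list(c("a", "b"), c("a", "c"), c("b", "c"),
                           c("x", "y"), c("x", "z"), c("y", "z")))
  lc <- detect_link_communities(two)
  expect_equal(length(lc$communities), 2)
  expect_equal(lc$partition_density, 1.0)
  sizes <- sort(vapply(lc$communities, nrow, integer(1)))
  expect_equal(sizes, c(3L, 3L))
})

test_that("partition density follows the closed formula", {
  # K4 as one community: D = 1
  k4 <- make_network(list(c("a","b"), c("a","c"), c("a","d"),
                          c("b","c"), c("b","d"), c("c","d")))
  expect_equal(partition_density(list(k4$edges), 6), 1.0)
  # all singletons: D = 0
  singles <- lapply(seq_len(6), function(r) k4$edges[r, , drop = FALSE])
  expect_equal(partition_density(singles, 6), 0)
  # two disjoint triangles as two communities
  two <- make_network(list(c("a", "b"), c("a", "c"), c("b", "c"),
                           c("x", "y"), c("x", "z"), c("y", "z")))
  halves <- list(two$edges[1:3, ], two$edges[4:6, ])
  expect_equal(partition_density(halves, 6), 1.0)
  expect_error(partition_density(list(k4$edges, k4$edges[1, , drop = FALSE]), 7),
               "overlap")
})

test_that("maximum-density cut equals exhaustive enumeration on small graphs", {
  fixtures <- list(
    triangle = list(c("a","b"), c("a","c"), c("b","c")),
    two_triangles = list(c("a","b"), c("a","c"), c("b","c"),
                         c("x","y"), c("x","z"), c("y","z")),
    bowtie = list(c("a","b"), c("a","c"), c("b","c"),
                  c("c","d"), c("c","e"), c("d","e")),
    star = list(c("h","a"), c("h","b"), c("h","c"), c("h","d")),
    path = list(c("a","b"), c("b","c"), c("c","d"), c("d","e")))
  set.seed(13)
  for (k in 1:4) {
    nodes <- letters[1:7]
    pairs <- t(combn(nodes, 2))
    keep <- sample(nrow(pairs), 10 + k %% 3)
    fixtures[[paste0("random", k)]] <- lapply(keep, function(r) pairs[r, ])
  }
  for (nm in names(fixtures)) {
    net <- make_network(fixtures[[nm]])
    lc <- detect_link_communities(net)
    oracle <- oracle_max_density(cbind(net$edges$i, net$edges$j))
    expect_equal(lc$partition_density, oracle, tolerance = 1e-12,
                 label = paste("partition density for", nm))
    expect_gte(lc$partition_density, 0)
  }
})

test_that("star graph ties resolve to the highest-similarity cut", {
  star <- make_network(list(c("h","a"), c("h","b"), c("h","c"), c("h","d")))
  lc <- detect_link_communities(star)
  expect_equal(lc$partition_density, 0)
  # every sub-star is a tree, so singletons (threshold 1) win the tie
  expect_equal(length(lc$communities), 4)
  expect_equal(lc$cut_similarity, 1)
})

test_that("community centrality counts communities touching a node", {
  bowtie <- make_network(list(c("a","b"), c("a","c"), c("b","c"),
                              c("c","d"), c("c","e"), c("d","e")))
  lc <- detect_link_communities(bowtie)
  expect_equal(length(lc$communities), 2)
  expect_equal(community_centrality(lc, "c"), 2)   # shared center
  expect_equal(community_centrality(lc, "a"), 1)
  expect_error(community_centrality(lc, "zz"), "unknown node")
  # membership bookkeeping invariant
  for (v in lc$nodes) {
    touching <- sum(vapply(lc$communities, function(ce) {
      v %in% c(lc$nodes[ce$i], lc$nodes[ce$j])
    }, logical(1)))
    expect_equal(community_centrality(lc, v), touching)
  }
})

test_that("network assembly applies the >= 3 node rule and centrality", {
  # butter-style 3-node chain community
  chain <- make_network(list(c("Butter", "Animal fat"),
                             c("Butter", "Margarine")),
                        partials = c(0.03, 0.06))
  lc <- detect_link_communities(chain)
  nets <- assemble_networks(lc)
  expect_equal(length(nets), 1)
  expect_setequal(nets[[1]]$nodes, c("Butter", "Animal fat", "Margarine"))
  expect_equal(nets[[1]]$central, "Butter")
  # components below 3 nodes are dropped
  mixed <- make_network(list(c("a","b"),
                             c("p","q"), c("p","r"), c("p","s"), c("q","r")))
  nets2 <- assemble_networks(detect_link_communities(mixed))
  expect_equal(length(nets2), 1)
  expect_setequal(nets2[[1]]$nodes, c("p", "q", "r", "s"))
  # empty input warns and returns nothing
  empty <- make_network(list(c("a", "b")))
  empty$edges <- empty$edges[0, ]
  expect_warning(d0 <- cluster_edges(empty), "fewer than 2")
  expect_warning(lc0 <- cut_at_max_density(d0), "no edges")
  expect_warning(n0 <- assemble_networks(lc0), "empty|no component")
  expect_equal(length(n0), 0)
})

test_that("planted six-community structure is recovered from its own graph", {
  # noiseless check: communities computed on the exact planted partials
  pp <- build_planted_precision(default_structure())
  reg35 <- food_group_registry()
  net <- precision_to_partial(pp, nodes = reg35$group)
  lc <- detect_link_communities(net)
  nets <- assemble_networks(lc)
  expect_equal(length(nets), 3)
  sizes <- sort(unname(vapply(nets, function(n) length(n$nodes), integer(1))))
  expect_equal(sizes, c(3L, 13L, 14L))
  # the saturated-fats block comes back intact (smallest network by rank)
  reg <- food_group_registry()
  expect_setequal(nets[["network3"]]$nodes, reg$group[c(29, 30, 31)])
})
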