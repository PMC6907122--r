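clique_network <- function(sizes, bridge = FALSE, weight = 1) {
  nodes <- unlist(lapply(seq_along(sizes), function(m)
    sprintf("%s%02d", LETTERS[m], seq_len(sizes[m]))))
  groups <- rep(seq_along(sizes), sizes)
  edges <- do.call(rbind, lapply(seq_along(sizes), function(m) {
    mem <- nodes[groups == m]
    p <- t(combn(mem, 2))
    data.frame(disease_i = p[, 1], disease_j = p[, 2], weight = weight)
  }))
  if (bridge)
    edges <- rbind(edges, data.frame(disease_i = nodes[groups == 1][1],
                                     disease_j = nodes[groups == 2][1],
                                     weight = weight))
  make_network(edges)
}

test_that("modularity closed forms hold", {
  net <- clique_network(c(4, 4))
  nodes <- net$nodes
  one <- stats::setNames(rep(0L, length(nodes)), nodes)
  expect_equal(modularity_q(net, one), 0)
  cliques <- stats::setNames(as.integer(substr(nodes, 1, 1) == "B"), nodes)
  expect_equal(modularity_q(net, cliques), 0.5)  # two disjoint K4s
  expect_error(modularity_q(net, one[-1]), "missing node")
})

test_that("modularity matches the brute-force formula on random inputs", {
  withr::with_seed(3, {
    for (g in 1:40) {
      net <- random_network(sample(4:12, 1), runif(1, 0.2, 0.8),
                            seed = 500 + g, max_weight = 5L)
      n <- length(net$nodes)
      part <- stats::setNames(sample(0:2, n, replace = TRUE), net$nodes)
      for (weighted in c(TRUE, FALSE)) {
        e <- net$edges
        w <- if (weighted) e$weight else rep(1, nrow(e))
        W <- sum(w)
        ci <- part[e$disease_i]; cj <- part[e$disease_j]
        q_brute <- 0
        for (c in unique(part)) {
          win <- sum(w[ci == c & cj == c])
          s <- sum(w[ci == c]) + sum(w[cj == c])
          q_brute <- q_brute + win / W - (s / (2 * W))^2
        }
        expect_equal(modularity_q(net, part, weighted = weighted), q_brute,
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("modularity stays within its bounds on random partitions", {
  withr::with_seed(8, {
    for (g in 1:200) {
      net <- random_network(sample(4:10, 1), runif(1, 0.2, 0.9),
                            seed = 2000 + g, max_weight = 4L)
      part <- stats::setNames(
        sample(0:3, length(net$nodes), replace = TRUE), net$nodes)
      q <- modularity_q(net, part)
      expect_gte(q, -0.5)
      expect_lte(q, 1)
    }
  })
})

test_that("louvain recovers two cliques joined by one edge", {
  net <- clique_network(c(5, 5), bridge = TRUE)
  part <- louvain(net, seed = 4)
  expect_equal(part$n_communities, 2L)
  truth <- substr(names(part$assignment), 1, 1)
  expect_equal(adjusted_rand_index(part$assignment,
                                   stats::setNames(truth, names(part$assignment))), 1)
  # returned Q is the modularity of the returned assignment
  expect_equal(part$modularity_q, modularity_q(net, part$assignment))
})

test_that("louvain output is deterministic and Q beats the singleton split", {
  net <- random_network(40, 0.15, seed = 91, max_weight = 10L)
  p1 <- louvain(net, seed = 6)
  p2 <- louvain(net, seed = 6)
  expect_identical(p1$assignment, p2$assignment)
  singletons <- stats::setNames(seq_along(net$nodes) - 1L, net$nodes)
  expect_gte(p1$modularity_q, modularity_q(net, singletons))
  expect_gte(p1$modularity_q, 0)
  # ids are contiguous from 0
  expect_equal(sort(unique(unname(p1$assignment))),
               0:(p1$n_communities - 1L))
})

test_that("node relabeling permutes but does not change the partition", {
  net <- random_network(20, 0.25, seed = 55, max_weight = 3L)
  part <- louvain(net, seed = 2)
  relab <- stats::setNames(sprintf("Q%02d", seq_along(net$nodes)), net$nodes)
  net2 <- make_network(data.frame(disease_i = relab[net$edges$disease_i],
                                  disease_j = relab[net$edges$disease_j],
                                  weight = net$edges$weight))
  part2 <- louvain(net2, seed = 2)
  a1 <- part$assignment[net$nodes]
  a2 <- part2$assignment[relab[net$nodes]]
  expect_equal(adjusted_rand_index(unname(a1), unname(a2)), 1)
})

test_that("adjusted Rand index behaves as a chance-corrected agreement", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, c(9, 9, 4, 4, 7, 7)), 1)  # relabeled
  b <- withr::with_seed(1, sample(1:3, 600, replace = TRUE))
  b2 <- withr::with_seed(2, sample(1:3, 600, replace = TRUE))
  expect_lt(abs(adjusted_rand_index(b, b2)), 0.05)  # independent labelings
  expect_error(adjusted_rand_index(1:3, 1:4), "same elements")
})

test_that("community composition counts chapters and flags unknowns", {
  part <- structure(list(
    assignment = stats::setNames(c(rep(0L, 10), rep(1L, 4)),
                                 c(sprintf("H%03d", 1:10),
                                   sprintf("I%03d", 1:4))),
    modularity_q = 0.3, n_communities = 2L), class = "community_partition")
  comp <- community_composition(part)
  expect_equal(comp$dominant$chapter, c("H", "I"))
  expect_equal(comp$dominant$fraction, c(1, 1))
  expect_equal(comp$table[, sum(fraction), by = community]$V1, c(1, 1))
  # the 157-of-210 composition reproduces its printed fraction
  part2 <- structure(list(
    assignment = stats::setNames(rep(0L, 210),
                                 c(sprintf("H%03d", 1:157),
                                   sprintf("X%03d", 1:53))),
    modularity_q = 0, n_communities = 1L), class = "community_partition")
  comp2 <- community_composition(part2)
  expect_equal(comp2$dominant$chapter, "H")
  expect_equal(round(comp2$dominant$fraction, 3), 0.748)
  # unmapped nodes fall into UNKNOWN with a warning
  cm <- stats::setNames(rep("H", 9), sprintf("H%03d", 1:9))
  expect_warning(comp3 <- community_composition(part2, cm), "UNKNOWN")
  expect_true("UNKNOWN" %in% comp3$table$chapter)
})
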