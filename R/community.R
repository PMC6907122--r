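#' Newman-Girvan modularity of a partition
#'
#' `Q = sum_c [ w_in(c)/W - (S_c / 2W)^2 ]` with `W` the total edge weight,
#' `w_in(c)` the weight inside community `c` and `S_c` the summed (weighted)
#' degree of its nodes. Unweighted mode sets all edge weights to 1. `Q = 0`
#' for an edgeless network.
#'
#' @param network a `comorbidity_network`.
#' @param assignment community ids, either named by node code or in the
#'   order of `network$nodes`; must cover every node.
#' @param weighted use co-occurrence edge weights (default) or unit weights.
#' @param resolution resolution parameter (1 = plain modularity).
#' @return modularity Q.
#' @export
modularity_q <- function(network, assignment, weighted = TRUE,
                         resolution = 1) {
  stopifnot(inherits(network, "comorbidity_network"))
  nodes <- network$nodes
  if (!is.null(names(assignment))) {
    missing_nodes <- setdiff(nodes, names(assignment))
    if (length(missing_nodes))
      stop_bad_arg("assignment missing node(s): ",
                   paste(head(missing_nodes, 5), collapse = ", "))
    assignment <- assignment[nodes]
  } else if (length(assignment) != length(nodes)) {
    stop_bad_arg("unnamed assignment must have one entry per node")
  }
  e <- network$edges
  w <- if (weighted) as.numeric(e$weight) else rep(1, nrow(e))
  W <- sum(w)
  if (W == 0) return(0)
  ci <- assignment[match(e$disease_i, nodes)]
  cj <- assignment[match(e$disease_j, nodes)]
  w_in <- tapply(w[ci == cj], ci[ci == cj], sum)
  strength <- tapply(c(w, w), c(ci, cj), sum)
  q_in <- sum(w_in) / W
  q_exp <- sum((resolution * (strength / (2 * W))^2))
  # communities with no internal weight still contribute their expectation
  q_in - q_exp
}

# one local-moving level of the BGLL loop; adj is a list of
# list(nb = integer neighbors, w = weights), self = self-loop weights;
# init optionally seeds the starting communities (for refinement cycles)
louvain_one_level <- function(adj, self, resolution, init = NULL) {
  n <- length(adj)
  k <- vapply(adj, function(a) sum(a$w), 0) + 2 * self
  m2 <- sum(k)
  comm <- init %||% seq_len(n)
  sigma_tot <- vapply(seq_len(n), function(c) sum(k[comm == c]), 0)
  visit <- sample.int(n)
  any_move <- FALSE
  repeat {
    moved <- FALSE
    for (i in visit) {
      c_old <- comm[i]
      nb <- adj[[i]]$nb
      if (length(nb) == 0L) next
      nbc <- comm[nb]
      w_ic <- tapply(adj[[i]]$w, nbc, sum)
      cand <- as.integer(names(w_ic))
      sigma_tot[c_old] <- sigma_tot[c_old] - k[i]
      gain <- as.numeric(w_ic) - resolution * sigma_tot[cand] * k[i] / m2
      stay <- if (c_old %in% cand) gain[cand == c_old] else
        -resolution * sigma_tot[c_old] * k[i] / m2
      best <- which.max(gain)  # first max in increasing community-id order
      if (gain[best] > stay + 1e-12) {
        comm[i] <- cand[best]
        sigma_tot[cand[best]] <- sigma_tot[cand[best]] + k[i]
        moved <- TRUE
        any_move <- TRUE
      } else {
        sigma_tot[c_old] <- sigma_tot[c_old] + k[i]
      }
    }
    if (!moved) break
  }
  list(comm = match(comm, sort(unique(comm))), any_move = any_move)
}

#' Louvain (BGLL) community detection
#'
#' The two-phase multi-level greedy modularity optimisation: local node moves
#' maximizing the modularity gain until no move helps, then aggregation of
#' communities into super-nodes, repeated until the partition stabilises.
#' Node visit order is shuffled from `seed`, making the result deterministic
#' given the seed. Ties and the move acceptance use the first-encountered
#' best community in increasing community-id order.
#'
#' Because the local-moving phase is greedy, small graphs can stall in local
#' optima; the optimiser therefore runs `restarts` independent multi-level
#' passes (visit orders drawn from sub-seeds of `seed`) and returns the
#' partition with the best modularity.
#'
#' @param network a `comorbidity_network`.
#' @param seed integer seed for the visit-order shuffles.
#' @param weighted optimise weighted modularity (default) or unweighted.
#' @param resolution resolution parameter (1 = plain BGLL).
#' @param restarts number of independent greedy runs; the best is kept.
#' @return an object of class `community_partition`: list with `assignment`
#'   (named integer, community ids contiguous from 0), `modularity_q`
#'   (equal to [modularity_q()] of the returned assignment) and
#'   `n_communities`.
#' @export
louvain <- function(network, seed = 1L, weighted = TRUE, resolution = 1,
                    restarts = 5L) {
  stopifnot(inherits(network, "comorbidity_network"))
  nodes <- network$nodes
  n <- length(nodes)
  if (n == 0L) stop_bad_arg("network has no nodes")
  e <- network$edges
  ei <- match(e$disease_i, nodes)
  ej <- match(e$disease_j, nodes)
  w <- if (weighted) as.numeric(e$weight) else rep(1, nrow(e))

  best <- NULL
  for (r in seq_len(check_count(restarts, "restarts"))) {
    membership <- louvain_multilevel(n, ei, ej, w, resolution,
                                     derive_seed(seed, paste0("louvain", r)))
    assignment <- stats::setNames(membership, nodes)
    assignment[] <- match(assignment, sort(unique(assignment))) - 1L
    q <- modularity_q(network, assignment, weighted = weighted,
                      resolution = 1)
    if (is.null(best) || q > best$modularity_q + 1e-12)
      best <- list(assignment = assignment, modularity_q = q,
                   n_communities = length(unique(assignment)))
  }
  structure(best, class = "community_partition")
}

build_adjacency <- function(n, ei, ej, w) {
  adj <- rep(list(list(nb = integer(0), w = numeric(0))), n)
  for (node in seq_len(n)) {
    sel_i <- ei == node
    sel_j <- ej == node
    adj[[node]] <- list(nb = c(ej[sel_i], ei[sel_j]),
                        w = c(w[sel_i], w[sel_j]))
  }
  adj
}

# aggregate an edge list by a community assignment; returns the super-node
# edge list plus per-node self-loop weights (within-community weight)
aggregate_graph <- function(ei, ej, w, self, comm) {
  ci <- comm[ei]; cj <- comm[ej]
  n_new <- max(comm)
  self_new <- rep(0, n_new)
  within <- ci == cj
  if (any(within)) {
    s <- tapply(w[within], ci[within], sum)
    self_new[as.integer(names(s))] <- as.numeric(s)
  }
  old_self <- tapply(self, comm, sum)
  self_new[as.integer(names(old_self))] <-
    self_new[as.integer(names(old_self))] + as.numeric(old_self)
  if (any(!within)) {
    a <- pmin(ci[!within], cj[!within])
    b <- pmax(ci[!within], cj[!within])
    agg <- data.table(i = a, j = b, w = w[!within])[, .(w = sum(w)),
                                                   by = .(i, j)]
    list(ei = agg$i, ej = agg$j, w = agg$w, self = self_new, n = n_new)
  } else {
    list(ei = integer(0), ej = integer(0), w = numeric(0),
         self = self_new, n = n_new)
  }
}

louvain_q <- function(ei, ej, w, comm, resolution) {
  W <- sum(w)
  if (W == 0) return(0)
  strength <- vapply(seq_len(max(comm)), function(c)
    sum(w[comm[ei] == c]) + sum(w[comm[ej] == c]), 0)
  sum(w[comm[ei] == comm[ej]]) / W -
    resolution * sum((strength / (2 * W))^2)
}

# one full multi-level greedy optimisation with iterated refinement: after
# each multi-level pass the node-level moving phase is re-run initialized
# from the final partition (single-node defections that aggregation locked
# in become possible), cycling while modularity improves
louvain_multilevel <- function(n, ei, ej, w, resolution, seed) {
  adj0 <- build_adjacency(n, ei, ej, w)
  zeros <- rep(0, n)
  membership <- seq_len(n)
  q_cur <- -Inf
  withr::with_seed(seed, {
    for (cycle in 1:20) {
      # phase A: node-level moves on the original graph from the current
      # partition (first cycle: singletons)
      lv <- louvain_one_level(adj0, zeros, resolution, init = membership)
      mem <- lv$comm
      # phase B: aggregate and optimise upward
      g <- aggregate_graph(ei, ej, w, zeros, mem)
      repeat {
        if (g$n <= 1L) break
        adj <- build_adjacency(g$n, g$ei, g$ej, g$w)
        lv2 <- louvain_one_level(adj, g$self, resolution)
        if (!lv2$any_move) break
        mem <- lv2$comm[mem]
        n_before <- g$n
        g <- aggregate_graph(g$ei, g$ej, g$w, g$self, lv2$comm)
        if (g$n == n_before) break
      }
      q_new <- louvain_q(ei, ej, w, mem, resolution)
      if (q_new <= q_cur + 1e-12) break
      q_cur <- q_new
      membership <- mem
    }
  })
  membership
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d communities, Q = %.4f\n",
              x$n_communities, x$modularity_q))
  invisible(x)
}

#' Community composition by ICD chapter
#'
#' Cross-tabulates each community against disease "chapters" (by default the
#' leading letter of the ICD code), reporting counts, fractions and the
#' dominant chapter per community.
#'
#' @param partition a `community_partition`.
#' @param chapter_map optional named character vector mapping node codes to
#'   chapters; unmapped nodes are assigned `"UNKNOWN"` with a warning.
#' @return list with `table` (`data.table`: `community`, `chapter`, `count`,
#'   `fraction`) and `dominant` (`data.table`: `community`, `chapter`,
#'   `fraction`, `size`).
#' @export
community_composition <- function(partition, chapter_map = NULL) {
  stopifnot(inherits(partition, "community_partition"))
  codes <- names(partition$assignment)
  if (is.null(chapter_map)) {
    chapters <- substr(codes, 1L, 1L)
  } else {
    chapters <- unname(chapter_map[codes])
    if (anyNA(chapters)) {
      warning(sprintf("%d node(s) missing from chapter_map; assigned UNKNOWN",
                      sum(is.na(chapters))))
      chapters[is.na(chapters)] <- "UNKNOWN"
    }
  }
  dt <- data.table(community = unname(partition$assignment),
                   chapter = chapters)
  tab <- dt[, .(count = .N), by = .(community, chapter)]
  tab[, fraction := count / sum(count), by = community]
  setorder(tab, community, -count, chapter)
  dominant <- tab[, .SD[1], by = community][
    , .(community, chapter, fraction, size = NA_integer_)]
  sizes <- dt[, .N, by = community]
  dominant[, size := sizes$N[match(community, sizes$community)]]
  list(table = tab[], dominant = dominant[])
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same elements;
#' 1 for identical partitions (up to label permutation), about 0 for
#' independent ones.
#'
#' @param a,b label vectors of equal length (named vectors are aligned on
#'   their common names).
#' @return the ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    a <- a[common]; b <- b[common]
  }
  if (length(a) != length(b))
    stop_bad_arg("partitions must label the same elements")
  tab <- table(a, b)
  comb2 <- function(x) sum(x * (x - 1) / 2)
  sum_ij <- comb2(tab)
  sum_a <- comb2(rowSums(tab))
  sum_b <- comb2(colSums(tab))
  n <- length(a)
  expected <- sum_a * sum_b / (n * (n - 1) / 2)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1)
  (sum_ij - expected) / denom
}
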