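# Independent brute-force oracles. These deliberately avoid the package's
# code paths (double loops, Floyd-Warshall, exhaustive enumeration) so that
# agreement is a real cross-check, not a tautology.

# patient-level contingency counts by double loop over patient disease sets
oracle_pair_counts <- function(disease_sets) {
  n <- length(disease_sets)
  diseases <- sort(unique(unlist(disease_sets)))
  prev <- sapply(diseases, function(d)
    sum(vapply(disease_sets, function(s) d %in% s, logical(1))))
  out <- list()
  for (a in seq_along(diseases)) {
    for (b in seq_len(a - 1L)) {
      i <- diseases[b]; j <- diseases[a]
      cij <- sum(vapply(disease_sets, function(s)
        i %in% s && j %in% s, logical(1)))
      out[[length(out) + 1L]] <- data.frame(
        disease_i = i, disease_j = j, c_ij = cij,
        p_i = prev[[i]], p_j = prev[[j]], n = n)
    }
  }
  do.call(rbind, out)
}

# phi via Pearson correlation of expanded binary indicator vectors
oracle_phi_indicator <- function(c_ij, p_i, p_j, n) {
  xi <- c(rep(1, c_ij), rep(1, p_i - c_ij), rep(0, p_j - c_ij),
          rep(0, n - p_i - p_j + c_ij))
  xj <- c(rep(1, c_ij), rep(0, p_i - c_ij), rep(1, p_j - c_ij),
          rep(0, n - p_i - p_j + c_ij))
  cor(xi, xj)
}

# random valid contingency table (both prevalences strictly inside (0, n))
random_contingency <- function(n_max = 500) {
  n <- sample(20:n_max, 1)
  p_i <- sample(seq_len(n - 1), 1)
  p_j <- sample(seq_len(n - 1), 1)
  c_lo <- max(0, p_i + p_j - n)
  c_hi <- min(p_i, p_j)
  c_ij <- sample(seq(c_lo, c_hi), 1)
  list(c_ij = c_ij, p_i = p_i, p_j = p_j, n = n)
}

# --- graph oracles (adjacency matrix input, 0/1) --------------------------

# all-pairs shortest-path distances (Floyd-Warshall) and path counts
# (distance-layered DP: sigma[s,t] sums sigma[s,u] over predecessors u of t)
oracle_paths <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj > 0, 1, Inf); diag(d) <- 0
  for (k in seq_len(n)) {
    alt <- outer(d[, k], d[k, ], `+`)
    d <- pmin(d, alt)
  }
  sig <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sig[s, s] <- 1
    reach <- which(is.finite(d[s, ]) & d[s, ] > 0)
    for (t in reach[order(d[s, reach])]) {
      pred <- which(adj[, t] > 0 & d[s, ] == d[s, t] - 1)
      sig[s, t] <- sum(sig[s, pred])
    }
  }
  list(d = d, sigma = sig)
}

oracle_topology <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  # clustering: triangles / choose(deg, 2)
  cc1 <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] > 0)
    if (length(nb) < 2) return(0)
    tri <- sum(adj[nb, nb, drop = FALSE]) / 2
    tri / choose(length(nb), 2)
  }, numeric(1))
  pc <- oracle_paths(adj)
  d <- pc$d; sig <- pc$sigma
  # betweenness via pair-dependency sums, normalized by (n-1)(n-2)/2
  btw <- vapply(seq_len(n), function(v) {
    tot <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s >= t || s == v || t == v) next
      if (!is.finite(d[s, t]) || sig[s, t] == 0) next
      if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t])
        tot <- tot + sig[s, v] * sig[v, t] / sig[s, t]
    }
    tot
  }, numeric(1))
  if (n > 2) btw <- btw / ((n - 1) * (n - 2) / 2)
  # closeness within components: (n_c - 1) / sum of distances
  cc2 <- vapply(seq_len(n), function(v) {
    reach <- which(is.finite(d[v, ]) & seq_len(n) != v)
    if (!length(reach)) return(0)
    length(reach) / sum(d[v, reach])
  }, numeric(1))
  finite <- is.finite(d) & d > 0
  apl <- if (any(finite)) mean(d[finite]) else NA_real_
  list(degree = deg, betweenness = btw, clustering = cc1, closeness = cc2,
       average_path_length = apl)
}

# --- partitions -----------------------------------------------------------

# all set partitions of n elements as restricted-growth strings
oracle_all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxid) {
    k <- length(prefix)
    if (k == n) { out[[length(out) + 1L]] <<- prefix; return(invisible()) }
    for (g in seq_len(maxid + 1L)) rec(c(prefix, g), max(maxid, g))
  }
  rec(integer(0), 0L)
  out
}

oracle_best_modularity <- function(net, weighted = TRUE) {
  n <- length(net$nodes)
  parts <- oracle_all_partitions(n)
  e <- net$edges
  w <- if (weighted) as.numeric(e$weight) else rep(1, nrow(e))
  W <- sum(w)
  ei <- match(e$disease_i, net$nodes)
  ej <- match(e$disease_j, net$nodes)
  best <- -Inf
  for (p in parts) {
    win <- sum(w[p[ei] == p[ej]])
    s <- vapply(seq_len(max(p)), function(c)
      sum(w[p[ei] == c]) + sum(w[p[ej] == c]), numeric(1))
    q <- win / W - sum((s / (2 * W))^2)
    if (q > best) best <- q
  }
  best
}

# --- misc -----------------------------------------------------------------

# comorbidity_network from a plain edge data.frame
make_network <- function(edges, n_patients = NA_integer_) {
  ed <- data.table::as.data.table(edges)
  if (!"weight" %in% names(ed)) ed[, weight := 1]
  if (!"rr" %in% names(ed)) ed[, rr := 2]
  if (!"phi" %in% names(ed)) ed[, phi := 0.1]
  sw <- ed$disease_i > ed$disease_j
  tmp <- ed$disease_i[sw]
  ed$disease_i[sw] <- ed$disease_j[sw]
  ed$disease_j[sw] <- tmp
  data.table::setorder(ed, disease_i, disease_j)
  structure(list(edges = ed,
                 nodes = sort(unique(c(ed$disease_i, ed$disease_j))),
                 n_patients = n_patients),
            class = "comorbidity_network")
}

# Erdos-Renyi comorbidity_network with integer weights
random_network <- function(n, p, seed, max_weight = 1L) {
  withr::with_seed(seed, {
    nodes <- sprintf("N%02d", seq_len(n))
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < p
    if (!any(keep)) keep[sample(nrow(pairs), 1)] <- TRUE
    make_network(data.frame(disease_i = pairs[keep, 1],
                            disease_j = pairs[keep, 2],
                            weight = sample(seq_len(max_weight),
                                            sum(keep), replace = TRUE)))
  })
}

adjacency_of <- function(net) {
  n <- length(net$nodes)
  adj <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  for (r in seq_len(nrow(net$edges)))
    adj[net$edges$disease_i[r], net$edges$disease_j[r]] <-
      adj[net$edges$disease_j[r], net$edges$disease_i[r]] <- 1
  adj
}

records_from_sets <- function(disease_sets) {
  # one visit per patient is enough for patient-level statistics
  data.table::data.table(
    patient_id = rep(sprintf("P%03d", seq_along(disease_sets)),
                     lengths(disease_sets)),
    visit_index = 1L,
    code = unlist(disease_sets, use.names = FALSE))
}
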