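#' Node centralities and global summaries of a comorbidity network
#'
#' Computes, on the unweighted thresholded graph: degree, betweenness
#' centrality normalized by `(n-1)(n-2)/2`, local clustering coefficient
#' (CC1; 0 for nodes of degree < 2), and closeness centrality (CC2) computed
#' within each connected component as `(n_c - 1) / sum(d)` (0 for isolated
#' nodes). Global summaries: node and edge counts, average degree
#' `2|E|/|V|`, average path length over connected pairs, and average CC1.
#'
#' Edge weights are deliberately ignored here (they remain available as edge
#' attributes): the reported clustering/betweenness conventions are the
#' unweighted ones.
#'
#' @param network a `comorbidity_network` or an igraph graph.
#' @return an object of class `topology_profile`: list with `nodes` (a
#'   `data.table` of per-node measures) and `summary`.
#' @export
compute_topology <- function(network) {
  g <- if (inherits(network, "comorbidity_network")) as_igraph(network)
       else network
  n <- igraph::vcount(g)
  if (n < 1L) stop_bad_arg("network must have at least one node")

  deg <- igraph::degree(g)
  btw <- if (n > 2) igraph::betweenness(g, directed = FALSE, weights = NA,
                                        normalized = TRUE)
         else rep(0, n)
  cc1 <- igraph::transitivity(g, type = "local", isolates = "zero",
                              weights = NA)

  # per-component closeness and path length over connected pairs
  d <- igraph::distances(g, weights = NA)
  finite <- is.finite(d) & d > 0
  d_fin <- d
  d_fin[!finite] <- 0  # Inf * FALSE would be NaN, zero the masked cells
  rows_sum <- rowSums(d_fin)
  reach <- rowSums(finite)
  cc2 <- ifelse(reach > 0, reach / rows_sum, 0)  # (n_c - 1) / sum(d)
  apl <- if (any(finite)) sum(d[finite]) / sum(finite) else NA_real_

  nodes <- data.table(code = igraph::V(g)$name, degree = as.integer(deg),
                      betweenness = as.numeric(btw),
                      clustering = as.numeric(cc1),
                      closeness = as.numeric(cc2))
  setorder(nodes, code)
  structure(list(
    nodes = nodes,
    summary = list(n_nodes = n, n_edges = igraph::ecount(g),
                   average_degree = 2 * igraph::ecount(g) / n,
                   average_path_length = apl,
                   average_clustering = mean(nodes$clustering))
  ), class = "topology_profile")
}

#' @export
print.topology_profile <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<topology_profile> %d nodes, %d edges, <k> = %.3f, ",
                     "<CC1> = %.3f, <path> = %.3f\n"),
              s$n_nodes, s$n_edges, s$average_degree, s$average_clustering,
              s$average_path_length))
  invisible(x)
}

log_binned_slope <- function(values) {
  values <- values[values > 0]
  if (length(values) < 2L || length(unique(values)) < 2L)
    return(list(slope = NA_real_, flagged = TRUE))
  edges <- 2^(0:ceiling(log2(max(values)) + 1))
  h <- graphics::hist(values, breaks = edges, plot = FALSE, right = FALSE)
  dens <- h$counts / diff(edges)          # counts per unit width
  keep <- dens > 0
  if (sum(keep) < 2L) return(list(slope = NA_real_, flagged = TRUE))
  fit <- stats::lm(log10(dens[keep]) ~ log10(h$mids[keep]))
  list(slope = unname(stats::coef(fit)[2]), flagged = FALSE)
}

#' Degree and edge-weight distributions with heavy-tail diagnostics
#'
#' Raw histograms plus a least-squares slope fitted to log-binned log-log
#' data. The slope is a qualitative heavy-tail diagnostic (a markedly
#' negative slope over decades is consistent with a scale-free degree
#' distribution), not a formal power-law fit.
#'
#' @param network a `comorbidity_network`.
#' @return list with `degree_histogram`, `weight_histogram` (tables) and
#'   `degree_slope`, `weight_slope` (each a list `slope`, `flagged`;
#'   `flagged = TRUE` marks a degenerate distribution with undefined slope).
#' @export
degree_and_weight_distributions <- function(network) {
  stopifnot(inherits(network, "comorbidity_network"))
  g <- as_igraph(network)
  deg <- igraph::degree(g)
  w <- network$edges$weight
  list(degree_histogram = table(deg),
       weight_histogram = table(w),
       degree_slope = log_binned_slope(deg),
       weight_slope = log_binned_slope(w))
}

topology_measure_pairs <- list(
  c("degree", "clustering"), c("closeness", "clustering"),
  c("degree", "closeness"), c("betweenness", "closeness"),
  c("degree", "betweenness"), c("clustering", "betweenness"))

#' Correlations between topological measures
#'
#' Pearson correlation (with two-sided t-test p-value) across nodes for the
#' six pairs of measures: degree/CC1, CC2/CC1, degree/CC2, BC/CC2, degree/BC
#' and CC1/BC. A strongly negative degree/CC1 correlation is the signature of
#' hierarchical modularity.
#'
#' @param profile a `topology_profile` from [compute_topology()].
#' @return `data.table` with columns `measure_x`, `measure_y`, `pcc`,
#'   `p_value`; zero-variance measures yield `NA` rows (with a warning).
#' @export
measure_correlations <- function(profile) {
  stopifnot(inherits(profile, "topology_profile"))
  nd <- profile$nodes
  if (nrow(nd) < 3L) stop_bad_arg("need at least 3 nodes for correlations")
  res <- lapply(topology_measure_pairs, function(pr) {
    x <- nd[[pr[1]]]; y <- nd[[pr[2]]]
    if (sd(x) == 0 || sd(y) == 0) {
      warning(sprintf("zero variance in %s/%s; correlation undefined",
                      pr[1], pr[2]))
      return(data.table(measure_x = pr[1], measure_y = pr[2],
                        pcc = NA_real_, p_value = NA_real_))
    }
    ct <- cor.test(x, y, method = "pearson")
    data.table(measure_x = pr[1], measure_y = pr[2],
               pcc = unname(ct$estimate), p_value = ct$p.value)
  })
  rbindlist(res)
}

#' Top-k nodes by a topological measure
#'
#' @param profile a `topology_profile`.
#' @param measure one of `"degree"`, `"betweenness"`, `"clustering"`,
#'   `"closeness"`.
#' @param k number of nodes to return; descending by measure, ties broken
#'   lexicographically by code.
#' @return `data.table` with columns `code` and the measure.
#' @export
top_k_nodes <- function(profile, measure = "degree", k = 10L) {
  stopifnot(inherits(profile, "topology_profile"))
  measure <- match.arg(measure, c("degree", "betweenness", "clustering",
                                  "closeness"))
  k <- check_count(k, "k")
  nd <- profile$nodes
  if (k > nrow(nd)) {
    warning(sprintf("k = %d exceeds node count %d; returning all", k, nrow(nd)))
    k <- nrow(nd)
  }
  ord <- order(-nd[[measure]], nd$code)
  keep <- c("code", measure)
  nd[ord[seq_len(k)], ..keep]
}
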