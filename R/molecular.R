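#' Shared-gene and shared-pathway overlap statistics for disease pairs
#'
#' For each pair: intersection counts plus Jaccard (`|A∩B|/|A∪B|`) and
#' set-cosine (`|A∩B|/sqrt(|A||B|)`) similarities, for genes and pathways.
#' Pairs whose diseases lack molecular annotations are skipped (their number
#' is recorded in the `"n_skipped"` attribute). Similarities involving two
#' empty sets are defined as 0.
#'
#' @param pairs a `pair_statistics` table (or any table with `disease_i`,
#'   `disease_j` columns).
#' @param disease_genes named list of gene sets per disease.
#' @param disease_pathways named list of pathway sets per disease.
#' @return `data.table` with one row per retained pair: `disease_i`,
#'   `disease_j`, `shared_genes`, `shared_pathways`, `jaccard_genes`,
#'   `cosine_genes`, `jaccard_pathways`, `cosine_pathways`.
#' @export
overlap_statistics <- function(pairs, disease_genes, disease_pathways) {
  dt <- as.data.table(pairs)[, .(disease_i, disease_j)]
  known <- names(disease_genes)
  keep <- dt$disease_i %in% known & dt$disease_j %in% known
  n_skipped <- sum(!keep)
  dt <- dt[keep]
  if (nrow(dt) == 0L) {
    dt[, `:=`(shared_genes = integer(0), shared_pathways = integer(0),
              jaccard_genes = numeric(0), cosine_genes = numeric(0),
              jaccard_pathways = numeric(0), cosine_pathways = numeric(0))]
    setattr(dt, "n_skipped", n_skipped)
    return(dt[])
  }
  sim <- function(a, b) {
    inter <- length(intersect(a, b))
    un <- length(union(a, b))
    c(inter,
      if (un == 0) 0 else inter / un,
      if (length(a) == 0 || length(b) == 0) 0
      else inter / sqrt(length(a) * length(b)))
  }
  g <- mapply(function(i, j) sim(disease_genes[[i]], disease_genes[[j]]),
              dt$disease_i, dt$disease_j)
  p <- mapply(function(i, j) sim(disease_pathways[[i]] %||% character(0),
                                 disease_pathways[[j]] %||% character(0)),
              dt$disease_i, dt$disease_j)
  dt[, `:=`(shared_genes = as.integer(g[1, ]), jaccard_genes = g[2, ],
            cosine_genes = g[3, ],
            shared_pathways = as.integer(p[1, ]), jaccard_pathways = p[2, ],
            cosine_pathways = p[3, ])]
  setcolorder(dt, c("disease_i", "disease_j", "shared_genes",
                    "shared_pathways", "jaccard_genes", "cosine_genes",
                    "jaccard_pathways", "cosine_pathways"))
  setattr(dt, "n_skipped", n_skipped)
  dt[]
}

pcc_row <- function(x, y, label_x, label_y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || sd(x) == 0 || sd(y) == 0) {
    warning(sprintf("zero variance or too few pairs for %s vs %s",
                    label_x, label_y))
    return(data.table(comorbidity = label_x, molecular = label_y,
                      pcc = NA_real_, p_value = NA_real_,
                      n = length(x)))
  }
  ct <- cor.test(x, y, method = "pearson")
  data.table(comorbidity = label_x, molecular = label_y,
             pcc = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Correlate comorbidity strength with shared molecular mechanisms
#'
#' Pearson correlations (two-sided t-test p-values) between comorbidity
#' strength (RR and phi) and shared gene/pathway counts, and between the
#' Jaccard/Cosine similarities and shared counts. By default all pairs with
#' computed statistics and molecular coverage are used; pass the edge table
#' of a thresholded network as `pairs` to restrict to network edges.
#'
#' @param pair_stats a `pair_statistics` table.
#' @param overlaps output of [overlap_statistics()] for (a superset of) the
#'   same pairs.
#' @param bin_edges passed to [binned_strength_curve()].
#' @return list of class `validation_report` with `correlations`
#'   (`data.table`: `comorbidity`, `molecular`, `pcc`, `p_value`, `n`),
#'   `gene_bins` and `pathway_bins` (binned strength tables).
#' @export
correlate_comorbidity_with_molecular <- function(pair_stats, overlaps,
                                                 bin_edges = c(0, 1, 6, 11,
                                                               21, Inf)) {
  m <- merge(as.data.table(pair_stats), as.data.table(overlaps),
             by = c("disease_i", "disease_j"))
  if (nrow(m) < 3L) stop_bad_arg("need at least 3 pairs with both statistics")
  correlations <- rbindlist(list(
    pcc_row(m$rr, m$shared_genes, "rr", "shared_genes"),
    pcc_row(m$rr, m$shared_pathways, "rr", "shared_pathways"),
    pcc_row(m$phi, m$shared_genes, "phi", "shared_genes"),
    pcc_row(m$phi, m$shared_pathways, "phi", "shared_pathways"),
    pcc_row(m$jaccard_genes, m$shared_genes, "jaccard_genes", "shared_genes"),
    pcc_row(m$cosine_genes, m$shared_genes, "cosine_genes", "shared_genes"),
    pcc_row(m$jaccard_pathways, m$shared_pathways,
            "jaccard_pathways", "shared_pathways"),
    pcc_row(m$cosine_pathways, m$shared_pathways,
            "cosine_pathways", "shared_pathways")))
  structure(list(
    correlations = correlations,
    gene_bins = binned_strength_curve(pair_stats, overlaps,
                                      bin_edges = bin_edges, count = "genes"),
    pathway_bins = binned_strength_curve(pair_stats, overlaps,
                                         bin_edges = bin_edges,
                                         count = "pathways")
  ), class = "validation_report")
}

#' Mean comorbidity strength per shared-count bin
#'
#' Assigns each pair to a bin of its shared gene (or pathway) count — the
#' default edges `0, 1, 6, 11, 21, Inf` give bins `{0}`, `[1,5]`, `[6,10]`,
#' `[11,20]`, `[21,Inf)` — and reports the number of pairs and the mean RR
#' and phi per bin. Empty bins are reported with `n = 0` and `NA` means.
#'
#' @param pair_stats a `pair_statistics` table.
#' @param overlaps output of [overlap_statistics()].
#' @param bin_edges strictly increasing numeric vector starting at 0.
#' @param count `"genes"` or `"pathways"`.
#' @return `data.table` with columns `bin`, `n_pairs`, `mean_rr`, `mean_phi`.
#' @export
binned_strength_curve <- function(pair_stats, overlaps,
                                  bin_edges = c(0, 1, 6, 11, 21, Inf),
                                  count = c("genes", "pathways")) {
  count <- match.arg(count)
  if (is.unsorted(bin_edges, strictly = TRUE) || bin_edges[1] != 0)
    stop_bad_arg("`bin_edges` must be strictly increasing and start at 0")
  m <- merge(as.data.table(pair_stats), as.data.table(overlaps),
             by = c("disease_i", "disease_j"))
  x <- if (count == "genes") m$shared_genes else m$shared_pathways
  idx <- findInterval(x, bin_edges)  # edges define [e_k, e_{k+1}) bins
  labels <- vapply(seq_len(length(bin_edges) - 1), function(k) {
    lo <- bin_edges[k]; hi <- bin_edges[k + 1] - 1
    if (!is.finite(hi)) sprintf("[%g,Inf)", lo)
    else if (lo == hi) sprintf("{%g}", lo)
    else sprintf("[%g,%g]", lo, hi)
  }, character(1))
  out <- rbindlist(lapply(seq_along(labels), function(k) {
    sel <- idx == k
    data.table(bin = labels[k], n_pairs = sum(sel),
               mean_rr = if (any(sel)) mean(m$rr[sel]) else NA_real_,
               mean_phi = if (any(sel)) mean(m$phi[sel]) else NA_real_)
  }))
  out[]
}

#' Shared genes and pathways of one disease pair
#'
#' @param disease_a,disease_b disease codes (must be present in the maps).
#' @param maps list with `disease_genes` and `disease_pathways` (as from
#'   [read_molecular_tables()] or [link_maps()]).
#' @return list with sorted `shared_genes` and `shared_pathways` vectors.
#' @export
shared_gene_report <- function(disease_a, disease_b, maps) {
  for (d in c(disease_a, disease_b))
    if (!d %in% names(maps$disease_genes))
      stop_bad_arg("unknown disease: ", d)
  list(
    shared_genes = sort(intersect(maps$disease_genes[[disease_a]],
                                  maps$disease_genes[[disease_b]])),
    shared_pathways = sort(intersect(
      maps$disease_pathways[[disease_a]] %||% character(0),
      maps$disease_pathways[[disease_b]] %||% character(0)))
  )
}

#' Display a p-value with the conventional machine-precision floor
#'
#' @param p numeric p-value(s).
#' @return character, e.g. `"< 2.2e-16"` for values below the floor.
#' @export
format_p_value <- function(p) {
  ifelse(p < 2.2e-16, "< 2.2e-16", formatC(p, format = "g", digits = 4))
}
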