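#' Relative Risk of disease co-occurrence
#'
#' `RR = C_ij * N / (P_i * P_j)`: the ratio of observed patient-level
#' co-occurrence to its expectation under independence. Vectorized.
#'
#' @param c_ij number of patients carrying both diseases.
#' @param p_i,p_j number of patients carrying each disease (counts, not
#'   proportions).
#' @param n total number of patients.
#' @return numeric relative risk.
#' @export
relative_risk <- function(c_ij, p_i, p_j, n) {
  if (any(p_i <= 0) || any(p_j <= 0) || any(n <= 0))
    stop_bad_arg("relative risk requires P_i > 0, P_j > 0, N > 0")
  # double arithmetic: integer counts overflow at population scale
  as.numeric(c_ij) * as.numeric(n) / (as.numeric(p_i) * as.numeric(p_j))
}

#' Phi-correlation of disease co-occurrence
#'
#' The Pearson correlation of the two binary patient-indicator vectors:
#' `phi = (C_ij * N - P_i * P_j) / sqrt(P_i * P_j * (N - P_i) * (N - P_j))`.
#' The prevalences enter as patient counts, as the `(N - P_i)` terms require.
#'
#' `printed_formula = TRUE` selects the variant with numerator
#' `C_ij - P_i * P_j` that sometimes appears in print; it is dimensionally
#' inconsistent for count-valued prevalences (it breaks the equivalence with
#' the indicator-vector Pearson correlation and the premise that RR > 1 and
#' phi > 0 coincide) and is provided for compatibility only.
#'
#' @inheritParams relative_risk
#' @param printed_formula use the compatibility numerator (see Details).
#' @return numeric phi in `[-1, 1]` (default formula).
#' @export
phi_correlation <- function(c_ij, p_i, p_j, n, printed_formula = FALSE) {
  if (any(p_i <= 0) || any(p_i >= n) || any(p_j <= 0) || any(p_j >= n))
    stop_bad_arg("phi requires 0 < P_i < N and 0 < P_j < N (non-degenerate indicators)")
  c_ij <- as.numeric(c_ij); p_i <- as.numeric(p_i)
  p_j <- as.numeric(p_j); n <- as.numeric(n)
  num <- if (printed_formula) c_ij - p_i * p_j else c_ij * n - p_i * p_j
  num / sqrt(p_i * p_j * (n - p_i) * (n - p_j))
}

#' Patient-level contingency counts for all co-occurring disease pairs
#'
#' Each patient contributes at most 1 to `C_ij` and to each prevalence
#' `P_i`, regardless of how many visits carry the diagnosis (the per-patient
#' disease set is the union over visits). Counting is done through a sparse
#' patient-by-disease incidence matrix.
#'
#' @param x diagnosis records (as from [read_records()] /
#'   [generate_cohort()]) or [build_profiles()] output.
#' @param all_pairs if `TRUE`, materialize every disease pair with positive
#'   prevalences (including `C_ij = 0`); default materializes only pairs
#'   with `C_ij >= 1`.
#' @param n_patients total patient count `N`. Defaults to the generating
#'   configuration's patient count when `x` carries cohort metadata, and to
#'   the number of distinct patients observed otherwise (the only definition
#'   available for real record files, where diagnosis-free patients are
#'   invisible).
#' @return an object of class `pair_statistics`: a `data.table` with one row
#'   per pair, columns `disease_i < disease_j`, `c_ij`, `p_i`, `p_j`, `n`,
#'   `rr`, `phi`. Pairs where either disease has zero or full prevalence are
#'   skipped (their number is recorded in the `"n_degenerate"` attribute).
#' @export
count_contingency <- function(x, all_pairs = FALSE, n_patients = NULL) {
  if (inherits(x, "patient_profiles")) {
    sets <- x$disease_set
    pid <- rep(x$patient_id, lengths(sets))
    code <- unlist(sets, use.names = FALSE)
  } else {
    dt <- unique(as.data.table(x)[, .(patient_id, code)])
    pid <- dt$patient_id
    code <- dt$code
  }
  patients <- sort(unique(pid))
  diseases <- sort(unique(code))
  n <- n_patients %||% attr(x, "cohort_meta")$config$n_patients %||%
    length(patients)
  if (n < length(patients))
    stop_bad_arg("`n_patients` smaller than the number of observed patients")
  inc <- Matrix::sparseMatrix(i = match(pid, patients),
                              j = match(code, diseases),
                              x = 1, dims = c(length(patients),
                                              length(diseases)))
  prev <- Matrix::colSums(inc)
  co <- Matrix::crossprod(inc)  # disease x disease co-occurrence counts
  co <- as(Matrix::triu(co, k = 1), "TsparseMatrix")
  pairs <- data.table(i = co@i + 1L, j = co@j + 1L, c_ij = co@x)
  if (all_pairs) {
    all_ij <- CJ(i = seq_along(diseases), j = seq_along(diseases))[i < j]
    pairs <- merge(all_ij, pairs, by = c("i", "j"), all.x = TRUE)
    pairs[is.na(c_ij), c_ij := 0]
  }
  pairs[, `:=`(disease_i = diseases[i], disease_j = diseases[j],
               p_i = prev[i], p_j = prev[j], n = n)]
  degenerate <- pairs$p_i == 0 | pairs$p_i == n | pairs$p_j == 0 | pairs$p_j == n
  n_degenerate <- sum(degenerate)
  pairs <- pairs[!degenerate]
  pairs[, `:=`(rr = relative_risk(c_ij, p_i, p_j, n),
               phi = phi_correlation(c_ij, p_i, p_j, n))]
  out <- pairs[, .(disease_i, disease_j, c_ij, p_i, p_j, n, rr, phi)]
  setorder(out, disease_i, disease_j)
  setattr(out, "n_degenerate", n_degenerate)
  setattr(out, "class", c("pair_statistics", class(out)))
  out[]
}

#' Build the thresholded Disease Comorbidity Network
#'
#' Retains exactly the disease pairs with `C_ij > min_cooccurrence`,
#' `RR > min_rr` and `phi > min_phi` (strict inequalities, the construction
#' "co-occurrence > 5, RR > 1.0 and phi > 0.0"). Edge weight is the
#' co-occurrence count; RR and phi are kept as edge attributes. Nodes are the
#' diseases incident to at least one retained edge.
#'
#' @param pair_stats a `pair_statistics` table from [count_contingency()].
#' @param min_cooccurrence,min_rr,min_phi strict lower thresholds.
#' @param strict use strict inequalities (default); `FALSE` makes all three
#'   thresholds inclusive.
#' @return an object of class `comorbidity_network`: list with `edges`
#'   (`data.table`: `disease_i`, `disease_j`, `weight`, `rr`, `phi`),
#'   `nodes` (character) and `n_patients`.
#' @export
build_network <- function(pair_stats, min_cooccurrence = 5, min_rr = 1.0,
                          min_phi = 0.0, strict = TRUE) {
  ps <- as.data.table(pair_stats)
  keep <- if (strict)
    ps$c_ij > min_cooccurrence & ps$rr > min_rr & ps$phi > min_phi
  else
    ps$c_ij >= min_cooccurrence & ps$rr >= min_rr & ps$phi >= min_phi
  edges <- ps[keep, .(disease_i, disease_j, weight = c_ij, rr, phi)]
  setorder(edges, disease_i, disease_j)
  if (nrow(edges) == 0L)
    warning("no disease pair survives the thresholds; empty network")
  structure(list(
    edges = edges,
    nodes = sort(unique(c(edges$disease_i, edges$disease_j))),
    n_patients = if (nrow(ps)) ps$n[1] else NA_integer_
  ), class = "comorbidity_network")
}

#' @export
print.comorbidity_network <- function(x, ...) {
  cat(sprintf("<comorbidity_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Convert a comorbidity network to an igraph graph
#'
#' @param network a `comorbidity_network`.
#' @return an undirected igraph graph with `weight`, `rr`, `phi` edge
#'   attributes.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "comorbidity_network"))
  igraph::graph_from_data_frame(
    as.data.frame(network$edges), directed = FALSE,
    vertices = data.frame(name = network$nodes))
}

#' Export a comorbidity network to edge-list TSV or GraphML
#'
#' @param network a `comorbidity_network`.
#' @param path output path.
#' @param format `"tsv"` (edge list with header
#'   `disease_i disease_j weight rr phi`) or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "comorbidity_network"))
  if (format == "tsv") {
    data.table::fwrite(network$edges, path, sep = "\t")
  } else {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  }
  invisible(path)
}

#' Read a comorbidity network written by [export_network()]
#'
#' @param path input path.
#' @param format `"tsv"` or `"graphml"`.
#' @param n_patients optional patient count to restore on the object.
#' @return a `comorbidity_network`.
#' @export
read_network <- function(path, format = c("tsv", "graphml"),
                         n_patients = NA_integer_) {
  format <- match.arg(format)
  if (format == "tsv") {
    edges <- data.table::fread(path, sep = "\t", showProgress = FALSE,
                               colClasses = list(character = c("disease_i",
                                                               "disease_j")))
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_data_frame(g, what = "edges")
    edges <- data.table(disease_i = pmin(el$from, el$to),
                        disease_j = pmax(el$from, el$to),
                        weight = el$weight, rr = el$rr, phi = el$phi)
  }
  setorder(edges, disease_i, disease_j)
  structure(list(
    edges = edges,
    nodes = sort(unique(c(edges$disease_i, edges$disease_j))),
    n_patients = n_patients
  ), class = "comorbidity_network")
}
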