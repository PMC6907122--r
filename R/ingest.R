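#' Normalize ICD-10 codes to 4-character form
#'
#' Uppercases, removes dots, and truncates to at most 4 characters (the
#' "four-digit" ICD-10 granularity): `"I25.1"` becomes `"I251"`, `"E11.01"`
#' becomes `"E110"`. Codes shorter than 4 characters after dot removal are
#' kept as-is. Idempotent.
#'
#' @param x character vector of raw codes.
#' @return character vector of normalized codes.
#' @export
normalize_icd10 <- function(x) {
  x <- gsub(".", "", toupper(trimws(as.character(x))), fixed = TRUE)
  substr(x, 1L, 4L)
}

#' Read and normalize patient diagnosis records
#'
#' Reads a delimited file with columns `patient_id`, `visit_index`,
#' `icd10_code` (comma or tab, auto-detected), drops rows with missing or
#' empty codes, normalizes codes with [normalize_icd10()], and collapses
#' duplicate (patient, visit, code) rows. A quality report is attached as the
#' `"quality_report"` attribute.
#'
#' @param path path to the delimited file.
#' @param sep field separator; `"auto"` (default) lets the reader detect it.
#' @return a `data.table` of records with columns `patient_id` (character),
#'   `visit_index` (integer), `code` (character).
#' @export
read_records <- function(path, sep = "auto") {
  required <- c("patient_id", "visit_index", "icd10_code")
  header <- data.table::fread(path, sep = sep, nrows = 0, showProgress = FALSE)
  missing_cols <- setdiff(required, names(header))
  if (length(missing_cols))
    stop_bad_arg("missing required column(s): ",
                 paste(missing_cols, collapse = ", "))
  dt <- data.table::fread(path, sep = sep, showProgress = FALSE,
                          colClasses = list(character = c("patient_id",
                                                          "icd10_code")))
  n_read <- nrow(dt)
  dt <- dt[, .(patient_id = as.character(patient_id),
               visit_index = as.integer(visit_index),
               code = as.character(icd10_code))]
  bad <- is.na(dt$code) | trimws(dt$code) == ""
  n_dropped <- sum(bad)
  dt <- dt[!bad]
  if (nrow(dt) == 0L)
    stop_bad_arg("no rows with a diagnosis code survive in ", path)
  dt[, code := normalize_icd10(code)]
  n_before <- nrow(dt)
  dt <- unique(dt, by = c("patient_id", "visit_index", "code"))
  setorder(dt, patient_id, visit_index, code)
  setattr(dt, "quality_report", list(
    n_read = n_read, n_dropped_missing_code = n_dropped,
    n_duplicates_collapsed = n_before - nrow(dt), n_records = nrow(dt)))
  dt[]
}

#' Write diagnosis records to delimited text
#'
#' Inverse of [read_records()] for normalized records: writes the columns
#' `patient_id,visit_index,icd10_code`.
#'
#' @param records records `data.table` (columns `patient_id`, `visit_index`,
#'   `code`).
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, sep = ",") {
  out <- data.table(patient_id = records$patient_id,
                    visit_index = records$visit_index,
                    icd10_code = records$code)
  data.table::fwrite(out, path, sep = sep)
  invisible(path)
}

#' Build per-patient visit profiles from diagnosis records
#'
#' One profile per distinct patient: the ordered sequence of per-visit
#' disease sets (ordered by `visit_index`, per-visit duplicates removed) and
#' the patient's disease set (union over visits).
#'
#' @param records records `data.table` as from [read_records()] or
#'   [generate_cohort()].
#' @return an object of class `patient_profiles`: a `data.table` with one row
#'   per patient and columns `patient_id`, `visit_index` (list of integer),
#'   `visits` (list of character vectors, one per visit, in visit order) and
#'   `disease_set` (list of character vectors).
#' @export
build_profiles <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    stop_bad_arg("`records` must be a nonempty record collection")
  rec <- unique(as.data.table(records)[, .(patient_id, visit_index, code)])
  setorder(rec, patient_id, visit_index, code)
  per_visit <- rec[, .(codes = list(code)), by = .(patient_id, visit_index)]
  prof <- per_visit[, .(visit_index = list(visit_index),
                        visits = list(codes),
                        disease_set = list(sort(unique(unlist(codes))))),
                    by = patient_id]
  if (!is.null(attr(records, "cohort_meta")))
    setattr(prof, "cohort_meta", attr(records, "cohort_meta"))
  setattr(prof, "class", c("patient_profiles", class(prof)))
  prof[]
}

#' @export
print.patient_profiles <- function(x, ...) {
  cat(sprintf("<patient_profiles> %d patients, %d visits\n",
              nrow(x), sum(lengths(x$visits))))
  invisible(x)
}

#' Read disease-gene and pathway-gene tables and link diseases to pathways
#'
#' Reads two two-column delimited files (`disease,gene` and `pathway,gene`)
#' and derives disease-pathway links: a disease maps to a pathway iff it
#' shares at least `min_shared_genes` genes with it.
#'
#' @param disease_gene_path,pathway_gene_path paths to the two tables.
#' @param min_shared_genes minimum gene overlap for a disease-pathway link.
#' @return list with `disease_genes` (named list of gene sets),
#'   `pathway_genes` (named list), and `disease_pathways` (named list of
#'   pathway sets).
#' @export
read_molecular_tables <- function(disease_gene_path, pathway_gene_path,
                                  min_shared_genes = 1L) {
  dg <- data.table::fread(disease_gene_path, showProgress = FALSE)
  pg <- data.table::fread(pathway_gene_path, showProgress = FALSE)
  if (nrow(dg) == 0L) stop_bad_arg("empty disease-gene table")
  if (nrow(pg) == 0L) stop_bad_arg("empty pathway-gene table")
  if (ncol(dg) < 2L || ncol(pg) < 2L)
    stop_bad_arg("molecular tables must have two columns")
  setnames(dg, 1:2, c("disease", "gene"))
  setnames(pg, 1:2, c("pathway", "gene"))
  link_maps(
    disease_genes = lapply(split(as.character(dg$gene), dg$disease),
                           function(g) sort(unique(g))),
    pathway_genes = lapply(split(as.character(pg$gene), pg$pathway),
                           function(g) sort(unique(g))),
    min_shared_genes = min_shared_genes)
}

#' Link in-memory molecular tables
#'
#' Same linking rule as [read_molecular_tables()] but starting from tables
#' already in memory (e.g. from [generate_molecular_tables()]).
#'
#' @param disease_genes named list of gene sets per disease (or a two-column
#'   `disease,gene` table).
#' @param pathway_genes named list of gene sets per pathway (or a two-column
#'   `pathway,gene` table).
#' @param min_shared_genes minimum gene overlap for a disease-pathway link.
#' @return as [read_molecular_tables()].
#' @export
link_maps <- function(disease_genes, pathway_genes, min_shared_genes = 1L) {
  if (is.data.frame(disease_genes))
    disease_genes <- lapply(split(as.character(disease_genes[[2]]),
                                  disease_genes[[1]]),
                            function(g) sort(unique(g)))
  if (is.data.frame(pathway_genes))
    pathway_genes <- lapply(split(as.character(pathway_genes[[2]]),
                                  pathway_genes[[1]]),
                            function(g) sort(unique(g)))
  # invert pathway_genes: gene -> pathways, then count per disease
  gene_pathway <- data.table(
    gene = unlist(pathway_genes, use.names = FALSE),
    pathway = rep(names(pathway_genes), lengths(pathway_genes)))
  disease_gene <- data.table(
    disease = rep(names(disease_genes), lengths(disease_genes)),
    gene = unlist(disease_genes, use.names = FALSE))
  links <- merge(disease_gene, gene_pathway, by = "gene",
                 allow.cartesian = TRUE)
  counts <- links[, .N, by = .(disease, pathway)][N >= min_shared_genes]
  disease_pathways <- lapply(split(counts$pathway, counts$disease), sort)
  # diseases with no links still get an (empty) entry
  missing <- setdiff(names(disease_genes), names(disease_pathways))
  disease_pathways[missing] <- list(character(0))
  list(disease_genes = disease_genes,
       pathway_genes = pathway_genes,
       disease_pathways = disease_pathways[names(disease_genes)])
}
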