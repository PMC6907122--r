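#' Run the full comorbidity pipeline from a single configuration
#'
#' Executes, in dependency order: cohort acquisition (synthetic generation or
#' reading a records file), network construction, topology, community
#' detection, molecular validation (optional) and trajectory prediction
#' (optional). Each stage writes its outputs under `out_dir` and the run ends
#' with a JSON manifest listing every output with its MD5 checksum;
#' re-running an identical configuration reproduces identical checksums.
#' Per-stage seeds are derived from the global seed and the stage name, so
#' stages are independently reproducible.
#'
#' The configuration is a named list (or a YAML/JSON file path) with blocks:
#' `seed`, `out_dir`, exactly one of `records` (path) or `synthetic`
#' (arguments for [cohort_config()], optionally `hierarchical: true` or a
#' `risk_rule` sub-block for [risk_rule_config()]), `thresholds`,
#' `communities`, `validation` (a [molecular_config()] block), and
#' `prediction` (`target`, `n_pos`, `n_neg`, `models`, `folds`).
#'
#' @param config named list or path to a YAML/JSON config file.
#' @param out_dir overrides the config's output directory.
#' @return the manifest, invisibly (also written to
#'   `file.path(out_dir, "manifest.json")`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.null(config$records) && !is.null(config$synthetic))
    stop_bad_arg("config must contain exactly one of `records` or `synthetic`")
  if (is.null(config$records) && is.null(config$synthetic))
    stop_bad_arg("config must contain one of `records` or `synthetic`")
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop_bad_arg("an output directory is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  stages <- list()
  outputs <- character(0)
  note <- function(stage, ...) {
    paths <- file.path(out_dir, c(...))
    stages[[stage]] <<- list(outputs = basename(paths))
    outputs <<- c(outputs, paths)
  }

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop_bad_arg(sprintf("stage '%s' failed: %s", stage,
                           conditionMessage(e))))
  }

  # -- stage 1: cohort ------------------------------------------------------
  module_map <- NULL
  records <- run_stage("cohort", {
    if (!is.null(config$records)) {
      rec <- read_records(config$records)
    } else {
      syn <- config$synthetic
      cc_args <- syn[intersect(names(syn), names(formals(cohort_config)))]
      cc_args$seed <- cc_args$seed %||% derive_seed(seed, "cohort")
      cc <- do.call(cohort_config, cc_args)
      rec <- if (isTRUE(syn$hierarchical)) {
        generate_hierarchical_cohort(cc)
      } else if (!is.null(syn$risk_rule)) {
        generate_trajectory_cohort(cc, do.call(risk_rule_config,
                                               syn$risk_rule))
      } else {
        generate_cohort(cc)
      }
      # the braces are evaluated in run_pipeline's frame, so plain
      # assignment updates the local module_map
      module_map <- attr(rec, "cohort_meta")$module_assignment
    }
    write_records(rec, file.path(out_dir, "records.csv"))
    rec
  })
  note("cohort", "records.csv")

  profiles <- build_profiles(records)

  # -- stage 2: network -----------------------------------------------------
  th <- config$thresholds %||% list()
  pair_stats <- run_stage("network", count_contingency(profiles))
  network <- run_stage("network", build_network(
    pair_stats,
    min_cooccurrence = th$min_cooccurrence %||% 5,
    min_rr = th$min_rr %||% 1.0,
    min_phi = th$min_phi %||% 0.0))
  data.table::fwrite(pair_stats, file.path(out_dir, "pairs.tsv"), sep = "\t")
  export_network(network, file.path(out_dir, "edges.tsv"))
  note("network", "pairs.tsv", "edges.tsv")

  # -- stage 3: topology ----------------------------------------------------
  profile <- run_stage("topology", compute_topology(network))
  corr <- run_stage("topology", measure_correlations(profile))
  data.table::fwrite(profile$nodes, file.path(out_dir, "topology.tsv"),
                     sep = "\t")
  data.table::fwrite(corr, file.path(out_dir, "correlations.tsv"), sep = "\t")
  note("topology", "topology.tsv", "correlations.tsv")

  # -- stage 4: communities -------------------------------------------------
  cm <- config$communities %||% list()
  partition <- run_stage("communities", louvain(
    network, seed = derive_seed(seed, "communities"),
    weighted = !isTRUE(cm$unweighted)))
  comp <- community_composition(partition)
  data.table::fwrite(
    data.table(code = names(partition$assignment),
               community = unname(partition$assignment)),
    file.path(out_dir, "partition.tsv"), sep = "\t")
  data.table::fwrite(comp$table, file.path(out_dir, "composition.tsv"),
                     sep = "\t")
  note("communities", "partition.tsv", "composition.tsv")

  # -- stage 5: molecular validation ---------------------------------------
  if (!is.null(config$validation)) {
    va <- config$validation
    report <- run_stage("validation", {
      if (!is.null(va$disease_gene_path)) {
        maps <- read_molecular_tables(va$disease_gene_path,
                                      va$pathway_gene_path)
      } else {
        if (is.null(module_map))
          stop("synthetic molecular tables need a synthetic cohort")
        mc_args <- va[intersect(names(va), names(formals(molecular_config)))]
        mc_args$seed <- mc_args$seed %||% derive_seed(seed, "validation")
        tabs <- generate_molecular_tables(module_map,
                                          do.call(molecular_config, mc_args))
        maps <- link_maps(tabs$disease_gene, tabs$pathway_gene)
      }
      ov <- overlap_statistics(pair_stats, maps$disease_genes,
                               maps$disease_pathways)
      correlate_comorbidity_with_molecular(pair_stats, ov)
    })
    data.table::fwrite(report$correlations,
                       file.path(out_dir, "validation.tsv"), sep = "\t")
    data.table::fwrite(rbind(cbind(count = "genes", report$gene_bins),
                             cbind(count = "pathways", report$pathway_bins)),
                       file.path(out_dir, "validation_bins.tsv"), sep = "\t")
    note("validation", "validation.tsv", "validation_bins.tsv")
  }

  # -- stage 6: prediction --------------------------------------------------
  if (!is.null(config$prediction)) {
    pr <- config$prediction
    res <- run_stage("prediction", {
      ds <- build_dataset(profiles, pr$target)
      n_pos <- pr$n_pos %||% sum(ds$y == 1L)
      bench <- assemble_benchmark(ds, n_pos, pr$n_neg %||% n_pos,
                                  seed = derive_seed(seed, "prediction"))
      train_evaluate(bench,
                     models = pr$models %||% c("lr", "svm", "rf", "nn"),
                     folds = pr$folds %||% 10L,
                     seed = derive_seed(seed, "prediction-models"))
    })
    risk <- extract_risk_features(res, k = pr$top_k %||% 10L)
    data.table::fwrite(res$metrics,
                       file.path(out_dir, "prediction_metrics.tsv"),
                       sep = "\t")
    data.table::fwrite(
      rbindlist(lapply(names(risk), function(m)
        cbind(model = m, risk[[m]]))),
      file.path(out_dir, "risk_features.tsv"), sep = "\t")
    note("prediction", "prediction_metrics.tsv", "risk_features.tsv")
  }

  manifest <- list(
    seed = seed,
    stages = stages,
    checksums = as.list(tools::md5sum(outputs))
  )
  names(manifest$checksums) <- basename(outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
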