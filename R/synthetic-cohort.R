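#' Configuration for a synthetic patient cohort
#'
#' Describes a cohort of inpatients with multi-visit trajectories and a
#' planted modular comorbidity structure. Diseases are partitioned into
#' modules; once a patient carries one disease of a module, every other
#' disease of that module has its per-patient probability multiplied by
#' `within_module_boost` (clamped at 0.99). Disease codes are synthetic
#' 4-character ICD-10-like strings (letter + 3 digits) whose leading letter
#' ("chapter") is aligned with the top-level module.
#'
#' @param n_patients number of patients.
#' @param n_diseases number of diseases (must be >= `n_modules`).
#' @param n_modules number of planted comorbidity modules.
#' @param baseline_prevalence either a single probability in (0, 1) used for
#'   every disease, or a vector of length `n_diseases`. With
#'   `heavy_tail_sdlog > 0` a single value is taken as the median of a
#'   log-normal prevalence distribution (heavy-tailed, as in real disease
#'   prevalence), capped at 0.5.
#' @param within_module_boost multiplicative risk factor >= 1 applied to a
#'   disease when the patient already carries another disease of the same
#'   module. 1 means full independence.
#' @param n_visits_range inclusive integer range of visits per patient;
#'   lower bound must be >= 2 (inpatients with at least two encounters).
#' @param heavy_tail_sdlog sdlog of the log-normal prevalence draw; 0
#'   disables the heavy tail (constant baseline).
#' @param module_assignment optional integer vector of length `n_diseases`
#'   mapping each disease to a module in `1:n_modules`; defaults to
#'   contiguous equal-sized blocks.
#' @param seed integer seed; all randomness of the generators flows from it.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients, n_diseases = 40L, n_modules = 4L,
                          baseline_prevalence = 0.02, within_module_boost = 8,
                          n_visits_range = c(2L, 5L), heavy_tail_sdlog = 0,
                          module_assignment = NULL, seed = 1L) {
  n_patients <- check_count(n_patients, "n_patients")
  n_diseases <- check_count(n_diseases, "n_diseases")
  n_modules <- check_count(n_modules, "n_modules")
  seed <- check_count(seed, "seed", min = 0L)
  if (n_diseases < n_modules)
    stop_bad_arg("`n_diseases` must be >= `n_modules`")
  if (!is.numeric(within_module_boost) || within_module_boost < 1)
    stop_bad_arg("`within_module_boost` must be >= 1")
  if (length(n_visits_range) != 2L || n_visits_range[1] < 2L ||
      n_visits_range[2] < n_visits_range[1])
    stop_bad_arg("`n_visits_range` must be an inclusive range with lower bound >= 2")
  if (n_modules > 26L)
    stop_bad_arg("at most 26 modules supported (one chapter letter each)")

  if (is.null(module_assignment)) {
    module_assignment <- sort(rep_len(seq_len(n_modules), n_diseases))
  } else {
    module_assignment <- as.integer(module_assignment)
    if (length(module_assignment) != n_diseases ||
        !all(module_assignment %in% seq_len(n_modules)))
      stop_bad_arg("`module_assignment` must map every disease to 1:n_modules")
  }

  if (length(baseline_prevalence) == 1L && heavy_tail_sdlog > 0) {
    baseline_prevalence <- withr::with_seed(seed, pmin(
      rlnorm(n_diseases, meanlog = log(baseline_prevalence),
             sdlog = heavy_tail_sdlog), 0.5))
  } else if (length(baseline_prevalence) == 1L) {
    baseline_prevalence <- rep(baseline_prevalence, n_diseases)
  }
  baseline_prevalence <- check_prob(baseline_prevalence, "baseline_prevalence")
  if (length(baseline_prevalence) != n_diseases)
    stop_bad_arg("`baseline_prevalence` must have length 1 or n_diseases")

  # chapter-aligned codes: letter = top-level module, digits = disease index
  idx_in_module <- stats::ave(seq_len(n_diseases), module_assignment,
                              FUN = seq_along)
  codes <- paste0(LETTERS[module_assignment], sprintf("%03d", idx_in_module))

  structure(list(
    n_patients = n_patients, n_diseases = n_diseases, n_modules = n_modules,
    baseline_prevalence = baseline_prevalence,
    within_module_boost = within_module_boost,
    n_visits_range = as.integer(n_visits_range),
    module_assignment = module_assignment,
    disease_codes = codes, seed = seed
  ), class = "cohort_config")
}

#' Configuration for synthetic disease-gene and pathway-gene tables
#'
#' @param n_genes size of the gene universe.
#' @param n_pathways number of pathways.
#' @param genes_per_disease_range inclusive range of genes per disease.
#' @param coupling fraction in \[0, 1\] of a disease's genes drawn from its
#'   module's shared gene pool; 0 makes gene sharing independent of
#'   comorbidity module structure.
#' @param pathway_size_range inclusive range of genes per pathway.
#' @param module_pool_size number of genes reserved for each module's shared
#'   pool (pools are disjoint across modules).
#' @param seed integer seed.
#' @return an object of class `molecular_config`.
#' @export
molecular_config <- function(n_genes = 2000L, n_pathways = 100L,
                             genes_per_disease_range = c(5L, 15L),
                             coupling = 0.8,
                             pathway_size_range = c(20L, 60L),
                             module_pool_size = 30L, seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  n_pathways <- check_count(n_pathways, "n_pathways")
  module_pool_size <- check_count(module_pool_size, "module_pool_size")
  seed <- check_count(seed, "seed", min = 0L)
  coupling <- check_prob(coupling, "coupling", open_lo = FALSE, open_hi = FALSE)
  if (length(genes_per_disease_range) != 2L || genes_per_disease_range[1] < 1L ||
      genes_per_disease_range[2] < genes_per_disease_range[1])
    stop_bad_arg("`genes_per_disease_range` must be a valid inclusive range")
  if (genes_per_disease_range[2] > n_genes)
    stop_bad_arg("`genes_per_disease_range` upper bound exceeds `n_genes`")
  if (length(pathway_size_range) != 2L || pathway_size_range[1] < 1L ||
      pathway_size_range[2] < pathway_size_range[1])
    stop_bad_arg("`pathway_size_range` must be a valid inclusive range")
  if (round(coupling * genes_per_disease_range[2]) > module_pool_size)
    stop_bad_arg("module pool too small for `coupling` at the maximum gene count")

  structure(list(
    n_genes = n_genes, n_pathways = n_pathways,
    genes_per_disease_range = as.integer(genes_per_disease_range),
    coupling = coupling,
    pathway_size_range = as.integer(pathway_size_range),
    module_pool_size = module_pool_size, seed = seed
  ), class = "molecular_config")
}

#' Configuration for a planted temporal risk rule
#'
#' The target disease appears at a visit with `trigger_probability` if any
#' risk disease occurred at a strictly earlier visit of the same patient, and
#' with `background_probability` otherwise.
#'
#' @param target_disease target disease code.
#' @param risk_diseases nonempty character vector of risk disease codes
#'   (must not contain the target).
#' @param trigger_probability per-visit occurrence probability given an
#'   earlier risk disease; must exceed `background_probability`.
#' @param background_probability per-visit occurrence probability otherwise.
#' @param risk_prevalence baseline prevalence assigned to each risk disease
#'   in the generated cohort. Defaults to 0.30, the scale of a common chronic
#'   condition, so that the planted mechanism dominates target occurrence.
#' @return an object of class `risk_rule_config`.
#' @export
risk_rule_config <- function(target_disease, risk_diseases,
                             trigger_probability = 0.8,
                             background_probability = 0.05,
                             risk_prevalence = 0.30) {
  trigger_probability <- check_prob(trigger_probability, "trigger_probability",
                                    open_hi = FALSE)
  background_probability <- check_prob(background_probability,
                                       "background_probability",
                                       open_lo = FALSE)
  risk_prevalence <- check_prob(risk_prevalence, "risk_prevalence")
  if (trigger_probability <= background_probability)
    stop_bad_arg("`trigger_probability` must exceed `background_probability`")
  if (length(risk_diseases) == 0L)
    stop_bad_arg("`risk_diseases` must be nonempty")
  if (target_disease %in% risk_diseases)
    stop_bad_arg("`target_disease` must not be one of `risk_diseases`")
  structure(list(
    target_disease = as.character(target_disease),
    risk_diseases = as.character(risk_diseases),
    trigger_probability = trigger_probability,
    background_probability = background_probability,
    risk_prevalence = risk_prevalence
  ), class = "risk_rule_config")
}

# draw per-patient disease sets, then scatter each disease over the patient's
# visits (each visit included w.p. 0.6, at least one forced) so that the
# per-patient union equals the sampled set exactly.
sample_records <- function(config, groups, boosts, hub, hub_boost,
                           baseline = NULL) {
  baseline <- baseline %||% config$baseline_prevalence
  sets <- sample_cohort_cpp(config$n_patients, baseline, groups, boosts,
                            hub, hub_boost)
  if (sets$n_clamped > 0)
    warning(sprintf("%d boosted probabilities clamped at 0.99", sets$n_clamped))
  lo <- config$n_visits_range[1]; hi <- config$n_visits_range[2]
  n_visits <- if (lo == hi) rep(lo, config$n_patients) else
    sample(lo:hi, config$n_patients, replace = TRUE)

  pid <- vector("list", config$n_patients)
  vis <- vector("list", config$n_patients)
  dis <- vector("list", config$n_patients)
  for (p in seq_len(config$n_patients)) {
    ds <- sets$diseases[[p]]
    k <- length(ds)
    if (k == 0L) next
    v <- n_visits[p]
    m <- matrix(runif(k * v) < 0.6, k, v)
    none <- rowSums(m) == 0L
    if (any(none))
      m[cbind(which(none), sample.int(v, sum(none), replace = TRUE))] <- TRUE
    hits <- which(m, arr.ind = TRUE)
    pid[[p]] <- rep.int(p, nrow(hits))
    vis[[p]] <- hits[, 2L]
    dis[[p]] <- ds[hits[, 1L]]
  }
  rec <- data.table(
    patient_id = sprintf("P%06d", unlist(pid)),
    visit_index = as.integer(unlist(vis)),
    code = config$disease_codes[unlist(dis)]
  )
  setorder(rec, patient_id, visit_index, code)
  attr(rec, "n_visits") <- n_visits
  rec
}

finish_cohort <- function(rec, config, extra = list()) {
  meta <- c(list(
    config = config,
    disease_codes = config$disease_codes,
    module_assignment = stats::setNames(config$module_assignment,
                                        config$disease_codes)
  ), extra)
  setattr(rec, "cohort_meta", meta)
  rec[]
}

#' Generate a synthetic patient cohort with planted comorbidity modules
#'
#' Each patient's disease set is drawn by sequential conditional sampling in
#' a fresh random disease order: a disease's baseline probability is
#' multiplied by `within_module_boost` once the patient already carries
#' another disease of the same module. Each disease is then scattered over
#' the patient's visits (at least one visit per disease), so the per-patient
#' union over visits equals the sampled set.
#'
#' @param config a [cohort_config()].
#' @return a `data.table` of diagnosis records with columns `patient_id`,
#'   `visit_index`, `code`, carrying the generating configuration and the
#'   disease-to-module map in the `"cohort_meta"` attribute.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, {
    groups <- matrix(config$module_assignment, ncol = 1)
    rec <- sample_records(config, groups, config$within_module_boost,
                          rep(FALSE, config$n_diseases), 1)
    finish_cohort(rec, config)
  })
}

#' Generate a cohort with hierarchically nested modules and hub diseases
#'
#' Modules are split recursively into sub-modules; the boost weakens going up
#' the hierarchy (level-l boost = `within_module_boost^(1/2^(l-1))` with level
#' 1 the finest), so sub-modules are tighter than their parents. A small set
#' of hub diseases receives a higher baseline prevalence and a cross-module
#' boost, producing a comorbidity network whose hubs have low clustering and
#' whose leaves have high clustering (the degree/clustering anticorrelation
#' signature of hierarchical modularity).
#'
#' @param config a [cohort_config()]; `module_assignment` gives the top level.
#' @param nesting_depth number of nesting levels (>= 2).
#' @param n_submodules sub-modules per module at each split.
#' @param hub_fraction fraction of diseases promoted to hubs (0 for none).
#' @param hub_boost cross-module multiplicative factor for hubs.
#' @param hub_prevalence_factor baseline multiplier for hubs (capped at 0.3).
#' @return diagnosis records as in [generate_cohort()]; the meta attribute
#'   additionally records `hub_codes` and the per-level group matrix.
#' @export
generate_hierarchical_cohort <- function(config, nesting_depth = 2L,
                                         n_submodules = 2L,
                                         hub_fraction = 0.05, hub_boost = 3,
                                         hub_prevalence_factor = 8) {
  stopifnot(inherits(config, "cohort_config"))
  nesting_depth <- check_count(nesting_depth, "nesting_depth", min = 2L)
  n_submodules <- check_count(n_submodules, "n_submodules", min = 1L)

  D <- config$n_diseases
  groups <- matrix(0L, D, nesting_depth)
  groups[, nesting_depth] <- config$module_assignment
  # split each parent group into n_submodules contiguous blocks per level down
  for (l in seq(nesting_depth - 1L, 1L)) {
    parent <- groups[, l + 1L]
    sub <- integer(D)
    nid <- 0L
    for (g in sort(unique(parent))) {
      members <- which(parent == g)
      blocks <- sort(rep_len(seq_len(n_submodules), length(members)))
      sub[members] <- nid + blocks
      nid <- nid + max(blocks)
    }
    groups[, l] <- sub
  }
  b <- config$within_module_boost
  boosts <- b^(1 / 2^(seq_len(nesting_depth) - 1))

  n_hubs <- if (hub_fraction > 0) max(1L, ceiling(hub_fraction * D)) else 0L
  hub <- rep(FALSE, D)
  baseline <- config$baseline_prevalence
  if (n_hubs > 0L) {
    # spread hubs across modules: first member of each module, cycling
    by_module <- split(seq_len(D), config$module_assignment)
    picks <- integer(0)
    r <- 1L
    while (length(picks) < n_hubs) {
      for (m in seq_along(by_module)) {
        if (length(picks) >= n_hubs) break
        if (length(by_module[[m]]) >= r) picks <- c(picks, by_module[[m]][r])
      }
      r <- r + 1L
    }
    hub[picks] <- TRUE
    baseline[hub] <- pmin(baseline[hub] * hub_prevalence_factor, 0.3)
  }

  withr::with_seed(config$seed, {
    rec <- sample_records(config, groups, boosts, hub,
                          if (n_hubs > 0L) hub_boost else 1,
                          baseline = baseline)
    finish_cohort(rec, config, extra = list(
      hub_codes = config$disease_codes[hub],
      level_groups = groups, level_boosts = boosts
    ))
  })
}

#' Generate synthetic disease-gene and pathway-gene association tables
#'
#' Each module owns a disjoint shared gene pool. A disease with k genes draws
#' `round(coupling * k)` of them from its module's pool and the remainder
#' uniformly from the rest of the gene universe, so `coupling` tunes how
#' strongly gene sharing tracks the planted comorbidity modules (0 = gene
#' sharing independent of module structure). Pathways are uniform random gene
#' sets.
#'
#' @param module_assignment named integer vector mapping disease codes to
#'   modules (e.g. the `module_assignment` entry of a cohort's meta).
#' @param config a [molecular_config()].
#' @return list with `disease_gene` and `pathway_gene` two-column
#'   `data.table`s.
#' @export
generate_molecular_tables <- function(module_assignment, config) {
  stopifnot(inherits(config, "molecular_config"))
  if (is.null(names(module_assignment)))
    stop_bad_arg("`module_assignment` must be named by disease code")
  modules <- sort(unique(module_assignment))
  if (length(modules) * config$module_pool_size > config$n_genes)
    stop_bad_arg("gene universe too small for disjoint module pools")

  withr::with_seed(config$seed, {
    genes <- sprintf("G%05d", seq_len(config$n_genes))
    pool_genes <- sample(genes, length(modules) * config$module_pool_size)
    pools <- split(pool_genes, rep(seq_along(modules),
                                   each = config$module_pool_size))
    names(pools) <- as.character(modules)

    gl <- config$genes_per_disease_range
    dg <- lapply(names(module_assignment), function(d) {
      k <- if (gl[1] == gl[2]) gl[1] else sample(gl[1]:gl[2], 1L)
      n_mod <- round(config$coupling * k)
      pool <- pools[[as.character(module_assignment[[d]])]]
      from_pool <- if (n_mod > 0) sample(pool, n_mod) else character(0)
      rest <- setdiff(genes, from_pool)
      from_rest <- if (k - n_mod > 0) sample(rest, k - n_mod) else character(0)
      data.table(disease = d, gene = c(from_pool, from_rest))
    })
    disease_gene <- rbindlist(dg)
    setorder(disease_gene, disease, gene)

    pl <- config$pathway_size_range
    pg <- lapply(seq_len(config$n_pathways), function(p) {
      s <- if (pl[1] == pl[2]) pl[1] else sample(pl[1]:pl[2], 1L)
      data.table(pathway = sprintf("PW%04d", p), gene = sample(genes, s))
    })
    pathway_gene <- rbindlist(pg)
    setorder(pathway_gene, pathway, gene)

    list(disease_gene = disease_gene[], pathway_gene = pathway_gene[])
  })
}

#' Generate a cohort with a planted temporal risk rule for a target disease
#'
#' A base cohort is generated from `base` (with the rule's risk diseases set
#' to `risk_prevalence` and the target removed from baseline sampling); the
#' target disease is then overlaid visit by visit: it appears at a visit with
#' `trigger_probability` if any risk disease occurred at a strictly earlier
#' visit, and with `background_probability` otherwise.
#'
#' @param base a [cohort_config()]; target and risk diseases must be among
#'   its disease codes.
#' @param rule a [risk_rule_config()].
#' @return diagnosis records as in [generate_cohort()]; meta additionally
#'   records the rule.
#' @export
generate_trajectory_cohort <- function(base, rule) {
  stopifnot(inherits(base, "cohort_config"), inherits(rule, "risk_rule_config"))
  codes <- base$disease_codes
  if (!rule$target_disease %in% codes)
    stop_bad_arg("target disease not in the cohort's disease universe")
  if (!all(rule$risk_diseases %in% codes))
    stop_bad_arg("some risk diseases not in the cohort's disease universe")

  baseline <- base$baseline_prevalence
  baseline[codes %in% rule$risk_diseases] <- rule$risk_prevalence
  baseline[codes == rule$target_disease] <- 0  # occurrences are rule-driven

  withr::with_seed(base$seed, {
    groups <- matrix(base$module_assignment, ncol = 1)
    rec <- sample_records(base, groups, base$within_module_boost,
                          rep(FALSE, base$n_diseases), 1, baseline = baseline)
    n_visits <- attr(rec, "n_visits")

    # earliest visit carrying any risk disease, per patient
    risk_rec <- rec[code %in% rule$risk_diseases,
                    .(first_risk = min(visit_index)), by = patient_id]
    first_risk <- stats::setNames(risk_rec$first_risk, risk_rec$patient_id)

    all_pid <- sprintf("P%06d", seq_len(base$n_patients))
    pid_rep <- rep(all_pid, n_visits)
    vis_rep <- unlist(lapply(n_visits, seq_len), use.names = FALSE)
    fr <- first_risk[pid_rep]
    triggered <- !is.na(fr) & vis_rep > fr
    p <- ifelse(triggered, rule$trigger_probability,
                rule$background_probability)
    hit <- runif(length(p)) < p
    target_rec <- data.table(patient_id = pid_rep[hit],
                             visit_index = as.integer(vis_rep[hit]),
                             code = rule$target_disease)
    out <- rbindlist(list(rec, target_rec))
    setorder(out, patient_id, visit_index, code)
    setattr(out, "n_visits", n_visits)
    finish_cohort(out, base, extra = list(rule = rule))
  })
}
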