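test_that("config constructors validate their invariants", {
  expect_error(cohort_config(10, n_diseases = 3, n_modules = 4), ">=")
  expect_error(cohort_config(10, within_module_boost = 0.5), ">= 1")
  expect_error(cohort_config(10, n_visits_range = c(1, 3)), "lower bound")
  expect_error(cohort_config(10, baseline_prevalence = 1.2), "lie in")
  expect_error(molecular_config(genes_per_disease_range = c(5, 3000),
                                n_genes = 2000), "exceeds")
  expect_error(molecular_config(coupling = 1, module_pool_size = 5,
                                genes_per_disease_range = c(5, 10)),
               "pool too small")
  expect_error(risk_rule_config("T00", "T00"), "must not be one of")
  expect_error(risk_rule_config("T00", "A00", trigger_probability = 0.1,
                                background_probability = 0.2), "exceed")
  expect_error(risk_rule_config("T00", character(0)), "nonempty")
})

test_that("all four generators are deterministic given their seed", {
  cc <- cohort_config(n_patients = 300, n_diseases = 20, n_modules = 4,
                      baseline_prevalence = 0.05, seed = 9)
  expect_identical(as.data.frame(generate_cohort(cc)),
                   as.data.frame(generate_cohort(cc)))
  expect_identical(
    as.data.frame(suppressWarnings(generate_hierarchical_cohort(cc))),
    as.data.frame(suppressWarnings(generate_hierarchical_cohort(cc))))
  rule <- risk_rule_config("B001", c("A001", "C001"))
  expect_identical(
    as.data.frame(suppressWarnings(generate_trajectory_cohort(cc, rule))),
    as.data.frame(suppressWarnings(generate_trajectory_cohort(cc, rule))))
  mc <- molecular_config(n_genes = 500, n_pathways = 20, seed = 3)
  mm <- attr(generate_cohort(cc), "cohort_meta")$module_assignment
  expect_identical(generate_molecular_tables(mm, mc),
                   generate_molecular_tables(mm, mc))
  # different seed changes the draw
  cc2 <- cohort_config(n_patients = 300, n_diseases = 20, n_modules = 4,
                       baseline_prevalence = 0.05, seed = 10)
  expect_false(identical(as.data.frame(generate_cohort(cc)),
                         as.data.frame(generate_cohort(cc2))))
})

test_that("cohorts have valid codes, visit structure and chapter alignment", {
  cc <- cohort_config(n_patients = 500, n_diseases = 30, n_modules = 3,
                      baseline_prevalence = 0.1, n_visits_range = c(2, 4),
                      seed = 2)
  rec <- generate_cohort(cc)
  expect_true(all(grepl("^[A-Z][0-9]{3}$", rec$code)))
  expect_true(all(rec$visit_index >= 1 & rec$visit_index <= 4))
  meta <- attr(rec, "cohort_meta")
  # chapter letter encodes the module
  expect_equal(unname(meta$module_assignment),
               match(substr(names(meta$module_assignment), 1, 1), LETTERS))
  expect_true(all(attr(rec, "n_visits") >= 2))
})

test_that("no boost means independence: within-module phi centred on 0", {
  cc <- cohort_config(n_patients = 20000, n_diseases = 20, n_modules = 4,
                      baseline_prevalence = 0.05, within_module_boost = 1,
                      seed = 31)
  rec <- generate_cohort(cc)
  ps <- count_contingency(rec)
  mods <- attr(rec, "cohort_meta")$module_assignment
  within <- ps[mods[ps$disease_i] == mods[ps$disease_j]]
  se <- 1 / sqrt(within$n[1])
  expect_true(all(abs(within$phi) < 3 * se))
  # and downstream RR has null mean near 1
  expect_gt(mean(ps$rr), 0.95)
  expect_lt(mean(ps$rr), 1.05)
})

test_that("planted modules order the pair statistics (RR and phi)", {
  cc <- cohort_config(n_patients = 20000, n_diseases = 40, n_modules = 4,
                      baseline_prevalence = 0.02, within_module_boost = 8,
                      seed = 5)
  rec <- generate_cohort(cc)
  ps <- count_contingency(rec)
  mods <- attr(rec, "cohort_meta")$module_assignment
  within <- mods[ps$disease_i] == mods[ps$disease_j]
  expect_gt(mean(ps$rr[within]), mean(ps$rr[!within]))
  # one-sided 3-SE separation of mean phi
  d <- mean(ps$phi[within]) - mean(ps$phi[!within])
  se <- sqrt(var(ps$phi[within]) / sum(within) +
             var(ps$phi[!within]) / sum(!within))
  expect_gt(d, 3 * se)
})

test_that("a weak boost still orders within vs between phi", {
  cc <- cohort_config(n_patients = 20000, n_diseases = 40, n_modules = 4,
                      baseline_prevalence = 0.02, within_module_boost = 2,
                      seed = 6)
  rec <- generate_cohort(cc)
  ps <- count_contingency(rec)
  mods <- attr(rec, "cohort_meta")$module_assignment
  within <- mods[ps$disease_i] == mods[ps$disease_j]
  d <- mean(ps$phi[within]) - mean(ps$phi[!within])
  se <- sqrt(var(ps$phi[within]) / sum(within) +
             var(ps$phi[!within]) / sum(!within))
  expect_gt(d, 3 * se)
})

test_that("hierarchical generator returns a valid cohort without hubs too", {
  cc <- cohort_config(n_patients = 400, n_diseases = 24, n_modules = 4,
                      baseline_prevalence = 0.08, seed = 8)
  rec <- generate_hierarchical_cohort(cc, nesting_depth = 2,
                                      hub_fraction = 0)
  expect_true(nrow(rec) > 0)
  expect_equal(attr(rec, "cohort_meta")$hub_codes, character(0))
  meta <- attr(rec, "cohort_meta")
  expect_equal(ncol(meta$level_groups), 2L)
  # finest level boost is the configured one, parent level its square root
  expect_equal(meta$level_boosts, c(8, sqrt(8)))
})

test_that("molecular coupling controls gene sharing across modules", {
  mods <- stats::setNames(rep(1:4, each = 25), sprintf("D%03d", 1:100))
  mc0 <- molecular_config(n_genes = 2000, n_pathways = 20, coupling = 0,
                          genes_per_disease_range = c(10, 10), seed = 21)
  tabs0 <- generate_molecular_tables(mods, mc0)
  genes0 <- split(tabs0$disease_gene$gene, tabs0$disease_gene$disease)
  pairs <- t(combn(names(mods), 2))
  shared0 <- mapply(function(a, b) length(intersect(genes0[[a]], genes0[[b]])),
                    pairs[, 1], pairs[, 2])
  same <- mods[pairs[, 1]] == mods[pairs[, 2]]
  # with coupling 0, same- and different-module sharing are equal in mean
  d <- mean(shared0[same]) - mean(shared0[!same])
  se <- sqrt(var(shared0[same]) / sum(same) + var(shared0[!same]) / sum(!same))
  expect_lt(abs(d), 3 * se)

  mc1 <- molecular_config(n_genes = 2000, n_pathways = 20, coupling = 1,
                          genes_per_disease_range = c(10, 10),
                          module_pool_size = 30, seed = 22)
  tabs1 <- generate_molecular_tables(mods, mc1)
  genes1 <- split(tabs1$disease_gene$gene, tabs1$disease_gene$disease)
  shared1 <- mapply(function(a, b)
    length(intersect(genes1[[a]], genes1[[b]])) >= 1,
    pairs[same, 1], pairs[same, 2])
  # hypergeometric: P(overlap >= 1) = 1 - C(20,10)/C(30,10) ~ 0.9994
  expect_gt(mean(shared1), 0.95)
  # every disease has exactly its configured gene count
  expect_true(all(lengths(genes1) == 10))
})

test_that("trajectory overlay honours degenerate probabilities exactly", {
  cc <- cohort_config(n_patients = 400, n_diseases = 20, n_modules = 2,
                      baseline_prevalence = 0.1, within_module_boost = 1,
                      n_visits_range = c(2, 4), seed = 13)
  rule <- risk_rule_config("B001", c("A001", "A002"),
                           trigger_probability = 1, background_probability = 0,
                           risk_prevalence = 0.3)
  rec <- generate_trajectory_cohort(cc, rule)
  n_visits <- attr(rec, "n_visits")
  rec_dt <- data.table::as.data.table(rec)
  first_risk <- rec_dt[code %in% rule$risk_diseases,
                       .(fr = min(visit_index)), by = patient_id]
  has_target <- unique(rec_dt[code == "B001", patient_id])
  expected <- first_risk[fr < n_visits[as.integer(substr(patient_id, 2, 7))],
                         patient_id]
  expect_setequal(has_target, expected)
  # with trigger 1, the target fills every visit after the first risk visit
  tv <- rec_dt[code == "B001", .(patient_id, visit_index)]
  merged <- merge(tv, first_risk, by = "patient_id")
  expect_true(all(merged$visit_index > merged$fr))
})

test_that("trajectory overlay matches its probabilities empirically", {
  cc <- cohort_config(n_patients = 10000, n_diseases = 20, n_modules = 2,
                      baseline_prevalence = 0.05, within_module_boost = 1,
                      n_visits_range = c(2, 4), seed = 17)
  rule <- risk_rule_config("B001", "A001", trigger_probability = 0.8,
                           background_probability = 0.05)
  rec <- generate_trajectory_cohort(cc, rule)
  n_visits <- attr(rec, "n_visits")
  rec_dt <- data.table::as.data.table(rec)
  first_risk <- rec_dt[code == "A001", .(fr = min(visit_index)),
                       by = patient_id]
  fr <- stats::setNames(first_risk$fr, first_risk$patient_id)
  pid <- rep(sprintf("P%06d", seq_along(n_visits)), n_visits)
  vis <- unlist(lapply(n_visits, seq_len))
  triggered <- !is.na(fr[pid]) & vis > fr[pid]
  tgt <- paste(rec_dt[code == "B001", patient_id],
               rec_dt[code == "B001", visit_index])
  hit <- paste(pid, vis) %in% tgt
  expect_lt(abs(mean(hit[triggered]) - 0.8), 0.03)
  expect_lt(abs(mean(hit[!triggered]) - 0.05), 0.03)
})
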