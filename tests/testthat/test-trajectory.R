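profiles_from_visits <- function(visit_lists) {
  rec <- data.table::rbindlist(lapply(seq_along(visit_lists), function(p)
    data.table::rbindlist(lapply(seq_along(visit_lists[[p]]), function(v) {
      codes <- visit_lists[[p]][[v]]
      if (!length(codes)) return(NULL)
      data.table::data.table(patient_id = sprintf("p%02d", p),
                             visit_index = v, code = codes)
    }))))
  build_profiles(rec)
}

test_that("build_dataset implements the protocol on minimal trajectories", {
  prof <- profiles_from_visits(list(
    list("A00", "T00"),           # risk then target: one positive instance
    list("T00", "A00"),           # target first: label 0, T00 not a feature
    list("B01")))                 # single visit: no instance
  ds <- build_dataset(prof, "T00")
  expect_false("T00" %in% ds$feature_names)
  expect_equal(length(ds$y), 2L)
  i1 <- which(ds$provenance$patient_id == "p01")
  expect_equal(ds$y[i1], 1L)
  expect_equal(unname(ds$X[i1, "A00"]), 1L)
  i2 <- which(ds$provenance$patient_id == "p02")
  expect_equal(ds$y[i2], 0L)
  expect_equal(sum(ds$X[i2, ]), 0L)  # earlier T00 excluded from features
})

test_that("build_dataset matches a hand-built matrix on a 6-patient fixture", {
  prof <- profiles_from_visits(list(
    list("A00", c("B01", "T00")),            # pos at visit 2, feature A00
    list(c("A00", "B01"), "C02", "T00"),     # pos at visit 3
    list("A00", "B01", "C02"),               # three negatives... visits 2,3
    list("T00", "A00", "T00"),               # pos at visit 3 (first eligible occurrence)
    list(c("A00", "C02"), "A00"),            # negative
    list("B01")))                            # no instance
  ds <- build_dataset(prof, "T00")
  expect_equal(ds$feature_names, c("A00", "B01", "C02"))
  want_y <- c(1L,            # p1 v2
              0L, 1L,        # p2 v2 (label 0), v3 (label 1)
              0L, 0L,        # p3 v2, v3
              0L, 1L,        # p4 v2, v3
              0L)            # p5 v2
  expect_equal(ds$y, want_y)
  want_X <- rbind(
    c(1, 0, 0),   # p1 v2: saw A00
    c(1, 1, 0),   # p2 v2
    c(1, 1, 1),   # p2 v3
    c(1, 0, 0),   # p3 v2
    c(1, 1, 0),   # p3 v3
    c(0, 0, 0),   # p4 v2: only T00 before, excluded
    c(1, 0, 0),   # p4 v3
    c(1, 0, 1))   # p5 v2
  dimnames(want_X) <- list(NULL, ds$feature_names)
  storage.mode(want_X) <- "integer"
  expect_equal(ds$X, want_X)
  # no instance after the first positive: p4 stops at visit 3
  expect_equal(sum(ds$provenance$patient_id == "p04"), 2L)
})

test_that("composite targets share the single-code path", {
  prof <- profiles_from_visits(list(
    list("A00", "T01"), list("A00", "T02"), list("A00", "B01")))
  ds <- build_dataset(prof, c("T01", "T02"))
  expect_equal(ds$y, c(1L, 1L, 0L))
  expect_false(any(c("T01", "T02") %in% ds$feature_names))
  expect_warning(build_dataset(prof, "ZZZ"), "absent")
})

test_that("assemble_benchmark samples deterministically and errors clearly", {
  withr::with_seed(2, {
    visit_lists <- lapply(1:80, function(p) {
      v1 <- sample(c("A00", "B01", "C02"), 2)
      v2 <- if (p <= 20) "T00" else sample(c("B01", "D03"), 1)
      list(v1, v2)
    })
  })
  ds <- build_dataset(profiles_from_visits(visit_lists), "T00")
  b <- assemble_benchmark(ds, 10, 10, seed = 3)
  expect_equal(sum(b$y == 1L), 10L)
  expect_equal(sum(b$y == 0L), 10L)
  b2 <- assemble_benchmark(ds, 10, 10, seed = 3)
  expect_identical(b$X, b2$X)
  expect_identical(b$provenance, b2$provenance)
  expect_error(assemble_benchmark(ds, 1000, 10, seed = 1),
               "insufficient positive")
  expect_error(assemble_benchmark(ds, 10, 1000, seed = 1),
               "insufficient negative")
})

test_that("case patients are excluded from the negative pool by default", {
  prof <- profiles_from_visits(list(
    list("A00", "B01", "T00"),    # case: one pre-onset negative + positive
    list("A00", "B01", "C02")))   # control: two negatives
  ds <- build_dataset(prof, "T00")
  b <- assemble_benchmark(ds, 1, 2, seed = 1)
  expect_true(all(b$provenance$patient_id[b$y == 0] == "p02"))
  # literal policy keeps pre-onset case visits in the pool
  b2 <- assemble_benchmark(ds, 1, 3, seed = 1, exclude_case_patients = FALSE)
  expect_equal(sum(b2$y == 0), 3L)
})

test_that("folds are grouped by patient and stratified", {
  withr::with_seed(4, {
    visit_lists <- lapply(1:60, function(p) {
      n_vis <- sample(2:4, 1)
      vis <- lapply(seq_len(n_vis), function(v)
        sample(c("A00", "B01", "C02", "D03"), 2))
      if (p <= 30) vis[[n_vis]] <- c(vis[[n_vis]], "T00")
      vis
    })
  })
  ds <- build_dataset(profiles_from_visits(visit_lists), "T00")
  bench <- assemble_benchmark(ds, 25, 25, seed = 5)
  fold_id <- comorbinet:::grouped_folds(bench$provenance, bench$y, 5,
                                        seed = 11)
  per_patient <- tapply(fold_id, bench$provenance$patient_id,
                        function(f) length(unique(f)))
  expect_true(all(per_patient == 1L))
  expect_equal(sort(unique(fold_id)), 1:5)
})

test_that("models separate a noise-free planted rule and expose features", {
  withr::with_seed(6, {
    n <- 400
    X <- matrix(rbinom(n * 12, 1, 0.3), n, 12,
                dimnames = list(NULL, sprintf("F%02d", 1:12)))
    X[, 12] <- 0L                       # all-zero column
    y <- X[, 1]                         # perfectly separable rule
  })
  bench <- structure(list(
    X = X, y = as.integer(y), feature_names = colnames(X),
    provenance = data.table::data.table(
      patient_id = sprintf("q%03d", seq_len(nrow(X))), visit_index = 2L),
    target = "T00"), class = "trajectory_dataset")
  res <- train_evaluate(bench, models = c("lr", "svm", "rf", "nn"),
                        folds = 5, seed = 7,
                        settings = list(rf = list(ntree = 60)))
  expect_gte(res$metrics[model == "rf"]$f1_mean, 0.99)
  expect_true(all(res$metrics$f1_mean > 0.95))
  expect_true(all(res$metrics$precision_sd >= 0))
  # feature extraction: the causal feature tops every rankable model
  rk <- extract_risk_features(res, k = 3)
  expect_setequal(names(rk), c("lr", "svm", "rf"))
  for (m in names(rk)) expect_equal(rk[[m]]$feature[1], "F01")
  # all-zero column carries no weight/importance
  final <- res$models
  expect_equal(unname(final$lr$coefficients["F12"]), 0)
  expect_equal(unname(final$rf$importance["F12"]), 0)
  w <- testthat::capture_warnings(extract_risk_features(res, k = 50))
  expect_true(all(grepl("exceeds", w)))
})

test_that("linear models give negative weight to an antitone feature", {
  withr::with_seed(8, {
    n <- 300
    X <- matrix(rbinom(n * 5, 1, 0.5), n, 5,
                dimnames = list(NULL, sprintf("F%d", 1:5)))
    y <- as.integer(X[, 2] == 0)        # presence predicts the negative class
  })
  lr <- fit_model("lr", X, y, seed = 1)
  svm <- fit_model("svm", X, y, seed = 1)
  expect_lt(lr$coefficients["F2"], 0)
  expect_lt(svm$coefficients["F2"], 0)
})

test_that("degenerate evaluation inputs fail with clear messages", {
  X <- matrix(0L, 10, 2, dimnames = list(NULL, c("A", "B")))
  bench <- structure(list(
    X = X, y = rep(0L, 10), feature_names = colnames(X),
    provenance = data.table::data.table(patient_id = sprintf("p%d", 1:10),
                                        visit_index = 2L),
    target = "T"), class = "trajectory_dataset")
  expect_error(train_evaluate(bench), "both classes")
  bench$y <- c(1L, rep(0L, 9))
  expect_error(train_evaluate(bench, models = "lr", folds = 10),
               "single class")
})
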