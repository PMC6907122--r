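#' Build a supervised trajectory dataset for a target disease
#'
#' Implements the trajectory-to-features protocol: for each patient with at
#' least two visits and each eligible index visit `v >= 2`, the features are
#' the diseases seen at visits strictly before `v` (the target excluded,
#' even if seen earlier) and the label is 1 iff the target appears at visit
#' `v`. Positive instances are capped at one per patient (the first
#' occurrence of the target); index visits after the first occurrence are
#' not emitted, so negatives from eventual cases are all pre-onset.
#'
#' @param profiles a `patient_profiles` object from [build_profiles()].
#' @param target a disease code, or a character vector of codes for a
#'   composite target (label 1 if any member occurs).
#' @return an object of class `trajectory_dataset`: list with `X` (binary
#'   integer matrix, instances x features), `y`, `feature_names` (never
#'   containing the target), `provenance` (`data.table`: `patient_id`,
#'   `visit_index`) and `target`.
#' @export
build_dataset <- function(profiles, target) {
  stopifnot(inherits(profiles, "patient_profiles"))
  target <- as.character(target)
  all_codes <- sort(unique(unlist(profiles$disease_set)))
  if (!any(target %in% all_codes))
    warning("target disease absent from all records; all labels will be 0")
  feature_names <- setdiff(all_codes, target)

  eligible <- lengths(profiles$visits) >= 2L
  prof <- profiles[eligible]
  inst_feat <- list(); inst_y <- integer(0)
  inst_pid <- character(0); inst_vis <- integer(0)
  ptr <- 0L
  for (r in seq_len(nrow(prof))) {
    visits <- prof$visits[[r]]
    vidx <- prof$visit_index[[r]]
    hist <- character(0)
    for (v in seq_along(visits)) {
      if (v >= 2L) {
        label <- as.integer(any(target %in% visits[[v]]))
        ptr <- ptr + 1L
        inst_feat[[ptr]] <- hist
        inst_y[ptr] <- label
        inst_pid[ptr] <- prof$patient_id[r]
        inst_vis[ptr] <- vidx[v]
        if (label == 1L) break  # one positive per patient, stop at onset
      }
      hist <- union(hist, setdiff(visits[[v]], target))
    }
  }
  X <- matrix(0L, length(inst_y), length(feature_names),
              dimnames = list(NULL, feature_names))
  fi <- unlist(lapply(inst_feat, match, table = feature_names),
               use.names = FALSE)
  ri <- rep.int(seq_along(inst_feat), lengths(inst_feat))
  if (length(ri)) X[cbind(ri, fi)] <- 1L
  structure(list(
    X = X, y = inst_y, feature_names = feature_names,
    provenance = data.table(patient_id = inst_pid, visit_index = inst_vis),
    target = target
  ), class = "trajectory_dataset")
}

#' @export
print.trajectory_dataset <- function(x, ...) {
  cat(sprintf("<trajectory_dataset> %d instances (%d positive), %d features, target %s\n",
              length(x$y), sum(x$y), length(x$feature_names),
              paste(x$target, collapse = "+")))
  invisible(x)
}

subset_dataset <- function(dataset, idx) {
  structure(list(
    X = dataset$X[idx, , drop = FALSE], y = dataset$y[idx],
    feature_names = dataset$feature_names,
    provenance = dataset$provenance[idx],
    target = dataset$target
  ), class = "trajectory_dataset")
}

#' Assemble a balanced benchmark from a trajectory dataset
#'
#' Draws `n_pos` positive and `n_neg` negative instances (seeded uniform
#' sampling). By default the negative pool is restricted to instances of
#' target-free patients (patients with no positive instance), the
#' incident case-control design: pre-onset visits of eventual cases carry the
#' case's risk profile with a label of 0 and would otherwise cap attainable
#' precision. Set `exclude_case_patients = FALSE` to draw from all
#' label-0 instances.
#'
#' @param dataset a `trajectory_dataset`.
#' @param n_pos,n_neg class sizes (the construction used balanced sets).
#' @param seed sampling seed.
#' @param exclude_case_patients see Description.
#' @return a `trajectory_dataset` restricted to the benchmark instances.
#' @export
assemble_benchmark <- function(dataset, n_pos, n_neg, seed = 1L,
                               exclude_case_patients = TRUE) {
  stopifnot(inherits(dataset, "trajectory_dataset"))
  pos_pool <- which(dataset$y == 1L)
  neg_pool <- which(dataset$y == 0L)
  if (exclude_case_patients) {
    case_patients <- unique(dataset$provenance$patient_id[pos_pool])
    neg_pool <- neg_pool[!dataset$provenance$patient_id[neg_pool] %in%
                           case_patients]
  }
  if (length(pos_pool) < n_pos)
    stop_bad_arg(sprintf("insufficient positive instances: %d available, %d requested",
                         length(pos_pool), n_pos))
  if (length(neg_pool) < n_neg)
    stop_bad_arg(sprintf("insufficient negative instances: %d available, %d requested",
                         length(neg_pool), n_neg))
  withr::with_seed(seed, {
    pos <- if (length(pos_pool) == n_pos) pos_pool else
      sample(pos_pool, n_pos)
    neg <- if (length(neg_pool) == n_neg) neg_pool else
      sample(neg_pool, n_neg)
  })
  subset_dataset(dataset, sort(c(pos, neg)))
}

# grouped stratified folds: all instances of a patient share a fold;
# patients are stratified by whether they contribute a positive instance
grouped_folds <- function(provenance, y, folds, seed) {
  pid <- provenance$patient_id
  patient_pos <- tapply(y, pid, max)
  withr::with_seed(seed, {
    fold_of <- integer(0)
    for (cls in c(1, 0)) {
      pats <- names(patient_pos)[patient_pos == cls]
      if (!length(pats)) next
      pats <- sample(pats)
      fold_of[pats] <- rep_len(seq_len(folds), length(pats))
    }
  })
  unname(fold_of[pid])
}

fold_metrics <- function(y_true, y_pred) {
  tp <- sum(y_pred == 1L & y_true == 1L)
  fp <- sum(y_pred == 1L & y_true == 0L)
  fn <- sum(y_pred == 0L & y_true == 1L)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Cross-validated evaluation of the four classifier families
#'
#' Runs stratified 10-fold cross-validation grouped by patient (no patient's
#' instances are split across folds) for the requested models, reporting
#' mean and standard deviation over folds of positive-class precision,
#' recall and F1. Final models are also fitted on the full benchmark for
#' feature-importance extraction.
#'
#' @param benchmark a `trajectory_dataset` (typically from
#'   [assemble_benchmark()]) containing both classes.
#' @param models subset of `c("lr", "svm", "rf", "nn")`.
#' @param folds number of folds.
#' @param seed seed controlling fold assignment and model randomness.
#' @param settings named list of per-model settings overrides, e.g.
#'   `list(rf = list(ntree = 50))`.
#' @return an object of class `evaluation_report`: list with `metrics`
#'   (`data.table`: model, mean/sd of precision, recall, F1), `models`
#'   (final fitted models) and `folds`.
#' @export
train_evaluate <- function(benchmark, models = c("lr", "svm", "rf", "nn"),
                           folds = 10L, seed = 1L, settings = list()) {
  stopifnot(inherits(benchmark, "trajectory_dataset"))
  models <- match.arg(models, c("lr", "svm", "rf", "nn"), several.ok = TRUE)
  folds <- check_count(folds, "folds", min = 2L)
  if (length(unique(benchmark$y)) < 2L)
    stop_bad_arg("benchmark must contain both classes")
  fold_id <- grouped_folds(benchmark$provenance, benchmark$y, folds,
                           derive_seed(seed, "folds"))
  for (f in seq_len(folds)) {
    ytr <- benchmark$y[fold_id != f]
    if (length(unique(ytr)) < 2L)
      stop_bad_arg(sprintf("training split of fold %d has a single class; use fewer folds", f))
  }
  metrics <- list(); fitted <- list()
  for (mod in models) {
    per_fold <- matrix(NA_real_, folds, 3,
                       dimnames = list(NULL, c("precision", "recall", "f1")))
    for (f in seq_len(folds)) {
      tr <- fold_id != f; te <- !tr
      fit <- fit_model(mod, benchmark$X[tr, , drop = FALSE],
                       benchmark$y[tr], settings = settings[[mod]] %||% list(),
                       seed = derive_seed(seed, paste0(mod, "-fold", f)))
      prob <- predict(fit, benchmark$X[te, , drop = FALSE])
      per_fold[f, ] <- fold_metrics(benchmark$y[te],
                                    as.integer(prob > 0.5))
    }
    fitted[[mod]] <- fit_model(mod, benchmark$X, benchmark$y,
                               settings = settings[[mod]] %||% list(),
                               seed = derive_seed(seed, paste0(mod, "-final")))
    metrics[[mod]] <- data.table(
      model = mod,
      precision_mean = mean(per_fold[, "precision"]),
      precision_sd = sd(per_fold[, "precision"]),
      recall_mean = mean(per_fold[, "recall"]),
      recall_sd = sd(per_fold[, "recall"]),
      f1_mean = mean(per_fold[, "f1"]),
      f1_sd = sd(per_fold[, "f1"]))
  }
  structure(list(metrics = rbindlist(metrics), models = fitted,
                 folds = folds),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> 10-fold grouped CV (mean +/- sd)\n")
  m <- x$metrics
  for (r in seq_len(nrow(m)))
    cat(sprintf("  %-4s precision %.4f +/- %.4f  recall %.4f +/- %.4f  F1 %.4f +/- %.4f\n",
                m$model[r], m$precision_mean[r], m$precision_sd[r],
                m$recall_mean[r], m$recall_sd[r], m$f1_mean[r], m$f1_sd[r]))
  invisible(x)
}

#' Ranked risk-disease features per fitted model
#'
#' Linear models (`lr`, `svm`) are ranked by coefficient magnitude with the
#' sign retained; the random forest by impurity importance. The network has
#' no comparable per-feature score and is skipped.
#'
#' @param report an `evaluation_report` (or a named list of
#'   `comorbinet_model`s).
#' @param k number of top features per model.
#' @return named list of `data.table`s (`feature`, `score`), one per model.
#' @export
extract_risk_features <- function(report, k = 10L) {
  models <- if (inherits(report, "evaluation_report")) report$models
            else report
  k <- check_count(k, "k")
  out <- list()
  for (nm in names(models)) {
    fit <- models[[nm]]
    score <- switch(fit$kind,
      lr = fit$coefficients,
      svm = fit$coefficients,
      rf = fit$importance,
      nn = NULL)
    if (is.null(score)) next
    kk <- k
    if (kk > length(score)) {
      warning(sprintf("k = %d exceeds feature count %d for %s; returning all",
                      kk, length(score), nm))
      kk <- length(score)
    }
    ord <- order(-abs(score), names(score))
    out[[nm]] <- data.table(feature = names(score)[ord[seq_len(kk)]],
                            score = unname(score[ord[seq_len(kk)]]))
  }
  out
}
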