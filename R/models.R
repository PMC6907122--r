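# The four classifier families (ridge logistic regression, linear SVM,
# random forest, two-hidden-layer feedforward network). The forest and the
# network are implemented in-package (no suitable library in the supported
# environment); the SVM is a primal squared-hinge minimiser; logistic
# regression is glmnet ridge.

#' Fit one of the four supported classifiers
#'
#' Settings default to: logistic regression with L2 penalty at regularization
#' intensity 1; linear-kernel max-margin classifier with error penalty
#' C = 10; random forest with 180 trees, bootstrap sampling, Gini impurity,
#' OOB scoring and per-node `mtry = floor(sqrt(p))`; feedforward network with
#' two hidden layers, Adam at learning rate 0.001, mini-batches of
#' `min(200, n)` and at most 200 epochs.
#'
#' @param kind one of `"lr"`, `"svm"`, `"rf"`, `"nn"`.
#' @param x binary 0/1 feature matrix.
#' @param y binary 0/1 labels.
#' @param settings named list overriding the model's defaults.
#' @param seed integer seed for the model's randomness.
#' @return a fitted model of class `comorbinet_model`.
#' @export
fit_model <- function(kind = c("lr", "svm", "rf", "nn"), x, y,
                      settings = list(), seed = 1L) {
  kind <- match.arg(kind)
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop_bad_arg("training data must contain both classes")
  fit <- switch(kind,
    lr = fit_lr(x, y, settings),
    svm = fit_svm(x, y, settings),
    rf = withr::with_seed(seed, fit_rf(x, y, settings)),
    nn = withr::with_seed(seed, fit_nn(x, y, settings)))
  structure(c(fit, list(kind = kind, feature_names = colnames(x))),
            class = "comorbinet_model")
}

#' @export
print.comorbinet_model <- function(x, ...) {
  cat(sprintf("<comorbinet_model> kind = %s, %d features\n",
              x$kind, length(x$feature_names)))
  invisible(x)
}

#' Predicted positive-class probabilities
#'
#' @param object a `comorbinet_model`.
#' @param newdata binary feature matrix with the training columns.
#' @param ... unused.
#' @return numeric vector of probabilities (a monotone margin transform for
#'   the SVM).
#' @export
predict.comorbinet_model <- function(object, newdata, ...) {
  switch(object$kind,
    lr = as.numeric(predict(object$fit, newx = newdata, type = "response",
                            s = object$lambda)),
    svm = stats::plogis(as.numeric(newdata %*% object$w + object$b)),
    rf = as.numeric(predict_forest_cpp(object$trees,
                                       storage_matrix(newdata))),
    nn = mlp_forward(object$params, newdata)$prob)
}

storage_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  x
}

fit_lr <- function(x, y, settings) {
  intensity <- settings$intensity %||% 1      # sklearn-style C
  lambda <- settings$lambda %||% (1 / (length(y) * intensity))
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  list(fit = fit, lambda = lambda,
       coefficients = stats::setNames(as.numeric(stats::coef(fit))[-1],
                                      colnames(x)))
}

# primal linear SVM: minimise 0.5 ||w||^2 + C * sum(max(0, 1 - y f)^2)
# (squared hinge keeps the objective differentiable for L-BFGS)
fit_svm <- function(x, y, settings) {
  C <- settings$C %||% 10
  ys <- ifelse(y == 1L, 1, -1)
  n <- nrow(x); d <- ncol(x)
  obj <- function(theta) {
    w <- theta[1:d]; b <- theta[d + 1]
    m <- 1 - ys * (as.numeric(x %*% w) + b)
    0.5 * sum(w^2) + C * sum(pmax(m, 0)^2)
  }
  grad <- function(theta) {
    w <- theta[1:d]; b <- theta[d + 1]
    m <- 1 - ys * (as.numeric(x %*% w) + b)
    act <- pmax(m, 0)
    gw <- w - 2 * C * as.numeric(crossprod(x, ys * act))
    gb <- -2 * C * sum(ys * act)
    c(gw, gb)
  }
  opt <- optim(rep(0, d + 1), obj, grad, method = "L-BFGS-B",
               control = list(maxit = 200))
  list(w = opt$par[1:d], b = opt$par[d + 1],
       coefficients = stats::setNames(opt$par[1:d], colnames(x)))
}

fit_rf <- function(x, y, settings) {
  ntree <- settings$ntree %||% 180L
  mtry <- settings$mtry %||% max(1L, floor(sqrt(ncol(x))))
  min_node <- settings$min_node %||% 2L
  max_depth <- settings$max_depth %||% 30L
  f <- grow_forest_cpp(storage_matrix(x), as.integer(y), as.integer(ntree),
                       as.integer(mtry), as.integer(min_node),
                       as.integer(max_depth), TRUE)
  list(trees = f$trees, oob_score = f$oob_score,
       importance = stats::setNames(as.numeric(f$importance), colnames(x)))
}

mlp_forward <- function(p, x) {
  a1 <- pmax(x %*% p$W1 + rep(p$b1, each = nrow(x)), 0)
  a2 <- pmax(a1 %*% p$W2 + rep(p$b2, each = nrow(a1)), 0)
  z <- as.numeric(a2 %*% p$W3 + p$b3)
  list(a1 = a1, a2 = a2, prob = stats::plogis(z))
}

# two-hidden-layer ReLU MLP, Adam, mini-batch, cross-entropy; stops early
# when the epoch loss stops improving (tol 1e-4 over 10 epochs)
fit_nn <- function(x, y, settings) {
  hidden <- settings$hidden %||% c(32L, 16L)
  lr <- settings$learning_rate %||% 0.001
  epochs <- settings$max_epochs %||% 200L
  batch <- settings$batch_size %||% min(200L, nrow(x))
  n <- nrow(x); d <- ncol(x)
  h1 <- hidden[1]; h2 <- hidden[2]
  p <- list(W1 = matrix(stats::rnorm(d * h1, 0, sqrt(2 / d)), d, h1),
            b1 = rep(0, h1),
            W2 = matrix(stats::rnorm(h1 * h2, 0, sqrt(2 / h1)), h1, h2),
            b2 = rep(0, h2),
            W3 = matrix(stats::rnorm(h2, 0, sqrt(2 / h2)), h2, 1),
            b3 = 0)
  m <- lapply(p, function(q) q * 0)
  v <- lapply(p, function(q) q * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0
  best <- Inf; stale <- 0L
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    loss <- 0
    for (start in seq(1, n, by = batch)) {
      sel <- ord[start:min(start + batch - 1, n)]
      xb <- x[sel, , drop = FALSE]; yb <- y[sel]
      fw <- mlp_forward(p, xb)
      prob <- pmin(pmax(fw$prob, 1e-12), 1 - 1e-12)
      loss <- loss - sum(yb * log(prob) + (1 - yb) * log(1 - prob))
      dz <- matrix(fw$prob - yb, ncol = 1) / length(sel)
      g <- list()
      g$W3 <- crossprod(fw$a2, dz); g$b3 <- sum(dz)
      da2 <- (dz %*% t(p$W3)) * (fw$a2 > 0)
      g$W2 <- crossprod(fw$a1, da2); g$b2 <- colSums(da2)
      da1 <- (da2 %*% t(p$W2)) * (fw$a1 > 0)
      g$W1 <- crossprod(xb, da1); g$b1 <- colSums(da1)
      t_step <- t_step + 1
      for (nm in names(p)) {
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g[[nm]]
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g[[nm]]^2
        mh <- m[[nm]] / (1 - beta1^t_step)
        vh <- v[[nm]] / (1 - beta2^t_step)
        p[[nm]] <- p[[nm]] - lr * mh / (sqrt(vh) + eps)
      }
    }
    loss <- loss / n
    if (loss < best - 1e-4) { best <- loss; stale <- 0L } else {
      stale <- stale + 1L
      if (stale >= 10L) break
    }
  }
  list(params = p, epochs_run = epoch)
}
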