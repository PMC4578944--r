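#' Binary regulator-to-target feature matrix
#'
#' Encodes the network as an n-by-m binary matrix: `x_ij = 1` when there is
#' a direct edge from regulator `j` to target `i`.  Targets are all
#' labelled nodes that are not themselves in the regulator list; rows with
#' all-zero features are retained (they are classified at the model
#' intercept or default).
#'
#' @param network a [grn].
#' @param regulator_ids ordered character vector of feature regulators.
#' @param labels named vector of +1/-1 labels (names are gene ids).
#' @return List of class `feature_matrix`: `X` (n x m binary), `y`
#'   (+1/-1), `regulator_ids`, `target_ids`.
#' @export
build_feature_matrix <- function(network, regulator_ids, labels) {
  stopifnot(inherits(network, "grn"))
  if (!length(regulator_ids))
    stop("configuration error: empty regulator list")
  if (!all(labels %in% c(-1, 1)))
    stop("labels must be +1 or -1")
  targets <- setdiff(names(labels), regulator_ids)
  known <- intersect(targets, grn_nodes(network)$id)
  targets <- targets[targets %in% known]
  X <- matrix(0L, length(targets), length(regulator_ids),
              dimnames = list(targets, regulator_ids))
  el <- grn_edges(network)
  el <- el[el$from %in% regulator_ids & el$to %in% targets, , drop = FALSE]
  if (nrow(el))
    X[cbind(match(el$to, targets), match(el$from, regulator_ids))] <- 1L
  structure(list(X = X, y = unname(labels[targets]),
                 regulator_ids = regulator_ids, target_ids = targets),
            class = "feature_matrix")
}

# Moore-Penrose pseudo-inverse via SVD.
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 1e-300)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Closed-form linear regression of expression labels on binary features
#'
#' Solves the normal equations for `y = b0 + X b + e` with an intercept
#' absorbed as a constant column; when the design is rank-deficient the
#' minimum-norm least-squares solution (pseudo-inverse) is returned.
#' Residuals are orthogonal to the design.
#'
#' @param X n x m binary feature matrix.
#' @param y length-n +1/-1 (or numeric) response.
#' @return List: `weights` (length m), `intercept`, `fitted`.
#' @export
fit_linear <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("no training rows")
  stopifnot(nrow(X) == length(y))
  D <- cbind(1, X)
  beta <- drop(pinv(D) %*% y)
  list(weights = beta[-1], intercept = beta[1],
       fitted = drop(D %*% beta))
}

# Score new rows with a fitted linear model.
predict_linear <- function(fit, X_new) {
  drop(cbind(1, as.matrix(X_new)) %*% c(fit$intercept, fit$weights))
}

#' First principal component as an unsupervised expression predictor
#'
#' Computes the unit eigenvector of the (uncentered, by default) n x n
#' matrix `X X^T` with the largest eigenvalue — equivalently the first
#' left singular vector of `X` — and uses it as the predicted expression
#' score of the n targets.  The eigenvector's sign is arbitrary, so it is
#' oriented to correlate non-negatively with the row sums of `X` (total
#' regulatory input); ties in the leading eigenvalue resolve to the first
#' singular vector returned by LAPACK, which is deterministic.  When
#' `newdata` is supplied the component is computed on `X` (training rows)
#' and new rows are projected onto the corresponding right singular
#' vector.
#'
#' @param X n x m feature matrix (training rows).
#' @param newdata optional matrix of rows to score instead of `X`.
#' @param center subtract column means first (default `FALSE`: the
#'   predictor operates on the raw binary design).
#' @return Numeric score vector for `X` rows, or for `newdata` rows.
#' @export
pca_first_component <- function(X, newdata = NULL, center = FALSE) {
  X <- as.matrix(X)
  if (center) {
    mu <- colMeans(X)
    X <- sweep(X, 2, mu)
  }
  s <- svd(X)
  if (max(s$d) <= 1e-12)
    stop("undefined principal component: feature matrix has rank 0")
  w <- s$v[, 1]
  train_scores <- drop(X %*% w)
  rs <- rowSums(X)
  orient <- suppressWarnings(stats::cor(train_scores, rs))
  if (is.na(orient)) orient <- sum(train_scores)
  if (orient < 0) w <- -w
  if (is.null(newdata)) {
    sc <- drop(X %*% w)
  } else {
    newdata <- as.matrix(newdata)
    if (center) newdata <- sweep(newdata, 2, mu)
    sc <- drop(newdata %*% w)
  }
  sc
}

#' SVM grid-search specification
#'
#' Radial-basis-function support vector models tuned over a grid of cost
#' `C` and kernel width `gamma`, spaced in powers of 4 over the standard
#' libsvm search ranges.
#'
#' @param model `"SVR"` or `"SVC"`.
#' @param C_grid,gamma_grid candidate values.
#' @return List of class `model_spec`.
#' @export
model_spec <- function(model = c("SVR", "SVC"),
                       C_grid = 2^seq(-5, 15, by = 4),
                       gamma_grid = 2^seq(-15, 3, by = 4)) {
  model <- match.arg(model)
  if (!length(C_grid) || !length(gamma_grid))
    stop("grid must be nonempty")
  structure(list(model = model, C_grid = C_grid, gamma_grid = gamma_grid),
            class = "model_spec")
}

#' Fit an RBF support vector model with nested grid search and predict
#'
#' `(C, gamma)` are selected by 5-fold cross-validation on the training
#' data — maximizing AUROC of the regression scores (SVR) or MCC of the
#' class predictions (SVC) — then the model is refit on all training rows
#' and applied to the test rows.  Grid order breaks selection ties
#' (first best wins), so results are deterministic under a fixed seed.
#'
#' @param X_train,y_train training rows and +1/-1 labels.
#' @param X_test rows to predict.
#' @param spec a [model_spec()].
#' @param rng_seed seed for the inner fold assignment.
#' @param inner_k inner cross-validation folds (default 5).
#' @return List: `scores` (real scores for SVR, +1/-1 predictions for
#'   SVC), `best_C`, `best_gamma`, `inner_metric`.
#' @export
svm_fit_predict <- function(X_train, y_train, X_test, spec = model_spec(),
                            rng_seed = 1L, inner_k = 5L) {
  stopifnot(inherits(spec, "model_spec"))
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  if (length(unique(y_train)) < 2)
    stop("single-class training labels")
  folds <- with_seed(rng_seed,
                     make_folds(length(y_train), min(inner_k, length(y_train))))
  grid <- expand.grid(C = spec$C_grid, gamma = spec$gamma_grid)
  inner_metric <- apply(grid, 1, function(p) {
    vals <- vapply(seq_along(folds), function(f) {
      tr <- setdiff(seq_along(y_train), folds[[f]])
      te <- folds[[f]]
      if (length(unique(y_train[tr])) < 2 ||
          length(unique(y_train[te])) < 2) return(NA_real_)
      sc <- svm_raw(X_train[tr, , drop = FALSE], y_train[tr],
                    X_train[te, , drop = FALSE], spec$model,
                    p[["C"]], p[["gamma"]])
      if (spec$model == "SVR") tryCatch(auroc(sc, y_train[te]),
                                        error = function(e) NA_real_)
      else mcc(confusion_counts(sc, y_train[te]))
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  })
  inner_metric[is.nan(inner_metric)] <- -Inf
  best <- which.max(inner_metric)
  scores <- svm_raw(X_train, y_train, X_test, spec$model,
                    grid$C[best], grid$gamma[best])
  list(scores = scores, best_C = grid$C[best], best_gamma = grid$gamma[best],
       inner_metric = inner_metric[best])
}

# One libsvm fit + prediction.  SVR returns real scores; SVC returns +1/-1.
svm_raw <- function(X_tr, y_tr, X_te, model, C, gamma) {
  if (model == "SVR") {
    fit <- e1071::svm(X_tr, y_tr, type = "eps-regression", kernel = "radial",
                      cost = C, gamma = gamma, scale = FALSE)
    if (nrow(X_te) == 0) return(numeric(0))
    unname(stats::predict(fit, X_te))
  } else {
    fit <- e1071::svm(X_tr, factor(y_tr, levels = c(-1, 1)),
                      type = "C-classification", kernel = "radial",
                      cost = C, gamma = gamma, scale = FALSE)
    if (nrow(X_te) == 0) return(numeric(0))
    as.numeric(as.character(stats::predict(fit, X_te)))
  }
}

#' Area under the ROC curve by trapezoidal integration
#'
#' Sweeps the decision threshold over the full score range (predicting +1
#' when the score is at least the threshold), accumulates TPR and FPR with
#' tied scores crossing the threshold simultaneously, and integrates the
#' ROC curve by the trapezoidal rule.  This equals the tie-corrected
#' Mann-Whitney statistic.
#'
#' @param scores real-valued predictions.
#' @param y +1/-1 labels.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, y) {
  stopifnot(length(scores) == length(y))
  pos <- y > 0
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("undefined AUROC: labels contain a single class")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  ## group tied scores: thresholds descend through distinct values
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / n1)
  fpr <- c(0, fp[last] / n0)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Confusion counts of +1/-1 predictions against labels
#'
#' @param pred,y +1/-1 vectors.
#' @return Named list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(pred, y) {
  list(TP = sum(pred > 0 & y > 0), FP = sum(pred > 0 & y < 0),
       TN = sum(pred < 0 & y < 0), FN = sum(pred < 0 & y > 0))
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, the
#' correlation between binary predictions and labels; a balanced measure
#' over both classes.  If any denominator factor is zero (a degenerate
#' prediction or label split) the value is 0 by convention.
#'
#' @param counts list or named vector with `TP`, `FP`, `TN`, `FN`.
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); fp <- as.numeric(counts[["FP"]])
  tn <- as.numeric(counts[["TN"]]); fn <- as.numeric(counts[["FN"]])
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

# Random near-equal partition of n items into k folds.
make_folds <- function(n, k) {
  idx <- sample.int(n)
  unname(split(idx, cut(seq_len(n), breaks = k, labels = FALSE)))
}

#' Cross-validated expression classification
#'
#' Randomly partitions the targets into `k` near-equal folds and evaluates
#' a model with each fold held out once: linear regression and the PCA
#' first component are fit (or computed) on the training rows and score
#' the test rows; the support vector models apply the nested protocol —
#' each rotation is an 80/20 split whose training portion undergoes an
#' inner 5-fold grid search, the tuned model is refit on the full training
#' portion and scored on the held-out fold.  The reported metric (AUROC,
#' or MCC for SVC) is the mean over folds; folds whose test labels are
#' single-class are pooled into one metric over all held-out scores
#' instead.
#'
#' @param matrix a [build_feature_matrix()] result.
#' @param model `"LR"`, `"PCA"`, `"SVR"` or `"SVC"`.
#' @param k number of folds (default 5).
#' @param rng_seed seed for the fold partition (recorded in the output).
#' @param spec a [model_spec()] for the SVM models.
#' @param pca_center passed to [pca_first_component()].
#' @return List of class `classification_result`: `model`, `metric`
#'   (`"auroc"` or `"mcc"`), `mean`, `per_fold`, `n_folds`, `rng_seed`,
#'   `pooled` (logical), and for SVMs `selected` (per-fold `C`, `gamma`).
#' @export
cross_validate <- function(matrix, model = c("LR", "PCA", "SVR", "SVC"),
                           k = 5L, rng_seed = 1L, spec = NULL,
                           pca_center = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(matrix, "feature_matrix"))
  X <- matrix$X; y <- matrix$y
  n <- nrow(X)
  if (k < 2 || k > n) stop("k must lie in [2, n]")
  if (is.null(spec) && model %in% c("SVR", "SVC"))
    spec <- model_spec(model)
  folds <- with_seed(rng_seed, make_folds(n, k))
  scores <- numeric(n)
  selected <- NULL
  for (f in seq_along(folds)) {
    te <- folds[[f]]
    tr <- setdiff(seq_len(n), te)
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    sc <- switch(model,
      LR = predict_linear(fit_linear(Xtr, y[tr]), Xte),
      PCA = pca_first_component(Xtr, newdata = Xte, center = pca_center),
      {
        res <- svm_fit_predict(Xtr, y[tr], Xte, spec,
                               rng_seed = derive_seed(rng_seed, f))
        selected <- rbind(selected,
                          data.frame(fold = f, C = res$best_C,
                                     gamma = res$best_gamma))
        res$scores
      })
    scores[te] <- sc
  }
  metric_fun <- if (model == "SVC")
    function(sc, yy) mcc(confusion_counts(sc, yy)) else auroc
  per_fold <- vapply(folds, function(te) {
    if (length(unique(y[te])) < 2) return(NA_real_)
    metric_fun(scores[te], y[te])
  }, numeric(1))
  pooled <- anyNA(per_fold)
  mean_metric <- if (pooled) metric_fun(scores, y)
                 else mean(per_fold)
  structure(list(model = model,
                 metric = if (model == "SVC") "mcc" else "auroc",
                 mean = mean_metric,
                 per_fold = unname(per_fold), n_folds = k,
                 rng_seed = rng_seed, pooled = pooled,
                 scores = stats::setNames(scores, matrix$target_ids),
                 selected = selected),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("%s: mean %s = %.4f over %d folds%s\n", x$model, x$metric,
              x$mean, x$n_folds, if (x$pooled) " (pooled)" else ""))
  invisible(x)
}
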