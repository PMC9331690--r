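#' Robust feature scaling (median / IQR)
#'
#' `x' = (x - median_train) / IQR_train` per feature, with statistics
#' fitted on the training rows only. A feature with zero IQR is centered
#' but not divided.
#'
#' @param train numeric matrix/data.frame of training features.
#' @param other optional matrix of further rows (validation/test) scaled
#'   with the training statistics.
#' @return list `train`, `other` (or `NULL`), and `params`
#'   (`center`, `scale`).
#' @export
robust_scale_fit_transform <- function(train, other = NULL) {
  train <- as.matrix(train)
  if (nrow(train) < 2L) stopf("need at least 2 training rows")
  ctr <- apply(train, 2, median)
  iqr <- apply(train, 2, function(x)
    diff(quantile(x, c(0.25, 0.75), names = FALSE, type = 7)))
  scl <- ifelse(iqr > 0, iqr, 1)
  params <- list(center = ctr, scale = scl)
  list(train = robust_scale_apply(params, train),
       other = if (!is.null(other)) robust_scale_apply(params, other),
       params = params)
}

#' @rdname robust_scale_fit_transform
#' @param params fitted scaler parameters.
#' @param x rows to scale.
#' @export
robust_scale_apply <- function(params, x) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, params$center), 2, params$scale, `/`)
}

# Decision scores oriented so that larger = favorable class "1".
svm_scores <- function(fit, x) {
  pr <- predict(fit, as.matrix(x), decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  sgn <- if (strsplit(colnames(dv)[1], "/")[[1]][1] == "1") 1 else -1
  as.numeric(dv) * sgn
}

# Stratified k-fold assignment.
stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

KERNEL_ORDER <- c(linear = 1, rbf = 2, poly = 3, sigmoid = 4)
E1071_KERNEL <- c(linear = "linear", rbf = "radial", poly = "polynomial",
                  sigmoid = "sigmoid")

# Cap on the effective cost of homogeneous polynomial candidates: with
# coef0 = 0, poly(gamma, C) is exactly equivalent to poly(1, C*gamma^3),
# and beyond ~1e4 on robust-scaled features the solution is numerically
# hard-margin while the SMO solver burns its full iteration budget.
POLY_COST_CAP <- 1e4

# Candidates that collapse to the same effective model share one fit.
svm_candidate_key <- function(kernel, C, gamma) {
  if (kernel == "poly")
    sprintf("poly_%g", min(C * gamma^3, POLY_COST_CAP))
  else if (kernel == "linear") sprintf("linear_%g", C)
  else sprintf("%s_%g_%g", kernel, C, gamma)
}

fit_svm_candidate <- function(x, yf, kernel, C, gamma, degree) {
  if (kernel == "poly") {
    e1071::svm(x, yf, kernel = "polynomial", degree = degree, coef0 = 0,
               gamma = 1, cost = min(C * gamma^degree, POLY_COST_CAP),
               scale = FALSE)
  } else {
    e1071::svm(x, yf, kernel = E1071_KERNEL[[kernel]], cost = C,
               gamma = gamma, degree = degree, scale = FALSE)
  }
}

#' Grid-search an SVM over kernels, C and gamma
#'
#' Evaluates every combination of the four kernel types with
#' `gamma` and `C` on decade grids `10^-2 ... 10^3` (144 candidates) by
#' mean AUC over stratified 5-fold cross-validation on the training
#' rows, then refits the winner on all training data. Ties are broken
#' toward smaller `C`, then simpler kernels (linear < rbf < poly <
#' sigmoid), then smaller `gamma`. Features must already be scaled (the
#' scaler is fitted on the full training set, as in the study
#' protocol).
#'
#' @param x training feature matrix (scaled).
#' @param y binary outcome vector (0/1).
#' @param folds number of CV folds (default 5).
#' @param seed seed for fold assignment.
#' @param kernels,C,gamma grid definition.
#' @param degree polynomial degree (fixed default 3).
#' @return A `svm_model_spec`: chosen `kernel`, `C`, `gamma`,
#'   `cv_auc`, the refitted `fit`, and the full `grid` of candidate
#'   results.
#' @export
grid_search_svm <- function(x, y, folds = 5, seed = 1,
                            kernels = c("linear", "rbf", "poly", "sigmoid"),
                            C = 10^(-2:3), gamma = 10^(-2:3), degree = 3) {
  x <- as.matrix(x); y <- as.integer(y)
  if (length(unique(y)) < 2L) stopf("training set must contain both classes")
  fold <- stratified_folds(y, folds, seed)
  if (any(vapply(seq_len(folds), function(f)
    length(unique(y[fold == f])) < 2L, TRUE)))
    stopf("stratified folds must contain both classes")
  grid <- expand.grid(kernel = kernels, C = C, gamma = gamma,
                      stringsAsFactors = FALSE)
  yf <- factor(y, levels = c(0, 1))
  auc_mat <- matrix(NA_real_, nrow(grid), folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    cache <- new.env(parent = emptyenv())
    for (g in seq_len(nrow(grid))) {
      key <- svm_candidate_key(grid$kernel[g], grid$C[g], grid$gamma[g])
      if (is.null(cache[[key]])) {
        fit <- fit_svm_candidate(x[tr, , drop = FALSE], yf[tr],
                                 grid$kernel[g], grid$C[g], grid$gamma[g],
                                 degree)
        cache[[key]] <- roc_auc(svm_scores(fit, x[!tr, , drop = FALSE]),
                                y[!tr])$auc
      }
      auc_mat[g, f] <- cache[[key]]
    }
  }
  grid$cv_auc <- rowMeans(auc_mat)
  ord <- order(-grid$cv_auc, grid$C, KERNEL_ORDER[grid$kernel], grid$gamma)
  best <- grid[ord[1], ]
  fit <- fit_svm_candidate(x, yf, best$kernel, best$C, best$gamma, degree)
  structure(list(kernel = best$kernel, C = best$C, gamma = best$gamma,
                 degree = degree, cv_auc = best$cv_auc, fit = fit,
                 grid = grid, feature_names = colnames(x)),
            class = "svm_model_spec")
}

#' Evaluate a fitted SVM on a train/test split
#'
#' Accuracy at the decision threshold, precision and recall for the
#' favorable class, and the Mann-Whitney AUC of the continuous decision
#' scores.
#'
#' @param model a [grid_search_svm()] result.
#' @param x_train,y_train,x_test,y_test scaled features and labels.
#' @return list of metrics plus the persisted test confusion counts.
#' @export
evaluate_svm <- function(model, x_train, y_train, x_test, y_test) {
  if (length(y_test) == 0L) stopf("test set is empty")
  if (length(unique(y_test)) < 2L)
    stopf("test set lacks a class: AUC undefined")
  pred_tr <- as.integer(as.character(predict(model$fit, as.matrix(x_train))))
  pred_te <- as.integer(as.character(predict(model$fit, as.matrix(x_test))))
  sc <- svm_scores(model$fit, x_test)
  tp <- sum(pred_te == 1 & y_test == 1)
  fp <- sum(pred_te == 1 & y_test == 0)
  fn <- sum(pred_te == 0 & y_test == 1)
  tn <- sum(pred_te == 0 & y_test == 0)
  list(train_accuracy = mean(pred_tr == y_train),
       test_accuracy = (tp + tn) / (tp + fp + fn + tn),
       auc = roc_auc(sc, y_test)$auc,
       precision = if (tp + fp > 0) tp / (tp + fp) else 0,
       recall = if (tp + fn > 0) tp / (tp + fn) else 0,
       scores = sc,
       confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
       kernel = model$kernel, C = model$C, gamma = model$gamma)
}

# Medoid background sample for SHAP: k-means on the training rows, then
# the nearest actual row to each center.
medoid_background <- function(x, size = 25, seed = 1) {
  x <- as.matrix(x)
  if (nrow(x) <= size) return(x)
  with_seed(seed, {
    km <- kmeans(x, centers = size, nstart = 3, iter.max = 50)
    idx <- vapply(seq_len(size), function(k) {
      d2 <- rowSums(sweep(x, 2, km$centers[k, ])^2)
      which.min(d2)
    }, 0L)
    x[unique(idx), , drop = FALSE]
  })
}
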