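#' ROC curve and Mann-Whitney AUC
#'
#' The AUC is the Mann-Whitney pair-counting estimator (ties credited
#' 1/2), computed from midranks; the curve is the threshold sweep over
#' unique score values. In the absence of ties the trapezoidal area of
#' the curve equals the estimator exactly.
#'
#' @param scores numeric decision scores (higher = more positive).
#' @param labels binary labels (0/1).
#' @return A `roc_result`: `auc`, `curve` (data.frame `fpr`, `tpr`),
#'   `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stopf("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1L - y)
  last <- !duplicated(grp, fromLast = TRUE)
  curve <- data.frame(fpr = c(0, fp[last] / n0), tpr = c(0, tp[last] / n1))
  structure(list(auc = auc, curve = curve, n_pos = n1, n_neg = n0),
            class = "roc_result")
}

# Placement values (structural components) for a set of classifiers:
# rows of `scores` are classifiers. Returns V10 (n_pos cols) / V01.
delong_placements <- function(scores, labels) {
  pos <- labels == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  v10 <- matrix(0, nrow(scores), n1)
  v01 <- matrix(0, nrow(scores), n0)
  auc <- numeric(nrow(scores))
  for (k in seq_len(nrow(scores))) {
    s <- scores[k, ]
    tx <- rank(s, ties.method = "average")
    ty <- rank(s[pos], ties.method = "average")
    tz <- rank(s[!pos], ties.method = "average")
    v10[k, ] <- (tx[pos] - ty) / n0
    v01[k, ] <- 1 - (tx[!pos] - tz) / n1
    auc[k] <- (sum(tx[pos]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
  }
  list(v10 = v10, v01 = v01, auc = auc, n_pos = n1, n_neg = n0)
}

#' DeLong's test for two correlated AUCs
#'
#' Fast placement-value implementation: per-subject structural
#' components of the Mann-Whitney statistic for each classifier, the
#' covariance matrix of the paired AUCs from the component covariances,
#' and a two-sided normal p-value for the AUC difference.
#'
#' @param scores_a,scores_b decision scores of the two classifiers on
#'   the same subjects.
#' @param labels shared binary labels.
#' @return A `delong_result`: `auc_a`, `auc_b`, `var_diff`, `z`,
#'   `p_two_sided`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stopf("scores and labels must be aligned")
  labels <- as.integer(labels)
  if (!all(labels %in% 0:1) || length(unique(labels)) < 2L)
    stopf("both classes must be present")
  pl <- delong_placements(rbind(scores_a, scores_b), labels)
  s10 <- stats::cov(t(pl$v10))
  s01 <- stats::cov(t(pl$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / pl$n_pos +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / pl$n_neg
  delta <- pl$auc[1] - pl$auc[2]
  if (var_diff <= .Machine$double.eps) {
    if (abs(delta) <= .Machine$double.eps^0.5) {
      z <- 0; p <- 1
    } else stopf("degenerate DeLong variance with a nonzero AUC difference")
  } else {
    z <- delta / sqrt(var_diff)
    p <- 2 * (1 - pnorm(abs(z)))
  }
  structure(list(auc_a = pl$auc[1], auc_b = pl$auc[2], var_diff = var_diff,
                 z = z, p_two_sided = p),
            class = "delong_result")
}

# Shapley kernel weight for a coalition of size s among m players.
shap_kernel_weight <- function(m, s) {
  (m - 1) / (choose(m, s) * s * (m - s))
}

#' Kernel SHAP attributions for a single instance
#'
#' Solves the Shapley-kernel weighted least-squares system over
#' coalitions of present/absent features; absent features are imputed by
#' averaging the model over the background rows. The empty and full
#' coalitions are always respected through the local-accuracy
#' constraint `sum(phi) = f(x) - E_background[f]`, enforced by
#' eliminating one coefficient. When all `2^m - 2` proper coalitions fit
#' into `n_samples` they are enumerated and the solution equals the
#' exact Shapley values.
#'
#' @param model_fn function mapping a feature matrix to numeric scores.
#' @param x numeric feature vector of the instance to explain.
#' @param background matrix of background rows (one per row).
#' @param n_samples number of coalitions to evaluate (default 2048).
#' @param seed RNG seed for coalition sampling.
#' @return A `shap_result`: `phi` (named like `x`), `base_value`,
#'   `fx`.
#' @export
kernel_shap <- function(model_fn, x, background, n_samples = 2048, seed = 1) {
  m <- length(x)
  background <- as.matrix(background)
  if (nrow(background) < 1L) stopf("background must be nonempty")
  if (n_samples < m + 2) stopf("n_samples must be at least n_features + 2")
  base_value <- mean(model_fn(background))
  fx <- as.numeric(model_fn(matrix(x, nrow = 1)))
  delta <- fx - base_value

  full <- (2^m - 2) <= n_samples && m <= 25
  Z <- if (full) {
    zz <- matrix(0L, 2^m - 2, m)
    for (s in seq_len(2^m - 2))
      zz[s, ] <- as.integer(intToBits(s)[1:m])
    zz
  } else {
    with_seed(seed, {
      sizes <- 1:(m - 1)
      pr <- 1 / (sizes * (m - sizes))
      smp <- sample(sizes, n_samples, replace = TRUE, prob = pr / sum(pr))
      t(vapply(smp, function(s) {
        z <- integer(m); z[sample.int(m, s)] <- 1L; z
      }, integer(m)))
    })
  }
  w <- vapply(rowSums(Z), function(s) shap_kernel_weight(m, s), 0)
  if (!full) w <- rep(1, nrow(Z)) # sampling already follows the kernel

  # model evaluations: coalition-present values from x, absent from the
  # background rows, averaged over the background
  nb <- nrow(background)
  big <- background[rep(seq_len(nb), times = nrow(Z)), , drop = FALSE]
  zrep <- Z[rep(seq_len(nrow(Z)), each = nb), , drop = FALSE] == 1L
  xrep <- matrix(x, nrow(big), m, byrow = TRUE)
  big[zrep] <- xrep[zrep]
  vals <- model_fn(big)
  v <- colMeans(matrix(vals, nrow = nb))

  # constrained WLS: eliminate feature m via sum(phi) = delta
  zm <- Z[, m]
  Zc <- Z[, -m, drop = FALSE] - zm
  yc <- v - base_value - zm * delta
  A <- crossprod(Zc * w, Zc)
  b <- crossprod(Zc * w, yc)
  phi_rest <- tryCatch(solve(A, b),
                       error = function(e) solve(A + diag(1e-10, m - 1), b))
  phi <- c(phi_rest, delta - sum(phi_rest))
  names(phi) <- names(x) %||% paste0("f", seq_len(m))
  structure(list(phi = phi, base_value = base_value, fx = fx),
            class = "shap_result")
}

#' Rank features by mean absolute SHAP value
#'
#' @param shap_list list of [kernel_shap()] results over subjects.
#' @param feature_names optional names (defaults to the first result's).
#' @param k number of top features to keep (default 15; capped at the
#'   feature count).
#' @return data.frame `feature`, `mean_abs_phi`, `rank`, plus the full
#'   per-subject phi matrix as attribute `phi_matrix`.
#' @export
importance_report <- function(shap_list, feature_names = NULL, k = 15) {
  if (length(shap_list) < 1L) stopf("need at least one explained subject")
  phi <- do.call(rbind, lapply(shap_list, `[[`, "phi"))
  feature_names <- feature_names %||% colnames(phi)
  imp <- colMeans(abs(phi))
  ord <- order(imp, decreasing = TRUE)
  k <- min(k, length(imp))
  out <- data.frame(feature = feature_names[ord][seq_len(k)],
                    mean_abs_phi = imp[ord][seq_len(k)],
                    rank = seq_len(k), stringsAsFactors = FALSE)
  attr(out, "phi_matrix") <- phi
  attr(out, "full_ranking") <- feature_names[ord]
  out
}
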