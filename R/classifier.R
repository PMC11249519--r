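# L2-penalised logistic regression and ROC machinery.
#
# The model minimises (1/(2C)) ||w||^2 + sum_i log(1 + exp(-y_i (x_i w + b)))
# with the intercept unpenalised, i.e. the scikit-learn parameterisation
# with inverse regularisation strength C (default 0.1 throughout the
# subtype analyses). Fitting is full Newton with step halving; the
# penalty keeps the optimum finite even on separable data.

#' Fit an L2-penalised logistic regression
#'
#' @param features numeric matrix, samples x features (no missing
#'   values).
#' @param labels binary labels; a factor/character vector whose second
#'   sorted level is the positive class, or a 0/1 vector.
#' @param C inverse regularisation strength (default 0.1).
#' @param standardize center/scale features before fitting (default
#'   FALSE; ln(count+1) features are already on a comparable scale).
#' @param tol convergence tolerance on the gradient max-norm (default 1e-6).
#' @param max_iter Newton iteration cap (default 200).
#' @return a `logistic_model`: list `weights`, `intercept`, `C`,
#'   `feature_names`, `positive_class`, plus standardization parameters.
#' @export
fit_logistic <- function(features, labels, C = 0.1, standardize = FALSE,
                         tol = 1e-6, max_iter = 200L) {
  stopifnot(C > 0)
  x <- as.matrix(features)
  if (any(!is.finite(x))) stop("non-finite feature values")
  enc <- encode_labels(labels)
  y <- enc$y
  if (length(unique(y)) < 2L) stop("both classes must be present")
  ctr <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
  if (standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2L, stats::sd)
    scl[scl == 0] <- 1
    x <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  }
  n <- nrow(x); d <- ncol(x)
  X <- cbind(`(Intercept)` = 1, x)
  lambda <- c(0, rep(1 / C, d))  # intercept unpenalised
  beta <- numeric(d + 1L)
  obj <- function(b) {
    yz <- y * drop(X %*% b)
    # numerically stable sum of log(1 + exp(-y z))
    sum(log1p(exp(-abs(yz))) + pmax(-yz, 0)) + sum(lambda * b^2) / 2
  }
  for (iter in seq_len(max_iter)) {
    z <- drop(X %*% beta)
    p <- 1 / (1 + exp(-z))
    g <- drop(crossprod(X, p - (y + 1) / 2)) + lambda * beta
    if (max(abs(g)) < tol) break
    w <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(X * w, X) + diag(lambda, d + 1L)
    step <- solve(H, g)
    f0 <- obj(beta)
    t_ <- 1
    repeat {
      b_new <- beta - t_ * step
      if (obj(b_new) <= f0 || t_ < 1e-8) break
      t_ <- t_ / 2
    }
    beta <- b_new
  }
  structure(list(weights = stats::setNames(beta[-1L], colnames(x)),
                 intercept = unname(beta[1L]), C = C,
                 feature_names = colnames(x),
                 positive_class = enc$positive,
                 center = ctr, scale = scl, standardize = standardize),
            class = "logistic_model")
}

encode_labels <- function(labels) {
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    list(y = ifelse(labels == 1, 1, -1), positive = "1",
         pos_mask = labels == 1)
  } else {
    lv <- sort(unique(as.character(labels)))
    if (length(lv) != 2L) stop("labels must have exactly two classes")
    pos <- lv[2L]
    list(y = ifelse(labels == pos, 1, -1), positive = pos,
         pos_mask = as.character(labels) == pos)
  }
}

#' Predict class probabilities
#'
#' @param model a `logistic_model` from [fit_logistic()].
#' @param features numeric matrix with the model's feature dimension.
#' @return probabilities of the positive class in `[0,1]`.
#' @export
predict_scores <- function(model, features) {
  x <- as.matrix(features)
  if (ncol(x) != length(model$weights)) {
    stop(sprintf("feature dimension mismatch: %d vs %d", ncol(x),
                 length(model$weights)))
  }
  if (model$standardize) {
    x <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
  }
  z <- drop(x %*% model$weights) + model$intercept
  1 / (1 + exp(-z))
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a random positive outscores a random negative,
#' with ties counted one half.
#'
#' @param scores numeric scores.
#' @param labels binary labels (second sorted level = positive).
#' @return AUC in `[0,1]`.
#' @export
auc <- function(scores, labels) {
  pos <- encode_labels(labels)$pos_mask
  m <- sum(pos); n <- sum(!pos)
  if (m == 0L || n == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - m * (m + 1) / 2) / (m * n)
}

#' DeLong 95% confidence interval for the AUC
#'
#' Structural-components (DeLong) variance of the Mann-Whitney AUC and a
#' normal interval `AUC +/- z * SE`, clipped to `[0,1]`.
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @param level confidence level (default 0.95).
#' @return list `auc`, `se`, `ci_low`, `ci_high`.
#' @export
delong_ci <- function(scores, labels, level = 0.95) {
  pos <- encode_labels(labels)$pos_mask
  xs <- scores[pos]; ys <- scores[!pos]
  m <- length(xs); n <- length(ys)
  if (m < 2L || n < 2L) stop("need at least two samples per class")
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  # V10_i = mean_j psi(x_i, y_j); V01_j = mean_i psi(x_i, y_j)
  M <- outer(xs, ys, psi)
  a <- mean(M)
  v10 <- rowMeans(M)
  v01 <- colMeans(M)
  s10 <- stats::var(v10)
  s01 <- stats::var(v01)
  se <- sqrt(s10 / m + s01 / n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(auc = a, se = se,
       ci_low = max(0, a - z * se), ci_high = min(1, a + z * se))
}

#' Cross-validated pooled ROC evaluation
#'
#' Scores every sample exactly once with a model never trained on it
#' (leave-one-out, or stratified k-fold), pools all held-out scores into
#' one ROC and reports AUC with a DeLong interval.
#'
#' @param features numeric samples x features matrix.
#' @param labels binary labels.
#' @param scheme `"loocv"` or `"kfold"`.
#' @param k folds for `"kfold"` (default 10).
#' @param seed integer seed for fold assignment (`"kfold"` only).
#' @param C inverse regularisation strength (default 0.1).
#' @param standardize passed to [fit_logistic()].
#' @param level confidence level (default 0.95).
#' @return a `roc_result`: list `auc`, `ci_low`, `ci_high`, `se`,
#'   `scores` (pooled held-out), `labels`, `accuracy` (at 0.5), `scheme`.
#' @export
cross_validate <- function(features, labels, scheme = c("loocv", "kfold"),
                           k = 10L, seed = 1L, C = 0.1, standardize = FALSE,
                           level = 0.95) {
  scheme <- match.arg(scheme)
  x <- as.matrix(features)
  n <- nrow(x)
  lab <- as.character(labels)
  enc <- encode_labels(lab)
  folds <- if (scheme == "loocv") {
    seq_len(n)
  } else {
    if (min(table(lab)) < 2L) stop("k-fold needs >= 2 samples per class")
    set.seed(seed)
    f <- integer(n)
    for (cl in unique(lab)) {
      idx <- sample(which(lab == cl))
      f[idx] <- rep_len(seq_len(k), length(idx))
    }
    f
  }
  scores <- rep(NA_real_, n)
  for (fold in sort(unique(folds))) {
    test <- folds == fold
    if (length(unique(lab[!test])) < 2L) {
      stop("training fold lost a class; use fewer folds")
    }
    model <- fit_logistic(x[!test, , drop = FALSE], lab[!test], C = C,
                          standardize = standardize)
    scores[test] <- predict_scores(model, x[test, , drop = FALSE])
  }
  ci <- delong_ci(scores, lab, level = level)
  pred_pos <- scores >= 0.5
  structure(list(auc = ci$auc, ci_low = ci$ci_low, ci_high = ci$ci_high,
                 se = ci$se, scores = scores, labels = lab,
                 accuracy = mean(pred_pos == enc$pos_mask),
                 scheme = scheme),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %s: AUC %.3f (95%% DeLong CI %.3f-%.3f), accuracy %.3f, n = %d\n",
              x$scheme, x$auc, x$ci_low, x$ci_high, x$accuracy,
              length(x$scores)))
  invisible(x)
}

#' Save / load a logistic model as JSON
#'
#' @param model a `logistic_model`.
#' @param path JSON path.
#' @return `path` (write) or a `logistic_model` (read).
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$weights <- stats::setNames(as.numeric(m$weights), m$feature_names)
  structure(m, class = "logistic_model")
}
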