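rbf_kernel <- function(a, b, gamma) {
  # ||x-y||^2 = |x|^2 + |y|^2 - 2 x.y, computed blockwise
  an <- rowSums(a * a)
  bn <- rowSums(b * b)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Train a soft-margin RBF-kernel SVM
#'
#' Sequential minimal optimization with maximal-violating-pair working-set
#' selection on the dual problem. Defaults follow the common library
#' convention: `C = 1` and `gamma = "scale"` = `1 / (ncol(x) * var(x))`. The
#' dual optimum is unique for a positive-definite kernel, so training is
#' deterministic and invariant to row order (up to the convergence
#' tolerance).
#'
#' @param x Numeric feature matrix, one row per training pair.
#' @param y Labels: logical, 0/1, or -1/+1. Both classes must be present.
#' @param C Box constraint (default 1).
#' @param gamma Kernel width, or `"scale"`.
#' @param tol Duality-gap tolerance for the stopping rule.
#' @param max_iter Safety cap on SMO iterations.
#' @return An object of class `svm_rbf`.
#' @export
svm_train <- function(x, y, C = 1, gamma = "scale", tol = 1e-6, max_iter = 200000L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.logical(y)) y <- ifelse(y, 1, -1)
  y <- as.numeric(y)
  y[y == 0] <- -1
  if (!all(y %in% c(-1, 1))) stop("svm_train: labels must be binary", call. = FALSE)
  if (length(unique(y)) < 2L) stop("svm_train: single-class input", call. = FALSE)
  n <- nrow(x)
  stopifnot(length(y) == n)
  if (identical(gamma, "scale")) {
    v <- var(as.numeric(x))
    gamma <- if (is.na(v) || v < 1e-12) 1 else 1 / (ncol(x) * v)
  }

  K <- rbf_kernel(x, x, gamma)
  Q <- K * tcrossprod(y)
  alpha <- numeric(n)
  grad <- rep(-1, n)  # dual gradient: Q alpha - 1
  eps <- 1e-12

  for (iter in seq_len(max_iter)) {
    up <- (y > 0 & alpha < C - eps) | (y < 0 & alpha > eps)
    low <- (y > 0 & alpha > eps) | (y < 0 & alpha < C - eps)
    score <- -y * grad
    if (!any(up) || !any(low)) break
    i <- which(up)[which.max(score[up])]
    j <- which(low)[which.min(score[low])]
    gap <- score[i] - score[j]
    if (gap < tol) break

    quad <- max(K[i, i] + K[j, j] - 2 * K[i, j], 1e-12)
    d <- gap / quad
    # box limits for alpha_i + y_i d and alpha_j - y_j d in [0, C]
    d_max <- min(if (y[i] > 0) C - alpha[i] else alpha[i],
                 if (y[j] > 0) alpha[j] else C - alpha[j])
    d <- min(d, d_max)
    if (d <= 0) break
    dai <- y[i] * d
    daj <- -y[j] * d
    alpha[i] <- alpha[i] + dai
    alpha[j] <- alpha[j] + daj
    grad <- grad + Q[, i] * dai + Q[, j] * daj
  }

  f <- as.numeric(K %*% (alpha * y))
  free <- alpha > eps & alpha < C - eps
  b <- if (any(free)) {
    mean(y[free] - f[free])
  } else if (any(alpha > eps)) {
    mean(y[alpha > eps] - f[alpha > eps])
  } else 0

  sv <- alpha > eps
  structure(list(
    sv_x = x[sv, , drop = FALSE],
    sv_coef = (alpha * y)[sv],
    b = b, gamma = gamma, C = C,
    features = colnames(x), n_train = n
  ), class = "svm_rbf")
}

#' Predict with an RBF SVM
#'
#' @param object An `svm_rbf` model.
#' @param newdata Numeric matrix or data frame of feature rows.
#' @param type `"class"` for -1/+1 labels, `"decision"` for the raw decision
#'   values.
#' @param ... Unused.
#' @return Numeric vector of labels or decision values.
#' @export
predict.svm_rbf <- function(object, newdata, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  f <- as.numeric(rbf_kernel(newdata, object$sv_x, object$gamma) %*% object$sv_coef) +
    object$b
  if (type == "decision") f else ifelse(f >= 0, 1, -1)
}

#' @export
print.svm_rbf <- function(x, ...) {
  cat(sprintf("<svm_rbf> %d SVs, gamma=%.4g, C=%g, features=%s\n",
              nrow(x$sv_x), x$gamma, x$C,
              paste(x$features, collapse = ",")))
  invisible(x)
}
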