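#' Train a maximum-margin classifier on a precomputed kernel
#'
#' Solves the standard soft-margin SVM dual
#' `min 1/2 a' Q a - e' a` subject to `0 <= a_i <= C`, `sum a_i y_i = 0`
#' (with `Q_ij = y_i y_j K_ij`) by sequential minimal optimization with
#' deterministic maximal-violating-pair working-set selection, so training
#' is reproducible given the same Gram matrix, labels and C. No external
#' solver is involved; the decision function follows the precomputed-kernel
#' contract `f(x) = sum_j alpha_j y_j K(x, j) + b`.
#'
#' @param K symmetric Gram matrix over the training instances.
#' @param labels logical (TRUE = interaction) or +/-1 numeric labels.
#' @param C box constraint (regularization), default 1.
#' @param tol KKT violation tolerance for convergence.
#' @param max_iter safety cap on working-set iterations.
#' @return object of class `hsp_svm`: list with `alpha`, `y`, `b`,
#'   `support` (indices with alpha > 0), `C`, `iterations`, `converged`.
#' @export
svm_train <- function(K, labels, C = 1.0, tol = 1e-4, max_iter = 100000L) {
  n <- nrow(K)
  if (n != ncol(K)) stop("gram matrix must be square")
  if (length(labels) != n) stop("labels length must match gram size")
  y <- if (is.logical(labels)) ifelse(labels, 1, -1) else as.numeric(labels)
  if (!all(y %in% c(-1, 1))) stop("labels must be logical or +/-1")
  if (length(unique(y)) < 2L) {
    stop("degenerate training set: only one class present")
  }

  alpha <- numeric(n)
  grad <- rep(-1, n)                    # gradient of the dual objective
  Qy <- K * tcrossprod(y)               # Q_ij = y_i y_j K_ij
  eps <- 1e-12
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    # maximal violating pair (LIBSVM WSS1): i from I_up, j from I_low
    up <- (y > 0 & alpha < C - eps) | (y < 0 & alpha > eps)
    lo <- (y > 0 & alpha > eps) | (y < 0 & alpha < C - eps)
    if (!any(up) || !any(lo)) { converged <- TRUE; break }
    f <- -y * grad
    i <- which(up)[which.max(f[up])]
    j <- which(lo)[which.min(f[lo])]
    if (f[i] - f[j] < tol) { converged <- TRUE; break }

    # two-variable subproblem along the constraint sum a y = const:
    # a_i moves by y_i * s, a_j by -y_j * s, s >= 0
    quad <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (quad <= eps) quad <- eps
    delta <- (f[i] - f[j]) / quad
    headroom_i <- if (y[i] > 0) C - alpha[i] else alpha[i]
    headroom_j <- if (y[j] > 0) alpha[j] else C - alpha[j]
    s <- min(delta, headroom_i, headroom_j)
    if (s < eps) { converged <- TRUE; break }
    ti <- y[i] * s
    tj <- -y[j] * s
    grad <- grad + Qy[, i] * ti + Qy[, j] * tj
    alpha[i] <- alpha[i] + ti
    alpha[j] <- alpha[j] + tj
  }

  # bias from the KKT conditions: average over free support vectors
  free <- alpha > eps & alpha < C - eps
  fi <- as.vector(K %*% (alpha * y))
  if (any(free)) {
    # for free SVs, y_i (f_raw(x_i) + b) = 1, i.e. b = y_i - f_raw(x_i)
    b <- mean((y - fi)[free])
  } else {
    up <- (y > 0 & alpha < C - eps) | (y < 0 & alpha > eps)
    lo <- (y > 0 & alpha > eps) | (y < 0 & alpha < C - eps)
    lower <- if (any(up)) max((y - fi)[up]) else 0
    upper <- if (any(lo)) min((y - fi)[lo]) else 0
    b <- (lower + upper) / 2
  }

  structure(list(alpha = alpha, y = y, b = b,
                 support = which(alpha > eps), C = C,
                 iterations = it, converged = converged),
            class = "hsp_svm")
}

#' @export
print.hsp_svm <- function(x, ...) {
  cat(sprintf(
    "hsp_svm: %d training instances, %d support vectors, C = %g, b = %.4g\n",
    length(x$alpha), length(x$support), x$C, x$b))
  if (!x$converged) cat("  warning: iteration cap reached before convergence\n")
  invisible(x)
}

#' Decision values for new instances
#'
#' @param model an `hsp_svm` from [svm_train()].
#' @param K_cross kernel matrix, rows = new instances, columns = the
#'   training instances the model was fit on (same order).
#' @return numeric vector of decision values; positive predicts an
#'   interaction.
#' @export
svm_decision <- function(model, K_cross) {
  if (ncol(K_cross) != length(model$alpha)) {
    stop("K_cross columns must match the training instances")
  }
  as.vector(K_cross %*% (model$alpha * model$y)) + model$b
}
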