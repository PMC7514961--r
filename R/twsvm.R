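# Kernel twin support vector machine. Two nonparallel hyperplanes in the
# kernel-expanded space,
#     K(x, C') u1 + b1 = 0   and   K(x, C') u2 + b2 = 0,
# are fitted by a pair of small quadratic programs: each plane is pulled
# close to its own class (least squares) and pushed at least unit distance
# from the other class (hinge constraints with penalty c1/c2). The duals are
# box-constrained QPs with no equality constraint, solved here by exact
# cyclic coordinate descent; the primal variables are recovered through the
# standard substitution w = -(H'H + eps I)^{-1} G' alpha (and its mirror
# image for the second plane). A test point is assigned to the class of the
# nearer plane.

#' Gaussian (RBF) kernel matrix
#'
#' Entry (i, j) is \eqn{\exp(-\lVert x_i - y_j \rVert^2 / (2\sigma^2))}.
#'
#' @param X,Y Numeric matrices with the same number of columns (rows are
#'   observations).
#' @param sigma Kernel width (> 0).
#' @return A `nrow(X)` x `nrow(Y)` kernel matrix.
#' @export
gaussian_kernel <- function(X, Y, sigma) {
  X <- as_feature_matrix(X)
  Y <- as_feature_matrix(Y)
  if (ncol(X) != ncol(Y)) {
    stop("`X` and `Y` must have the same number of columns", call. = FALSE)
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("`sigma` must be a single positive number", call. = FALSE)
  }
  same <- identical(X, Y)
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0  # numerical negative zeros
  K <- exp(-d2 / (2 * sigma^2))
  if (same) {
    # enforce exact symmetry and unit diagonal for Gram matrices
    K <- (K + t(K)) / 2
    diag(K) <- 1
  }
  K
}

as_feature_matrix <- function(X) {
  if (is.null(dim(X))) X <- matrix(as.numeric(X), nrow = 1L)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("feature matrix must be finite", call. = FALSE)
  X
}

kernel_matrix <- function(X, Y, kernel, sigma) {
  switch(kernel,
         gaussian = gaussian_kernel(X, Y, sigma),
         linear = tcrossprod(as_feature_matrix(X), as_feature_matrix(Y)),
         stop(sprintf("unknown kernel '%s'", kernel), call. = FALSE))
}

# Exact cyclic coordinate descent for  min 1/2 a'Qa - e'a,  0 <= a <= upper.
# Q must be symmetric positive semidefinite. Each coordinate update is the
# exact box-clipped minimiser, so the objective is monotonically
# non-increasing; iteration stops when the KKT conditions hold: the
# projected-gradient residual  a - clip(a - (Qa - e), 0, upper)  is the
# exact optimality measure for a box-constrained QP and, unlike the raw step
# size, does not stall on degenerate (flat) faces of the feasible box. The
# tolerance is scaled by the curvature of Q so that badly scaled duals
# (Q entries ~1e6 when the Gram block is nearly singular) terminate once
# the solution is converged relative to machine precision at that scale.
solve_box_qp <- function(Q, upper, tol = 1e-12, max_sweeps = 50000L) {
  m <- nrow(Q)
  a <- numeric(m)
  g <- rep(-1, m)          # gradient Qa - e at a = 0
  qdiag <- diag(Q)
  tol <- tol * max(1, upper, max(qdiag))
  for (sweep in seq_len(max_sweeps)) {
    for (i in seq_len(m)) {
      new_ai <- if (qdiag[i] > 1e-14) {
        min(max(a[i] - g[i] / qdiag[i], 0), upper)
      } else {
        # (near-)linear coordinate: slope decides which bound
        if (g[i] < 0) upper else 0
      }
      d <- new_ai - a[i]
      if (d != 0) {
        a[i] <- new_ai
        g <- g + Q[, i] * d
      }
    }
    g <- drop(Q %*% a) - 1  # refresh: incremental updates accumulate fp drift
    residual <- max(abs(a - pmin(pmax(a - g, 0), upper)))
    if (residual <= tol) {
      return(list(solution = a, sweeps = sweep, converged = TRUE))
    }
  }
  stop(sprintf("box-QP coordinate descent did not converge in %d sweeps (KKT residual %.3e)",
               max_sweeps, residual), call. = FALSE)
}

# Solve one of the two TWSVM problems. H_own = [K(own,C) e], G_other =
# [K(other,C) e]; returns the dual vector and the primal (u, b) with the
# plane-specific sign.
solve_twsvm_plane <- function(H_own, G_other, penalty, sign, ridge) {
  p <- ncol(H_own)
  M <- crossprod(H_own) + diag(ridge, p)
  R <- chol(M)
  # Q = G M^{-1} G'
  GM <- t(backsolve(R, forwardsolve(t(R), t(G_other))))
  Q <- tcrossprod(GM, G_other)
  Q <- (Q + t(Q)) / 2
  sol <- solve_box_qp(Q, penalty)
  alpha <- sol$solution
  w <- sign * backsolve(R, forwardsolve(t(R), crossprod(G_other, alpha)))
  dual_obj <- sum(alpha) - 0.5 * sum(alpha * (Q %*% alpha))
  list(u = w[-length(w)], b = w[length(w)], dual = alpha,
       dual_objective = dual_obj, sweeps = sol$sweeps)
}

#' Fit a kernel twin support vector machine
#'
#' Fits the two nonparallel hyperplanes. The positive class (+1, abnormal)
#' is matrix A, the negative class (-1, normal) matrix B, and C stacks all
#' training rows. Features are z-scored with training statistics by default
#' (subband norms, entropy and fractal dimension live on very different
#' scales, and a Gaussian kernel would otherwise be dominated by the norms).
#'
#' @param X Numeric matrix of training feature vectors (rows = samples).
#' @param y Labels in \{+1, -1\} (+1 = abnormal/positive).
#' @param c1,c2 Penalty parameters of the two problems (> 0); default 3.5.
#' @param sigma1,sigma2 Gaussian kernel widths of the two planes (> 0);
#'   default 3.5. Ignored for `kernel = "linear"`.
#' @param kernel `"gaussian"` (default) or `"linear"`.
#' @param standardize Z-score features using training statistics.
#' @param ridge Tikhonov term added before inversion (the Gram blocks are
#'   singular whenever the class size + 1 is below the number of training
#'   rows).
#' @return An object of class `twsvm_model`.
#' @export
twsvm_fit <- function(X, y, c1 = 3.5, c2 = 3.5, sigma1 = 3.5, sigma2 = 3.5,
                      kernel = c("gaussian", "linear"), standardize = TRUE,
                      ridge = 1e-6) {
  kernel <- match.arg(kernel)
  X <- as_feature_matrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (!all(y %in% c(-1, 1))) stop("labels must be +1 or -1", call. = FALSE)
  if (!any(y == 1) || !any(y == -1)) {
    stop("both classes must be non-empty", call. = FALSE)
  }
  stopifnot(c1 > 0, c2 > 0, sigma1 > 0, sigma2 > 0, ridge >= 0)

  if (standardize) {
    center <- colMeans(X)
    scale_ <- apply(X, 2L, stats::sd)
    scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  } else {
    center <- numeric(ncol(X))
    scale_ <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2L, center), 2L, scale_, "/")

  A <- Xs[y == 1, , drop = FALSE]
  B <- Xs[y == -1, , drop = FALSE]
  C <- Xs
  e1 <- rep(1, nrow(A))
  e2 <- rep(1, nrow(B))

  # plane 1 (positive class): close to A, pushed from B
  KA1 <- kernel_matrix(A, C, kernel, sigma1)
  KB1 <- kernel_matrix(B, C, kernel, sigma1)
  p1 <- solve_twsvm_plane(cbind(KA1, e1), cbind(KB1, e2), c1, -1, ridge)

  # plane 2 (negative class): close to B, pushed from A
  KB2 <- kernel_matrix(B, C, kernel, sigma2)
  KA2 <- kernel_matrix(A, C, kernel, sigma2)
  p2 <- solve_twsvm_plane(cbind(KB2, e2), cbind(KA2, e1), c2, +1, ridge)

  KCC1 <- kernel_matrix(C, C, kernel, sigma1)
  KCC2 <- kernel_matrix(C, C, kernel, sigma2)
  den1 <- sqrt(max(drop(crossprod(p1$u, KCC1 %*% p1$u)), 0))
  den2 <- sqrt(max(drop(crossprod(p2$u, KCC2 %*% p2$u)), 0))
  if (den1 <= 1e-12 || den2 <= 1e-12) {
    stop("degenerate hyperplane: u' K u is zero within tolerance", call. = FALSE)
  }

  structure(
    list(u1 = p1$u, b1 = p1$b, u2 = p2$u, b2 = p2$b,
         alpha = p1$dual, gamma = p2$dual,
         c1 = c1, c2 = c2, sigma1 = sigma1, sigma2 = sigma2,
         kernel = kernel, ridge = ridge,
         C_train = C, scaler = list(center = center, scale = scale_,
                                    enabled = standardize),
         plane_norms = c(den1, den2),
         version = "twinpcg-twsvm-1"),
    class = "twsvm_model"
  )
}

#' @export
print.twsvm_model <- function(x, ...) {
  cat(sprintf(
    "<twsvm_model> %s kernel, %d training rows; c=(%g, %g), sigma=(%g, %g)\n",
    x$kernel, nrow(x$C_train), x$c1, x$c2, x$sigma1, x$sigma2))
  invisible(x)
}

#' Perpendicular distances to the two twin hyperplanes
#'
#' For each row x of `newdata`, returns
#' \eqn{d_k = |K(x, C')u_k + b_k| / \sqrt{u_k' K(C, C') u_k}} for k = 1
#' (abnormal plane) and k = 2 (normal plane). The stored training scaler is
#' applied to `newdata` first.
#'
#' @param model A [twsvm_fit()] model.
#' @param newdata Numeric matrix (or single vector) of feature vectors.
#' @return A matrix with columns `d1`, `d2`.
#' @export
decision_distances <- function(model, newdata) {
  stopifnot(inherits(model, "twsvm_model"))
  X <- as_feature_matrix(newdata)
  if (ncol(X) != ncol(model$C_train)) {
    stop(sprintf("expected %d features, got %d", ncol(model$C_train), ncol(X)),
         call. = FALSE)
  }
  Xs <- sweep(sweep(X, 2L, model$scaler$center), 2L, model$scaler$scale, "/")
  K1 <- kernel_matrix(Xs, model$C_train, model$kernel, model$sigma1)
  K2 <- kernel_matrix(Xs, model$C_train, model$kernel, model$sigma2)
  d1 <- abs(drop(K1 %*% model$u1) + model$b1) / model$plane_norms[1L]
  d2 <- abs(drop(K2 %*% model$u2) + model$b2) / model$plane_norms[2L]
  cbind(d1 = d1, d2 = d2)
}

#' Predict class labels from a twin SVM model
#'
#' A point is assigned to the class whose hyperplane is nearer: +1
#' (abnormal) if its distance to the positive plane is strictly smaller than
#' to the negative plane, otherwise -1 (normal). Ties therefore go to the
#' normal class.
#'
#' @param object A [twsvm_fit()] model.
#' @param newdata Numeric matrix (or single vector) of feature vectors.
#' @param ... Unused.
#' @return Numeric vector of labels in \{+1, -1\}.
#' @export
predict.twsvm_model <- function(object, newdata, ...) {
  d <- decision_distances(object, newdata)
  ifelse(d[, "d1"] < d[, "d2"], 1, -1)
}

#' Save / load a twin SVM model
#'
#' The model is stored as a single-file serialized container carrying the
#' dual coefficients, offsets, hyperparameters, scaler, training matrix and
#' a format version field.
#'
#' @param model A `twsvm_model`.
#' @param path File path.
#' @return `twsvm_save` returns `path` invisibly; `twsvm_load` the model.
#' @export
twsvm_save <- function(model, path) {
  stopifnot(inherits(model, "twsvm_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname twsvm_save
#' @export
twsvm_load <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "twsvm_model") ||
      !identical(model$version, "twinpcg-twsvm-1")) {
    stop(sprintf("'%s' does not contain a twinpcg twin-SVM model", path),
         call. = FALSE)
  }
  model
}
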