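# BLUP Hat matrices and sparse selection indices.
#
# The BLUP of the prediction-set breeding values is u_PS = B y_TS with
# B = K_PS,TS (K_TS + lambda0 I)^(-1) (a Hat matrix: regression
# coefficients of breeding values on training phenotypes).  The sparse
# selection index replaces each row b_i of B by the minimizer of
#   0.5 b' (K_TS + lambda0 I) b - g_i' b + lambda ||b||_1
# where g_i holds the similarities of prediction individual i to the
# training set.  lambda = 0 recovers the BLUP row exactly; lambda >=
# max|g_i| makes the row identically zero.  Rows are independent problems,
# so the Hat matrix may be assembled in any order (or in parallel) with
# identical results.

# ---- hat matrix container ----------------------------------------------

new_hat_matrix <- function(B, training_ids, prediction_ids, lambda, lambda0,
                           kind) {
  dimnames(B) <- list(prediction_ids, training_ids)
  structure(list(B = B, training_ids = training_ids,
                 prediction_ids = prediction_ids, lambda = lambda,
                 lambda0 = lambda0, kind = kind),
            class = "hat_matrix")
}

#' @export
print.hat_matrix <- function(x, ...) {
  nz <- rowSums(x$B != 0)
  cat("hat_matrix (", x$kind, "): ", nrow(x$B), " x ", ncol(x$B),
      ", lambda = ", signif(x$lambda, 4),
      ", mean support = ", round(mean(nz), 1), "\n", sep = "")
  invisible(x)
}

ridge_system <- function(K_TS, lambda0) {
  C <- kernel_mat(K_TS)
  if (nrow(C) != ncol(C) ||
      max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C))))
    stop("K_TS must be symmetric")
  if (lambda0 < 0) stop("'lambda0' must be non-negative")
  C + lambda0 * diag(nrow(C))
}

resolve_blocks <- function(K_TS, K_PS_TS) {
  if (is.list(K_TS) && !inherits(K_TS, "kernel_matrix") &&
      all(c("K_TS", "K_PS_TS") %in% names(K_TS))) {
    # a partition_kernel() result passed as first argument
    part <- K_TS
    return(part)
  }
  KT <- kernel_mat(K_TS)
  KP <- as.matrix(K_PS_TS)
  if (ncol(KP) != nrow(KT))
    stop("K_PS_TS must have one column per training individual (",
         nrow(KT), "), got ", ncol(KP))
  list(K_TS = KT, K_PS_TS = KP,
       training_ids = colnames(KP) %||% rownames(KT) %||%
         paste0("T", seq_len(ncol(KP))),
       prediction_ids = rownames(KP) %||% paste0("P", seq_len(nrow(KP))))
}

# ---- BLUP ---------------------------------------------------------------

#' BLUP Hat matrix B = K_PS,TS (K_TS + lambda0 I)^(-1)
#'
#' Solved as a symmetric positive-definite linear system (Cholesky), never
#' by explicit inversion.
#'
#' @param K_TS training-set kernel block (square), or a
#'   [partition_kernel()] result (in which case `K_PS_TS` is taken from
#'   it).
#' @param K_PS_TS prediction-by-training kernel block.
#' @param lambda0 ridge term sigma2_e / sigma2_u (> 0, or 0 with a
#'   positive-definite kernel).
#' @return A dense `hat_matrix` with `lambda = 0`.
#' @export
blup_hat <- function(K_TS, K_PS_TS = NULL, lambda0) {
  blk <- resolve_blocks(K_TS, K_PS_TS)
  C <- ridge_system(blk$K_TS, lambda0)
  ch <- tryCatch(chol(C), error = function(e)
    stop("system K_TS + lambda0*I is not positive definite; ",
         "use lambda0 > 0 with a PSD-only kernel"))
  Bt <- backsolve(ch, forwardsolve(t(ch), t(blk$K_PS_TS)))
  new_hat_matrix(t(Bt), blk$training_ids, blk$prediction_ids,
                 lambda = 0, lambda0 = lambda0, kind = "blup")
}

# ---- SSI path solver ----------------------------------------------------

#' Geometric lambda grid for the SSI path
#'
#' @param lambda_max largest penalty (zero-solution threshold).
#' @param n number of geometric points from `lambda_max` down to
#'   `min_ratio * lambda_max`.
#' @param min_ratio smallest grid fraction.
#' @param include_zero append lambda = 0 (the BLUP end of the path).
#' @return Decreasing numeric vector.
#' @export
default_lambda_grid <- function(lambda_max, n = 100, min_ratio = 0.001,
                                include_zero = TRUE) {
  g <- lambda_max * exp(seq(0, log(min_ratio), length.out = n))
  if (include_zero) g <- c(g, 0)
  g
}

#' Solve the SSI problem for one prediction individual along a penalty path
#'
#' Cyclic coordinate descent with soft-thresholding and warm starts down a
#' descending lambda grid; after the first full sweep per lambda, iteration
#' is restricted to the active set, followed by a full verification sweep.
#' At lambda = 0 the exact ridge solution C^(-1) g is used (the problem is
#' smooth there and equals the BLUP row).
#'
#' @param g_i similarity vector of the prediction individual to the
#'   training set.
#' @param C the system matrix K_TS + lambda0 I (symmetric positive
#'   definite).
#' @param lambda_grid descending penalty grid; default
#'   [default_lambda_grid()] from this row's lambda_max = max(abs(g_i)).
#' @param tol convergence tolerance on the maximum coefficient change.
#' @param maxit maximum coordinate-descent sweeps per lambda.
#' @return Object of class `ssi_path`: `lambda`, `coef` (n_TS x n_lambda),
#'   `n_sup`, `objective`, `sweeps`, `lambda_max`.
#' @export
ssi_solve_path <- function(g_i, C, lambda_grid = NULL, tol = 1e-5,
                           maxit = 5000) {
  g_i <- as.numeric(g_i)
  C <- as.matrix(C)
  if (length(g_i) != nrow(C)) stop("length(g_i) must match nrow(C)")
  lmax <- max(abs(g_i))
  if (is.null(lambda_grid)) lambda_grid <- default_lambda_grid(lmax)
  if (is.unsorted(rev(lambda_grid)))
    stop("'lambda_grid' must be descending")
  pos <- lambda_grid > 0
  res <- if (any(pos))
    cd_path_cpp(C, g_i, lambda_grid[pos], tol, maxit)
  else list(coef = matrix(0, nrow(C), 0), sweeps = integer(0),
            objective = numeric(0))
  coef <- res$coef
  obj <- res$objective
  sweeps <- res$sweeps
  if (any(!pos)) {
    b0 <- as.numeric(solve(C, g_i))
    coef <- cbind(coef, matrix(b0, ncol = sum(!pos), nrow = nrow(C)))
    obj <- c(obj, rep(0.5 * sum(b0 * (C %*% b0)) - sum(g_i * b0),
                      sum(!pos)))
    sweeps <- c(sweeps, rep(0L, sum(!pos)))
  }
  structure(list(lambda = lambda_grid, coef = coef,
                 n_sup = colSums(coef != 0), objective = obj,
                 sweeps = sweeps, lambda_max = lmax),
            class = "ssi_path")
}

#' Karush-Kuhn-Tucker stationarity check for an SSI solution
#'
#' For r = g - C b: zero coordinates must satisfy |r_j| <= lambda + tol and
#' non-zero ones r_j = lambda * sign(b_j) within tol.
#'
#' @param C system matrix; @param g similarity vector; @param b candidate
#'   solution; @param lambda penalty; @param tol tolerance.
#' @return TRUE if the certificate holds; the largest violation is attached
#'   as attribute `"violation"`.
#' @export
kkt_check <- function(C, g, b, lambda, tol = 1e-6) {
  r <- as.numeric(g - C %*% b)
  viol <- max(ifelse(b == 0, pmax(abs(r) - lambda, 0),
                     abs(r - lambda * sign(b))))
  structure(viol <= tol, violation = viol)
}

# ---- SSI hat matrix -----------------------------------------------------

#' Row-sparse SSI Hat matrix at a common penalty
#'
#' Stacks the per-individual SSI solutions at a shared lambda.  Each row is
#' an independent problem (solved with a short warm-start path from its own
#' lambda_max down to the target), so results do not depend on the order in
#' which rows are computed.  lambda = 0 returns the BLUP Hat matrix.
#'
#' @inheritParams blup_hat
#' @param lambda shared L1 penalty (>= 0).
#' @param bridge number of warm-start path points from lambda_max to
#'   `lambda`.
#' @param tol,maxit passed to the coordinate-descent solver.
#' @return A row-sparse `hat_matrix`.
#' @export
ssi_hat <- function(K_TS, K_PS_TS = NULL, lambda0, lambda, bridge = 10,
                    tol = 1e-5, maxit = 5000) {
  blk <- resolve_blocks(K_TS, K_PS_TS)
  if (lambda < 0) stop("'lambda' must be non-negative")
  if (lambda == 0) {
    h <- blup_hat(blk, lambda0 = lambda0)
    h$kind <- "ssi"
    return(h)
  }
  C <- ridge_system(blk$K_TS, lambda0)
  n_ps <- nrow(blk$K_PS_TS)
  B <- matrix(0, n_ps, ncol(blk$K_PS_TS))
  for (i in seq_len(n_ps)) {
    g_i <- blk$K_PS_TS[i, ]
    lmax <- max(abs(g_i))
    if (lambda >= lmax) next  # zero row is optimal
    grid <- exp(seq(log(lmax), log(lambda), length.out = max(2, bridge)))
    res <- tryCatch(
      cd_path_cpp(C, g_i, grid, tol, maxit),
      error = function(e) stop("SSI row ", i, " (",
                               blk$prediction_ids[i], "): ",
                               conditionMessage(e)))
    B[i, ] <- res$coef[, length(grid)]
  }
  new_hat_matrix(B, blk$training_ids, blk$prediction_ids,
                 lambda = lambda, lambda0 = lambda0, kind = "ssi")
}

# ---- cross-validation ---------------------------------------------------

#' Cross-validate the SSI penalty within the training set
#'
#' Partitions the training set into `n_folds` folds; each fold in turn is a
#' pseudo-prediction set whose SSI paths are solved against the remaining
#' training data on a common relative grid (fractions of each pseudo-
#' problem's lambda_max), and scored by the correlation between the
#' held-out phenotypes and their predictions.  The fraction maximizing the
#' mean accuracy is selected; ties break to the largest (sparsest)
#' fraction.  A single lambda is selected for the whole run.
#'
#' @param y_TS centered training phenotypes (named or in `K_TS` order).
#' @param K_TS training kernel block.
#' @param lambda0 ridge term.
#' @param n_folds number of folds (default 10).
#' @param n_lambda,min_ratio relative grid: `n_lambda` geometric fractions
#'   from 1 down to `min_ratio`, plus 0.
#' @param seed fold-assignment seed.
#' @param tol,maxit solver controls.
#' @return Object of class `cv_result`: `fractions`, `acc` (fold x
#'   fraction), `mean_acc`, `selected_fraction`, `lambda_cv` (selected
#'   fraction times the mean fold lambda_max, an absolute within-TS
#'   value), `seed`.
#' @export
cross_validate_lambda <- function(y_TS, K_TS, lambda0, n_folds = 10,
                                  n_lambda = 100, min_ratio = 0.001,
                                  seed = NULL, tol = 1e-5, maxit = 5000) {
  K <- kernel_mat(K_TS)
  y <- as.numeric(y_TS)
  n <- length(y)
  if (nrow(K) != n) stop("dimension mismatch between y and K")
  if (n < n_folds) stop("training set smaller than the number of folds")
  fractions <- c(exp(seq(0, log(min_ratio), length.out = n_lambda)), 0)
  fold_of <- with_seed(seed,
    sample(rep(seq_len(n_folds), length.out = n)))
  if (min(table(fold_of)) < 3)
    stop("a fold has fewer than 3 individuals (correlation unstable); ",
         "use fewer folds")
  acc <- matrix(NA_real_, n_folds, length(fractions))
  fold_lmax <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    hold <- which(fold_of == f)
    keep <- which(fold_of != f)
    C <- K[keep, keep, drop = FALSE] + lambda0 * diag(length(keep))
    Gp <- K[hold, keep, drop = FALSE]
    lmax <- max(abs(Gp))
    fold_lmax[f] <- lmax
    pos <- fractions > 0
    grid <- fractions[pos] * lmax
    pred <- matrix(0, length(hold), length(fractions))
    for (i in seq_along(hold)) {
      res <- cd_path_cpp(C, Gp[i, ], grid, tol, maxit)
      pred[i, pos] <- as.numeric(crossprod(res$coef, y[keep]))
    }
    if (any(!pos)) {
      # lambda = 0 column: the BLUP prediction, one factorization per fold
      ch <- chol(C)
      B0 <- t(backsolve(ch, forwardsolve(t(ch), t(Gp))))
      pred[, !pos] <- as.numeric(B0 %*% y[keep])
    }
    yv <- y[hold]
    acc[f, ] <- apply(pred, 2, function(p)
      if (sd(p) == 0 || sd(yv) == 0) NA_real_ else cor(yv, p))
  }
  mean_acc <- colMeans(acc, na.rm = TRUE)
  mean_acc[is.nan(mean_acc)] <- -Inf
  best <- max(mean_acc)
  sel <- which(mean_acc >= best - 1e-12)[1]  # first = largest fraction
  structure(list(fractions = fractions, acc = acc, mean_acc = mean_acc,
                 selected_fraction = fractions[sel],
                 lambda_cv = fractions[sel] * mean(fold_lmax),
                 fold_of = fold_of, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result: selected fraction ", signif(x$selected_fraction, 4),
      " of lambda_max (lambda_cv = ", signif(x$lambda_cv, 4), ")\n",
      sep = "")
  invisible(x)
}

# ---- prediction ---------------------------------------------------------

#' Predict breeding values from a Hat matrix
#'
#' u_PS = B y_TS, plus sparsity summaries: n_sup (number of training
#' individuals with a non-zero coefficient) per row and its mean, and
#' %sparsity = 100 * mean(n_sup) / n_TS.
#'
#' @param hat a `hat_matrix`.
#' @param y_TS centered training phenotypes; if named, they are matched to
#'   the Hat matrix's training IDs.
#' @return Object of class `prediction_result`: `u_hat` (named), `n_sup`
#'   (per row), `n_sup_mean`, `pct_sparsity`, `lambda`.
#' @export
predict_hat <- function(hat, y_TS) {
  if (!inherits(hat, "hat_matrix")) stop("'hat' must be a hat_matrix")
  y <- y_TS
  if (!is.null(names(y))) {
    if (!all(hat$training_ids %in% names(y)))
      stop("training phenotypes missing for some Hat-matrix training IDs")
    y <- y[hat$training_ids]
  } else if (length(y) != ncol(hat$B)) {
    stop("phenotype length does not match the Hat matrix training size")
  }
  u <- as.numeric(hat$B %*% y)
  names(u) <- hat$prediction_ids
  n_sup <- rowSums(hat$B != 0)
  structure(list(u_hat = u, n_sup = n_sup, n_sup_mean = mean(n_sup),
                 pct_sparsity = 100 * mean(n_sup) / ncol(hat$B),
                 lambda = hat$lambda, kind = hat$kind),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat("prediction_result (", x$kind, "): ", length(x$u_hat),
      " predictions, mean n_sup = ", round(x$n_sup_mean, 1),
      " (", round(x$pct_sparsity, 1), "% of TS)\n", sep = "")
  invisible(x)
}
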