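#' @useDynLib ssindex, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor dist optimize pchisq rbinom rnorm sd setNames var
#'   rchisq aggregate lm.fit
NULL

# ---- kernel_matrix container -------------------------------------------

#' Kernel (genetic similarity) matrix
#'
#' A symmetric n-by-n similarity matrix over a set of lines, tagged with its
#' kind: `"additive"` for the genomic relationship matrix G = ZZ'/p,
#' `"gaussian"` for K(theta) = exp(-theta * d2tilde), or `"averaged"` for a
#' variance-weighted convex combination of kernels.
#'
#' @param K symmetric numeric matrix.
#' @param ids line IDs in row/column order.
#' @param kind one of `"additive"`, `"gaussian"`, `"averaged"`.
#' @param params list of provenance parameters (theta, dbar, weights, ...).
#' @return An object of class `kernel_matrix`.
#' @export
kernel_matrix <- function(K, ids, kind = c("additive", "gaussian", "averaged"),
                          params = list()) {
  kind <- match.arg(kind)
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("kernel must be square")
  ids <- as.character(ids)
  if (length(ids) != nrow(K)) stop("length of 'ids' != kernel dimension")
  if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K))))
    stop("kernel is not symmetric")
  K <- (K + t(K)) / 2
  dimnames(K) <- list(ids, ids)
  structure(list(K = K, ids = ids, kind = kind, params = params),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat("kernel_matrix (", x$kind, "): ", nrow(x$K), " x ", ncol(x$K), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.kernel_matrix <- function(x) dim(x$K)

# ---- marker standardization and GRM ------------------------------------

#' Center and scale a marker matrix
#'
#' Each marker column is centered by its mean and scaled by its standard
#' deviation, giving the Z matrix used in the genomic relationship matrix
#' G = ZZ'/p.  The scaling denominator is the sample standard deviation
#' (n - 1) by default; the population convention (n) only rescales G by a
#' scalar and is available via `denominator = "n"`.
#'
#' @param markers a [marker_matrix()] or a plain numeric matrix.
#' @param denominator `"n-1"` (sample sd, default) or `"n"`.
#' @return Numeric matrix Z with columns of mean 0 and unit sd.
#' @export
center_scale_markers <- function(markers, denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  X <- if (inherits(markers, "marker_matrix")) markers$X else as.matrix(markers)
  n <- nrow(X)
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  if (denominator == "n") s <- s * sqrt((n - 1) / n)
  mono <- which(s == 0 | !is.finite(s))
  if (length(mono))
    stop("monomorphic marker column(s) cannot be scaled: ",
         paste(colnames(X)[utils::head(mono, 5)], collapse = ", "),
         if (length(mono) > 5) " ..." else "",
         " (run marker QC first)")
  Z <- sweep(sweep(X, 2, mu, "-"), 2, s, "/")
  rownames(Z) <- rownames(X)
  Z
}

#' Additive genomic relationship matrix G = ZZ'/p
#'
#' @param Z centered and scaled marker matrix from [center_scale_markers()].
#' @param p number of markers; must equal `ncol(Z)`.
#' @return A `kernel_matrix` of kind `"additive"`.  Because Z's columns are
#'   centered, the grand sum of G is zero.
#' @export
grm <- function(Z, p = ncol(Z)) {
  if (p != ncol(Z))
    stop("'p' (", p, ") must equal the number of marker columns (",
         ncol(Z), ")")
  G <- tcrossprod(Z) / p
  kernel_matrix(G, ids = rownames(Z) %||% paste0("L", seq_len(nrow(Z))),
                kind = "additive", params = list(p = p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- Gaussian kernels ---------------------------------------------------

#' Scaled squared Euclidean marker distances
#'
#' Computes d2_ij = sum_m (x_im - x_jm)^2 on the raw 0/1 marker codes (for
#' 0/1 data this is the Hamming distance), then divides by the average
#' dbar = (1/n^2) * sum_ij d2_ij taken over all n^2 ordered pairs including
#' the zero diagonal.  The scaled distances average exactly 1 over all n^2
#' pairs.
#'
#' @param markers a [marker_matrix()] or numeric matrix.
#' @return list with `d2tilde` (n x n scaled squared distances), `dbar`
#'   (scalar average squared distance), and `ids`.
#' @export
scaled_sq_distances <- function(markers) {
  X <- if (inherits(markers, "marker_matrix")) markers$X else as.matrix(markers)
  n <- nrow(X)
  if (n < 2) stop("at least two lines are required to compute distances")
  D2 <- as.matrix(dist(X, method = "euclidean"))^2
  dbar <- sum(D2) / n^2
  if (dbar == 0) stop("all lines are identical; distances are degenerate")
  list(d2tilde = D2 / dbar, dbar = dbar,
       ids = rownames(X) %||% paste0("L", seq_len(n)))
}

#' Gaussian kernel K_ij = exp(-theta * d2tilde_ij)
#'
#' @param d2 output of [scaled_sq_distances()] (or a plain matrix of scaled
#'   squared distances).
#' @param theta bandwidth parameter (> 0).  The study's standard bandwidths
#'   are 0.2, 1 and 5; large theta gives a "local" kernel whose similarities
#'   decay quickly with distance.
#' @return A `kernel_matrix` of kind `"gaussian"` with unit diagonal.
#' @export
gaussian_kernel <- function(d2, theta) {
  if (!is.numeric(theta) || length(theta) != 1 || theta <= 0)
    stop("'theta' must be a positive scalar")
  if (is.list(d2)) {
    M <- d2$d2tilde; ids <- d2$ids; dbar <- d2$dbar
  } else {
    M <- as.matrix(d2); ids <- rownames(M) %||% paste0("L", seq_len(nrow(M)))
    dbar <- NA_real_
  }
  K <- exp(-theta * M)
  diag(K) <- 1
  kernel_matrix(K, ids = ids, kind = "gaussian",
                params = list(theta = theta, dbar = dbar))
}

# ---- kernel averaging ---------------------------------------------------

#' Variance-weighted kernel average K_A
#'
#' Combines kernels with weights proportional to their estimated genetic
#' variances: w_k = sigma2_ak / sum(sigma2_a), K_A = sum w_k K_k.
#'
#' @param kernels list of >= 2 `kernel_matrix` objects over the same lines in
#'   the same order.
#' @param variances non-negative per-kernel genetic variances, not all zero.
#' @return A `kernel_matrix` of kind `"averaged"`, with the weights stored in
#'   `params$weights`.
#' @export
kernel_average <- function(kernels, variances) {
  if (length(kernels) < 2) stop("need at least two kernels to average")
  if (length(variances) != length(kernels))
    stop("one variance per kernel is required")
  if (any(variances < 0)) stop("variances must be non-negative")
  if (sum(variances) == 0) stop("variances must not all be zero")
  ids <- kernels[[1]]$ids
  for (k in kernels[-1])
    if (!identical(k$ids, ids))
      stop("kernels do not share the same line ordering")
  w <- variances / sum(variances)
  KA <- Reduce(`+`, Map(function(k, wk) wk * k$K, kernels, w))
  kernel_matrix(KA, ids = ids, kind = "averaged",
                params = list(weights = w,
                              member_kinds = vapply(kernels, `[[`, "",
                                                    "kind")))
}

# ---- partitioning -------------------------------------------------------

#' Extract training and prediction blocks of a kernel
#'
#' Returns the training-by-training block K_TS and the prediction-by-training
#' block K_PS,TS, with rows/columns ordered exactly as the supplied ID lists.
#'
#' @param K a `kernel_matrix`.
#' @param training_ids,prediction_ids disjoint subsets of `K$ids`.
#' @return list with `K_TS` (square), `K_PS_TS` (n_PS x n_TS), and the two ID
#'   vectors.
#' @export
partition_kernel <- function(K, training_ids, prediction_ids) {
  training_ids <- as.character(training_ids)
  prediction_ids <- as.character(prediction_ids)
  unk <- setdiff(c(training_ids, prediction_ids), K$ids)
  if (length(unk))
    stop("IDs not present in kernel: ",
         paste(utils::head(unk, 5), collapse = ", "))
  ov <- intersect(training_ids, prediction_ids)
  if (length(ov))
    stop("training and prediction sets overlap: ",
         paste(utils::head(ov, 5), collapse = ", "))
  it <- match(training_ids, K$ids)
  ip <- match(prediction_ids, K$ids)
  list(K_TS = K$K[it, it, drop = FALSE],
       K_PS_TS = K$K[ip, it, drop = FALSE],
       training_ids = training_ids, prediction_ids = prediction_ids)
}
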