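# Variance-component estimation on the training set.
#
# The working model is y ~ N(0, sigma2_u K + sigma2_e I) for centered
# phenotypes y.  Two estimators are provided:
#  * reml_single_kernel(): deterministic maximum likelihood over the
#    variance ratio after an eigendecomposition of K (the model has no
#    fixed effects once phenotypes are centered, so the restricted and
#    full likelihoods coincide); used by default for reproducibility.
#  * gibbs_multi_kernel(): a Gibbs sampler for the three-kernel model
#    y = u1 + u2 + u3 + e with scaled-inverse-chi-square priors, used to
#    estimate kernel-specific variances for kernel averaging.
# Both report sigma2_u, sigma2_e, lambda0 = sigma2_e/sigma2_u and
# h2 = sigma2_u/(sigma2_u + sigma2_e).

new_varcomp <- function(sigma2_u, sigma2_e, estimator, extra = list()) {
  structure(c(list(sigma2_u = sigma2_u, sigma2_e = sigma2_e,
                   lambda0 = if (sigma2_u > 0) sigma2_e / sigma2_u else Inf,
                   h2 = sigma2_u / (sigma2_u + sigma2_e),
                   estimator = estimator), extra),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("variance_components (", x$estimator, "): sigma2_u = ",
      signif(x$sigma2_u, 4), ", sigma2_e = ", signif(x$sigma2_e, 4),
      ", h2 = ", signif(x$h2, 4), ", lambda0 = ", signif(x$lambda0, 4),
      "\n", sep = "")
  invisible(x)
}

kernel_mat <- function(K) if (inherits(K, "kernel_matrix")) K$K else as.matrix(K)

#' REML variance components for a single kernel
#'
#' Maximizes the likelihood of y ~ N(0, sigma2_p (h2 K + (1 - h2) I)) over
#' h2 by 1-D search after an eigendecomposition of K; the scale sigma2_p is
#' profiled out in closed form.  Deterministic given the inputs.
#'
#' @param y_TS centered phenotypes of the training set.
#' @param K_TS `kernel_matrix` (or plain symmetric matrix) over the same
#'   lines, positive semi-definite.
#' @param tol_psd tolerance on the minimum eigenvalue PSD check.
#' @return A `variance_components` object with fields `sigma2_u`,
#'   `sigma2_e`, `lambda0`, `h2`.
#' @export
reml_single_kernel <- function(y_TS, K_TS, tol_psd = 1e-6) {
  K <- kernel_mat(K_TS)
  y <- as.numeric(y_TS)
  n <- length(y)
  if (nrow(K) != n) stop("dimension mismatch between y and K")
  if (n < 10) stop("need at least 10 training individuals")
  eig <- eigen(K, symmetric = TRUE)
  if (min(eig$values) < -tol_psd * max(abs(eig$values)))
    stop("kernel is not positive semi-definite (min eigenvalue ",
         signif(min(eig$values), 3), ")")
  d <- pmax(eig$values, 0)
  yt <- crossprod(eig$vectors, y)[, 1]
  nll <- function(h2) {
    v <- h2 * d + (1 - h2)
    s2 <- mean(yt^2 / v)
    n * log(s2) + sum(log(v))
  }
  opt <- optimize(nll, interval = c(1e-8, 1 - 1e-8), tol = 1e-10)
  h2 <- opt$minimum
  if (h2 < 1e-6 || h2 > 1 - 1e-6)
    warning("variance-ratio estimate at the boundary (h2 = ",
            signif(h2, 3), "); likelihood may be flat")
  v <- h2 * d + (1 - h2)
  s2p <- mean(yt^2 / v)
  new_varcomp(s2p * h2, s2p * (1 - h2), "reml")
}

#' Gibbs sampler for the multi-kernel variance model
#'
#' Samples from the posterior of y = u_1 + ... + u_K + e with
#' u_k ~ N(0, sigma2_ak K_k), e ~ N(0, sigma2_e I), and scaled-inverse-
#' chi-square priors on all variances (df = 5; scales set so the prior mode
#' of each genetic term explains an equal share of half the sample variance
#' of y, and the residual prior mode explains the other half).  Returns
#' posterior means after burn-in.
#'
#' @param y_TS centered phenotypes.
#' @param kernels list of `kernel_matrix` objects sharing line order.
#' @param n_iter,burn_in chain length and burn-in (defaults 12000 / 2000).
#' @param df_prior prior degrees of freedom.
#' @param seed RNG seed.
#' @param keep_samples if TRUE, post-burn-in draws of the variances are
#'   returned in `samples` (columns: one per kernel, then residual) for
#'   convergence diagnostics.
#' @return A `variance_components` object whose `sigma2_u` is the total
#'   genetic variance sum(sigma2_ak); per-kernel variances in `sigma2_ak`
#'   and averaging weights in `weights`.
#' @export
gibbs_multi_kernel <- function(y_TS, kernels, n_iter = 12000,
                               burn_in = 2000, df_prior = 5, seed = NULL,
                               keep_samples = FALSE) {
  if (!is.list(kernels) || length(kernels) < 1) stop("need >= 1 kernel")
  y <- as.numeric(y_TS)
  n <- length(y)
  nk <- length(kernels)
  ids <- if (inherits(kernels[[1]], "kernel_matrix")) kernels[[1]]$ids else NULL
  for (k in kernels)
    if (inherits(k, "kernel_matrix") && !identical(k$ids, ids))
      stop("kernels do not share the same line ordering")
  if (n_iter <= burn_in) stop("'n_iter' must exceed 'burn_in'")
  eigs <- lapply(kernels, function(k) {
    e <- eigen(kernel_mat(k), symmetric = TRUE)
    keep <- e$values > 1e-8 * max(e$values)
    list(U = e$vectors[, keep, drop = FALSE], d = e$values[keep])
  })
  vy <- var(y)
  if (vy == 0) {
    warning("zero-variance phenotype; posterior collapses to the prior ",
            "scale (degenerate)")
    vy <- 1
  }
  nu <- df_prior
  Sg <- (0.5 * vy / nk) * (nu + 2) / nu   # prior scale, genetic terms
  Se <- (0.5 * vy) * (nu + 2) / nu        # prior scale, residual
  with_seed(seed, {
    s2a <- rep(0.5 * vy / nk, nk)
    s2e <- 0.5 * vy
    u <- matrix(0, n, nk)
    keep <- n_iter - burn_in
    acc_a <- rep(0, nk); acc_e <- 0; acc_u <- matrix(0, n, nk)
    samples <- if (keep_samples) matrix(NA_real_, keep, nk + 1) else NULL
    for (it in seq_len(n_iter)) {
      for (k in seq_len(nk)) {
        ek <- y - rowSums(u[, -k, drop = FALSE])
        et <- crossprod(eigs[[k]]$U, ek)[, 1]
        prec <- 1 / s2e + 1 / (s2a[k] * eigs[[k]]$d)
        mu <- (et / s2e) / prec
        delta <- mu + rnorm(length(mu)) / sqrt(prec)
        u[, k] <- eigs[[k]]$U %*% delta
        ss <- sum(delta^2 / eigs[[k]]$d)
        s2a[k] <- (ss + nu * Sg) / rchisq(1, df = length(delta) + nu)
      }
      r <- y - rowSums(u)
      s2e <- (sum(r^2) + nu * Se) / rchisq(1, df = n + nu)
      if (!all(is.finite(c(s2a, s2e))))
        stop("divergent chain (non-finite draw) at iteration ", it)
      if (it > burn_in) {
        acc_a <- acc_a + s2a; acc_e <- acc_e + s2e; acc_u <- acc_u + u
        if (keep_samples) samples[it - burn_in, ] <- c(s2a, s2e)
      }
    }
    s2a_hat <- acc_a / keep
    s2e_hat <- acc_e / keep
    new_varcomp(sum(s2a_hat), s2e_hat, "gibbs",
                extra = list(sigma2_ak = s2a_hat,
                             weights = s2a_hat / sum(s2a_hat),
                             n_iter = n_iter, burn_in = burn_in,
                             u_mean = acc_u / keep, samples = samples))
  })
}

#' Residual-to-genetic variance ratio lambda0
#'
#' @param vc a `variance_components` object (or a list with `sigma2_u`,
#'   `sigma2_e`).
#' @return lambda0 = sigma2_e / sigma2_u, the ridge term of the BLUP
#'   system.
#' @export
variance_ratio <- function(vc) {
  if (vc$sigma2_u <= 0)
    stop("sigma2_u = 0: BLUP is undefined (no genetic variance)")
  vc$sigma2_e / vc$sigma2_u
}
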