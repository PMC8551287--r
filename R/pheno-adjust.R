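# Adjusted phenotypes (BLUEs) from plot-level trial records.
#
# Two models are supported, matching stage-I analyses of alpha-lattice
# trials:
#   multi-location:  Y = mu + G + L + R(L) + B(RL) + GxL + e
#   single-location: Y = mu + G + R + B(R) + e
# with genotype, location, replicate and GxL fixed, and incomplete block
# random, iid N(0, sigma2_b).  Because each record belongs to exactly one
# block, the marginal covariance V = sigma2_e I + sigma2_b Z Z' is block
# diagonal with an intra-class structure, so REML reduces to a 1-D profiled
# likelihood in the ratio gamma = sigma2_b / sigma2_e, maximized by golden-
# section search on the log scale; whitening by V^(-1/2) is a closed-form
# per-block shrinkage of the block mean.  Fixed effects use sum-to-zero
# contrasts so that mu + G_i (the adjusted phenotype) is invariant to
# relabeling of locations, replicates and blocks; inestimable interaction
# cells in incomplete designs are dropped (coefficient 0) with a warning.

ctr_sum <- function(f) {
  f <- droplevels(as.factor(f))
  k <- nlevels(f)
  if (k == 1) return(matrix(0, nrow = length(f), ncol = 0))
  C <- stats::contr.sum(k)
  M <- C[as.integer(f), , drop = FALSE]
  colnames(M) <- paste0(levels(f)[-k])
  M
}

# whiten y (or columns of X) by V^{-1/2} for V = I + gamma * ZZ',
# Z = block indicators: within block of size m, subtract
# (1 - 1/sqrt(1 + gamma m)) * block mean.
whiten <- function(M, block, gamma) {
  M <- as.matrix(M)
  bs <- table(block)[as.character(block)]
  shr <- 1 - 1 / sqrt(1 + gamma * as.numeric(bs))
  bm <- rowsum(M, block) / as.numeric(rowsum(rep(1, nrow(M)), block))
  M - shr * bm[as.character(block), , drop = FALSE]
}

reml_profile <- function(y, X, block, log_gamma) {
  gamma <- exp(log_gamma)
  yw <- whiten(y, block, gamma)
  Xw <- whiten(X, block, gamma)
  fit <- lm.fit(Xw, yw)
  r <- fit$rank
  n <- length(y)
  rss <- sum(fit$residuals^2)
  sig2 <- rss / (n - r)
  m <- as.numeric(table(block))
  logdetV <- sum(log(1 + gamma * m))
  Rd <- abs(diag(fit$qr$qr))[seq_len(r)]
  logdetXVX <- 2 * sum(log(Rd))
  # restricted log-likelihood up to an additive constant
  -0.5 * ((n - r) * log(sig2) + logdetV + logdetXVX)
}

fit_block_model <- function(records, X, gname, glevels, se_rows) {
  y <- records$value
  block <- as.factor(records$block)
  n <- length(y)
  opt <- optimize(function(lg) -reml_profile(y, X, block, lg),
                  interval = c(-20, 12), tol = 1e-8)
  gamma <- exp(opt$minimum)
  # boundary: effectively no block variance
  if (opt$minimum < -18) gamma <- 0
  yw <- whiten(y, block, gamma)
  Xw <- whiten(X, block, gamma)
  fit <- lm.fit(Xw, yw)
  r <- fit$rank
  sigma2_e <- sum(fit$residuals^2) / (n - r)
  sigma2_b <- gamma * sigma2_e
  beta <- fit$coefficients
  dropped <- which(is.na(beta))
  if (length(dropped)) {
    if (any(names(beta)[dropped] %in% glevels))
      stop("genotype effects are aliased with the design (confounding ",
           "between genotype and ", gname, "); cannot adjust")
    warning(length(dropped), " inestimable fixed-effect contrast(s) ",
            "(incomplete interaction cells) set to 0")
    beta[dropped] <- 0
  }
  # adjusted value per genotype: mu + G_i under sum-to-zero contrasts
  adj <- as.numeric(se_rows %*% beta)
  # standard errors from the retained-column covariance
  keep <- setdiff(seq_along(beta), dropped)
  XtX <- crossprod(Xw[, keep, drop = FALSE])
  covb <- tryCatch(solve(XtX) * sigma2_e, error = function(e) NULL)
  se <- if (is.null(covb)) rep(NA_real_, nrow(se_rows)) else
    sqrt(pmax(0, rowSums((se_rows[, keep, drop = FALSE] %*% covb) *
                           se_rows[, keep, drop = FALSE])))
  list(adj = adj, se = se, sigma2_b = sigma2_b, sigma2_e = sigma2_e,
       beta = beta, rank = r)
}

check_records <- function(records) {
  need <- c("line", "rep", "block", "value")
  if (!all(need %in% names(records)))
    stop("records need columns ", paste(need, collapse = ", "))
  if (anyNA(records$value)) stop("missing trait values are not supported")
  invisible(records)
}

#' Adjusted phenotypes from multi-location trial records
#'
#' Fits Y = mu + G + L + R(L) + B(RL) + GxL + e with random incomplete
#' blocks (REML) and returns one adjusted value mu + G_i per genotype.
#'
#' @param records data.frame with columns `line`, `location`, `rep`,
#'   `block`, `value` (one row per plot).
#' @return Object of class `adjusted_phenotypes`: data.frame `values`
#'   (genotype, value, se), plus `sigma2_b`, `sigma2_e` and the fitted
#'   fixed-effect vector.
#' @export
fit_multilocation_model <- function(records) {
  check_records(records)
  if (!"location" %in% names(records))
    stop("multi-location model needs a 'location' column")
  records$location <- as.factor(records$location)
  if (nlevels(records$location) < 2)
    stop("multi-location model requires records from at least 2 locations; ",
         "use fit_singlelocation_model() for a single location")
  Gf <- droplevels(as.factor(records$line))
  Lf <- records$location
  CG <- ctr_sum(Gf); CL <- ctr_sum(Lf)
  if (ncol(CG)) colnames(CG) <- paste0("G_", colnames(CG))
  if (ncol(CL)) colnames(CL) <- paste0("L_", colnames(CL))
  # replicate within location: sum-to-zero rep contrasts, zeroed outside
  # each location
  RL <- do.call(cbind, lapply(levels(Lf), function(l) {
    sel <- Lf == l
    M <- matrix(0, length(Gf), 0)
    Rf <- droplevels(as.factor(records$rep[sel]))
    if (nlevels(Rf) > 1) {
      M <- matrix(0, length(Gf), nlevels(Rf) - 1)
      M[sel, ] <- ctr_sum(Rf)
      colnames(M) <- paste0("R", l, ".", seq_len(ncol(M)))
    }
    M
  }))
  GL <- if (ncol(CG) && ncol(CL)) {
    M <- do.call(cbind, lapply(seq_len(ncol(CL)), function(j) CG * CL[, j]))
    colnames(M) <- paste0("G:", rep(colnames(CG), ncol(CL)), ":L",
                          rep(seq_len(ncol(CL)), each = ncol(CG)))
    M
  } else matrix(0, length(Gf), 0)
  X <- cbind(`(Intercept)` = 1, CG, CL, RL, GL)
  # rows evaluating mu + G_i for every genotype level
  glev <- levels(Gf)
  SR <- matrix(0, length(glev), ncol(X),
               dimnames = list(glev, colnames(X)))
  SR[, 1] <- 1
  SR[, 1 + seq_len(ncol(CG))] <- stats::contr.sum(length(glev))
  res <- fit_block_model(records, X, "location", colnames(CG), SR)
  structure(list(values = data.frame(genotype = glev, value = res$adj,
                                     se = res$se, stringsAsFactors = FALSE),
                 sigma2_b = res$sigma2_b, sigma2_e = res$sigma2_e,
                 beta = res$beta, model = "multilocation"),
            class = "adjusted_phenotypes")
}

#' Adjusted phenotypes from single-location trial records
#'
#' Fits Y = mu + G + R + B(R) + e with random incomplete blocks (REML).
#'
#' @inheritParams fit_multilocation_model
#' @return Object of class `adjusted_phenotypes` (see
#'   [fit_multilocation_model()]).
#' @export
fit_singlelocation_model <- function(records) {
  check_records(records)
  if ("location" %in% names(records) &&
      length(unique(records$location)) > 1)
    stop("records span several locations; use fit_multilocation_model()")
  Gf <- droplevels(as.factor(records$line))
  CG <- ctr_sum(Gf)
  if (ncol(CG)) colnames(CG) <- paste0("G_", colnames(CG))
  CR <- ctr_sum(records$rep)
  if (ncol(CR)) colnames(CR) <- paste0("R", seq_len(ncol(CR)))
  X <- cbind(`(Intercept)` = 1, CG, CR)
  glev <- levels(Gf)
  SR <- matrix(0, length(glev), ncol(X),
               dimnames = list(glev, colnames(X)))
  SR[, 1] <- 1
  SR[, 1 + seq_len(ncol(CG))] <- stats::contr.sum(length(glev))
  res <- fit_block_model(records, X, "replicate", colnames(CG), SR)
  structure(list(values = data.frame(genotype = glev, value = res$adj,
                                     se = res$se, stringsAsFactors = FALSE),
                 sigma2_b = res$sigma2_b, sigma2_e = res$sigma2_e,
                 beta = res$beta, model = "singlelocation"),
            class = "adjusted_phenotypes")
}

#' @export
print.adjusted_phenotypes <- function(x, ...) {
  cat("adjusted_phenotypes (", x$model, "): ", nrow(x$values),
      " genotypes; sigma2_b = ", signif(x$sigma2_b, 4),
      ", sigma2_e = ", signif(x$sigma2_e, 4), "\n", sep = "")
  invisible(x)
}

#' Center adjusted phenotypes on a reference (training) set
#'
#' Subtracts the mean computed over the reference IDs from every value, so
#' the reference set has mean exactly 0 (the centering assumed by the
#' intercept-free prediction models).
#'
#' @param adjusted an `adjusted_phenotypes` object or a named numeric
#'   vector.
#' @param reference_ids IDs whose mean defines the center.
#' @return Named numeric vector of centered values (all genotypes).
#' @export
center_phenotypes <- function(adjusted, reference_ids) {
  v <- if (inherits(adjusted, "adjusted_phenotypes"))
    setNames(adjusted$values$value, adjusted$values$genotype)
  else adjusted
  if (is.null(names(v))) stop("phenotypes must be named by genotype")
  reference_ids <- as.character(reference_ids)
  if (length(reference_ids) == 0) stop("empty reference set")
  if (!all(reference_ids %in% names(v)))
    stop("reference IDs missing from phenotypes")
  v - mean(v[reference_ids])
}
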