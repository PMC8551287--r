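# Marker quality control for dominant 0/1 markers.
#
# DH lines from a biparental cross segregate; a dominant marker scored as
# band presence/absence is expected at a 3:1 presence:absence ratio when the
# band allele is present in one parent as a duplicated locus, which is the
# expectation used for segregation-distortion screening here.  Markers whose
# counts deviate from the expected ratio (chi-square goodness-of-fit,
# Benjamini-Hochberg FDR) are removed first, then markers with low minor
# allele frequency.  For dominant markers only band presence is observable,
# so MAF = min(freq_presence, 1 - freq_presence).

#' Segregation-distortion test for a dominant marker
#'
#' One-degree-of-freedom chi-square goodness-of-fit of observed
#' presence/absence counts against an expected presence:absence ratio
#' (default 3:1).
#'
#' @param marker_column 0/1 vector of marker calls.
#' @param expected_ratio length-2 positive vector `c(presence, absence)`;
#'   default `c(3, 1)`.
#' @param method `"chisq"` (default) or `"binomial"` for an exact binomial
#'   test of the presence count.
#' @return list with `statistic`, `p_value`, `n_present`, `n_absent`.
#' @export
segregation_test <- function(marker_column, expected_ratio = c(3, 1),
                             method = c("chisq", "binomial")) {
  method <- match.arg(method)
  if (length(marker_column) == 0) stop("empty marker column")
  if (anyNA(marker_column)) stop("missing marker calls are not supported")
  if (!all(marker_column %in% c(0, 1))) stop("marker calls must be 0/1")
  if (length(expected_ratio) != 2 || any(expected_ratio <= 0))
    stop("'expected_ratio' must be two positive numbers (presence:absence)")
  n <- length(marker_column)
  n1 <- sum(marker_column)
  n0 <- n - n1
  pr <- expected_ratio[1] / sum(expected_ratio)
  if (method == "binomial") {
    p <- stats::binom.test(n1, n, p = pr)$p.value
    stat <- NA_real_
  } else {
    e1 <- n * pr
    e0 <- n * (1 - pr)
    stat <- (n1 - e1)^2 / e1 + (n0 - e0)^2 / e0
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  list(statistic = stat, p_value = p, n_present = n1, n_absent = n0)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment: sort p ascending,
#' multiply by m/rank, enforce monotonicity from the largest rank down, cap
#' at 1.
#'
#' @param p_values vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1] with no NA")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- pmin(1, cummin(rev(p[o] * m / seq_len(m))))
  out <- numeric(m)
  out[o] <- rev(adj)
  out
}

#' Marker QC pipeline: distortion filter then MAF filter
#'
#' Applies the segregation-distortion test to every marker, adjusts p-values
#' by Benjamini-Hochberg, removes markers with adjusted p below `alpha_fdr`,
#' then removes markers with MAF below `maf_min`.  The report records both
#' criteria for every input marker regardless of removal order.
#'
#' @param markers a [marker_matrix()].
#' @param alpha_fdr FDR level for the distortion filter (default 0.05).
#'   `alpha_fdr = 0` disables the distortion filter (useful on simulated
#'   panels from small founder pools, where population-level frequencies
#'   deviate from the per-family segregation ratio by construction).
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param expected_ratio expected presence:absence ratio (default `c(3, 1)`).
#' @param method test passed to [segregation_test()].
#' @return list with `markers` (filtered `marker_matrix`) and `report`
#'   (data.frame: marker, n_present, statistic, p_value, p_adj, maf,
#'   retained, reason).
#' @export
qc_pipeline <- function(markers, alpha_fdr = 0.05, maf_min = 0.05,
                        expected_ratio = c(3, 1),
                        method = c("chisq", "binomial")) {
  method <- match.arg(method)
  if (!inherits(markers, "marker_matrix")) stop("'markers' must be a marker_matrix")
  X <- markers$X
  if (ncol(X) == 0) stop("marker matrix has no markers")
  tests <- apply(X, 2, segregation_test, expected_ratio = expected_ratio,
                 method = method)
  stat <- vapply(tests, `[[`, 0, "statistic")
  pval <- vapply(tests, `[[`, 0, "p_value")
  npres <- vapply(tests, `[[`, 0, "n_present")
  padj <- bh_adjust(pval)
  freq <- colMeans(X)
  maf <- pmin(freq, 1 - freq)
  distorted <- padj < alpha_fdr
  low_maf <- maf < maf_min
  retained <- !distorted & !low_maf
  # a low-MAF marker is reported as "maf" even when also distorted: it
  # would be removed by the MAF rule regardless of the distortion test
  reason <- ifelse(low_maf, "maf", ifelse(distorted, "distortion", "none"))
  report <- data.frame(marker = colnames(X), n_present = npres,
                       statistic = stat, p_value = pval, p_adj = padj,
                       maf = maf, retained = retained, reason = reason,
                       row.names = NULL, stringsAsFactors = FALSE)
  if (!any(retained))
    warning("all markers removed by QC; returning an empty marker matrix")
  out <- markers
  out$X <- X[, retained, drop = FALSE]
  list(markers = out, report = report)
}

#' Write a marker QC report to CSV
#' @param report the `report` element of [qc_pipeline()] output.
#' @param path output file path.
#' @export
write_qc_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
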