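#' Marker matrix container
#'
#' Holds a lines-by-markers table of dominant markers coded 0 (band absence)
#' and 1 (band presence), together with per-line metadata: a line identifier,
#' the breeding cycle (generation/year) the line belongs to, and optionally
#' the biparental family it was derived from.
#'
#' @param X numeric matrix of 0/1 marker calls, one row per line.  Row names
#'   are used as line IDs when `ids` is not given; column names as marker IDs.
#' @param cycle character or factor vector of cycle labels, one per line.
#' @param ids character vector of unique line IDs (default: rownames of `X`).
#' @param family optional character vector of family labels, one per line.
#'
#' @return An object of class `marker_matrix`: a list with elements `X`
#'   (integer matrix), `ids`, `cycle`, `family`.
#' @export
marker_matrix <- function(X, cycle, ids = rownames(X), family = NULL) {
  X <- as.matrix(X)
  if (is.null(ids)) ids <- paste0("L", seq_len(nrow(X)))
  ids <- as.character(ids)
  cycle <- as.character(cycle)
  if (length(ids) != nrow(X))
    stop("length of 'ids' (", length(ids), ") != number of lines (",
         nrow(X), ")")
  if (anyDuplicated(ids))
    stop("duplicate line IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(cycle) == 1L) cycle <- rep(cycle, nrow(X))
  if (length(cycle) != nrow(X))
    stop("length of 'cycle' != number of lines")
  if (anyNA(X))
    stop("missing marker calls are not supported (no imputation); ",
         "first NA at row ", which(rowSums(is.na(X)) > 0)[1])
  bad <- which(!(X %in% c(0, 1)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(X))
    stop("marker values must be 0 or 1; found ", X[bad[1]],
         " at line ", rc[1], ", marker ", rc[2])
  }
  if (!is.null(family)) {
    family <- as.character(family)
    if (length(family) != nrow(X)) stop("length of 'family' != number of lines")
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("M", seq_len(ncol(X)))
  storage.mode(X) <- "integer"
  rownames(X) <- ids
  structure(list(X = X, ids = ids, cycle = cycle, family = family),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat("marker_matrix: ", nrow(x$X), " lines x ", ncol(x$X), " markers, ",
      length(unique(x$cycle)), " cycle(s)\n", sep = "")
  invisible(x)
}

#' @export
dim.marker_matrix <- function(x) dim(x$X)

#' Subset a marker matrix by line and/or marker
#'
#' @param x a [marker_matrix()].
#' @param i line index (integer, logical or line IDs).
#' @param j marker index.
#' @param ... ignored.
#' @return A `marker_matrix` restricted to the selected lines/markers.
#' @export
`[.marker_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$X))
  if (missing(j)) j <- seq_len(ncol(x$X))
  if (is.character(i)) i <- match(i, x$ids)
  marker_matrix(x$X[i, j, drop = FALSE], cycle = x$cycle[i],
                ids = x$ids[i],
                family = if (is.null(x$family)) NULL else x$family[i])
}

presence_frequency <- function(m) colMeans(m$X)
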