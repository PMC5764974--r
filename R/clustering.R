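#' Column-wise z-scores
#'
#' Standardises each column to mean 0 and unit sample standard deviation —
#' the scaling used for heat-map display of peak areas together with ALT/AST
#' levels, so columns with very different units become comparable shades.
#' Constant columns cannot be standardised; they are set to all zeros with a
#' warning.
#'
#' @param M Numeric matrix with at least 2 rows.
#' @return Matrix of the same shape.
#' @export
zscore_columns <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) < 2) stop("z-scoring needs at least 2 rows")
  stopifnot(all(is.finite(M)))
  mu <- colMeans(M)
  sdv <- apply(M, 2L, stats::sd)
  const <- sdv == 0
  if (any(const)) {
    warning("constant column(s) set to zero: ",
            paste(colnames(M)[const], collapse = ", "))
    sdv[const] <- 1
  }
  Z <- sweep(sweep(M, 2L, mu), 2L, sdv, "/")
  Z[, const] <- 0
  Z
}

# Deterministic leaf order: traverse the merge tree left-before-right after
# swapping children so the subtree holding the lowest original index comes
# first.
.ordered_leaves <- function(merge) {
  subtree <- function(k) {
    # returns leaf vector with attr "min"
    if (k < 0) return(structure(-k, min = -k))
    a <- subtree(merge[k, 1L]); b <- subtree(merge[k, 2L])
    if (attr(a, "min") <= attr(b, "min")) {
      structure(c(a, b), min = attr(a, "min"))
    } else {
      structure(c(b, a), min = attr(b, "min"))
    }
  }
  as.integer(subtree(nrow(merge)))
}

#' Agglomerative hierarchical clustering of rows
#'
#' Standard agglomerative clustering (via [stats::hclust()]) of the rows of
#' a matrix, with either euclidean distance or correlation distance
#' (1 - Pearson r) and average or complete linkage. The leaf order is made
#' deterministic: at every internal node the subtree containing the lower
#' original row index is placed first.
#'
#' @param M Numeric matrix (>= 2 rows, finite values).
#' @param metric `"euclidean"` or `"correlation"`.
#' @param linkage `"average"` or `"complete"`.
#' @return List with `merge` (hclust-style merge matrix), `height`
#'   (non-decreasing merge heights), `order` (deterministic leaf order),
#'   `labels`, and the underlying `hclust` object.
#' @export
hierarchical_cluster <- function(M, metric = c("euclidean", "correlation"),
                                 linkage = c("average", "complete")) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  M <- as.matrix(M)
  stopifnot(nrow(M) >= 2, all(is.finite(M)))
  d <- switch(metric,
    euclidean = stats::dist(M),
    correlation = stats::as.dist(1 - stats::cor(t(M))))
  hc <- stats::hclust(d, method = linkage)
  list(merge = hc$merge, height = hc$height,
       order = .ordered_leaves(hc$merge),
       labels = if (is.null(rownames(M))) as.character(seq_len(nrow(M)))
                else rownames(M),
       hclust = hc)
}

#' Heat-map matrix of common peaks and toxicity endpoints
#'
#' Joins the common-peak areas with per-sample mean ALT/AST, z-scores every
#' column, and clusters both samples (rows) and variables (columns) so that
#' peaks co-varying with the enzyme endpoints end up adjacent in the column
#' dendrogram — the visual argument that a peak tracks hepatotoxicity.
#'
#' @param t A [common_peak_table()].
#' @param toxicity Matrix/data frame of per-sample endpoint means with
#'   columns `ALT` and `AST` and rows matching `t`'s samples, or a
#'   `toxicity_table` from [generate_toxicity()].
#' @param metric,linkage Passed to [hierarchical_cluster()].
#' @return Object of class `heatmap_matrix`: `values` (z-scored matrix),
#'   `row_order`, `col_order`, `row_cluster`, `col_cluster`.
#' @export
heatmap_matrix <- function(t, toxicity,
                           metric = c("euclidean", "correlation"),
                           linkage = c("average", "complete")) {
  stopifnot(inherits(t, "common_peak_table"))
  if (inherits(toxicity, "toxicity_table")) toxicity <- toxicity$group_means
  toxicity <- as.matrix(toxicity)
  stopifnot(all(c("ALT", "AST") %in% colnames(toxicity)))
  tox <- toxicity[t$sample_ids, c("ALT", "AST"), drop = FALSE]
  M <- cbind(t$areas, tox)
  Z <- zscore_columns(M)
  rc <- hierarchical_cluster(Z, metric, linkage)
  cc <- hierarchical_cluster(t(Z), metric, linkage)
  structure(list(values = Z, row_order = rc$order, col_order = cc$order,
                 row_cluster = rc, col_cluster = cc),
            class = "heatmap_matrix")
}

#' @export
print.heatmap_matrix <- function(x, ...) {
  cat("Heat-map matrix:", nrow(x$values), "samples x", ncol(x$values),
      "columns (z-scored)\n")
  cat("  column order:",
      paste(colnames(x$values)[x$col_order], collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.heatmap_matrix <- function(x, col = grDevices::hcl.colors(64, "Blue-Red 2"),
                                ...) {
  Z <- x$values[x$row_order, x$col_order, drop = FALSE]
  graphics::image(seq_len(ncol(Z)), seq_len(nrow(Z)), t(Z), col = col,
                  axes = FALSE, xlab = "", ylab = "", ...)
  graphics::axis(1, seq_len(ncol(Z)), colnames(Z), las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(nrow(Z)), rownames(Z), las = 2, cex.axis = 0.7)
  invisible(x)
}
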