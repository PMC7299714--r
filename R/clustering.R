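#' Rank miRNAs by coefficient of variation
#'
#' CV is the sample standard deviation divided by the mean, computed across
#' samples on the expression scale. Returns the `k` miRNAs with the largest
#' CV, in descending-CV order; ties are broken by panel order. miRNAs whose
#' mean is zero have no defined CV and are never selected.
#'
#' @param expr an `expr_table`.
#' @param k number of miRNAs to select, default 40. If fewer have a defined
#'   CV, all of them are returned with a warning.
#' @return Character vector of selected miRNA ids.
#' @export
select_top_cv <- function(expr, k = 40) {
  stopifnot(inherits(expr, "expr_table"))
  v <- expr$values
  mu <- rowMeans(v)
  sdv <- apply(v, 1, stats::sd)
  cv <- ifelse(mu == 0, NA_real_, sdv / mu)
  ok <- which(!is.na(cv))
  if (length(ok) < k) {
    warning("only ", length(ok), " miRNAs have a defined CV; returning all")
    k <- length(ok)
  }
  ord <- ok[order(-cv[ok])]  # stable sort: ties keep panel order
  rownames(v)[ord[seq_len(k)]]
}

#' Standardize miRNAs across samples
#'
#' Per-miRNA z-scores: each selected row is centered and scaled to unit
#' standard deviation across samples. Rows with zero variance cannot be
#' standardized and are dropped with a warning.
#'
#' @param expr an `expr_table`.
#' @param mirnas miRNA ids to standardize; default all.
#' @return Numeric matrix (miRNA x sample) of z-scores.
#' @export
standardize_mirnas <- function(expr, mirnas = NULL) {
  stopifnot(inherits(expr, "expr_table"))
  ids <- if (is.null(mirnas)) rownames(expr$values) else mirnas
  miss <- setdiff(ids, rownames(expr$values))
  if (length(miss)) stop("unknown miRNAs: ", paste(miss, collapse = ", "))
  v <- expr$values[ids, , drop = FALSE]
  sdv <- apply(v, 1, stats::sd)
  if (any(sdv == 0)) {
    warning("dropping zero-variance miRNAs: ",
            paste(ids[sdv == 0], collapse = ", "))
    v <- v[sdv > 0, , drop = FALSE]
    sdv <- sdv[sdv > 0]
  }
  (v - rowMeans(v)) / sdv
}

#' Correlation distance between samples
#'
#' `d(i, j) = 1 - Pearson(sample_i, sample_j)` across the supplied miRNA
#' rows; values lie in `[0, 2]`.
#'
#' @param z numeric matrix (miRNA x sample), typically from
#'   [standardize_mirnas].
#' @return Symmetric distance matrix with zero diagonal.
#' @export
sample_distance <- function(z) {
  z <- as.matrix(z)
  if (nrow(z) < 2) stop("need at least 2 miRNAs for a correlation distance")
  sdv <- apply(z, 2, stats::sd)
  if (any(sdv == 0))
    stop("zero-variance sample vector: ",
         paste(colnames(z)[sdv == 0], collapse = ", "))
  d <- 1 - stats::cor(z)
  diag(d) <- 0
  d
}

#' Agglomerative hierarchical clustering of samples
#'
#' Thin wrapper around [stats::hclust] on a correlation-distance matrix,
#' returning the tree together with the inputs needed to reproduce it.
#'
#' @param d symmetric distance matrix (see [sample_distance]).
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return Object of class `mir_clustering`: `hclust` (the tree),
#'   `merge`/`height`/`order` copied from it, `distance` (the input matrix),
#'   and `linkage`.
#' @export
hierarchical_cluster <- function(d, linkage = c("average", "complete",
                                                "single")) {
  linkage <- match.arg(linkage)
  d <- as.matrix(d)
  h <- stats::hclust(stats::as.dist(d), method = linkage)
  structure(list(hclust = h, merge = h$merge, height = h$height,
                 order = h$order, labels = h$labels, distance = d,
                 linkage = linkage, selected_mirnas = character(0)),
            class = "mir_clustering")
}

#' Cluster samples on the most variable miRNAs
#'
#' End-to-end convenience: select the top-CV miRNAs, standardize them,
#' compute the 1 - Pearson sample distance, and build the tree.
#'
#' @param expr an `expr_table` (normalized by default in the pipeline).
#' @param k_top number of top-CV miRNAs, default 40.
#' @param linkage linkage method passed to [hierarchical_cluster].
#' @return A `mir_clustering` with `selected_mirnas` filled in.
#' @export
cluster_samples <- function(expr, k_top = 40,
                            linkage = c("average", "complete", "single")) {
  sel <- select_top_cv(expr, k = k_top)
  z <- standardize_mirnas(expr, sel)
  cl <- hierarchical_cluster(sample_distance(z), linkage = match.arg(linkage))
  cl$selected_mirnas <- sel
  cl
}

#' Cut a sample tree into flat clusters
#'
#' @param clustering a `mir_clustering`.
#' @param k number of clusters (or `h` a height; one of the two).
#' @param h cut height.
#' @return Named integer vector of cluster memberships.
#' @export
cut_clusters <- function(clustering, k = NULL, h = NULL) {
  stopifnot(inherits(clustering, "mir_clustering"))
  stats::cutree(clustering$hclust, k = k, h = h)
}

#' @export
print.mir_clustering <- function(x, ...) {
  cat(sprintf("mir_clustering: %d samples, %s linkage, %d selected miRNAs\n",
              length(x$labels), x$linkage, length(x$selected_mirnas)))
  invisible(x)
}

#' @export
plot.mir_clustering <- function(x, ...) {
  plot(x$hclust, xlab = "", sub = "",
       main = "Sample clustering (1 - Pearson)", ...)
  invisible(x)
}

#' Export a sample tree as Newick
#'
#' @param clustering a `mir_clustering`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(clustering, path) {
  stopifnot(inherits(clustering, "mir_clustering"))
  ape::write.tree(ape::as.phylo(clustering$hclust), file = path)
  invisible(path)
}
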