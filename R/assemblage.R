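#' Cluster genera into temporal assemblages
#'
#' Agglomerative clustering of the compositional variation matrix (pairwise
#' log-ratio variances) treated as a dissimilarity, cut at `k` groups. Ward
#' linkage treats the variation matrix as squared dissimilarities
#' (`hclust` method `"ward.D"`); average and complete linkage are available.
#'
#' @param vm A symmetric variation matrix with zero diagonal (see
#'   [variation_matrix()]), or a covariance-of-CLR matrix converted to a
#'   dissimilarity upstream.
#' @param k Number of clusters (default 17, the scale used for multi-decadal
#'   genus panels).
#' @param linkage One of `"ward"`, `"average"`, `"complete"`.
#' @return A `cluster_solution`: genus -> cluster id (1..k, ordered by first
#'   appearance), the dendrogram (`hclust` object), `k`, and the distance
#'   matrix used.
#' @export
cluster_genera <- function(vm, k = 17, linkage = c("ward", "average",
                                                   "complete")) {
  linkage <- match.arg(linkage)
  if (nrow(vm) != ncol(vm) || max(abs(vm - t(vm))) > 1e-8) {
    stop("variation matrix must be symmetric")
  }
  if (k > nrow(vm)) stop("k exceeds the number of genera")
  method <- switch(linkage, ward = "ward.D", average = "average",
                   complete = "complete")
  hc <- hclust(as.dist(vm), method = method)
  raw <- cutree(hc, k = k)
  # relabel so ids are contiguous in order of first appearance
  ids <- match(raw, unique(raw))
  names(ids) <- rownames(vm)
  structure(
    list(cluster = ids, dendrogram = hc, k = k, linkage = linkage),
    class = "cluster_solution"
  )
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf(
    "cluster_solution: %d genera in %d clusters (%s linkage)\n",
    length(x$cluster), x$k, x$linkage
  ))
  print(table(x$cluster))
  invisible(x)
}

#' Aggregate compositions to cluster-level weekly shares
#'
#' Cluster share = sum of member genus relative abundances; weekly shares
#' close to 1.
#'
#' @param solution A [cluster_genera()] result.
#' @param comp A `composition_matrix` over the same genera.
#' @return Cluster x week matrix of relative abundances.
#' @export
aggregate_clusters <- function(solution, comp) {
  m <- unclass(comp)
  ids <- solution$cluster[rownames(m)]
  if (anyNA(ids)) stop("composition contains genera missing from solution")
  out <- rowsum(m, group = ids)
  rownames(out) <- sprintf("C%d", sort(unique(ids)))
  attr(out, "meta") <- attr(comp, "meta")
  out
}

#' Median seasonal profile per cluster
#'
#' For each cluster and calendar week in `week_range`, the median (across
#' years and member genera) of the log-ratio transformed abundances: the
#' cluster's seasonal fingerprint.
#'
#' @param solution A [cluster_genera()] result.
#' @param lr A `logratio_matrix` of CLR coordinates (weeks x genera) with
#'   metadata carrying the calendar `week`.
#' @param week_range Calendar weeks to profile (default 21:41).
#' @return Cluster x calendar-week matrix of medians.
#' @export
seasonal_profile <- function(solution, lr, week_range = 21:41) {
  if (!length(week_range)) stop("empty week range")
  meta <- lr$meta
  if (is.null(meta) || is.null(meta$week)) {
    stop("metadata with calendar weeks required")
  }
  coords <- lr$coords # weeks x genera (CLR)
  ids <- solution$cluster[colnames(coords)]
  if (anyNA(ids)) stop("log-ratio matrix contains genera missing from solution")
  clusters <- sort(unique(ids))
  out <- matrix(NA_real_, length(clusters), length(week_range),
                dimnames = list(sprintf("C%d", clusters), week_range))
  for (ci in seq_along(clusters)) {
    member <- coords[, ids == clusters[ci], drop = FALSE]
    for (wi in seq_along(week_range)) {
      rows <- meta$week == week_range[wi]
      if (any(rows)) out[ci, wi] <- median(member[rows, , drop = FALSE])
    }
  }
  out
}

#' Export a dendrogram as a Newick string
#'
#' @param solution A [cluster_genera()] result.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly if written to file.
#' @export
dendrogram_newick <- function(solution, path = NULL) {
  phy <- ape::as.phylo(solution$dendrogram)
  nwk <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Write cluster membership as TSV
#'
#' @param solution A [cluster_genera()] result.
#' @param path Output path.
#' @export
write_clusters <- function(solution, path) {
  df <- data.frame(genus = names(solution$cluster),
                   cluster = unname(solution$cluster))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
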