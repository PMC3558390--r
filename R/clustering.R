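## Hierarchical clustering of cell types by their window-sweep association
## profiles, and cluster summaries (high / medium / low association).

#' Assemble association profiles into a cell-type x window matrix
#'
#' @param profiles list of [association_profile()] objects sharing one window
#'   grid.
#' @return numeric matrix (class `profile_matrix`): one row per cell type,
#'   one column per window; `dimnames` carry labels and window sizes.
#' @export
build_profile_matrix <- function(profiles) {
  if (length(profiles) == 0L) stop("build_profile_matrix: no profiles")
  grids <- lapply(profiles, `[[`, "windows")
  ref <- grids[[1]]
  bad <- which(!vapply(grids, function(g) identical(g, ref), TRUE))
  if (length(bad))
    stop("build_profile_matrix: window grid mismatch for profile(s): ",
         paste(vapply(profiles[bad], `[[`, "", "cell_type"), collapse = ", "))
  m <- do.call(rbind, lapply(profiles, `[[`, "f_scores"))
  rownames(m) <- vapply(profiles, `[[`, "", "cell_type")
  colnames(m) <- as.character(ref)
  class(m) <- c("profile_matrix", class(m))
  m
}

#' Read / write a profile matrix as TSV
#'
#' TSV layout: first column `cell_type`, remaining columns named by window
#' size in bp.
#' @param path file path.
#' @export
read_profile_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          row.names = 1)
  m <- as.matrix(df)
  class(m) <- c("profile_matrix", class(m))
  m
}

#' @rdname read_profile_matrix
#' @param matrix `profile_matrix`.
#' @export
write_profile_matrix <- function(matrix, path) {
  df <- data.frame(cell_type = rownames(matrix), matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Agglomerative clustering of association profiles
#'
#' Euclidean distance between profile rows; agglomerative merge tree with the
#' requested linkage (default average).
#'
#' @param matrix `profile_matrix` (>= 2 rows).
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return An `hclust` merge tree.
#' @export
hierarchical_cluster <- function(matrix, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  if (nrow(matrix) < 2L) stop("hierarchical_cluster: need at least 2 rows")
  stats::hclust(stats::dist(matrix, method = "euclidean"), method = linkage)
}

#' Cut a profile merge tree into k clusters
#'
#' Clusters are relabelled in descending order of mean F score over all
#' member cells and windows, so cluster 1 is the "high association" cluster.
#'
#' @param tree `hclust` object from [hierarchical_cluster()].
#' @param k number of clusters (default 3: high / medium / low).
#' @param matrix the `profile_matrix` the tree was built from.
#' @param h optional height threshold used instead of `k`.
#' @return A `cluster_assignment` list: `labels` (cell type -> cluster id),
#'   `k`, `mean_f` (cluster id -> mean F), `merge_tree`.
#' @export
cut_clusters <- function(tree, k = 3L, matrix, h = NULL) {
  n <- nrow(matrix)
  if (is.null(h)) {
    if (k < 1L || k > n) stop("cut_clusters: k out of range [1, n]")
    raw <- stats::cutree(tree, k = k)
  } else {
    raw <- stats::cutree(tree, h = h)
    k <- length(unique(raw))
  }
  means <- vapply(sort(unique(raw)), function(cl)
    mean(matrix[names(raw)[raw == cl], , drop = FALSE]), 0)
  ord <- order(means, decreasing = TRUE)
  remap <- match(raw, sort(unique(raw))[ord])
  labels <- stats::setNames(remap, rownames(matrix))
  structure(list(labels = labels, k = k,
                 mean_f = stats::setNames(means[ord], seq_len(k)),
                 merge_tree = tree),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> k=%d clusters over %d cell types\n",
              x$k, length(x$labels)))
  for (cl in seq_len(x$k))
    cat(sprintf("  cluster %d (mean F=%.3f): %s\n", cl, x$mean_f[[cl]],
                paste(names(x$labels)[x$labels == cl], collapse = ", ")))
  invisible(x)
}

#' Write a cluster assignment as TSV
#' @param assignment `cluster_assignment`.
#' @param path output path.
#' @export
write_clusters_tsv <- function(assignment, path) {
  df <- data.frame(cell_type = names(assignment$labels),
                   cluster = unname(assignment$labels),
                   cluster_mean_f = unname(assignment$mean_f[assignment$labels]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
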