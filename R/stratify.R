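#' @title Patient stratification
#' @description Hierarchical clustering (Euclidean distance, complete
#' linkage) of task-activity or sensitivity matrices, row
#' standardization for heatmap-style comparison, per-cluster
#' metabo-group contribution proportions, and a chance-corrected
#' agreement measure (adjusted Rand index) for recovery checks.
#' @name stratify-module
NULL

#' Hierarchical clustering with a flat cut
#'
#' Agglomerative clustering with Euclidean metric and complete linkage
#' (ties resolved deterministically by item order), cut into `k` flat
#' clusters.
#'
#' @param matrix numeric matrix.
#' @param axis cluster `"rows"` or `"columns"`.
#' @param k number of flat clusters.
#' @return a `cluster_assignment`: `assignment` (named integer),
#'   `leaf_order`, `heights`, `hclust`, `k`.
#' @export
hierarchical_cluster <- function(matrix, axis = c("rows", "columns"), k) {
  axis <- match.arg(axis)
  M <- if (axis == "columns") t(matrix) else as.matrix(matrix)
  if (nrow(M) < 2) stop("need at least 2 items to cluster")
  if (k > nrow(M)) stop("k exceeds item count (", nrow(M), ")")
  hc <- stats::hclust(stats::dist(M, method = "euclidean"),
                      method = "complete")
  structure(list(assignment = stats::cutree(hc, k = k),
                 leaf_order = hc$order, heights = hc$height,
                 hclust = hc, k = k, axis = axis),
            class = "cluster_assignment")
}

#' Z-score each row of a matrix
#'
#' Rows with (near-)zero variance are set to 0 and flagged in the
#' `flagged_rows` attribute.
#' @param matrix numeric matrix.
#' @return standardized matrix.
#' @export
row_standardize <- function(matrix) {
  M <- as.matrix(matrix)
  mu <- rowMeans(M, na.rm = TRUE)
  sdv <- apply(M, 1, stats::sd, na.rm = TRUE)
  flag <- sdv < 1e-12 | is.na(sdv)
  out <- (M - mu) / ifelse(flag, 1, sdv)
  out[flag, ] <- 0
  attr(out, "flagged_rows") <- which(flag)
  out
}

#' Per-cluster group contribution proportions
#'
#' For each flat cluster, the proportion of members contributed by
#' each group (0 = no contribution, 1 = full contribution); proportions
#' are reported over all group levels present in `group_labels`.
#'
#' @param assignment a `cluster_assignment` (or named integer vector).
#' @param group_labels named vector item -> group.
#' @return matrix clusters x groups of proportions (rows sum to 1).
#' @export
cluster_group_contributions <- function(assignment, group_labels) {
  asg <- if (inherits(assignment, "cluster_assignment"))
    assignment$assignment else assignment
  items <- names(asg)
  if (is.null(items)) stop("assignment must be named by item")
  gl <- group_labels[items]
  if (any(is.na(gl)))
    stop("missing group label for: ",
         paste(items[is.na(gl)], collapse = ", "))
  groups <- sort(unique(as.character(group_labels)))
  cl <- sort(unique(asg))
  out <- matrix(0, length(cl), length(groups),
                dimnames = list(paste0("cluster", cl), groups))
  for (i in seq_along(cl)) {
    members <- gl[asg == cl[i]]
    tab <- table(factor(members, levels = groups))
    out[i, ] <- as.numeric(tab) / length(members)
  }
  out
}

#' Adjusted Rand index between two partitions
#' @param a,b partition label vectors of equal length.
#' @return ARI in `[-1, 1]` (1 = identical partitions, ~0 = chance).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (abs(maxi - expected) < 1e-12) return(0)
  (sum_ij - expected) / (maxi - expected)
}

#' Export a clustered heatmap as TSV (reordered matrix + leaf orders)
#'
#' @param matrix the data matrix.
#' @param row_assignment,col_assignment `cluster_assignment`s for the
#'   two axes (either may be NULL).
#' @param path TSV path for the reordered matrix; leaf orders and flat
#'   assignments go to `<path>.json`.
#' @export
export_heatmap_tsv <- function(matrix, row_assignment = NULL,
                               col_assignment = NULL, path) {
  M <- as.matrix(matrix)
  ro <- if (!is.null(row_assignment)) row_assignment$leaf_order
        else seq_len(nrow(M))
  co <- if (!is.null(col_assignment)) col_assignment$leaf_order
        else seq_len(ncol(M))
  Mo <- M[ro, co, drop = FALSE]
  utils::write.table(data.frame(id = rownames(Mo), Mo, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    row_order = ro, col_order = co,
    row_clusters = if (!is.null(row_assignment))
      as.list(row_assignment$assignment) else NULL,
    col_clusters = if (!is.null(col_assignment))
      as.list(col_assignment$assignment) else NULL),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
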