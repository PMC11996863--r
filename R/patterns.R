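# Row standardization, hierarchical clustering and variable-height cutting —
# the machinery behind the heatmap classes.

#' Z-score matrix rows
#'
#' Each row is centered and scaled to unit standard deviation (n-1
#' denominator). Constant rows cannot be scaled and are dropped with a
#' warning.
#'
#' @param x numeric matrix
#' @export
zscore_rows <- function(x) {
  stopifnot(is.matrix(x))
  sds <- apply(x, 1, stats::sd)
  constant <- sds == 0 | is.na(sds)
  if (any(constant)) {
    warning(sum(constant), " constant row(s) dropped before z-scoring")
    x <- x[!constant, , drop = FALSE]
    sds <- sds[!constant]
  }
  (x - rowMeans(x)) / sds
}

#' Hierarchical clustering of rows by Euclidean distance
#'
#' Agglomerative clustering (default complete linkage) of the matrix rows.
#' In the pipeline the rows are the SV-adjusted, z-scored profiles of sites
#' passing the moderated-F FDR filter.
#'
#' @param x numeric matrix with at least 2 rows
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default "complete")
#' @return an [stats::hclust] dendrogram
#' @export
hcluster <- function(x, linkage = "complete") {
  stopifnot(is.matrix(x))
  if (nrow(x) < 2) stop("hcluster needs at least 2 rows")
  stats::hclust(stats::dist(x, method = "euclidean"), method = linkage)
}

#' Cut a dendrogram at variable heights
#'
#' Recursive top-down rule: a node is split into its two children iff both
#' children contain at least `min_size` leaves and the node's merge height
#' exceeds `split_fraction` times the root height; unsplit subtrees become
#' clusters. Adapting the decision per branch (rather than one global cut
#' height) lets tight clusters survive next to loose ones. Cluster ids are
#' assigned in leaf order, so relabeling is deterministic.
#'
#' @param dendrogram an [stats::hclust] object
#' @param min_size minimum leaves per cluster (default 20)
#' @param split_fraction fraction of the root height above which a node may
#'   split, in (0, 1) (default 0.8)
#' @return integer cluster labels named by the dendrogram's leaf labels
#' @export
cut_variable_height <- function(dendrogram, min_size = 20, split_fraction = 0.8) {
  stopifnot(inherits(dendrogram, "hclust"), min_size >= 1,
            split_fraction > 0, split_fraction < 1)
  merge <- dendrogram$merge
  height <- dendrogram$height
  n <- length(dendrogram$order)
  root_height <- max(height)

  leaves_of <- vector("list", nrow(merge))
  for (i in seq_len(nrow(merge))) {
    get_leaves <- function(idx) {
      if (idx < 0) -idx else leaves_of[[idx]]
    }
    leaves_of[[i]] <- c(get_leaves(merge[i, 1]), get_leaves(merge[i, 2]))
  }

  labels <- integer(n)
  next_id <- 0L
  assign_cluster <- function(leaf_set) {
    next_id <<- next_id + 1L
    labels[leaf_set] <<- next_id
  }
  walk <- function(node) {
    if (node < 0) {
      assign_cluster(-node)
      return(invisible())
    }
    left <- merge[node, 1]
    right <- merge[node, 2]
    n_left <- if (left < 0) 1L else length(leaves_of[[left]])
    n_right <- if (right < 0) 1L else length(leaves_of[[right]])
    if (height[node] > split_fraction * root_height &&
        n_left >= min_size && n_right >= min_size) {
      walk(left)
      walk(right)
    } else {
      assign_cluster(leaves_of[[node]])
    }
  }
  if (n == 1) {
    labels <- 1L
  } else {
    walk(nrow(merge))
  }
  # renumber in leaf (plot) order for a canonical labeling
  first_seen <- labels[dendrogram$order]
  remap <- stats::setNames(seq_along(unique(first_seen)), unique(first_seen))
  labels <- unname(remap[as.character(labels)])
  names(labels) <- if (!is.null(dendrogram$labels)) dendrogram$labels else
    as.character(seq_len(n))
  labels
}
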