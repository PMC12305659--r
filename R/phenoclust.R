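#' Spearman correlation distance matrix
#'
#' \eqn{d(a,b) = 1 - \rho_s(a,b)} over the rows of a fingerprint matrix.
#' Rank-invariant: any strictly increasing transform of a fingerprint leaves
#' its distances unchanged. Constant fingerprints have undefined rank
#' correlation; their off-diagonal distances are set to 1 with a notice.
#'
#' @param fingerprints numeric matrix, rows = samples (ids in rownames),
#'   columns = features (>= 3).
#' @return symmetric matrix of distances in \[0, 2\] with zero diagonal.
#' @export
spearman_distance <- function(fingerprints) {
  x <- as.matrix(fingerprints)
  stopifnot(nrow(x) >= 2L, ncol(x) >= 3L)
  if (is.null(rownames(x))) rownames(x) <- paste0("s", seq_len(nrow(x)))
  const <- apply(x, 1L, function(r) length(unique(r)) == 1L)
  if (any(const))
    notice("spearman_distance: %d constant fingerprint(s), distance set to 1 (e.g. '%s')",
           sum(const), rownames(x)[which(const)[1L]])
  rho <- suppressWarnings(stats::cor(t(x), method = "spearman"))
  d <- 1 - rho
  d[is.na(d)] <- 1
  diag(d) <- 0
  d[d < 0] <- 0 # numerical guard
  d
}

#' Ward hierarchical clustering of a distance matrix
#'
#' Agglomerates with the Ward criterion via the generalized Lance-Williams
#' update (`stats::hclust`, method `"ward.D2"`), applied directly to the
#' (generally non-Euclidean) 1 - Spearman distance matrix. Deterministic
#' for a given matrix; duplicate points merge at height 0 first.
#'
#' @param distances symmetric distance matrix or `dist` object.
#' @return an `hclust` tree.
#' @export
ward_cluster <- function(distances) {
  d <- stats::as.dist(distances)
  stats::hclust(d, method = "ward.D2")
}

#' Gate a dendrogram with positive-control replicates
#'
#' Finds the lowest cut height at which all designated positive-control
#' replicates fall into a single flat cluster (so the control cluster is
#' contiguous by construction) and returns the flat cluster assignment at
#' that height.
#'
#' @param tree an `hclust` tree.
#' @param positive_ids character vector (>= 2) of leaf labels of the
#'   positive-control replicates.
#' @return list with `assignment` (named integer vector over all leaves),
#'   `gate_height` (numeric) and `n_clusters`.
#' @export
gate_clusters <- function(tree, positive_ids) {
  stopifnot(inherits(tree, "hclust"))
  positive_ids <- unique(positive_ids)
  if (length(positive_ids) < 2L)
    stop("need at least two positive-control replicates", call. = FALSE)
  missing <- setdiff(positive_ids, tree$labels)
  if (length(missing) > 0L)
    stop(sprintf("positive ids missing from tree: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  heights <- sort(unique(c(0, tree$height)))
  for (h in heights) {
    cl <- stats::cutree(tree, h = h)
    if (length(unique(cl[positive_ids])) == 1L) {
      return(list(assignment = cl, gate_height = h,
                  n_clusters = length(unique(cl))))
    }
  }
  # unreachable: at the top height everything is one cluster
  stop("failed to gate clusters", call. = FALSE)
}

#' Export the clustered fingerprint heatmap and its CSV twin
#'
#' Writes a PNG heatmap of the fingerprints in dendrogram leaf order with a
#' diverging palette centred at 0 and a cluster-id row annotation, plus a
#' CSV of exactly the plotted matrix (same row order). Round-tripping the
#' CSV recovers the matrix.
#'
#' @param fingerprints matrix samples x features (HistDiff units).
#' @param tree the `hclust` tree over the fingerprint rows.
#' @param gating result of [gate_clusters()] (or a named cluster vector).
#' @param path output path prefix; writes `<path>.png` and `<path>.csv`.
#' @return invisibly, the paths written.
#' @export
heatmap_export <- function(fingerprints, tree, gating, path) {
  x <- as.matrix(fingerprints)
  assignment <- if (is.list(gating)) gating$assignment else gating
  stopifnot(all(rownames(x) %in% names(assignment)))
  ord <- tree$labels[tree$order]
  x <- x[ord, , drop = FALSE]
  csv <- paste0(path, ".csv")
  png_path <- paste0(path, ".png")
  write.csv(data.frame(id = rownames(x), cluster = assignment[ord],
                       x, check.names = FALSE),
            csv, row.names = FALSE)
  lim <- max(abs(x), 1e-9)
  ann <- data.frame(cluster = factor(assignment[ord]), row.names = ord)
  ok <- tryCatch({
    pheatmap::pheatmap(
      x, cluster_rows = tree, cluster_cols = FALSE,
      annotation_row = ann,
      breaks = seq(-lim, lim, length.out = 101),
      color = grDevices::colorRampPalette(
        c("#313695", "#F7F7F7", "#FFD92F"))(100),
      filename = png_path, silent = TRUE)
    TRUE
  }, error = function(e) {
    notice("heatmap_export: PNG device unavailable (%s); CSV written",
           conditionMessage(e))
    FALSE
  })
  invisible(c(csv = csv, png = if (ok) png_path else NA_character_))
}

#' Serialize an hclust dendrogram to Newick
#'
#' @param tree an `hclust` tree.
#' @param path output file.
#' @return the path, invisibly.
#' @export
dendrogram_newick <- function(tree, path) {
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}
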