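#' Feature presence across samples
#'
#' A sample contains a feature iff its intensity strictly exceeds
#' `min_intensity` (default 0: any nonzero intensity counts, matching
#' upstream peak-filtered exports).
#'
#' @param table MS feature table data frame (`feature_id`, `rt`, `mz`, then
#'   one intensity column per sample).
#' @param min_intensity nonnegative intensity threshold.
#' @return named list: feature id -> character vector of containing samples.
#' @export
detect_presence <- function(table, min_intensity = 0) {
  stopifnot(min_intensity >= 0)
  samples <- setdiff(colnames(table), c("feature_id", "rt", "mz"))
  mat <- as.matrix(table[, samples, drop = FALSE])
  out <- lapply(seq_len(nrow(table)),
                function(i) samples[mat[i, ] > min_intensity])
  names(out) <- table$feature_id
  out
}

#' Per-feature activity score (phenotype strength)
#'
#' Mean over the extracts containing a feature of the mean squared
#' bioactivity fingerprint value: for containing extracts \eqn{e} with
#' fingerprints \eqn{a_e \in [0,1]^p},
#' \eqn{\mathrm{activity} = \mathrm{mean}_e\, \mathrm{mean}_j\, a_{ej}^2},
#' which stays in \[0, 1\]. The literal sum-over-extracts variant is
#' available with `aggregate = "sum"`.
#'
#' @param feature feature id.
#' @param profiles matrix samples x fingerprint features, values in \[0, 1\].
#' @param presence presence list from [detect_presence()].
#' @param aggregate `"mean"` (default) or `"sum"` over containing extracts.
#' @return nonnegative activity score, or `NA` (with a notice) when the
#'   feature is contained in no profiled sample.
#' @export
activity_score <- function(feature, profiles, presence,
                           aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  contain <- intersect(presence[[feature]], rownames(profiles))
  if (length(contain) == 0L) {
    notice("activity_score: feature '%s' absent from all profiled samples; skipped",
           feature)
    return(NA_real_)
  }
  per_extract <- rowMeans(profiles[contain, , drop = FALSE]^2)
  if (aggregate == "mean") mean(per_extract) else sum(per_extract)
}

#' Per-feature cluster score (phenotype consistency)
#'
#' Mean Pearson correlation over all unordered pairs of extracts containing
#' the feature. A feature contained in a single extract scores 1 by
#' convention (no pair contradicts consistency); a pair involving a
#' constant fingerprint contributes 0 with a notice.
#'
#' @inheritParams activity_score
#' @param singleton_score score assigned to single-extract features.
#' @return cluster score in \[-1, 1\], or `NA` for unprofiled features.
#' @export
cluster_score <- function(feature, profiles, presence, singleton_score = 1) {
  contain <- intersect(presence[[feature]], rownames(profiles))
  if (length(contain) == 0L) {
    notice("cluster_score: feature '%s' absent from all profiled samples; skipped",
           feature)
    return(NA_real_)
  }
  if (length(contain) == 1L) return(singleton_score)
  x <- profiles[contain, , drop = FALSE]
  const <- apply(x, 1L, function(r) stats::sd(r) == 0)
  if (any(const))
    notice("cluster_score: constant fingerprint(s) in pairs for feature '%s'; those pairs score 0",
           feature)
  rho <- suppressWarnings(stats::cor(t(x), method = "pearson"))
  rho[is.na(rho)] <- 0
  mean(rho[upper.tri(rho)])
}

#' Activity and cluster scores for every feature in a table
#'
#' @inheritParams activity_score
#' @param table MS feature table data frame.
#' @param min_intensity presence threshold, see [detect_presence()].
#' @param singleton_score see [cluster_score()].
#' @return data frame `feature_id`, `activity_score`, `cluster_score`,
#'   `n_samples` (containing-sample count); unprofiled features are dropped
#'   with a notice.
#' @export
feature_scores <- function(table, profiles, min_intensity = 0,
                           aggregate = c("mean", "sum"),
                           singleton_score = 1) {
  aggregate <- match.arg(aggregate)
  presence <- detect_presence(table, min_intensity)
  ids <- names(presence)
  act <- vapply(ids, activity_score, 0, profiles = profiles,
                presence = presence, aggregate = aggregate)
  cls <- vapply(ids, cluster_score, 0, profiles = profiles,
                presence = presence, singleton_score = singleton_score)
  n <- vapply(ids, function(f)
    length(intersect(presence[[f]], rownames(profiles))), 0L)
  out <- data.frame(feature_id = ids, activity_score = act,
                    cluster_score = cls, n_samples = n,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[!is.na(out$activity_score), , drop = FALSE]
}

#' Build the thresholded bipartite bioactivity network
#'
#' Retains features with `activity_score >= min_activity` and
#' `cluster_score >= min_cluster` (the published defaults 0.03 and 0.5),
#' connects each retained feature to its containing samples, and drops
#' isolated samples. Sample nodes are "squares", feature nodes "circles";
#' the feature activity score is stored as the node `activity_score`
#' attribute (drawn as circle radius).
#'
#' @param scores data frame from [feature_scores()].
#' @param presence presence list from [detect_presence()] (restricted to
#'   profiled samples when building edges).
#' @param min_activity minimum activity score (default 0.03).
#' @param min_cluster minimum cluster score (default 0.5).
#' @param samples optional character vector restricting the sample universe.
#' @return an `igraph` bipartite graph with vertex attributes `type`
#'   (`TRUE` = feature), `kind` (`"sample"`/`"feature"`), `activity_score`,
#'   `cluster_score`.
#' @export
build_network <- function(scores, presence, min_activity = 0.03,
                          min_cluster = 0.5, samples = NULL) {
  stopifnot(min_cluster >= -1, min_cluster <= 1, min_activity >= 0)
  keep <- scores$feature_id[scores$activity_score >= min_activity &
                            scores$cluster_score >= min_cluster]
  edges <- do.call(rbind, lapply(keep, function(f) {
    s <- presence[[f]]
    if (!is.null(samples)) s <- intersect(s, samples)
    if (length(s) == 0L) return(NULL)
    data.frame(sample = s, feature = f, stringsAsFactors = FALSE)
  }))
  g <- igraph::make_empty_graph(directed = FALSE)
  if (is.null(edges)) return(g)
  snodes <- unique(edges$sample)
  fnodes <- unique(edges$feature)
  g <- igraph::add_vertices(g, length(snodes), name = snodes, type = FALSE,
                            kind = "sample")
  g <- igraph::add_vertices(g, length(fnodes), name = fnodes, type = TRUE,
                            kind = "feature")
  g <- igraph::add_edges(g, rbind(match(edges$sample, c(snodes, fnodes)),
                                  match(edges$feature, c(snodes, fnodes))))
  idx <- match(fnodes, scores$feature_id)
  act <- c(rep(NA_real_, length(snodes)), scores$activity_score[idx])
  cls <- c(rep(NA_real_, length(snodes)), scores$cluster_score[idx])
  igraph::vertex_attr(g, "activity_score") <- act
  igraph::vertex_attr(g, "cluster_score") <- cls
  g
}

#' Modularity-based community detection on the bioactivity network
#'
#' Louvain modularity optimization on the bipartite graph treated as an
#' undirected unipartite graph, under a fixed RNG seed for determinism.
#' Communities never span disconnected components.
#'
#' @param net igraph network from [build_network()]; must be nonempty.
#' @param seed integer RNG seed.
#' @return named integer vector of community labels per vertex.
#' @export
detect_communities <- function(net, seed = 1L) {
  if (igraph::vcount(net) == 0L) stop("empty network", call. = FALSE)
  set.seed(as.integer(seed))
  comm <- igraph::cluster_louvain(net)
  membership <- igraph::membership(comm)
  stats::setNames(as.integer(membership), names(membership))
}

#' Export the network as GraphML plus node/edge CSVs
#'
#' @param net igraph network from [build_network()].
#' @param path output path prefix; writes `<path>.graphml`,
#'   `<path>_nodes.csv` and `<path>_edges.csv`.
#' @param communities optional named community labels from
#'   [detect_communities()], stored as a node attribute/column.
#' @return invisibly, the three paths.
#' @export
export_network <- function(net, path, communities = NULL) {
  if (!is.null(communities) && igraph::vcount(net) > 0L)
    igraph::vertex_attr(net, "community") <-
      as.integer(communities[igraph::V(net)$name])
  graphml <- paste0(path, ".graphml")
  nodes_csv <- paste0(path, "_nodes.csv")
  edges_csv <- paste0(path, "_edges.csv")
  igraph::write_graph(net, graphml, format = "graphml")
  if (igraph::vcount(net) > 0L) {
    nodes <- data.frame(
      id = igraph::V(net)$name,
      type = igraph::V(net)$kind,
      activity_score = igraph::V(net)$activity_score,
      cluster_score = igraph::V(net)$cluster_score,
      community = if (is.null(communities)) NA_integer_ else
        as.integer(communities[igraph::V(net)$name]),
      stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(net)
    edges <- data.frame(sample = el[, 1], feature = el[, 2],
                        stringsAsFactors = FALSE)
  } else {
    nodes <- data.frame(id = character(0), type = character(0),
                        activity_score = numeric(0),
                        cluster_score = numeric(0),
                        community = integer(0))
    edges <- data.frame(sample = character(0), feature = character(0))
  }
  write.csv(nodes, nodes_csv, row.names = FALSE)
  write.csv(edges, edges_csv, row.names = FALSE)
  invisible(c(graphml = graphml, nodes = nodes_csv, edges = edges_csv))
}
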