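#' Partition a subnetwork into clusters with the Leiden algorithm
#'
#' Runs modularity-objective Leiden community detection
#' ([igraph::cluster_leiden()]) on an induced subnetwork. Isolated nodes
#' come back as singleton clusters; size filtering is a separate step
#' ([filter_clusters()]). Edge weights are used when present.
#'
#' @param subnet An [igraph::igraph] (typically from [induce_subgraph()]).
#' @param iterations Number of Leiden iterations (default 100, the
#'   conventional setting); a negative value iterates until the partition
#'   stops improving, which yields the same converged partition at a
#'   fraction of the cost on networks of the sizes used here.
#' @param seed Integer seed, or `NULL` to consume the current RNG stream.
#' @param use_weights Use the `weight` edge attribute when present.
#' @return Named list of character vectors (cluster id -> member genes),
#'   ordered by decreasing size then first member name.
#' @export
partition_leiden <- function(subnet, iterations = 100L, seed = NULL,
                             use_weights = TRUE) {
  if (igraph::vcount(subnet) == 0L) return(list())
  if (!is.null(seed)) set.seed(seed)
  w <- if (use_weights && "weight" %in% igraph::edge_attr_names(subnet)) {
    igraph::E(subnet)$weight
  } else {
    NULL
  }
  cl <- igraph::cluster_leiden(subnet, objective_function = "modularity",
                               weights = w, n_iterations = iterations)
  memb <- igraph::membership(cl)
  groups <- split(igraph::V(subnet)$name, memb)
  groups <- lapply(groups, sort)
  ord <- order(-lengths(groups),
               vapply(groups, `[[`, "", 1L))
  groups <- groups[ord]
  names(groups) <- sprintf("c%d", seq_along(groups))
  groups
}

#' Drop clusters below a minimum size
#'
#' @param clusters Named list of character vectors.
#' @param min_size Minimum member count (default 5).
#' @return The retained clusters, input order preserved.
#' @export
filter_clusters <- function(clusters, min_size = 5L) {
  clusters[lengths(clusters) >= min_size]
}

#' Convert clusters to a long-format data frame (and back)
#'
#' @param clusters Named list of character vectors.
#' @param owner Owner (disease/trait) label to attach.
#' @return `clusters_to_df`: data.frame with columns `owner`, `cluster_id`,
#'   `gene`.
#' @export
clusters_to_df <- function(clusters, owner = NA_character_) {
  data.frame(owner = owner,
             cluster_id = rep(names(clusters), lengths(clusters)),
             gene = unlist(clusters, use.names = FALSE))
}

#' @rdname clusters_to_df
#' @param df A data.frame with columns `cluster_id` and `gene`.
#' @return `df_to_clusters`: named list of character vectors.
#' @export
df_to_clusters <- function(df) {
  split(df$gene, df$cluster_id)
}

#' Annotation over-representation for one cluster
#'
#' One-sided hypergeometric tail probability of seeing at least the observed
#' overlap between a cluster and an annotation set, with `background` genes
#' in the universe, plus the fold enrichment
#' (overlap / cluster size) / (annotation size / background).
#'
#' @param cluster Character vector of cluster genes.
#' @param annotation Character vector of annotation genes, already
#'   restricted to the universe (see [annotate_clusters()]).
#' @param background Universe size (> 0).
#' @return List with `overlap`, `fold`, `p`.
#' @export
annotate_cluster <- function(cluster, annotation, background) {
  if (background <= 0) stop("background must be a positive count")
  ov <- length(intersect(cluster, annotation))
  fold <- (ov / length(cluster)) / (length(annotation) / background)
  p <- hyper_p(ov, length(annotation), background, length(cluster))
  list(overlap = ov, fold = fold, p = p)
}

#' Annotation enrichment across the clusters of one owner
#'
#' Restricts each annotation set to the network, applies the usual size
#' bounds, tests every (cluster, annotation) pair with
#' [annotate_cluster()], and Benjamini-Hochberg-adjusts p-values across
#' annotations within each cluster. Annotation sets disjoint from the
#' network are skipped with a message.
#'
#' @param clusters Named list of character vectors.
#' @param annotations Named list of character vectors.
#' @param net The clustering network (defines the universe).
#' @param min_ann_size,max_ann_size Size bounds on the network-restricted
#'   annotation sets (defaults 5 and 100).
#' @return data.frame with columns `cluster_id`, `annotation`, `overlap`,
#'   `fold`, `p`, `fdr`.
#' @export
annotate_clusters <- function(clusters, annotations, net,
                              min_ann_size = 5L, max_ann_size = 100L) {
  nodes <- igraph::V(net)$name
  background <- length(nodes)
  ann_net <- lapply(annotations, intersect, nodes)
  skipped <- names(ann_net)[lengths(ann_net) == 0L & lengths(annotations) > 0L]
  if (length(skipped) > 0L) {
    message("skipping ", length(skipped),
            " annotation set(s) disjoint from the network")
  }
  keep <- lengths(ann_net) >= min_ann_size & lengths(ann_net) <= max_ann_size
  ann_net <- ann_net[keep]
  rows <- lapply(names(clusters), function(cid) {
    res <- lapply(names(ann_net), function(aid) {
      r <- annotate_cluster(clusters[[cid]], ann_net[[aid]], background)
      data.frame(cluster_id = cid, annotation = aid, overlap = r$overlap,
                 fold = r$fold, p = r$p)
    })
    out <- do.call(rbind, res)
    if (!is.null(out)) out$fdr <- stats::p.adjust(out$p, method = "BH")
    out
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cluster_id = character(0), annotation = character(0),
                      overlap = integer(0), fold = numeric(0),
                      p = numeric(0), fdr = numeric(0))
  }
  rownames(out) <- NULL
  out
}
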