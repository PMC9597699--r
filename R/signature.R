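#' Mean closest shortest-path distance from one gene set to another
#'
#' d(A, B) = mean over a in A of the shortest-path distance from a to the
#' closest gene of B, on the unweighted topology. Directional: d(A,B) and
#' d(B,A) generally differ. Unreachable pairs contribute a finite penalty,
#' by default one more than the diameter of the network's largest component
#' (dropping them would bias the distance downward).
#'
#' @param net The interactome.
#' @param A,B Character vectors of genes; both must intersect the network.
#' @param dmat Optional precomputed distance matrix
#'   ([network_distance_matrix()]) to avoid repeated BFS.
#' @param penalty Distance charged for unreachable pairs; default
#'   `diameter + 1` computed from the network (or from `dmat`).
#' @return Nonnegative scalar distance.
#' @export
closest_distance <- function(net, A, B, dmat = NULL, penalty = NULL) {
  nodes <- igraph::V(net)$name
  A <- intersect(A, nodes)
  B <- intersect(B, nodes)
  if (length(A) == 0L || length(B) == 0L) {
    stop("gene set empty after restriction to the network")
  }
  if (is.null(dmat)) {
    sub <- igraph::distances(net, v = A, to = B, weights = NA)
    if (is.null(penalty)) {
      # diameter of the largest component + 1
      comp <- igraph::components(net)
      big <- igraph::induced_subgraph(
        net, which(comp$membership == which.max(comp$csize)))
      penalty <- igraph::diameter(big, weights = NA) + 1
    }
  } else {
    sub <- dmat[A, B, drop = FALSE]
    if (is.null(penalty)) {
      finite <- dmat[is.finite(dmat)]
      penalty <- (if (length(finite) > 0L) max(finite) else 0) + 1
    }
  }
  mins <- apply(sub, 1L, min)
  mins[!is.finite(mins)] <- penalty
  mean(mins)
}

#' Precompute the all-pairs unweighted distance matrix
#'
#' @param net The interactome.
#' @return Numeric matrix with gene names on both dimensions; attribute
#'   `"penalty"` holds diameter + 1 of the largest component.
#' @export
network_distance_matrix <- function(net) {
  d <- igraph::distances(net, weights = NA)
  finite <- d[is.finite(d)]
  attr(d, "penalty") <- (if (length(finite) > 0L) max(finite) else 0) + 1
  d
}

set_similarity <- function(net, A, B, dmat, penalty) {
  d_ab <- closest_distance(net, A, B, dmat = dmat, penalty = penalty)
  d_ba <- closest_distance(net, B, A, dmat = dmat, penalty = penalty)
  c(d_ab = d_ab, d_ba = d_ba, s_ab = 1 / (1 + d_ab), s_ba = 1 / (1 + d_ba))
}

#' Network similarity of two clusters with a degree-matched empirical null
#'
#' Directional similarities s = 1 / (1 + d) from the mean closest distances
#' in each direction; each direction's empirical p-value is computed over
#' `n_null` random pairs of degree-matched sets preserving the size and
#' degree multiset of each cluster, as (#\{null s >= observed s\} + 1) /
#' (n_null + 1). The two one-sided p-values are combined with Stouffer's
#' method and the two similarities averaged, giving one symmetric record
#' per pair.
#'
#' @param net The interactome.
#' @param A,B Cluster gene vectors.
#' @param index [build_degree_index()] of `net`.
#' @param n_null Number of null pairs (at least 20; default 1000).
#' @param seed Integer seed, or `NULL` to consume the current stream.
#' @param dmat Optional precomputed [network_distance_matrix()].
#' @param k_min Degree-match pool width.
#' @return One-row data.frame: `d_ab`, `d_ba`, `s_ab`, `s_ba`, `p_ab`,
#'   `p_ba`, `p_combined`, `s_mean`.
#' @export
cluster_similarity <- function(net, A, B, index, n_null = 1000L,
                               seed = NULL, dmat = NULL, k_min = 10L) {
  if (n_null < 20L) stop("n_null < 20: null distribution too coarse")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dmat)) dmat <- network_distance_matrix(net)
  penalty <- attr(dmat, "penalty")
  obs <- set_similarity(net, A, B, dmat, penalty)
  nodes <- igraph::V(net)$name
  A_n <- intersect(A, nodes); B_n <- intersect(B, nodes)
  null_ab <- numeric(n_null); null_ba <- numeric(n_null)
  for (i in seq_len(n_null)) {
    Ar <- degree_matched_sample(A_n, index, k_min = k_min)
    Br <- degree_matched_sample(B_n, index, k_min = k_min)
    s <- set_similarity(net, Ar, Br, dmat, penalty)
    null_ab[i] <- s[["s_ab"]]; null_ba[i] <- s[["s_ba"]]
  }
  p_ab <- (sum(null_ab >= obs[["s_ab"]]) + 1) / (n_null + 1)
  p_ba <- (sum(null_ba >= obs[["s_ba"]]) + 1) / (n_null + 1)
  data.frame(d_ab = obs[["d_ab"]], d_ba = obs[["d_ba"]],
             s_ab = obs[["s_ab"]], s_ba = obs[["s_ba"]],
             p_ab = p_ab, p_ba = p_ba,
             p_combined = stouffer_p(p_ab, p_ba),
             s_mean = (obs[["s_ab"]] + obs[["s_ba"]]) / 2)
}

#' Pairwise similarity records for a collection of clusters
#'
#' Runs [cluster_similarity()] for every unordered pair of clusters
#' (typically the CI-enriched clusters pooled across diseases).
#'
#' @param net The interactome.
#' @param clusters Named list of cluster gene vectors; names must be unique
#'   across owners (e.g. `"disease01.c1"`).
#' @param index [build_degree_index()] of `net`.
#' @inheritParams cluster_similarity
#' @return data.frame with `cluster_a`, `cluster_b` and the
#'   [cluster_similarity()] columns.
#' @export
pairwise_cluster_similarity <- function(net, clusters, index,
                                        n_null = 1000L, seed = NULL,
                                        dmat = NULL, k_min = 10L) {
  stopifnot(length(clusters) >= 2L)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dmat)) dmat <- network_distance_matrix(net)
  ids <- names(clusters)
  pairs <- utils::combn(ids, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    rec <- cluster_similarity(net, clusters[[a]], clusters[[b]], index,
                              n_null = n_null, seed = NULL, dmat = dmat,
                              k_min = k_min)
    cbind(data.frame(cluster_a = a, cluster_b = b), rec)
  })
  do.call(rbind, rows)
}

#' Group CI-enriched clusters into cross-disease signatures
#'
#' Builds a graph over clusters with an edge (weighted by `s_mean`) for
#' every pair whose Stouffer-combined p-value survives Benjamini-Hochberg
#' adjustment across all pairs at level `alpha`, then partitions it with
#' modularity-objective Leiden. When no pair is significant every cluster
#' becomes its own singleton group (with a message).
#'
#' @param records Output of [pairwise_cluster_similarity()].
#' @param clusters The named list of cluster gene vectors the records refer
#'   to.
#' @param alpha Significance level on the BH-adjusted combined p (default
#'   0.05).
#' @param seed Integer seed for the Leiden step.
#' @param iterations Leiden iterations.
#' @return List of groups, each with `group_id`, `members`, `union_genes`,
#'   `unique_genes` (genes in this group's union and no other's); also a
#'   `membership` attribute (named vector cluster -> group_id).
#' @export
group_signatures <- function(records, clusters, alpha = 0.05, seed = 1L,
                             iterations = 100L) {
  stopifnot(length(clusters) >= 2L)
  records$fdr_pair <- stats::p.adjust(records$p_combined, method = "BH")
  sig <- records[records$fdr_pair < alpha, , drop = FALSE]
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(names(clusters))
  if (nrow(sig) > 0L) {
    el <- as.vector(t(as.matrix(sig[, c("cluster_a", "cluster_b")])))
    g <- igraph::add_edges(g, el, weight = sig$s_mean)
  } else {
    message("no significant cluster pairs: every cluster is its own group")
  }
  part <- partition_leiden(g, iterations = iterations, seed = seed,
                           use_weights = TRUE)
  membership <- stats::setNames(
    rep(names(part), lengths(part)), unlist(part, use.names = FALSE))
  unions <- lapply(part, function(members) {
    unique(unlist(clusters[members], use.names = FALSE))
  })
  groups <- lapply(seq_along(part), function(i) {
    others <- unique(unlist(unions[-i], use.names = FALSE))
    list(group_id = names(part)[i],
         members = part[[i]],
         union_genes = unions[[i]],
         unique_genes = setdiff(unions[[i]], others))
  })
  attr(groups, "membership") <- membership[names(clusters)]
  groups
}

#' Annotation enrichment of the genes unique to each signature group
#'
#' Applies the cluster annotation machinery to each group's unique gene
#' set, with Benjamini-Hochberg adjustment across annotations within each
#' group. Groups with an empty unique set are skipped with a message.
#'
#' @param groups Output of [group_signatures()].
#' @param annotations Named list of annotation gene sets.
#' @param net The network defining the universe.
#' @param min_ann_size,max_ann_size Annotation size bounds.
#' @return data.frame as [annotate_clusters()], with `cluster_id` holding
#'   the group id.
#' @export
characterize_groups <- function(groups, annotations, net,
                                min_ann_size = 5L, max_ann_size = 100L) {
  uniq <- lapply(groups, `[[`, "unique_genes")
  names(uniq) <- vapply(groups, `[[`, "", "group_id")
  empty <- names(uniq)[lengths(uniq) == 0L]
  if (length(empty) > 0L) {
    message("skipping ", length(empty), " group(s) with no unique genes")
    uniq <- uniq[lengths(uniq) > 0L]
  }
  annotate_clusters(uniq, annotations, net,
                    min_ann_size = min_ann_size,
                    max_ann_size = max_ann_size)
}
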