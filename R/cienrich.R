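#' Draw a degree-matched random gene set
#'
#' Replaces each input gene independently with a gene drawn uniformly from
#' the genes of the same degree; when fewer than `k_min` genes share that
#' degree, the candidate pool is widened to the nearest occupied degrees
#' (by absolute degree difference, ties towards the smaller degree) until it
#' holds at least `k_min` genes. Duplicates among the replacements are
#' redrawn so the output is a set of distinct genes of the input's size.
#' This preserves hubness while destroying set identity, the null model
#' behind every permutation test in the pipeline.
#'
#' @param genes Character vector of network genes.
#' @param index [build_degree_index()] of the network.
#' @param k_min Minimum candidate-pool size before widening stops
#'   (default 10). With `k_min = 1`, a gene of unique degree maps to itself.
#' @return Character vector of `length(genes)` distinct genes.
#' @export
degree_matched_sample <- function(genes, index, k_min = 10L) {
  n <- length(genes)
  if (n == 0L) return(character(0))
  degs <- index$degree_of[genes]
  if (anyNA(degs)) stop("gene not in the network: ", genes[is.na(degs)][1])
  pools <- lapply(unique(degs), function(d) degree_pool(index, d, k_min))
  names(pools) <- as.character(unique(degs))
  draw_one <- function(i) {
    pool <- pools[[as.character(degs[i])]]
    pool[sample.int(length(pool), 1L)]
  }
  out <- vapply(seq_len(n), draw_one, "")
  # resolve duplicates by redrawing the colliding positions
  for (iter in 1:100) {
    dup <- duplicated(out)
    if (!any(dup)) break
    out[dup] <- vapply(which(dup), draw_one, "")
  }
  if (anyDuplicated(out)) {
    # deterministic fallback: fill remaining collisions from unused pool genes
    dup <- which(duplicated(out))
    avail <- setdiff(unique(unlist(pools, use.names = FALSE)), out)
    if (length(avail) < length(dup)) {
      stop("cannot draw ", n, " distinct degree-matched genes")
    }
    out[dup] <- avail[seq_along(dup)]
  }
  out
}

# candidate pool for one degree, widened to >= k_min genes; cached per index
degree_pool <- function(index, d, k_min) {
  key <- paste0(d, ":", k_min)
  cached <- index$pool_cache[[key]]
  if (!is.null(cached)) return(cached)
  sd <- index$sorted_degrees
  ord <- order(abs(sd - d), sd)
  pool <- character(0)
  for (dd in sd[ord]) {
    pool <- c(pool, index$genes_at[[as.character(dd)]])
    if (length(pool) >= k_min) break
  }
  index$pool_cache[[key]] <- pool
  pool
}

#' CI enrichment score of a cluster
#'
#' E = log2( (|CG n CI| / |CG|) / (|CI| / background) ): the log2 ratio of
#' the cluster's CI-gene fraction to the background CI-gene fraction, where
#' CG are the cluster genes, CI the (network-restricted) CI genes, and the
#' background is the number of genes in the clustering network. A cluster
#' with no CI gene gets `-Inf`.
#'
#' @param cluster_genes Character vector of cluster genes (nonempty).
#' @param ci Character vector of CI genes, restricted to the clustering
#'   network by the caller.
#' @param background Number of genes in the clustering network.
#' @return The enrichment score E (possibly `-Inf`).
#' @export
enrichment_score <- function(cluster_genes, ci, background) {
  if (length(cluster_genes) == 0L) stop("empty cluster")
  if (background <= 0) stop("background must be a positive count")
  if (length(ci) == 0L || length(ci) > background) {
    stop("CI set must be nonempty on the network and no larger than the background")
  }
  ov <- length(intersect(cluster_genes, ci))
  if (ov == 0L) return(-Inf)
  log2((ov / length(cluster_genes)) / (length(ci) / background))
}

#' Permutation p-value of an observed enrichment score
#'
#' p = #\{null scores >= E_obs\} / (n + 1), with n the number of null
#' cluster scores — the published form, which carries no pseudo-count in the
#' numerator and can return 0. `pseudo_count = TRUE` switches to the
#' conventional (1 + #exceedances) / (n + 1). An observed score of `-Inf`
#' is matched (ties count) by every null score, giving p = n / (n + 1).
#'
#' @param E_obs Observed enrichment score (may be `-Inf`).
#' @param null_scores Numeric vector of null cluster scores (nonempty;
#'   `-Inf` entries allowed).
#' @param pseudo_count Add 1 to the numerator (default `FALSE`: verbatim).
#' @return Permutation p-value in `[0, 1]`.
#' @export
permutation_pvalue <- function(E_obs, null_scores, pseudo_count = FALSE) {
  if (length(null_scores) == 0L) stop("empty null score vector")
  n <- length(null_scores)
  (sum(null_scores >= E_obs) + as.integer(pseudo_count)) / (n + 1)
}

#' Build the degree-matched null ensemble for one owner
#'
#' Generates `n_lists` degree-matched random versions of the owner's gene
#' list; each is induced on the network, Leiden-partitioned with the same
#' settings as the real list, filtered to clusters of at least `min_size`
#' genes, and every surviving cluster's enrichment score against the CI set
#' is pooled into one null score vector. Owners whose random lists yield no
#' qualifying cluster at all cannot be tested and must be excluded by the
#' caller (the ensemble records this).
#'
#' @param owner_genes The owner's (expanded) gene list, all on the network.
#' @param net The clustering network.
#' @param index [build_degree_index()] of `net`.
#' @param ci CI gene set (restricted to `net` internally).
#' @param n_lists Number of random lists (default 5000).
#' @param min_size Cluster size filter (default 5).
#' @param seed Integer seed, or `NULL` to consume the current stream.
#' @param iterations Leiden iterations (default 100).
#' @param k_min Degree-match pool width (default 10).
#' @param use_weights Use edge weights in Leiden when present.
#' @return Object of class `null_ensemble`: `scores` (E of every null
#'   cluster), `n_lists`, `n_random_clusters`, `n_lists_with_clusters`.
#' @export
build_null_ensemble <- function(owner_genes, net, index, ci,
                                n_lists = 5000L, min_size = 5L, seed = NULL,
                                iterations = 100L, k_min = 10L,
                                use_weights = TRUE) {
  if (length(owner_genes) == 0L) stop("empty owner gene list")
  if (n_lists <= 0L) stop("n_lists must be positive: cannot form a null")
  if (!is.null(seed)) set.seed(seed)
  nodes <- igraph::V(net)$name
  ci_net <- intersect(ci, nodes)
  if (length(ci_net) == 0L) stop("CI set has no genes on the network")
  background <- length(nodes)
  is_ci <- stats::setNames(nodes %in% ci_net, nodes)
  log2_base <- log2(length(ci_net) / background)
  scores <- vector("list", n_lists)
  n_with <- 0L
  for (i in seq_len(n_lists)) {
    rand <- degree_matched_sample(owner_genes, index, k_min = k_min)
    sg <- igraph::induced_subgraph(net, rand)
    cl <- partition_leiden(sg, iterations = iterations,
                           use_weights = use_weights)
    sizes <- lengths(cl)
    keep <- sizes >= min_size
    if (!any(keep)) next
    n_with <- n_with + 1L
    ov <- vapply(cl[keep], function(g) sum(is_ci[g]), 0)
    e <- ifelse(ov == 0, -Inf, log2(ov / sizes[keep]) - log2_base)
    scores[[i]] <- unname(e)
  }
  all_scores <- unlist(scores, use.names = FALSE)
  structure(
    list(scores = if (is.null(all_scores)) numeric(0) else all_scores,
         n_lists = n_lists,
         n_random_clusters = length(all_scores),
         n_lists_with_clusters = n_with),
    class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat("degree-matched null ensemble:", x$n_lists, "random lists,",
      x$n_random_clusters, "qualifying null clusters\n")
  invisible(x)
}

#' Score the CI enrichment of an owner's clusters against a null ensemble
#'
#' Computes E and the permutation p-value for every cluster, then applies
#' [call_ci_clusters()] (Benjamini-Hochberg within the owner; a cluster is
#' called CI-enriched when FDR < 0.05 and E > 0).
#'
#' @param clusters Named list of (size-filtered) cluster gene vectors.
#' @param null_ensemble A `null_ensemble` for the same owner.
#' @param ci CI gene set.
#' @param net The clustering network.
#' @param owner Owner label to attach.
#' @param pseudo_count Passed to [permutation_pvalue()].
#' @param fdr_threshold Call threshold (default 0.05).
#' @return data.frame: `owner`, `cluster_id`, `size`, `E`, `p`, `fdr`,
#'   `is_ci_enriched`, `n_null_clusters`.
#' @export
ci_enrichment <- function(clusters, null_ensemble, ci, net,
                          owner = NA_character_, pseudo_count = FALSE,
                          fdr_threshold = 0.05) {
  nodes <- igraph::V(net)$name
  ci_net <- intersect(ci, nodes)
  background <- length(nodes)
  if (length(clusters) == 0L) {
    return(data.frame(owner = character(0), cluster_id = character(0),
                      size = integer(0), E = numeric(0), p = numeric(0),
                      fdr = numeric(0), is_ci_enriched = logical(0),
                      n_null_clusters = integer(0)))
  }
  if (null_ensemble$n_random_clusters == 0L) {
    stop("owner has no qualifying null clusters; exclude it from the analysis")
  }
  E <- vapply(clusters, enrichment_score, 0, ci = ci_net,
              background = background)
  p <- vapply(E, permutation_pvalue, 0,
              null_scores = null_ensemble$scores,
              pseudo_count = pseudo_count)
  res <- data.frame(owner = owner, cluster_id = names(clusters),
                    size = unname(lengths(clusters)),
                    E = unname(E), p = unname(p),
                    n_null_clusters = null_ensemble$n_random_clusters)
  call_ci_clusters(res, fdr_threshold = fdr_threshold)
}

#' Adjust and call CI-enriched clusters within one owner
#'
#' Benjamini-Hochberg adjustment of the permutation p-values across the
#' owner's clusters; a cluster is called CI-enriched when its FDR is below
#' `fdr_threshold` and E > 0.
#'
#' @param results data.frame with columns `owner`, `cluster_id`, `E`, `p`
#'   (one owner only).
#' @param fdr_threshold Call threshold (default 0.05).
#' @return The input with `fdr` and `is_ci_enriched` columns added/updated.
#' @export
call_ci_clusters <- function(results, fdr_threshold = 0.05) {
  if (nrow(results) > 0L && length(unique(results$owner)) != 1L) {
    stop("call_ci_clusters expects the clusters of a single owner")
  }
  results$fdr <- stats::p.adjust(results$p, method = "BH")
  results$is_ci_enriched <- results$fdr < fdr_threshold & results$E > 0
  cols <- c("owner", "cluster_id", "size", "E", "p", "fdr",
            "is_ci_enriched", "n_null_clusters")
  results[, intersect(cols, names(results)), drop = FALSE]
}

#' Contrast CI probabilities of unannotated genes by cluster status
#'
#' Restricts to cluster genes absent from the CI set, scores them with a
#' CI expansion model, and compares the scores of genes in CI-enriched
#' versus non-enriched clusters: group means, a one-sided Wilcoxon rank-sum
#' p-value that the enriched group scores higher, and a one-sided Fisher's
#' exact p on the 2x2 of (score above/below the global median) x (cluster
#' enriched/not). The guilt-by-association check that an enriched cluster
#' is inflammation-like as a whole, not just through its known CI members.
#'
#' @param clusters Named list of cluster gene vectors (one owner or pooled).
#' @param calls data.frame with `cluster_id` and `is_ci_enriched` covering
#'   `clusters`.
#' @param ci CI gene set.
#' @param ci_model An `expansion_model` trained on the CI set.
#' @param net The interactome.
#' @return List: `mean_enriched`, `mean_non_enriched`, `p_ranksum`,
#'   `p_fisher`, `n_enriched`, `n_non_enriched`.
#' @export
unannotated_ci_probability_contrast <- function(clusters, calls, ci,
                                                ci_model, net) {
  enr_ids <- calls$cluster_id[calls$is_ci_enriched]
  non_ids <- calls$cluster_id[!calls$is_ci_enriched]
  g_enr <- setdiff(unique(unlist(clusters[names(clusters) %in% enr_ids])), ci)
  g_non <- setdiff(unique(unlist(clusters[names(clusters) %in% non_ids])), ci)
  g_enr <- intersect(g_enr, igraph::V(net)$name)
  g_non <- intersect(g_non, igraph::V(net)$name)
  if (length(g_enr) == 0L) stop("no unannotated genes in CI-enriched clusters")
  if (length(g_non) == 0L) stop("no unannotated genes in non-enriched clusters")
  s_enr <- predict(ci_model, net, genes = g_enr)
  s_non <- predict(ci_model, net, genes = g_non)
  p_rs <- stats::wilcox.test(s_enr, s_non, alternative = "greater",
                             exact = FALSE)$p.value
  med <- stats::median(c(s_enr, s_non))
  tab <- matrix(c(sum(s_enr > med), sum(s_enr <= med),
                  sum(s_non > med), sum(s_non <= med)), 2, 2)
  p_f <- stats::fisher.test(tab, alternative = "greater")$p.value
  list(mean_enriched = mean(s_enr), mean_non_enriched = mean(s_non),
       p_ranksum = p_rs, p_fisher = p_f,
       n_enriched = length(s_enr), n_non_enriched = length(s_non))
}
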