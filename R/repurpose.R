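#' Proximity score of one drug against one disease cluster
#'
#' Network proximity d between the drug's target genes T and the cluster
#' genes C is the symmetrized mean closest distance
#' (d(T,C) + d(C,T)) / 2 (or the drug-to-disease direction alone), mapped
#' to a similarity s = 1 / (1 + d). The empirical p-value compares s with
#' `n_null` random (targets, cluster) pairs matching the size and degree
#' multiset of each original set:
#' p = (#\{null s >= s\} + 1) / (n_null + 1), so with the default 200 null
#' pairs the smallest achievable p is 1/201 and no p is ever zero.
#'
#' @param net The interactome.
#' @param targets Drug target genes (must intersect the network).
#' @param cluster_genes Disease cluster genes.
#' @param index [build_degree_index()] of `net`.
#' @param n_null Number of null pairs (default 200).
#' @param seed Integer seed, or `NULL` to consume the current stream.
#' @param dmat Optional precomputed [network_distance_matrix()].
#' @param direction `"sym"` (default) or `"drug_to_disease"`.
#' @param k_min Degree-match pool width.
#' @return One-row data.frame: `similarity`, `p`.
#' @export
drug_cluster_score <- function(net, targets, cluster_genes, index,
                               n_null = 200L, seed = NULL, dmat = NULL,
                               direction = c("sym", "drug_to_disease"),
                               k_min = 10L) {
  direction <- match.arg(direction)
  if (!is.null(seed)) set.seed(seed)
  nodes <- igraph::V(net)$name
  T_n <- intersect(targets, nodes)
  C_n <- intersect(cluster_genes, nodes)
  if (length(T_n) == 0L) stop("no drug target on the network")
  if (length(C_n) == 0L) stop("empty cluster on the network")
  if (is.null(dmat)) dmat <- network_distance_matrix(net)
  penalty <- attr(dmat, "penalty")
  prox <- function(A, B) {
    d1 <- closest_distance(net, A, B, dmat = dmat, penalty = penalty)
    if (direction == "drug_to_disease") return(d1)
    d2 <- closest_distance(net, B, A, dmat = dmat, penalty = penalty)
    (d1 + d2) / 2
  }
  s_obs <- 1 / (1 + prox(T_n, C_n))
  null_s <- numeric(n_null)
  for (i in seq_len(n_null)) {
    Tr <- degree_matched_sample(T_n, index, k_min = k_min)
    Cr <- degree_matched_sample(C_n, index, k_min = k_min)
    null_s[i] <- 1 / (1 + prox(Tr, Cr))
  }
  p <- (sum(null_s >= s_obs) + 1) / (n_null + 1)
  data.frame(similarity = s_obs, p = p)
}

ic_min_mean <- function(dmat, ai, bi, penalty, direction) {
  m <- dmat[ai, bi, drop = FALSE]
  rmin <- m[cbind(seq_along(ai), max.col(-m, ties.method = "first"))]
  rmin[!is.finite(rmin)] <- penalty
  d1 <- mean(rmin)
  if (direction == "drug_to_disease") return(d1)
  tm <- t(m)
  cmin <- tm[cbind(seq_along(bi), max.col(-tm, ties.method = "first"))]
  cmin[!is.finite(cmin)] <- penalty
  (d1 + mean(cmin)) / 2
}

#' Score every drug against every CI-enriched cluster of every disease
#'
#' Applies the [drug_cluster_score()] proximity statistic to every
#' (drug, cluster) pair. The `n_null` degree-matched null draws are
#' generated once per drug and once per cluster and paired up, which keeps
#' the empirical null identical in distribution while avoiding redundant
#' sampling across pairs. Drugs with no target on the network are skipped
#' with a message.
#'
#' @param net The interactome.
#' @param drug_targets Named list drug -> character vector of target genes.
#' @param clusters Named list of cluster gene vectors.
#' @param owners Named character vector mapping cluster id -> disease.
#' @inheritParams drug_cluster_score
#' @return data.frame: `drug_id`, `owner`, `cluster_id`, `similarity`, `p`.
#' @export
score_drugs <- function(net, drug_targets, clusters, owners, index,
                        n_null = 200L, seed = NULL, dmat = NULL,
                        direction = c("sym", "drug_to_disease"),
                        k_min = 10L) {
  direction <- match.arg(direction)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dmat)) dmat <- network_distance_matrix(net)
  penalty <- attr(dmat, "penalty")
  nodes <- rownames(dmat)
  on_net <- lapply(drug_targets, intersect, nodes)
  usable <- names(on_net)[lengths(on_net) > 0L]
  dropped <- setdiff(names(drug_targets), usable)
  if (length(dropped) > 0L) {
    message("skipping ", length(dropped), " drug(s) with no on-network target")
  }
  cl_net <- lapply(clusters, intersect, nodes)
  draw_idx <- function(genes) {
    t(vapply(seq_len(n_null), function(i) {
      match(degree_matched_sample(genes, index, k_min = k_min), nodes)
    }, integer(length(genes))))
  }
  drug_null <- lapply(on_net[usable], draw_idx)
  clust_null <- lapply(cl_net, draw_idx)
  rows <- vector("list", length(usable) * length(clusters))
  k <- 0L
  for (drug in usable) {
    ti <- match(on_net[[drug]], nodes)
    tn <- drug_null[[drug]]
    for (cid in names(clusters)) {
      ci_ <- match(cl_net[[cid]], nodes)
      cn <- clust_null[[cid]]
      s_obs <- 1 / (1 + ic_min_mean(dmat, ti, ci_, penalty, direction))
      null_s <- vapply(seq_len(n_null), function(i) {
        1 / (1 + ic_min_mean(dmat, tn[i, ], cn[i, ], penalty, direction))
      }, 0)
      k <- k + 1L
      rows[[k]] <- data.frame(
        drug_id = drug, owner = unname(owners[cid]), cluster_id = cid,
        similarity = s_obs, p = (sum(null_s >= s_obs) + 1) / (n_null + 1))
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  out
}

#' Normalize similarities, adjust p-values and call predicted treatments
#'
#' Within each disease: min-max normalizes the similarity to [0, 1] (a
#' single record, or all-equal similarities, normalizes to 1), applies
#' Benjamini-Hochberg to the empirical p-values across all of the disease's
#' drug-cluster records, keeps for each drug the record with the lowest FDR
#' (ties broken by higher normalized similarity, then cluster id), and
#' flags predicted treatments at `fdr < fdr_threshold`.
#'
#' @param preds Output of [score_drugs()] (any number of diseases).
#' @param fdr_threshold Prediction threshold (default 0.01).
#' @return data.frame: one row per (drug, disease) with
#'   `similarity_normalized`, `fdr`, `is_predicted` added.
#' @export
normalize_and_call <- function(preds, fdr_threshold = 0.01) {
  stopifnot(nrow(preds) >= 1L)
  out <- do.call(rbind, lapply(split(preds, preds$owner), function(d) {
    rng <- range(d$similarity)
    d$similarity_normalized <- if (diff(rng) == 0) {
      rep(1, nrow(d))
    } else {
      (d$similarity - rng[1]) / diff(rng)
    }
    d$fdr <- stats::p.adjust(d$p, method = "BH")
    # disease-level record per drug: lowest fdr wins
    d <- d[order(d$drug_id, d$fdr, -d$similarity_normalized, d$cluster_id), ]
    d[!duplicated(d$drug_id), ]
  }))
  out$is_predicted <- out$fdr < fdr_threshold
  rownames(out) <- NULL
  out
}
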