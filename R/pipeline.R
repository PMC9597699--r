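#' Run the CI-signature pipeline over the owners of a scenario
#'
#' End-to-end orchestration of the analysis on in-memory inputs: (1) expand
#' the CI seed set with a network-feature model (negatives drawn from the
#' non-overlapping annotation sets); (2) per owner (disease or trait):
#' select negatives, train the expansion model, optionally cross-validate
#' and record the qualification gate (>= `min_genes` on-network seeds and
#' median log2(auPRC/prior) >= 1), expand the seeds, induce the owner's
#' subnetwork, Leiden-partition it and keep clusters of at least
#' `min_cluster_size` genes; (3) score every kept cluster's CI enrichment
#' against a degree-matched permutation null of `n_lists` random lists, BH-
#' adjust within the owner and call CI-enriched clusters (FDR < 0.05,
#' E > 0). Owners whose random lists produce no qualifying cluster are
#' marked excluded.
#'
#' Owners with no qualifying cluster of their own skip the (expensive) null
#' ensemble: they can have no enrichment result either way.
#'
#' @param scenario A `ci_scenario` from [generate_scenario()], or a list
#'   with the same fields built from files.
#' @param owners Character vector of owner names; default all disease and
#'   trait sets.
#' @param n_lists Random lists per owner for the permutation null
#'   (default 5000).
#' @param expand_threshold Expansion probability threshold (default 0.80).
#' @param reg Regularization strength of the expansion models.
#' @param compute_cv Run 3-fold cross-validation per owner (default TRUE).
#' @param k CV folds.
#' @param min_cluster_size Cluster size filter (default 5).
#' @param leiden_iterations Leiden iterations for both the real and the
#'   null clustering (default -1: iterate to convergence, which matches the
#'   conventional 100-iteration setting on these subnetwork sizes while
#'   keeping the 5,000-list nulls tractable).
#' @param k_min Degree-match pool width (default 10).
#' @param pseudo_count Use the +1-corrected permutation p (default FALSE:
#'   the published form).
#' @param enforce_qualification Drop owners failing the qualification gate
#'   before clustering (default FALSE: the gate is recorded per owner but
#'   all owners are analysed).
#' @param expand_ci Expand the CI seed set before scoring (default TRUE).
#' @param fdr_threshold Cluster call threshold (default 0.05).
#' @param seed Integer seed for the whole run.
#' @return Object of class `ci_pipeline`: `network`, `degree_index`,
#'   `ci_genes` (expanded), `ci_model`, and `owners`, a named list with per
#'   owner: `seeds`, `cv`, `qualified`, `expanded`, `n_predicted`,
#'   `clusters` (size-filtered), `enrichment` (data.frame), `excluded`.
#' @export
run_ci_pipeline <- function(scenario, owners = NULL, n_lists = 5000L,
                            expand_threshold = 0.80, reg = 1,
                            compute_cv = TRUE, k = 3L,
                            min_cluster_size = 5L, leiden_iterations = -1L,
                            k_min = 10L, pseudo_count = FALSE,
                            enforce_qualification = FALSE,
                            expand_ci = TRUE, fdr_threshold = 0.05,
                            seed = 1L) {
  net <- scenario$network
  index <- scenario$degree_index
  if (is.null(index)) index <- build_degree_index(net)
  annotations <- scenario$all_disease_annotations
  all_seed_sets <- c(scenario$disease_seeds, scenario$trait_seeds)
  if (is.null(owners)) owners <- names(all_seed_sets)
  set.seed(seed)

  ci_model <- NULL
  ci_genes <- intersect(scenario$ci_genes, igraph::V(net)$name)
  if (expand_ci) {
    ci_neg <- select_negatives(scenario$ci_genes, annotations, net)
    ci_model <- train_expansion_model(net, scenario$ci_genes, ci_neg,
                                      reg = reg, seed = seed)
    ci_genes <- intersect(
      expand_gene_set(ci_model, net, scenario$ci_genes,
                      threshold = expand_threshold),
      igraph::V(net)$name)
  }

  res <- vector("list", length(owners))
  names(res) <- owners
  for (ow in owners) {
    seeds <- all_seed_sets[[ow]]
    if (is.null(seeds)) stop("unknown owner: ", ow)
    negatives <- select_negatives(seeds, annotations, net)
    model <- train_expansion_model(net, seeds, negatives, reg = reg,
                                   seed = seed)
    cv <- NULL
    qualified <- NA
    if (compute_cv) {
      cv <- cross_validate(net, seeds, negatives, k = k, reg = reg,
                           seed = seed)
      qualified <- qualify_gene_set(seeds, cv, net)
    }
    if (enforce_qualification && isFALSE(qualified)) {
      res[[ow]] <- list(seeds = seeds, cv = cv, qualified = FALSE,
                        expanded = NULL, n_predicted = NA_integer_,
                        clusters = list(),
                        enrichment = empty_enrichment(ow),
                        excluded = TRUE, excluded_reason = "qualification")
      next
    }
    expanded <- expand_gene_set(model, net, seeds,
                                threshold = expand_threshold)
    on_net <- intersect(expanded, igraph::V(net)$name)
    sg <- induce_subgraph(net, on_net)
    clusters <- filter_clusters(
      partition_leiden(sg, iterations = leiden_iterations),
      min_size = min_cluster_size)
    if (length(clusters) == 0L) {
      res[[ow]] <- list(seeds = seeds, cv = cv, qualified = qualified,
                        expanded = expanded,
                        n_predicted = length(attr(expanded, "predicted")),
                        clusters = list(),
                        enrichment = empty_enrichment(ow),
                        excluded = FALSE)
      next
    }
    null_ens <- build_null_ensemble(on_net, net, index, ci_genes,
                                    n_lists = n_lists,
                                    min_size = min_cluster_size,
                                    iterations = leiden_iterations,
                                    k_min = k_min)
    if (null_ens$n_random_clusters == 0L) {
      message("owner ", ow, " excluded: no qualifying null clusters")
      res[[ow]] <- list(seeds = seeds, cv = cv, qualified = qualified,
                        expanded = expanded,
                        n_predicted = length(attr(expanded, "predicted")),
                        clusters = clusters,
                        enrichment = empty_enrichment(ow),
                        excluded = TRUE, excluded_reason = "empty null")
      next
    }
    enr <- ci_enrichment(clusters, null_ens, ci_genes, net, owner = ow,
                         pseudo_count = pseudo_count,
                         fdr_threshold = fdr_threshold)
    res[[ow]] <- list(seeds = seeds, cv = cv, qualified = qualified,
                      expanded = expanded,
                      n_predicted = length(attr(expanded, "predicted")),
                      clusters = clusters, enrichment = enr,
                      excluded = FALSE)
  }
  structure(list(network = net, degree_index = index,
                 ci_genes = ci_genes, ci_model = ci_model,
                 owners = res, seed = seed),
            class = "ci_pipeline")
}

empty_enrichment <- function(owner) {
  data.frame(owner = character(0), cluster_id = character(0),
             size = integer(0), E = numeric(0), p = numeric(0),
             fdr = numeric(0), is_ci_enriched = logical(0),
             n_null_clusters = integer(0))
}

#' @export
print.ci_pipeline <- function(x, ...) {
  s <- summary(x)
  cat("CI-signature pipeline:", nrow(s), "owners;",
      sum(s$any_ci_enriched), "with >=1 CI-enriched cluster\n")
  invisible(x)
}

#' Per-owner summary of a pipeline run
#'
#' @param object A `ci_pipeline`.
#' @param ... Unused.
#' @return data.frame: `owner`, `qualified`, `n_expanded`, `n_clusters`,
#'   `n_ci_enriched`, `any_ci_enriched`, `excluded`.
#' @export
summary.ci_pipeline <- function(object, ...) {
  rows <- lapply(names(object$owners), function(ow) {
    r <- object$owners[[ow]]
    data.frame(owner = ow,
               qualified = if (is.null(r$cv)) NA else r$qualified,
               n_expanded = if (is.null(r$expanded)) NA_integer_
                            else length(r$expanded),
               n_clusters = length(r$clusters),
               n_ci_enriched = sum(r$enrichment$is_ci_enriched),
               any_ci_enriched = any(r$enrichment$is_ci_enriched),
               excluded = isTRUE(r$excluded))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Collect the CI-enriched clusters of a pipeline run
#'
#' @param pipeline A `ci_pipeline`.
#' @return Named list of cluster gene vectors (names `"owner.cluster_id"`),
#'   with an `"owners"` attribute mapping cluster name -> owner.
#' @export
ci_enriched_clusters <- function(pipeline) {
  out <- list()
  owners <- character(0)
  for (ow in names(pipeline$owners)) {
    r <- pipeline$owners[[ow]]
    enr_ids <- r$enrichment$cluster_id[r$enrichment$is_ci_enriched]
    for (cid in enr_ids) {
      nm <- paste(ow, cid, sep = ".")
      out[[nm]] <- r$clusters[[cid]]
      owners[nm] <- ow
    }
  }
  attr(out, "owners") <- owners
  out
}

#' Predict treatments against the CI-enriched clusters of a pipeline run
#'
#' Scores every drug against every CI-enriched cluster by network proximity
#' with the empirical degree/size-matched null ([score_drugs()]), then
#' normalizes, BH-adjusts within disease, assigns each drug to its
#' lowest-FDR cluster and calls predictions ([normalize_and_call()]).
#'
#' @param pipeline A `ci_pipeline`.
#' @param drug_targets Named list drug -> target genes (e.g.
#'   `scenario$drugs$targets`).
#' @param n_null Null pairs per drug-cluster score (default 200).
#' @param fdr_threshold Prediction threshold (default 0.01).
#' @param direction Proximity direction, see [drug_cluster_score()].
#' @param seed Integer seed.
#' @param dmat Optional precomputed [network_distance_matrix()].
#' @return List with `scores` (all drug-cluster records) and `calls`
#'   (disease-level records from [normalize_and_call()]).
#' @export
predict_treatments <- function(pipeline, drug_targets, n_null = 200L,
                               fdr_threshold = 0.01,
                               direction = c("sym", "drug_to_disease"),
                               seed = 1L, dmat = NULL) {
  direction <- match.arg(direction)
  clusters <- ci_enriched_clusters(pipeline)
  if (length(clusters) == 0L) stop("pipeline has no CI-enriched clusters")
  if (is.null(dmat)) dmat <- network_distance_matrix(pipeline$network)
  scores <- score_drugs(pipeline$network, drug_targets, clusters,
                        attr(clusters, "owners"), pipeline$degree_index,
                        n_null = n_null, seed = seed, dmat = dmat,
                        direction = direction)
  list(scores = scores,
       calls = normalize_and_call(scores, fdr_threshold = fdr_threshold))
}
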