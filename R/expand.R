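#' Deduplicate overlapping gene sets
#'
#' Builds a graph over the sets with an edge wherever the overlap
#' coefficient |A n B| / min(|A|, |B|) reaches `threshold`, and keeps one
#' representative per connected component: the largest set, ties broken by
#' the lexicographically smallest id. Mirrors the curation step that keeps
#' disease annotation sets largely non-redundant before modelling.
#'
#' @param sets Named list of character vectors (at least one).
#' @param threshold Overlap coefficient threshold in (0, 1]; default 0.6.
#' @return The representative subset of `sets`, in original order.
#' @export
dedup_gene_sets <- function(sets, threshold = 0.6) {
  stopifnot(length(sets) >= 1L, threshold > 0, threshold <= 1)
  if (any(lengths(sets) == 0L)) {
    stop("gene set with 0 genes: overlap coefficient undefined")
  }
  m <- length(sets)
  # union-find over sets
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (m > 1L) {
    for (i in 1:(m - 1L)) {
      for (j in (i + 1L):m) {
        ov <- length(intersect(sets[[i]], sets[[j]])) /
          min(length(sets[[i]]), length(sets[[j]]))
        if (ov >= threshold) parent[find(j)] <- find(i)
      }
    }
  }
  comp <- vapply(seq_len(m), find, 1L)
  reps <- vapply(split(seq_len(m), comp), function(members) {
    sz <- lengths(sets[members])
    best <- members[sz == max(sz)]
    best[order(names(sets)[best])][1]
  }, 1L)
  sets[sort(unname(reps))]
}

#' Select negative example genes for the expansion model
#'
#' Negatives are the union of all annotation sets, minus the seed genes,
#' minus every gene of any annotation set whose overlap with the seeds is
#' significant (one-sided Fisher's exact test, p < 0.05, with the network
#' node set as universe). All sets are restricted to network nodes first.
#'
#' @param seeds Character vector of seed (positive) genes.
#' @param annotations Named list of character vectors (the full annotation
#'   collection, e.g. all disease gene sets).
#' @param net The interactome; its node set is the statistical universe.
#' @param p_cutoff Exclusion threshold for the overlap test (default 0.05).
#' @return Character vector of negative genes.
#' @export
select_negatives <- function(seeds, annotations, net, p_cutoff = 0.05) {
  stopifnot(length(seeds) > 0L, length(annotations) > 0L)
  nodes <- igraph::V(net)$name
  seeds_n <- intersect(seeds, nodes)
  universe <- length(nodes)
  excluded <- character(0)
  for (ann in annotations) {
    ann_n <- intersect(ann, nodes)
    if (length(ann_n) == 0L) next
    ov <- length(intersect(ann_n, seeds_n))
    p <- hyper_p(ov, length(ann_n), universe, length(seeds_n))
    if (p < p_cutoff) excluded <- c(excluded, ann_n)
  }
  pool <- intersect(unique(unlist(annotations, use.names = FALSE)), nodes)
  negatives <- setdiff(pool, c(seeds_n, excluded))
  if (length(negatives) == 0L) {
    stop("no negative genes remain after overlap-based exclusion; ",
         "supply more (non-overlapping) annotation sets")
  }
  negatives
}

training_matrix <- function(net, use_weights = TRUE) {
  has_w <- use_weights && "weight" %in% igraph::edge_attr_names(net)
  igraph::as_adjacency_matrix(net, sparse = TRUE,
                              attr = if (has_w) "weight" else NULL)
}

#' Train a network-feature expansion model
#'
#' Fits an L2-regularized (ridge) logistic regression where each training
#' gene's feature vector is its adjacency row in the interactome (weighted
#' if the network carries weights). Features are standardized internally, so
#' the penalty is scale-free. The regularization strength is defined on the
#' summed log-likelihood: the glmnet penalty is `lambda = reg / n_train`.
#'
#' @param net The interactome.
#' @param positives,negatives Disjoint character vectors of training genes;
#'   each must retain at least 2 members on the network.
#' @param reg Regularization strength (> 0); default 1.
#' @param seed Integer seed (recorded; the fit itself is deterministic).
#' @param use_weights Use edge weights as feature values when present.
#' @return Object of class `expansion_model` with elements `fit` (glmnet),
#'   `feature_genes`, `lambda`, `reg`, `n_pos`, `n_neg`, `seed`.
#' @export
train_expansion_model <- function(net, positives, negatives, reg = 1,
                                  seed = 1L, use_weights = TRUE) {
  stopifnot(reg > 0)
  nodes <- igraph::V(net)$name
  pos <- sort(intersect(positives, nodes))
  neg <- sort(intersect(negatives, nodes))
  if (length(intersect(pos, neg)) > 0L) {
    stop("positives and negatives overlap")
  }
  if (length(pos) < 2L || length(neg) < 2L) {
    stop("need at least 2 on-network genes in each training class")
  }
  A <- training_matrix(net, use_weights)
  train <- c(pos, neg)
  y <- c(rep(1L, length(pos)), rep(0L, length(neg)))
  lambda <- reg / length(train)
  set.seed(seed)
  # a decreasing log-spaced path down to the target lambda keeps the
  # coordinate-descent warm starts stable; coefficients are read at `lambda`
  path <- exp(seq(log(lambda * 1000), log(lambda), length.out = 30))
  fit <- withCallingHandlers(
    glmnet::glmnet(A[train, , drop = FALSE], y, family = "binomial",
                   alpha = 0, lambda = path, standardize = TRUE),
    warning = function(w) {
      # small-class sizes are validated above; glmnet's advisory is noise here
      if (grepl("fewer than 8", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  structure(
    list(fit = fit, feature_genes = colnames(A), lambda = lambda,
         reg = reg, n_pos = length(pos), n_neg = length(neg), seed = seed,
         use_weights = use_weights),
    class = "expansion_model")
}

#' @export
print.expansion_model <- function(x, ...) {
  cat("network-feature expansion model:", length(x$feature_genes),
      "adjacency features;", x$n_pos, "positives,", x$n_neg,
      "negatives; reg =", x$reg, "\n")
  invisible(x)
}

#' Model coefficients on the feature-gene axis
#' @param object An `expansion_model`.
#' @param ... Unused.
#' @return Named numeric vector of per-feature-gene coefficients, with the
#'   intercept in attribute `"intercept"`.
#' @export
coef.expansion_model <- function(object, ...) {
  cf <- as.numeric(stats::coef(object$fit, s = object$lambda))
  out <- stats::setNames(cf[-1], object$feature_genes)
  attr(out, "intercept") <- cf[1]
  out
}

#' Predict gene association probabilities
#'
#' Scores genes by their adjacency rows in `net` (which must be the network
#' the model was trained on, or one with identical node naming).
#'
#' @param object An `expansion_model`.
#' @param net The interactome supplying adjacency features.
#' @param genes Genes to score; default all network genes.
#' @param ... Unused.
#' @return Named numeric vector of probabilities in `[0, 1]`.
#' @export
predict.expansion_model <- function(object, net, genes = NULL, ...) {
  A <- training_matrix(net, object$use_weights)
  if (!identical(colnames(A), object$feature_genes)) {
    A <- A[, object$feature_genes, drop = FALSE]
  }
  if (is.null(genes)) genes <- rownames(A)
  p <- stats::predict(object$fit, A[genes, , drop = FALSE],
                      type = "response", s = object$lambda)
  stats::setNames(as.numeric(p), genes)
}

#' Cross-validate an expansion model
#'
#' Stratified k-fold cross-validation; each fold's score is
#' log2(auPRC / prior) over the held-out genes, where auPRC is the average
#' precision and prior the held-out positive fraction. A score of 0 is
#' chance level; 1 means the model ranks positives twice as well as chance.
#'
#' @inheritParams train_expansion_model
#' @param k Number of folds (default 3); needs at least `k` genes per class.
#' @return Object of class `cv_report`: `fold_scores`, `median_score`,
#'   `n_positives`.
#' @export
cross_validate <- function(net, positives, negatives, k = 3L, reg = 1,
                           seed = 1L, use_weights = TRUE) {
  # sorted so fold assignment is invariant to the input gene order
  nodes <- igraph::V(net)$name
  pos <- sort(intersect(positives, nodes))
  neg <- sort(intersect(negatives, nodes))
  if (length(pos) < k || length(neg) < k) {
    stop("need at least k genes per class for stratified k-fold CV")
  }
  set.seed(seed)
  fold_pos <- sample(rep(seq_len(k), length.out = length(pos)))
  fold_neg <- sample(rep(seq_len(k), length.out = length(neg)))
  scores <- vapply(seq_len(k), function(f) {
    tr_pos <- pos[fold_pos != f]; te_pos <- pos[fold_pos == f]
    tr_neg <- neg[fold_neg != f]; te_neg <- neg[fold_neg == f]
    model <- train_expansion_model(net, tr_pos, tr_neg, reg = reg,
                                   seed = seed, use_weights = use_weights)
    held <- c(te_pos, te_neg)
    prob <- predict(model, net, genes = held)
    labels <- held %in% te_pos
    ap <- average_precision(prob, labels)
    prior <- length(te_pos) / length(held)
    log2(ap / prior)
  }, 0)
  structure(list(fold_scores = scores,
                 median_score = stats::median(scores),
                 n_positives = length(pos)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("cross-validation:", length(x$fold_scores), "folds; log2(auPRC/prior) =",
      paste(sprintf("%.2f", x$fold_scores), collapse = ", "),
      sprintf("(median %.2f)\n", x$median_score))
  invisible(x)
}

#' Decide whether a gene set qualifies for downstream analysis
#'
#' A set qualifies when it has at least `min_genes` genes on the network and
#' its cross-validated median log2(auPRC/prior) is at least `min_median`
#' (i.e. its genes are learnably coherent on the interactome).
#'
#' @param seeds Character vector of seed genes.
#' @param cv A `cv_report` from [cross_validate()].
#' @param net The interactome.
#' @param min_genes Minimum on-network seed count (default 15).
#' @param min_median Minimum median fold score (default 1).
#' @return Logical scalar.
#' @export
qualify_gene_set <- function(seeds, cv, net, min_genes = 15L,
                             min_median = 1) {
  n_on <- length(intersect(seeds, igraph::V(net)$name))
  n_on >= min_genes && cv$median_score >= min_median
}

#' Expand a seed gene set with model predictions
#'
#' Returns the union of the seeds with every network gene whose predicted
#' probability reaches `threshold`. Seed genes are always retained,
#' whatever their own scores.
#'
#' @param model An `expansion_model`.
#' @param net The interactome.
#' @param seeds Character vector of seed genes.
#' @param threshold Inclusion probability threshold (default 0.80).
#' @return Character vector: seeds plus predicted genes. The predicted
#'   (non-seed) genes are also available in attribute `"predicted"`.
#' @export
expand_gene_set <- function(model, net, seeds, threshold = 0.80) {
  prob <- predict(model, net)
  predicted <- setdiff(names(prob)[prob >= threshold], seeds)
  out <- c(seeds, predicted)
  attr(out, "predicted") <- predicted
  out
}
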