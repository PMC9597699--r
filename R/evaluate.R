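#' Ranked-retrieval quality of disease-level drug predictions
#'
#' Ranks a disease's drugs by -log10(FDR) (ties broken by normalized
#' similarity, then drug id) and scores the ranking against a set of known
#' positives with log2(auPRC / prior), where auPRC is the average precision
#' and prior the positive prevalence. 0 is chance level. Diseases with
#' fewer than `min_positives` positives among the ranked drugs are skipped
#' (returns `NULL` with a message), as are rankings with no negative.
#'
#' @param preds Disease-level predictions for one disease
#'   ([normalize_and_call()] rows): needs `drug_id`, `fdr`,
#'   `similarity_normalized`.
#' @param positives Character vector of positive drug ids.
#' @param min_positives Minimum positives required (default 5).
#' @return One-row data.frame (`auprc`, `prior`, `log2_auprc_over_prior`,
#'   `n_positives`, `n_drugs`) or `NULL`.
#' @export
ranked_retrieval <- function(preds, positives, min_positives = 5L) {
  labels <- preds$drug_id %in% positives
  if (sum(labels) < min_positives) {
    message("skipping ranked retrieval: fewer than ", min_positives,
            " positives among ranked drugs")
    return(NULL)
  }
  if (all(labels)) {
    message("skipping ranked retrieval: no negative among ranked drugs")
    return(NULL)
  }
  ord <- order(-(-log10(preds$fdr)), -preds$similarity_normalized,
               preds$drug_id)
  y <- labels[ord]
  ap <- average_precision(rev(seq_along(y)), y)  # rank order as score
  prior <- mean(labels)
  data.frame(auprc = ap, prior = prior,
             log2_auprc_over_prior = log2(ap / prior),
             n_positives = sum(labels), n_drugs = length(labels))
}

#' Enrichment of predicted drugs among previously indicated drugs
#'
#' One-sided (greater) Fisher's exact test on the 2x2 table of
#' indicated-vs-not by predicted-vs-not, over the universe of `all_drugs`
#' drugs with curated targets.
#'
#' @param all_drugs Total number of drugs.
#' @param indicated Number of those indicated for the disease of interest.
#' @param predicted Number predicted to treat the disease.
#' @param predicted_and_indicated Overlap of the last two.
#' @return One-sided Fisher p-value.
#' @export
indication_enrichment <- function(all_drugs, indicated, predicted,
                                  predicted_and_indicated) {
  if (predicted_and_indicated > min(indicated, predicted) ||
      indicated > all_drugs || predicted > all_drugs ||
      predicted + indicated - predicted_and_indicated > all_drugs) {
    stop("inconsistent contingency counts")
  }
  tab <- matrix(c(predicted_and_indicated,
                  indicated - predicted_and_indicated,
                  predicted - predicted_and_indicated,
                  all_drugs - indicated - predicted +
                    predicted_and_indicated), 2, 2)
  stats::fisher.test(tab, alternative = "greater")$p.value
}

#' Indication enrichment across diseases with BH adjustment
#'
#' @param counts data.frame with one row per disease and columns
#'   `disease_id`, `all_drugs`, `indicated`, `predicted`,
#'   `predicted_and_indicated`.
#' @return The input with `p` and `fdr` columns added.
#' @export
indication_enrichment_table <- function(counts) {
  counts$p <- mapply(indication_enrichment, counts$all_drugs,
                     counts$indicated, counts$predicted,
                     counts$predicted_and_indicated)
  counts$fdr <- stats::p.adjust(counts$p, method = "BH")
  counts
}

# weighted Kolmogorov-Smirnov running-sum enrichment score for member
# positions `hits` (logical over the ranked list) with weights |score|.
gsea_es <- function(scores, hits) {
  w <- abs(scores[hits])
  if (sum(w) == 0) w <- w + 1  # all-zero weights: fall back to equal steps
  n_miss <- sum(!hits)
  run <- numeric(length(scores))
  run[hits] <- w / sum(w)
  run[!hits] <- -1 / n_miss
  cs <- cumsum(run)
  cs[which.max(abs(cs))]
}

#' Preranked set enrichment of a drug class
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment score (weights
#' |score|, exponent 1) of a drug class within a ranked drug list, with a
#' permutation p-value over random placements of the class members. The
#' p-value is one-sided in the direction of the observed score. Classes
#' with fewer than 2 members in the ranking, or spanning the whole ranking,
#' are skipped (`NULL` with a message). When the number of distinct
#' placements is at most `n_perm` the null is enumerated exhaustively.
#'
#' @param ranked_drugs data.frame with `drug_id` and `score`
#'   (e.g. -log10(FDR)), already ordered by decreasing score.
#' @param class_members Character vector of drug ids in the class.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed, or `NULL` to consume the current stream.
#' @return One-row data.frame (`es`, `p`, `n_members`, `exhaustive`) or
#'   `NULL`.
#' @export
drug_class_gsea <- function(ranked_drugs, class_members, n_perm = 10000L,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hits <- ranked_drugs$drug_id %in% class_members
  n <- length(hits); k <- sum(hits)
  if (k < 2L) {
    message("skipping class: fewer than 2 members in the ranking")
    return(NULL)
  }
  if (k == n) {
    message("skipping class spanning every ranked drug")
    return(NULL)
  }
  scores <- ranked_drugs$score
  if (any(!is.finite(scores))) stop("ranking scores must be finite")
  es_obs <- gsea_es(scores, hits)
  n_comb <- choose(n, k)
  exhaustive <- is.finite(n_comb) && n_comb <= n_perm
  if (exhaustive) {
    placements <- utils::combn(n, k)
    es_null <- vapply(seq_len(ncol(placements)), function(j) {
      h <- logical(n); h[placements[, j]] <- TRUE
      gsea_es(scores, h)
    }, 0)
    p <- if (es_obs >= 0) mean(es_null >= es_obs) else mean(es_null <= es_obs)
  } else {
    es_null <- vapply(seq_len(n_perm), function(j) {
      h <- logical(n); h[sample.int(n, k)] <- TRUE
      gsea_es(scores, h)
    }, 0)
    p <- if (es_obs >= 0) {
      (sum(es_null >= es_obs) + 1) / (n_perm + 1)
    } else {
      (sum(es_null <= es_obs) + 1) / (n_perm + 1)
    }
  }
  data.frame(es = es_obs, p = p, n_members = k, exhaustive = exhaustive)
}

#' Drug-class enrichment across classes within one disease
#'
#' Ranks the disease's predicted drugs by -log10(FDR) and runs
#' [drug_class_gsea()] for every class, Benjamini-Hochberg-adjusting across
#' classes.
#'
#' @param preds Disease-level predictions for one disease
#'   ([normalize_and_call()] rows).
#' @param classes Named list class -> character vector of drug ids.
#' @param n_perm,seed Passed to [drug_class_gsea()].
#' @return data.frame with `class`, `es`, `p`, `adjusted_p`, `n_members`.
#' @export
drug_class_gsea_table <- function(preds, classes, n_perm = 10000L,
                                  seed = 1L) {
  set.seed(seed)
  ranked <- preds[order(-(-log10(preds$fdr)), -preds$similarity_normalized,
                        preds$drug_id), ]
  ranked <- data.frame(drug_id = ranked$drug_id,
                       score = -log10(pmax(ranked$fdr, 1e-300)))
  rows <- lapply(names(classes), function(cl) {
    r <- drug_class_gsea(ranked, classes[[cl]], n_perm = n_perm, seed = NULL)
    if (is.null(r)) return(NULL)
    cbind(data.frame(class = cl), r)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(class = character(0), es = numeric(0), p = numeric(0),
                      adjusted_p = numeric(0), n_members = integer(0)))
  }
  out$adjusted_p <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
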