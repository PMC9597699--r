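test_that("average precision matches a quadratic oracle and its bounds", {
  # O(n^2) oracle: precision at each positive computed by explicit counting
  ap_oracle <- function(scores, labels) {
    ord <- order(scores, decreasing = TRUE)
    y <- labels[ord]
    vals <- vapply(which(y), function(i) sum(y[1:i]) / i, 0)
    mean(vals)
  }
  set.seed(17)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    scores <- stats::rnorm(n)
    labels <- stats::runif(n) < 0.4
    if (!any(labels)) labels[1] <- TRUE
    expect_equal(average_precision(scores, labels),
                 ap_oracle(scores, labels), tolerance = 1e-12)
  }
  # equals 1 iff all positives precede all negatives
  expect_equal(average_precision(10:1, c(TRUE, TRUE, rep(FALSE, 8))), 1)
  expect_lt(average_precision(10:1, c(TRUE, FALSE, TRUE, rep(FALSE, 7))), 1)
})

test_that("ranked retrieval scores follow log2(auPRC/prior)", {
  preds <- data.frame(drug_id = sprintf("d%02d", 1:10),
                      fdr = seq(0.001, 0.9, length.out = 10),
                      similarity_normalized = seq(1, 0, length.out = 10))
  # perfect ranking at prior 0.5
  r <- ranked_retrieval(preds, positives = sprintf("d%02d", 1:5),
                        min_positives = 5)
  expect_equal(r$log2_auprc_over_prior, 1)
  expect_equal(r$prior, 0.5)

  # one positive ranked last: auPRC = prior = 0.1, score exactly 0
  r2 <- ranked_retrieval(preds, positives = "d10", min_positives = 1)
  expect_equal(r2$auprc, 0.1)
  expect_equal(r2$log2_auprc_over_prior, 0)

  expect_message(expect_null(
    ranked_retrieval(preds, positives = "d10", min_positives = 5)),
    "fewer than 5")
  expect_message(expect_null(
    ranked_retrieval(preds, positives = preds$drug_id, min_positives = 1)),
    "no negative")
})

test_that("random rankings score near zero on average", {
  # exact enumeration oracle for 6 drugs, 3 positives
  n <- 6; k <- 3
  placements <- utils::combn(n, k)
  exact <- mean(vapply(seq_len(ncol(placements)), function(j) {
    y <- logical(n); y[placements[, j]] <- TRUE
    log2(average_precision(n:1, y) / (k / n))
  }, 0))
  # Monte-Carlo over 1000 shuffles agrees with the enumeration within 3 SE
  set.seed(23)
  mc <- vapply(1:1000, function(i) {
    y <- logical(n); y[sample.int(n, k)] <- TRUE
    log2(average_precision(n:1, y) / (k / n))
  }, 0)
  se <- stats::sd(mc) / sqrt(length(mc))
  expect_lt(abs(mean(mc) - exact), 3 * se)
  expect_lt(abs(exact), 0.5)  # log2 concavity pulls it slightly below 0
})

test_that("indication enrichment matches the hypergeometric oracle", {
  # all 10 predicted are the 10 indicated among 100 drugs
  expect_equal(indication_enrichment(100, 10, 10, 10),
               1 / choose(100, 10), tolerance = 1e-9)
  expect_equal(indication_enrichment(50, 10, 5, 0), 1)
  expect_equal(indication_enrichment(50, 10, 0, 0), 1)
  expect_error(indication_enrichment(50, 3, 4, 4), "inconsistent")

  # exhaustive-summation oracle for small totals
  enum_p <- function(N, K, n, ov) {
    ks <- max(0, n + K - N):min(K, n)
    probs <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
    sum(probs[ks >= ov])
  }
  set.seed(31)
  for (i in 1:20) {
    N <- sample(10:60, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    ov <- sample(max(0, n + K - N):min(K, n), 1)
    expect_equal(indication_enrichment(N, K, n, ov), enum_p(N, K, n, ov),
                 tolerance = 1e-10)
  }

  tab <- indication_enrichment_table(data.frame(
    disease_id = c("a", "b"), all_drugs = 50, indicated = c(10, 5),
    predicted = c(8, 8), predicted_and_indicated = c(6, 0)))
  expect_equal(tab$fdr, stats::p.adjust(tab$p, "BH"))
})

test_that("the running-sum enrichment score behaves like preranked GSEA", {
  ranked <- data.frame(drug_id = sprintf("d%d", 1:8),
                       score = c(5, 4, 3, 2.5, 2, 1.5, 1, 0.5))
  # class at the very top: positive and maximal among achievable ES
  top <- drug_class_gsea(ranked, c("d1", "d2"), n_perm = 100, seed = 1)
  expect_gt(top$es, 0)
  placements <- utils::combn(8, 2)
  all_es <- vapply(seq_len(ncol(placements)), function(j) {
    drug_class_gsea(ranked, ranked$drug_id[placements[, j]],
                    n_perm = 100, seed = 1)$es
  }, 0)
  expect_equal(top$es, max(all_es))

  # sign flips when the ranking is reversed
  rev_ranked <- ranked[8:1, ]
  rev_ranked$score <- ranked$score
  bottom <- drug_class_gsea(rev_ranked, c("d1", "d2"), n_perm = 100, seed = 1)
  expect_lt(bottom$es, 0)

  expect_message(expect_null(
    drug_class_gsea(ranked, ranked$drug_id, n_perm = 10)), "spanning")
  expect_message(expect_null(
    drug_class_gsea(ranked, "d1", n_perm = 10)), "fewer than 2")
})

test_that("the ES agrees with fgsea's statistic", {
  skip_if_not_installed("fgsea")
  set.seed(41)
  for (i in 1:10) {
    n <- 12
    scores <- sort(stats::rnorm(n, 2, 1), decreasing = TRUE)
    hits <- sort(sample.int(n, 3))
    mine <- gsea_es(scores, seq_len(n) %in% hits)
    ref <- fgsea::calcGseaStat(scores, selectedStats = hits,
                               gseaParam = 1, scoreType = "std")
    expect_equal(mine, ref, tolerance = 1e-8)
  }
})

test_that("permutation p matches exhaustive enumeration for 8 drugs, 2 members", {
  ranked <- data.frame(drug_id = sprintf("d%d", 1:8),
                       score = c(5, 4, 3, 2.5, 2, 1.5, 1, 0.5))
  members <- c("d1", "d3")
  # exhaustive path (C(8,2) = 28 <= n_perm)
  exact <- drug_class_gsea(ranked, members, n_perm = 100, seed = 1)
  expect_true(exact$exhaustive)
  # sampled path, forced by a small n_perm
  sam <- drug_class_gsea(ranked, members, n_perm = 25, seed = 3)
  expect_false(sam$exhaustive)
  se <- sqrt(exact$p * (1 - exact$p) / 25)
  expect_lt(abs(sam$p - exact$p), 3 * se + 2 / 25)

  tab <- drug_class_gsea_table(
    data.frame(drug_id = ranked$drug_id, fdr = 10^(-ranked$score),
               similarity_normalized = 1, owner = "z"),
    classes = list(top = c("d1", "d2"), spread = c("d2", "d7")),
    n_perm = 200, seed = 2)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$adjusted_p, stats::p.adjust(tab$p, "BH"))
})
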