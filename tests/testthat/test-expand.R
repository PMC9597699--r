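test_that("gene-set dedup keeps one representative per overlap component", {
  A <- sprintf("g%d", 1:5); B <- sprintf("g%d", 1:3)
  # overlap coefficient 3/3 = 1 >= 0.6: one component, largest set wins
  out <- dedup_gene_sets(list(A = A, B = B))
  expect_identical(names(out), "A")

  out2 <- dedup_gene_sets(list(A = c("g1", "g2"), B = c("g8", "g9")))
  expect_identical(names(out2), c("A", "B"))

  # chain A~B, B~C with A,C disjoint: connectivity is transitive
  sets <- list(A = sprintf("g%d", 1:5), B = c("g4", "g5", "g6"), C = "g6")
  # brute-force component oracle on the 3-node overlap graph
  ov <- function(x, y) length(intersect(x, y)) / min(length(x), length(y))
  adj <- outer(seq_along(sets), seq_along(sets),
               Vectorize(function(i, j) i != j && ov(sets[[i]], sets[[j]]) >= 0.6))
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(adj, "undirected"))
  expect_equal(comp$no, 1)
  out3 <- dedup_gene_sets(sets, threshold = 0.6)
  expect_length(out3, 1)
  expect_identical(names(out3), "A")  # ties at size 3 break to smallest id

  expect_error(dedup_gene_sets(list(A = character(0))), "0 genes")
})

test_that("negative selection excludes significantly overlapping annotation sets", {
  set.seed(8)
  g <- igraph::sample_gnp(1000, 0.01)
  igraph::V(g)$name <- sprintf("v%04d", 1:1000)
  nodes <- igraph::V(g)$name
  seeds <- nodes[1:10]
  far <- nodes[501:540]

  # disjoint annotation with hypergeometric-oracle p >= 0.05 is retained
  p_far <- sum(stats::dhyper(0:0, 40, 960, 10) * 0) +
    stats::phyper(-1, 40, 960, 10, lower.tail = FALSE)
  expect_gte(p_far, 0.05)
  negs <- select_negatives(seeds, list(other = far), g)
  expect_setequal(negs, far)

  # 8 of 10 seed genes shared: oracle tail p < 0.05, the whole set excluded
  overlapping <- c(seeds[1:8], nodes[900:910])
  p_oracle <- sum(stats::dhyper(8:10, length(overlapping), 1000 - length(overlapping), 10))
  expect_lt(p_oracle, 0.05)
  negs2 <- select_negatives(seeds, list(bad = overlapping, other = far), g)
  expect_setequal(negs2, far)

  expect_error(select_negatives(seeds, list(self = seeds), g),
               "no negative genes")
})

test_that("expansion model separates planted classes and honors symmetry", {
  net <- two_clique_net(10)
  pos_train <- sprintf("p%02d", 1:9)
  neg_train <- sprintf("n%02d", 1:9)
  m <- train_expansion_model(net, pos_train, neg_train, reg = 1, seed = 1)
  pr <- predict(m, net, genes = c("p10", "n10"))
  expect_gt(pr[["p10"]], pr[["n10"]])

  # genes with identical adjacency rows score identically: held-out clique
  # members p10 and p09 differ only by self-row position symmetry
  pr2 <- predict(m, net, genes = c("p10"))
  expect_true(all(pr2 >= 0 & pr2 <= 1))
  # two leaves of a star have identical adjacency rows
  st <- star_graph("h", sprintf("l%d", 1:6))
  ms <- train_expansion_model(st, c("l1", "l2"), c("l3", "h"), reg = 1, seed = 1)
  prs <- predict(ms, st, genes = c("l5", "l6"))
  expect_equal(unname(prs[1]), unname(prs[2]), tolerance = 1e-10)
})

test_that("stronger regularization shrinks the coefficient norm", {
  net <- two_clique_net(10)
  m1 <- train_expansion_model(net, sprintf("p%02d", 1:9),
                              sprintf("n%02d", 1:9), reg = 1, seed = 1)
  m2 <- train_expansion_model(net, sprintf("p%02d", 1:9),
                              sprintf("n%02d", 1:9), reg = 2, seed = 1)
  n1 <- sqrt(sum(coef(m1)^2)); n2 <- sqrt(sum(coef(m2)^2))
  expect_lt(n2, n1)
})

test_that("training validates its inputs", {
  net <- two_clique_net(5)
  expect_error(train_expansion_model(net, c("p01", "p02"), c("p02", "n01")),
               "overlap")
  expect_error(train_expansion_model(net, "p01", c("n01", "n02")),
               "at least 2")
})

test_that("cross-validation scores perfect separation above chance", {
  net <- two_clique_net(12)
  cv <- cross_validate(net, sprintf("p%02d", 1:12), sprintf("n%02d", 1:12),
                       k = 3, reg = 1, seed = 2)
  expect_length(cv$fold_scores, 3)
  expect_true(all(cv$fold_scores > 0))
  expect_equal(cv$median_score, median(cv$fold_scores))

  # worst ranking: all positives last gives a negative score
  ap_worst <- average_precision(10:1, c(rep(FALSE, 5), rep(TRUE, 5)))
  expect_lt(log2(ap_worst / 0.5), 0)
  # perfect ranking at prior 0.5 gives exactly log2(1/0.5) = 1
  ap_best <- average_precision(10:1, c(rep(TRUE, 5), rep(FALSE, 5)))
  expect_equal(log2(ap_best / 0.5), 1)
})

test_that("cv fold scores ignore the input gene order", {
  net <- two_clique_net(12)
  pos <- sprintf("p%02d", 1:12); neg <- sprintf("n%02d", 1:12)
  cv1 <- cross_validate(net, pos, neg, k = 3, reg = 1, seed = 7)
  cv2 <- cross_validate(net, rev(pos), sample(neg), k = 3, reg = 1, seed = 7)
  expect_equal(cv1$fold_scores, cv2$fold_scores)
})

test_that("the qualification gate applies both thresholds inclusively", {
  net <- clique_graph(sprintf("g%02d", 1:25))
  cv_of <- function(m) structure(list(fold_scores = m, median_score = median(m),
                                      n_positives = 10), class = "cv_report")
  expect_false(qualify_gene_set(sprintf("g%02d", 1:14), cv_of(c(2, 2, 2)), net))
  expect_false(qualify_gene_set(sprintf("g%02d", 1:20), cv_of(c(0.99, 0.99, 0.99)), net))
  expect_true(qualify_gene_set(sprintf("g%02d", 1:15), cv_of(c(1, 1, 1)), net))
})

test_that("expansion respects the probability threshold and retains seeds", {
  net <- path_graph(c("a", "b", "c", "d", "e"))
  m <- stub_model(c(a = 0.1, b = 0.79, c = 0.80, d = 0.95, e = 0.2))
  out <- expand_gene_set(m, net, seeds = "a", threshold = 0.80)
  expect_setequal(out, c("a", "c", "d"))  # 0.79 out, 0.80 in, seed kept
  expect_setequal(attr(out, "predicted"), c("c", "d"))

  none <- expand_gene_set(m, net, seeds = "a", threshold = 1.01)
  expect_identical(unclass(none)[seq_along(none)], "a")

  # monotone in threshold: lower threshold gives a superset
  lo <- expand_gene_set(m, net, seeds = "a", threshold = 0.5)
  expect_true(all(out %in% lo))
})
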