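test_that("degree-matched sampling is forced on unique degrees", {
  p3 <- path_graph(c("a", "b", "c"))
  idx <- build_degree_index(p3)
  set.seed(1)
  expect_identical(degree_matched_sample("b", idx, k_min = 1), "b")

  st <- star_graph("h", sprintf("l%d", 1:5))
  idx_st <- build_degree_index(st)
  expect_identical(degree_matched_sample("h", idx_st, k_min = 1), "h")
  expect_error(degree_matched_sample("zz", idx_st), "not in the network")
})

test_that("degree-matched sampling preserves degree and is uniform in its bucket", {
  # complete bipartite K(2,8): hubs of degree 8, leaves of degree 2
  hubs <- c("h1", "h2"); leaves <- sprintf("l%d", 1:8)
  g <- make_net(as.vector(rbind(rep(hubs, each = 8), rep(leaves, 2))))
  idx <- build_degree_index(g)
  set.seed(2)
  draws <- vapply(1:10000, function(i) {
    degree_matched_sample("l1", idx, k_min = 2)
  }, "")
  expect_true(all(idx$degree_of[draws] == 2))  # degree preserved exactly
  counts <- table(factor(draws, levels = leaves))
  expected <- 10000 / 8
  se <- sqrt(10000 * (1 / 8) * (7 / 8))
  expect_true(all(abs(counts - expected) <= 3 * se))

  # drawing a whole degree class returns it intact (distinctness resolution)
  out <- degree_matched_sample(leaves, idx, k_min = 2)
  expect_setequal(out, leaves)
})

test_that("the enrichment score follows its closed form", {
  cg <- sprintf("g%d", 1:10)
  ci <- c(sprintf("g%d", 1:4), sprintf("c%d", 1:46))
  expect_equal(enrichment_score(cg, ci, background = 1000), 3)
  expect_identical(enrichment_score(c("x", "y"), ci, background = 1000), -Inf)
  # cluster fully CI when CI is the whole background: E = 0
  expect_equal(enrichment_score(sprintf("c%d", 1:5), sprintf("c%d", 1:50),
                                background = 50), 0)
  expect_error(enrichment_score(character(0), ci, 100), "empty")
  expect_error(enrichment_score(cg, character(0), 100), "nonempty")
  # strictly increasing in overlap at fixed sizes
  ci_big <- c(sprintf("g%d", 1:10), sprintf("c%d", 1:40))
  e_seq <- vapply(1:10, function(ov) {
    enrichment_score(c(sprintf("g%d", 1:ov), sprintf("x%d", seq_len(10 - ov))),
                     ci_big, background = 1000)
  }, 0)
  expect_true(all(diff(e_seq) > 0))
})

test_that("the permutation p-value is the published exceedance form", {
  null5000 <- c(rep(10, 10), rep(-5, 4990))
  expect_equal(permutation_pvalue(3, null5000), 10 / 5001)
  expect_equal(permutation_pvalue(99, null5000), 0)
  expect_equal(permutation_pvalue(99, null5000, pseudo_count = TRUE), 1 / 5001)
  expect_equal(permutation_pvalue(-Inf, rep(1, 100)), 100 / 101)
  # p non-increasing in the observed score over a fixed null
  set.seed(3)
  null <- stats::rnorm(500)
  ps <- vapply(seq(-3, 3, 0.5), permutation_pvalue, 0, null_scores = null)
  expect_true(all(diff(ps) <= 0))
})

test_that("CI calls require both the FDR and the positive-score condition", {
  res <- data.frame(owner = "d", cluster_id = c("c1", "c2", "c3"),
                    E = c(2, 1, 0.5), p = c(0.01, 0.02, 0.03))
  out <- call_ci_clusters(res)
  # brute-force BH oracle
  bh <- function(p) {
    m <- length(p); o <- order(p); adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj))); pmin(adj, 1)[order(o)]
  }
  expect_equal(out$fdr, bh(res$p))
  expect_equal(out$fdr, rep(0.03, 3))
  expect_true(all(out$is_ci_enriched))

  one <- call_ci_clusters(data.frame(owner = "d", cluster_id = "c1",
                                     E = 1, p = 0.2))
  expect_equal(one$fdr, 0.2)

  neg <- call_ci_clusters(data.frame(owner = "d", cluster_id = "c1",
                                     E = -Inf, p = 0.001))
  expect_false(neg$is_ci_enriched)

  two_owners <- data.frame(owner = c("d1", "d2"), cluster_id = "c1",
                           E = 1, p = 0.5)
  expect_error(call_ci_clusters(two_owners), "single owner")

  # BH oracle on random vectors
  set.seed(9)
  for (i in 1:10) {
    p <- stats::runif(sample(2:100, 1))
    expect_equal(stats::p.adjust(p, "BH"), bh(p))
  }
})

test_that("null ensembles validate inputs and are reproducible", {
  net <- clique_graph(sprintf("g%02d", 1:12))
  idx <- build_degree_index(net)
  ci <- sprintf("g%02d", 1:6)
  expect_error(build_null_ensemble(sprintf("g%02d", 1:8), net, idx, ci,
                                   n_lists = 0), "positive")
  ne1 <- build_null_ensemble(sprintf("g%02d", 1:8), net, idx, ci,
                             n_lists = 30, seed = 4)
  ne2 <- build_null_ensemble(sprintf("g%02d", 1:8), net, idx, ci,
                             n_lists = 30, seed = 4)
  expect_identical(sort(ne1$scores), sort(ne2$scores))
  # dense clique: every random list is itself a single >= 5-gene cluster
  expect_equal(ne1$n_lists_with_clusters, 30)
})

test_that("sampled permutation p matches full enumeration on a tiny graph", {
  # 12 nodes: a 6-clique and a 6-path; list of 3 genes
  cl <- sprintf("a%d", 1:6)
  pa <- sprintf("p%d", 1:6)
  net <- igraph::union(clique_graph(cl), path_graph(pa))
  idx <- build_degree_index(net)
  ci <- c("a1", "a2", "a3", "p1")
  nodes <- igraph::V(net)$name
  background <- length(nodes)
  glist <- c("a1", "a2", "p3")

  # all degree-valid replacement triples (k_min = 1: exact-degree buckets)
  buckets <- lapply(glist, function(g) {
    idx$genes_at[[as.character(idx$degree_of[[g]])]]
  })
  combos <- expand.grid(buckets, stringsAsFactors = FALSE)
  combos <- combos[apply(combos, 1, function(r) !anyDuplicated(r)), ]
  enum_scores <- unlist(lapply(seq_len(nrow(combos)), function(i) {
    sg <- induce_subgraph(net, unlist(combos[i, ], use.names = FALSE))
    parts <- partition_leiden(sg, iterations = 10)
    vapply(parts, enrichment_score, 0, ci = ci, background = background)
  }))

  E_obs <- enrichment_score(glist, ci, background)
  f_enum <- mean(enum_scores >= E_obs)

  ens <- build_null_ensemble(glist, net, idx, ci, n_lists = 600,
                             min_size = 1, seed = 10, iterations = 10,
                             k_min = 1)
  f_samp <- mean(ens$scores >= E_obs)
  se <- sqrt(f_enum * (1 - f_enum) / length(ens$scores))
  expect_lt(abs(f_samp - f_enum), 3 * se + 1e-12)
})

test_that("ci_enrichment produces calls end-to-end on a planted fixture", {
  # CI block = one clique; a diffuse path provides the degree diversity
  cl <- sprintf("a%d", 1:8)
  rest <- sprintf("r%02d", 1:40)
  set.seed(21)
  g_rest <- igraph::sample_gnp(40, 0.12)
  igraph::V(g_rest)$name <- rest
  net <- igraph::union(clique_graph(cl), g_rest)
  net <- igraph::add_edges(net, c("a1", "r01"))
  idx <- build_degree_index(net)
  ci <- cl
  clusters <- list(c1 = cl)
  ens <- build_null_ensemble(cl, net, idx, ci, n_lists = 100, seed = 2)
  res <- ci_enrichment(clusters, ens, ci, net, owner = "dz")
  expect_equal(nrow(res), 1)
  expect_gt(res$E, 0)
  expect_true(res$p <= 1 && res$p >= 0)
  expect_named(res, c("owner", "cluster_id", "size", "E", "p", "fdr",
                      "is_ci_enriched", "n_null_clusters"))
})

test_that("unannotated-gene CI probabilities contrast by cluster status", {
  net <- path_graph(sprintf("x%d", 1:8))
  clusters <- list(c1 = sprintf("x%d", 1:4), c2 = sprintf("x%d", 5:8))
  calls <- data.frame(cluster_id = c("c1", "c2"),
                      is_ci_enriched = c(TRUE, FALSE))
  prob <- stats::setNames(c(0.9, 0.9, 0.9, 0.9, 0.1, 0.1, 0.1, 0.1),
                          sprintf("x%d", 1:8))
  m <- stub_model(prob)
  out <- unannotated_ci_probability_contrast(clusters, calls, ci = character(0),
                                             ci_model = m, net = net)
  expect_equal(out$mean_enriched - out$mean_non_enriched, 0.8)
  expect_lt(out$p_ranksum, 0.05)
  expect_lt(out$p_fisher, 0.05)

  # identical score distributions: no signal
  m0 <- stub_model(stats::setNames(rep(0.5, 8), sprintf("x%d", 1:8)))
  out0 <- unannotated_ci_probability_contrast(clusters, calls, character(0),
                                              m0, net)
  expect_equal(out0$mean_enriched, out0$mean_non_enriched)
  expect_gt(out0$p_ranksum, 0.4)

  calls_bad <- data.frame(cluster_id = c("c1", "c2"),
                          is_ci_enriched = c(TRUE, TRUE))
  expect_error(
    unannotated_ci_probability_contrast(clusters, calls_bad, character(0),
                                        m, net),
    "non-enriched")
})
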