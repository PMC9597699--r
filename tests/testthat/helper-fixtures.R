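# fixtures built in code; everything is deterministic under fixed seeds

make_net <- function(edges, nodes = NULL) {
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  if (!is.null(nodes)) {
    g <- g + igraph::vertices(setdiff(nodes, igraph::V(g)$name))
  }
  g
}

path_graph <- function(nodes) {
  n <- length(nodes)
  make_net(as.vector(rbind(nodes[-n], nodes[-1])))
}

clique_graph <- function(nodes) {
  pairs <- utils::combn(nodes, 2)
  make_net(as.vector(pairs))
}

# two disjoint cliques, the canonical perfectly-separable fixture
two_clique_net <- function(n_each = 10) {
  a <- sprintf("p%02d", seq_len(n_each))
  b <- sprintf("n%02d", seq_len(n_each))
  igraph::union(clique_graph(a), clique_graph(b))
}

star_graph <- function(center, leaves) {
  make_net(as.vector(rbind(center, leaves)))
}

# small scenario for fast end-to-end tests
small_config <- function(rng_seed = 1L) {
  scenario_config(
    n_genes = 600L, n_blocks = 6L, p_within = 0.2, p_between = 0.01,
    ci_blocks = c(1L, 2L), n_ci_genes = 40L,
    disease_specs = data.frame(name = c("dA", "dB"), n_seed_genes = 30L,
                               fraction_from_ci_blocks = 0.6),
    trait_specs = data.frame(name = c("tA", "tB"), n_seed_genes = 30L),
    drug_specs = data.frame(
      drug_id = c("ci1", "ci2", "rn1", "rn2"), n_targets = 4L,
      placement = c("ci_module", "ci_module", "random", "random"),
      class = c("anti", "anti", "other", "other")),
    n_decoy_annotations = 10L, decoy_annotation_size = 30L,
    rng_seed = rng_seed)
}

# stub expansion model with externally fixed probabilities, for tests that
# need exact probability values at the expansion threshold
stub_model <- function(prob) {
  structure(list(prob = prob), class = c("stub_model", "expansion_model"))
}
predict.stub_model <- function(object, net, genes = NULL, ...) {
  p <- object$prob
  if (!is.null(genes)) p <- p[genes]
  p
}
registerS3method("predict", "stub_model", predict.stub_model,
                 envir = asNamespace("stats"))
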