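#' Configuration of a synthetic benchmark scenario
#'
#' A scenario is a planted-partition (stochastic block model) interactome
#' with a designated pair of chronic-inflammation (CI) blocks, plus gene sets
#' and drugs arranged around them: "disease-like" seed sets concentrated in
#' the CI blocks, "trait-like" diffuse seed sets drawn degree-matched at
#' random, a CI gene set planted inside the CI blocks, decoy annotation sets
#' emulating the breadth of a disease-annotation collection, and drugs whose
#' targets sit inside (`ci_module`) or outside (`random`) the CI blocks.
#'
#' The defaults are the reference study conditions used throughout the
#' package's validation: 2,000 genes in 20 blocks (p_within = 0.15,
#' p_between = 0.004), 2 CI blocks carrying 80 CI genes (40 each),
#' 10 disease-like sets of 60 seeds with 60% drawn from the CI blocks,
#' 10 trait-like sets of 60 seeds, and 10 `ci_module` plus 20 `random`
#' drugs with 5 targets each.
#'
#' @param n_genes Number of genes (network nodes).
#' @param n_blocks Number of equal-size blocks; must divide `n_genes`.
#' @param p_within,p_between Within-/between-block edge probabilities,
#'   `0 < p_between < p_within <= 1`.
#' @param ci_blocks Integer indices (1-based) of the CI-planted blocks.
#' @param n_ci_genes Size of the planted CI gene set, split evenly across
#'   `ci_blocks`.
#' @param disease_specs Data frame with columns `name`, `n_seed_genes`,
#'   `fraction_from_ci_blocks` (remainder drawn from the other blocks).
#' @param trait_specs Data frame with columns `name`, `n_seed_genes`.
#' @param drug_specs Data frame with columns `drug_id`, `n_targets`,
#'   `placement` (`"ci_module"` or `"random"`), and optionally `class`
#'   (flat drug-class label).
#' @param n_decoy_annotations,decoy_annotation_size Number and size of
#'   diffuse decoy annotation sets added to the negative-selection universe.
#' @param rng_seed Integer seed; the whole scenario is a deterministic
#'   function of the configuration.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_genes = 2000L,
                            n_blocks = 20L,
                            p_within = 0.15,
                            p_between = 0.004,
                            ci_blocks = c(1L, 2L),
                            n_ci_genes = 80L,
                            disease_specs = NULL,
                            trait_specs = NULL,
                            drug_specs = NULL,
                            n_decoy_annotations = 20L,
                            decoy_annotation_size = 60L,
                            rng_seed = 1L) {
  if (is.null(disease_specs)) {
    disease_specs <- data.frame(
      name = sprintf("disease%02d", 1:10),
      n_seed_genes = 60L,
      fraction_from_ci_blocks = 0.6)
  }
  if (is.null(trait_specs)) {
    trait_specs <- data.frame(
      name = sprintf("trait%02d", 1:10),
      n_seed_genes = 60L)
  }
  if (is.null(drug_specs)) {
    drug_specs <- data.frame(
      drug_id = c(sprintf("cidrug%02d", 1:10), sprintf("rndrug%02d", 1:20)),
      n_targets = 5L,
      placement = c(rep("ci_module", 10), rep("random", 20)),
      class = c(rep("antiinflammatory", 10), rep("other", 20)))
  }
  cfg <- structure(
    list(n_genes = as.integer(n_genes), n_blocks = as.integer(n_blocks),
         p_within = p_within, p_between = p_between,
         ci_blocks = as.integer(ci_blocks), n_ci_genes = as.integer(n_ci_genes),
         disease_specs = disease_specs, trait_specs = trait_specs,
         drug_specs = drug_specs,
         n_decoy_annotations = as.integer(n_decoy_annotations),
         decoy_annotation_size = as.integer(decoy_annotation_size),
         rng_seed = as.integer(rng_seed)),
    class = "scenario_config")
  validate_scenario_config(cfg)
  cfg
}

validate_scenario_config <- function(cfg) {
  stopifnot(cfg$n_genes > 0, cfg$n_blocks > 0,
            cfg$n_genes %% cfg$n_blocks == 0L)
  if (!(cfg$p_between >= 0 && cfg$p_between <= cfg$p_within &&
        cfg$p_within <= 1 && cfg$p_within > 0)) {
    stop("need 0 <= p_between <= p_within <= 1 with p_within > 0")
  }
  if (any(cfg$ci_blocks < 1L | cfg$ci_blocks > cfg$n_blocks)) {
    stop("ci_blocks must index blocks in 1..n_blocks")
  }
  if (cfg$n_ci_genes <= 0) stop("n_ci_genes must be positive")
  if (any(cfg$disease_specs$fraction_from_ci_blocks < 0 |
          cfg$disease_specs$fraction_from_ci_blocks > 1)) {
    stop("fraction_from_ci_blocks must lie in [0, 1]")
  }
  if (any(cfg$disease_specs$n_seed_genes <= 0) ||
      any(cfg$trait_specs$n_seed_genes <= 0) ||
      any(cfg$drug_specs$n_targets <= 0)) {
    stop("all gene/target counts must be positive")
  }
  bad <- setdiff(unique(cfg$drug_specs$placement), c("ci_module", "random"))
  if (length(bad) > 0L) stop("unknown drug placement: ", bad[1])
  invisible(cfg)
}

#' Generate the planted-partition interactome of a scenario
#'
#' Genes are assigned to `n_blocks` equal blocks; each within-block pair is
#' an edge with probability `p_within` and each between-block pair with
#' `p_between`. Block labels are stored in the vertex attribute `block`.
#' Deterministic for a fixed seed.
#'
#' @param cfg A [scenario_config()].
#' @param seed Seed used for generation; defaults to `cfg$rng_seed`. Pass
#'   `NULL` to consume the current RNG stream (used by [generate_scenario()]).
#' @return An undirected [igraph::igraph] with vertex attributes `name` and
#'   `block`.
#' @export
generate_interactome <- function(cfg, seed = cfg$rng_seed) {
  size <- cfg$n_genes / cfg$n_blocks
  mean_deg <- cfg$p_within * (size - 1) +
    cfg$p_between * (cfg$n_genes - size)
  if (mean_deg < 1) {
    stop(sprintf("expected mean degree %.2f < 1; the analysis assumes a giant component",
                 mean_deg))
  }
  if (!is.null(seed)) set.seed(seed)
  pm <- matrix(cfg$p_between, cfg$n_blocks, cfg$n_blocks)
  diag(pm) <- cfg$p_within
  g <- igraph::sample_sbm(cfg$n_genes, pref.matrix = pm,
                          block.sizes = rep(size, cfg$n_blocks))
  igraph::V(g)$name <- sprintf("g%05d", seq_len(cfg$n_genes))
  igraph::V(g)$block <- rep(seq_len(cfg$n_blocks), each = size)
  g$name <- "synthetic interactome"
  g
}

block_members <- function(net, blocks) {
  igraph::V(net)$name[igraph::V(net)$block %in% blocks]
}

#' Sample a disease-like seed gene set
#'
#' Draws `fraction_from_ci_blocks * n_seed_genes` seeds (rounded) uniformly
#' without replacement from the CI-planted blocks and the remainder from the
#' other blocks, emulating a disease whose annotated genes are concentrated
#' in specific network modules.
#'
#' @param net Interactome from [generate_interactome()] (needs the `block`
#'   vertex attribute).
#' @param cfg The [scenario_config()].
#' @param spec One row of `cfg$disease_specs`.
#' @return Character vector of seed genes.
#' @export
generate_disease_seeds <- function(net, cfg, spec) {
  n <- spec$n_seed_genes
  n_ci <- round(spec$fraction_from_ci_blocks * n)
  ci_pool <- block_members(net, cfg$ci_blocks)
  other_pool <- setdiff(igraph::V(net)$name, ci_pool)
  if (n_ci > length(ci_pool) || (n - n_ci) > length(other_pool)) {
    stop("requested more seed genes than available in a stratum")
  }
  c(sample(ci_pool, n_ci), sample(other_pool, n - n_ci))
}

#' Sample a trait-like diffuse seed gene set
#'
#' Draws a reference set uniformly over network nodes, then applies a
#' degree-preserving reshuffle ([degree_matched_sample()]). The result has a
#' realistic degree profile but no block coherence, emulating a non-disease
#' GWAS trait.
#'
#' @param net Interactome.
#' @param index [build_degree_index()] of `net`.
#' @param spec One row of `cfg$trait_specs` (needs `n_seed_genes`).
#' @return Character vector of seed genes (empty when `n_seed_genes` is 0).
#' @export
generate_trait_seeds <- function(net, index, spec) {
  n <- spec$n_seed_genes
  if (n == 0L) return(character(0))
  ref <- sample(igraph::V(net)$name, n)
  degree_matched_sample(ref, index)
}

#' Sample the scenario's drugs and their truth indications
#'
#' `ci_module` drugs draw targets uniformly from the CI-planted blocks;
#' `random` drugs draw degree-matched random targets. Every `ci_module` drug
#' is recorded as a trial-status positive for each disease whose seeds were
#' CI-block-enriched (`fraction_from_ci_blocks >= 0.5`), providing ground
#' truth for the evaluation stage.
#'
#' @param net Interactome.
#' @param cfg The [scenario_config()].
#' @param index [build_degree_index()] of `net`.
#' @return List with `drugs` (as from [read_drug_targets()]) and
#'   `indications` (data.frame `drug_id`, `disease_id`, `status`).
#' @export
generate_drugs <- function(net, cfg, index) {
  ci_pool <- block_members(net, cfg$ci_blocks)
  specs <- cfg$drug_specs
  targets <- vector("list", nrow(specs))
  names(targets) <- specs$drug_id
  for (i in seq_len(nrow(specs))) {
    n <- specs$n_targets[i]
    targets[[i]] <- if (specs$placement[i] == "ci_module") {
      sample(ci_pool, n)
    } else {
      degree_matched_sample(sample(igraph::V(net)$name, n), index)
    }
  }
  class_of <- if ("class" %in% names(specs)) {
    stats::setNames(as.list(specs$class), specs$drug_id)
  } else {
    stats::setNames(rep(list(character(0)), nrow(specs)), specs$drug_id)
  }
  ci_diseases <- cfg$disease_specs$name[
    cfg$disease_specs$fraction_from_ci_blocks >= 0.5]
  ci_drugs <- specs$drug_id[specs$placement == "ci_module"]
  indications <- if (length(ci_drugs) > 0L && length(ci_diseases) > 0L) {
    expand.grid(drug_id = ci_drugs, disease_id = ci_diseases,
                status = "trial", stringsAsFactors = FALSE,
                KEEP.OUT.ATTRS = FALSE)
  } else {
    data.frame(drug_id = character(0), disease_id = character(0),
               status = character(0))
  }
  list(drugs = list(targets = targets, class_of = class_of),
       indications = indications)
}

#' Generate a complete synthetic scenario
#'
#' Consumes a single RNG stream seeded by `cfg$rng_seed` in a fixed substream
#' order (interactome, CI genes, disease seeds, trait seeds, decoy
#' annotations, drugs), so regenerating with the same configuration yields an
#' identical scenario.
#'
#' @param cfg A [scenario_config()].
#' @return Object of class `ci_scenario`: `network`, `degree_index`,
#'   `disease_seeds`, `trait_seeds`, `ci_genes`, `all_disease_annotations`
#'   (disease seed sets plus decoy sets; the negative-selection universe),
#'   `drugs`, `indications`, and `truth` (CI blocks and their genes, the
#'   CI-block-enriched diseases, per-drug placement).
#' @export
generate_scenario <- function(cfg) {
  validate_scenario_config(cfg)
  net <- generate_interactome(cfg, seed = cfg$rng_seed)
  index <- build_degree_index(net)
  # CI genes: split evenly across the CI blocks
  per_block <- distribute_evenly(cfg$n_ci_genes, length(cfg$ci_blocks))
  ci_genes <- unlist(lapply(seq_along(cfg$ci_blocks), function(i) {
    pool <- block_members(net, cfg$ci_blocks[i])
    if (per_block[i] > length(pool)) stop("n_ci_genes exceeds CI block size")
    sample(pool, per_block[i])
  }), use.names = FALSE)
  disease_seeds <- lapply(seq_len(nrow(cfg$disease_specs)), function(i) {
    generate_disease_seeds(net, cfg, cfg$disease_specs[i, ])
  })
  names(disease_seeds) <- cfg$disease_specs$name
  trait_seeds <- lapply(seq_len(nrow(cfg$trait_specs)), function(i) {
    generate_trait_seeds(net, index, cfg$trait_specs[i, ])
  })
  names(trait_seeds) <- cfg$trait_specs$name
  decoys <- lapply(seq_len(cfg$n_decoy_annotations), function(i) {
    sample(igraph::V(net)$name, cfg$decoy_annotation_size)
  })
  names(decoys) <- sprintf("decoy%02d", seq_len(cfg$n_decoy_annotations))
  drug_out <- generate_drugs(net, cfg, index)
  ci_diseases <- cfg$disease_specs$name[
    cfg$disease_specs$fraction_from_ci_blocks >= 0.5]
  structure(
    list(config = cfg,
         network = net,
         degree_index = index,
         disease_seeds = disease_seeds,
         trait_seeds = trait_seeds,
         ci_genes = ci_genes,
         all_disease_annotations = c(disease_seeds, decoys),
         drugs = drug_out$drugs,
         indications = drug_out$indications,
         truth = list(
           ci_blocks = cfg$ci_blocks,
           ci_block_genes = block_members(net, cfg$ci_blocks),
           blocks = stats::setNames(igraph::V(net)$block,
                                    igraph::V(net)$name),
           ci_diseases = ci_diseases,
           drug_placement = stats::setNames(cfg$drug_specs$placement,
                                            cfg$drug_specs$drug_id))),
    class = "ci_scenario")
}

distribute_evenly <- function(total, k) {
  base <- total %/% k
  extra <- total %% k
  base + c(rep(1L, extra), rep(0L, k - extra))
}

#' @export
print.ci_scenario <- function(x, ...) {
  cat("synthetic CI scenario:",
      igraph::vcount(x$network), "genes,",
      igraph::ecount(x$network), "edges,",
      x$config$n_blocks, "blocks (CI:",
      paste(x$config$ci_blocks, collapse = ","), ")\n")
  cat(" ", length(x$disease_seeds), "disease sets,",
      length(x$trait_seeds), "trait sets,",
      length(x$ci_genes), "CI genes,",
      length(x$drugs$targets), "drugs\n")
  invisible(x)
}

#' Write a scenario to a directory of plain-text files
#'
#' Writes `network.tsv`, `disease_seeds.gmt`, `trait_seeds.gmt`,
#' `ci_genes.gmt`, `annotations.gmt`, `drug_targets.tsv`,
#' `indications.tsv` and `truth.json` (without a JSON library, the truth file
#' is a small hand-rendered object).
#'
#' @param scenario A `ci_scenario`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_network(scenario$network, file.path(dir, "network.tsv"))
  write_gmt(scenario$disease_seeds, file.path(dir, "disease_seeds.gmt"))
  write_gmt(scenario$trait_seeds, file.path(dir, "trait_seeds.gmt"))
  write_gmt(list(ci = scenario$ci_genes), file.path(dir, "ci_genes.gmt"))
  write_gmt(scenario$all_disease_annotations,
            file.path(dir, "annotations.gmt"))
  tg <- scenario$drugs$targets
  df <- data.frame(
    drug_id = rep(names(tg), lengths(tg)),
    gene = unlist(tg, use.names = FALSE),
    class = rep(vapply(scenario$drugs$class_of, function(x) {
      if (length(x) == 0L) "" else x[1]
    }, ""), lengths(tg)))
  utils::write.table(df, file.path(dir, "drug_targets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(scenario$indications, file.path(dir, "indications.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- scenario$truth
  json <- paste0(
    '{"ci_blocks": [', paste(tr$ci_blocks, collapse = ","), '], ',
    '"ci_diseases": [', paste(sprintf('"%s"', tr$ci_diseases), collapse = ","),
    '], "drug_placement": {',
    paste(sprintf('"%s": "%s"', names(tr$drug_placement), tr$drug_placement),
          collapse = ", "), "}}")
  writeLines(json, file.path(dir, "truth.json"))
  invisible(dir)
}
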