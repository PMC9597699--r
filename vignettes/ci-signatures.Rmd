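---
title: "Isolating chronic-inflammation signatures on gene networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isolating chronic-inflammation signatures on gene networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Complex diseases are heterogeneous: the genes annotated to one disease
typically span several biological processes, only some of which drive a
given endophenotype. This package isolates, for each disease, the part of
its gene signature attributable to one shared endophenotype — chronic
inflammation (CI), represented operationally as a gene set — and then uses
that isolated signature to prioritize drugs. The unit of analysis is a
*disease cluster*: a densely interconnected subset of a disease's
(expanded) gene set in an interactome.

The pipeline has five stages, all exposed as ordinary functions and
orchestrated by `run_ci_pipeline()`:

1. **Expansion.** Disease seed genes are positives for an L2-regularized
   logistic regression whose features are each gene's adjacency row in the
   interactome; negatives come from the remaining annotation collection
   after removing sets that significantly overlap the seeds (one-sided
   Fisher test, p < 0.05, network nodes as universe). Genes predicted with
   probability ≥ 0.80 join the seed list. The same machinery expands the CI
   gene set itself.
2. **Clustering.** The expanded list induces a disease-specific subnetwork,
   partitioned by modularity-objective Leiden (100 iterations); clusters
   with fewer than 5 genes are discarded.
3. **CI enrichment.** Each cluster's score is
   `E = log2((|CG∩CI|/|CG|) / (|CI|/background))`, with the background equal
   to the clustering network's gene count. Significance comes from a
   degree-matched permutation null: each of `n_lists` random lists replaces
   every disease gene by a random gene of (near-)equal degree, is clustered
   identically, and all surviving null clusters' scores are pooled. The
   p-value is the published exceedance form `p = #{E_null ≥ E_obs}/(n+1)`.
   Benjamini–Hochberg runs within disease; clusters with FDR < 0.05 and
   E > 0 form the disease's CI signature.
4. **Signature comparison.** CI-enriched clusters across diseases are
   compared by mean closest shortest-path distance in both directions,
   converted to similarities `s = 1/(1+d)`, tested against degree- and
   size-matched random pairs, combined with Stouffer's method, and grouped
   by Leiden on the significant-pair graph.
5. **Repurposing and evaluation.** Drugs are scored against each enriched
   cluster by symmetrized closest-distance proximity with a 200-pair
   empirical null, min–max normalized and BH-adjusted within disease, each
   drug assigned to its lowest-FDR cluster, and predictions called at
   FDR < 0.01. Evaluation offers ranked retrieval (`log2(auPRC/prior)`),
   one-tailed Fisher enrichment of indicated drugs, and preranked
   set-enrichment of drug classes.

## What the synthetic scenarios emulate

Real inputs for this analysis are large curated resources (disease
annotation databases, GWAS gene scores, literature-derived CI gene lists,
curated drug–target tables). The package instead ships a generator
(`scenario_config()` / `generate_scenario()`) that reproduces their
*statistical structure* with known ground truth:

- a planted-partition (stochastic block model) interactome — blocks play
  the role of pathways/modules;
- two designated **CI blocks** carrying a planted CI gene set;
- **disease-like** seed sets drawn mostly (60%) from the CI blocks, so each
  disease has a coherent inflammatory component plus diffuse remainder;
- **trait-like** seed sets drawn uniformly with a degree-preserving
  reshuffle — realistic degrees, no modular coherence (negative controls);
- decoy annotation sets of uniform random genes. These stand in for the
  breadth of a disease-annotation collection and keep the negative pool
  non-empty: the synthetic diseases all share the CI blocks, so without
  decoys the overlap filter would exclude every other disease set and leave
  nothing to train against;
- drugs whose 5 targets are drawn either inside the CI blocks
  (`ci_module`) or degree-matched at random, with `ci_module` drugs
  recorded as trial-status indications for every CI-block-enriched disease
  (`fraction_from_ci_blocks ≥ 0.5`) as evaluation truth.

The reference conditions are 2,000 genes in 20 blocks with
`p_within = 0.15` and `p_between = 0.004` (mean degree ≈ 22, a connected,
modular graph at desk scale), 80 CI genes split over 2 CI blocks, ten
disease-like and ten trait-like sets of 60 seeds, and 30 drugs.

What passing on these scenarios does **not** show: real interactomes have
heavy-tailed degree distributions and overlapping pathways; real disease
sets carry annotation bias; drug targets are few and hub-biased. The block
model makes every block degree-homogeneous, which is *harder* on the
degree-matched null than a heavy-tailed network (degree carries no block
information at all), but it cannot exhibit hub-driven artifacts.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `reg` | 1.0 | ridge strength on the summed log-likelihood; glmnet `lambda = reg/n_train` |
| `expand_threshold` | 0.80 | probability gate for adding predicted genes |
| `min_cluster_size` | 5 | genes per retained cluster |
| `leiden_iterations` | -1 (converge) | Leiden passes; the pipeline iterates to convergence, equivalent to the conventional fixed 100 passes on these subnetwork sizes |
| `n_lists` | 5000 | degree-matched random lists per owner |
| `k_min` | 10 | degree bucket widened to the nearest degrees until it holds this many candidates |
| `fdr_threshold` | 0.05 | CI-cluster call (with E > 0) |
| drug `n_null` | 200 | empirical null pairs per drug–cluster score |
| drug FDR | 0.01 | predicted-treatment call |
| pair `alpha` | 0.05 | BH level for the signature-graph edges |

## Numerical and design choices

- **Permutation p-value.** The published form `Σxᵢ/(n+1)` has no
  pseudo-count and can return exactly 0. It is implemented verbatim
  (default); `pseudo_count = TRUE` switches to `(1+Σxᵢ)/(n+1)`. Drug and
  cluster-similarity p-values always use the +1 form because their nulls
  are small (200–1000 draws) and downstream ranking takes `-log10(FDR)`.
- **Regularization mapping.** `reg` is defined on the *summed*
  log-likelihood (the convention of scikit-learn, which the original
  expansion tool builds on), hence `lambda = reg/n_train` in glmnet, which
  penalizes the per-observation likelihood. Fits use a 30-point log-spaced
  lambda path ending at the target, which keeps coordinate descent stable;
  coefficients are read at the target value. Features are standardized
  internally so the penalty is scale-free.
- **Qualification gate.** The ≥15-gene / median `log2(auPRC/prior) ≥ 1`
  gate is computed and reported per owner, but the pipeline analyses all
  owners by default (`enforce_qualification = FALSE`). The diffuse
  synthetic traits would mostly fail the gate; analysing them anyway is the
  conservative choice for specificity claims, since every trait gets the
  chance to produce a false call.
- **Null-ensemble shortcut.** An owner with no ≥5-gene cluster of its own
  can have no enrichment result, so its (expensive) null ensemble is
  skipped. This changes nothing statistically.
- **Degree matching.** Exact-degree buckets are widened symmetrically to
  the nearest occupied degrees until they hold ≥ `k_min` candidates
  (nearest by absolute difference, ties to the smaller degree); duplicate
  replacements are redrawn so null lists have the original size.
- **Unreachable distances.** Mean-closest distances charge unreachable
  pairs `diameter + 1` of the largest component rather than dropping them,
  which would bias similarities upward.
- **Similarity.** The published repurposing tool rescales similarity with
  an undocumented sigmoid; this package uses the plain bounded transform
  `s = 1/(1+d)` with the degree-matched empirical null, which is monotone
  in proximity and fully testable. Drug proximity is symmetrized by
  default (`direction = "sym"`); the one-directional drug→disease variant
  is available.
- **Annotation enrichment.** Over-representation is a one-sided
  hypergeometric tail with BH within cluster/group and annotation-set size
  bounds 5–100. No ontology decorrelation is attempted: the annotation
  interface takes arbitrary gene-set collections, not a GO DAG.
- **Ties and determinism.** Training genes are sorted before fold
  assignment, drug rankings break `-log10(FDR)` ties by normalized
  similarity then drug id, and every stochastic step takes a seed.
  Set-enrichment p-values enumerate all member placements exhaustively
  whenever there are no more than `n_perm` of them.
- **Shared null draws in batch drug scoring.** `score_drugs()` draws its
  `n_null` degree-matched null sets once per drug and once per cluster and
  pairs them across combinations — the same null distribution as fresh
  per-pair draws (which `drug_cluster_score()` still uses), without
  redundant sampling.
- **CI probability contrast.** The comparison of model probabilities for
  unannotated genes in enriched vs non-enriched clusters reports both a
  one-sided rank-sum test on gene-level scores and a one-sided Fisher test
  on the above/below-global-median 2×2 table; a Fisher test "on mean
  probabilities" alone is not well defined.

## Problem sizes used in the shipped checks

The validation suite runs the reference scenario with `n_lists = 1000`
random lists per owner for disease sensitivity, ten scenario replicates of
the ten trait sets for specificity, 200 simulated clusters for the
uniformity check of the permutation p-values, and five scenario replicates
for cluster-recovery scoring; drug scoring uses the full 30-drug panel
with 200-pair nulls. These sizes give stable estimates of every reported
quantity at desk scale; `scripts/acceptance.R` recomputes them all from
scratch for any seed.

## Known limitations

- **Modularity splits sparse subnetworks.** On a disease-specific
  subnetwork, the genes a planted block contributes form a sparse
  ER-like subgraph, and modularity at resolution 1 tends to split it into
  a main cluster plus small satellites. The resulting clusters are almost
  always pure subsets of a single block (mean majority-block purity ≈ 0.92
  in the reference conditions) even though gene-level agreement with the
  block labels is diluted; on the full interactome the planted partition
  is recovered essentially exactly. CI enrichment is unaffected — a pure
  sub-cluster of a CI block scores like its parent.
- **FDR floor of the drug null.** With 200 null pairs the smallest
  empirical p is 1/201 ≈ 0.005; after BH across a disease's drug–cluster
  records, FDR < 0.01 is only reachable when a large fraction of records
  sit at that floor. In the reference scenario (a third of drugs
  on-module) no call passes 0.01 — ranking by FDR with similarity
  tie-breaks is unaffected, and both `n_null` and the threshold are
  config-exposed.
- Opaque gene identifiers; no species mapping, no ID conversion.
- Undirected, positively weighted networks only; weights affect Leiden
  modularity and the expansion features, never degrees or shortest paths.
- The generator does not imitate real degree distributions or real
  annotation-set size spectra, and decoy annotation sets are independent
  of the network structure.
- With the verbatim p-value and very large `n_lists`, owners whose null
  ensembles are small can only attain a coarse grid of p-values; the BH
  step inherits that granularity.
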