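#' Read an undirected gene-gene interaction network from an edge-list TSV
#'
#' The file holds one edge per line with two (or, if `weighted = TRUE`, three)
#' tab-separated columns: `gene_a`, `gene_b` and an optional positive weight.
#' Lines starting with `#` are skipped, and a single header line is detected
#' (non-numeric third field on the first data line) and dropped. Duplicate
#' edges are collapsed keeping the maximum weight; self-loops are dropped with
#' a warning. The returned network is the background universe for all
#' downstream statistics.
#'
#' @param path Path to the edge-list TSV.
#' @param weighted If `TRUE`, a third column with a positive weight is
#'   expected and stored as the `weight` edge attribute.
#' @param name Optional network name (stored as a graph attribute).
#' @return An undirected [igraph::igraph] object with named vertices.
#' @export
read_network <- function(path, weighted = FALSE, name = basename(path)) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g$name <- name
    return(g)
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  expected <- if (weighted) 3L else 2L
  # header detection: right column count but non-numeric weight field, or
  # an unweighted first line repeated nowhere as data is impossible to tell
  # apart from data, so only the weighted case is sniffed.
  start <- 1L
  if (weighted && ncols[1] == 3L &&
      is.na(suppressWarnings(as.numeric(fields[[1]][3])))) {
    start <- 2L
  } else if (!weighted && ncols[1] == 2L &&
             identical(tolower(fields[[1]][1]), "gene_a")) {
    start <- 2L
  }
  if (start > length(idx)) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g$name <- name
    return(g)
  }
  fields <- fields[start:length(fields)]
  lineno <- idx[start:length(idx)]
  bad <- which(lengths(fields) != expected)
  if (length(bad) > 0L) {
    stop(sprintf("line %d: expected %d tab-separated fields, found %d",
                 lineno[bad[1]], expected, lengths(fields)[bad[1]]))
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  if (weighted) {
    w <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
    badw <- which(is.na(w) | w <= 0)
    if (length(badw) > 0L) {
      stop(sprintf("line %d: weight must be a positive number",
                   lineno[badw[1]]))
    }
  } else {
    w <- NULL
  }
  loops <- a == b
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop edge(s)", sum(loops)))
    a <- a[!loops]; b <- b[!loops]
    if (!is.null(w)) w <- w[!loops]
  }
  # collapse duplicates (undirected): canonical order, keep max weight
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  if (!is.null(w)) {
    ord <- order(key, -w)
    dup <- duplicated(key[ord])
    lo <- lo[ord][!dup]; hi <- hi[ord][!dup]; w <- w[ord][!dup]
  } else {
    dup <- duplicated(key)
    lo <- lo[!dup]; hi <- hi[!dup]
  }
  el <- cbind(lo, hi)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (!is.null(w)) igraph::E(g)$weight <- w
  g$name <- name
  g
}

#' Write a network as an edge-list TSV
#'
#' @param net An undirected [igraph::igraph] with named vertices.
#' @param path Output path.
#' @export
write_network <- function(net, path) {
  el <- igraph::as_edgelist(net)
  df <- data.frame(gene_a = el[, 1], gene_b = el[, 2])
  if ("weight" %in% igraph::edge_attr_names(net)) {
    df$weight <- igraph::E(net)$weight
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line with tab-separated fields
#' `id`, `description`, then gene identifiers. Duplicate genes within a line
#' are removed.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (one per set, in file order),
#'   with per-set descriptions in the `"description"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) {
    out <- list()
    attr(out, "description") <- character(0)
    return(out)
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop(sprintf("line %d: GMT line needs at least 3 fields (id, description, gene...)",
                 keep[short[1]]))
  }
  ids <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  attr(sets, "description") <- stats::setNames(desc, ids)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors; optional `"description"`
#'   attribute (named character vector) supplies the second GMT column.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  lines <- vapply(seq_along(sets), function(i) {
    id <- names(sets)[i]
    d <- if (!is.null(desc) && id %in% names(desc)) desc[[id]] else "na"
    paste(c(id, d, sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a drug-to-target-gene table
#'
#' Two-column TSV (`drug_id`, `gene`), with an optional third column of
#' flat drug-class labels (a drug may appear with several classes). Every
#' drug must have at least one target gene.
#'
#' @param path Path to the TSV (header required).
#' @return A list with `targets` (named list drug -> character vector of
#'   genes) and `class_of` (named list drug -> character vector of class
#'   labels, possibly empty).
#' @export
read_drug_targets <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2L) stop("drug target table needs columns drug_id, gene")
  targets <- lapply(split(df[[2]], df[[1]]), unique)
  class_of <- if (ncol(df) >= 3L) {
    lapply(split(df[[3]], df[[1]]), function(x) setdiff(unique(x), c(NA, "")))
  } else {
    stats::setNames(rep(list(character(0)), length(targets)), names(targets))
  }
  empty <- names(targets)[lengths(targets) == 0L]
  if (length(empty) > 0L) stop("drug without target genes: ", empty[1])
  list(targets = targets, class_of = class_of[names(targets)])
}

#' Read a known drug-disease indication table
#'
#' Three-column TSV (`drug_id`, `disease_id`, `status`) where status is one of
#' `approved`, `off_label`, `trial`. Duplicate triples are dropped.
#'
#' @param path Path to the TSV (header required).
#' @return A data.frame with columns `drug_id`, `disease_id`, `status`.
#' @export
read_indications <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  names(df)[1:3] <- c("drug_id", "disease_id", "status")
  bad <- setdiff(unique(df$status), c("approved", "off_label", "trial"))
  if (length(bad) > 0L) stop("unknown indication status: ", bad[1])
  unique(df[, 1:3])
}

#' Build the degree index of a network
#'
#' Tabulates unweighted node degrees and inverts the map, the bookkeeping
#' behind every degree-matched null in the pipeline. Edge weights are
#' ignored: randomization preserves topological degree only.
#'
#' @param net An undirected [igraph::igraph] with named vertices.
#' @return An object of class `degree_index`: `degree_of` (named integer),
#'   `genes_at` (list keyed by degree), `sorted_degrees` (ascending integer
#'   vector of occupied degrees).
#' @export
build_degree_index <- function(net) {
  deg <- igraph::degree(net, loops = FALSE)
  genes_at <- split(names(deg), deg)
  sorted_degrees <- sort(unique(unname(deg)))
  structure(
    list(degree_of = deg,
         genes_at = genes_at,
         sorted_degrees = sorted_degrees,
         pool_cache = new.env(parent = emptyenv())),
    class = "degree_index")
}

#' @export
print.degree_index <- function(x, ...) {
  cat("degree index:", length(x$degree_of), "genes,",
      length(x$sorted_degrees), "distinct degrees",
      sprintf("(range %d-%d)\n", min(x$sorted_degrees), max(x$sorted_degrees)))
  invisible(x)
}

#' Induce the subnetwork spanned by a gene set
#'
#' Keeps the genes present in the network and every edge directly connecting
#' two kept genes. Genes absent from the network are silently dropped but
#' tallied in the `"n_dropped"` attribute of the result. Genes that lose all
#' neighbours are retained as isolated nodes (small clusters are filtered
#' later).
#'
#' @param net An undirected [igraph::igraph] with named vertices.
#' @param genes Character vector of gene identifiers.
#' @return The induced [igraph::igraph]; attribute `n_dropped` counts genes
#'   not found in `net`.
#' @export
induce_subgraph <- function(net, genes) {
  genes <- unique(genes)
  present <- genes[genes %in% igraph::V(net)$name]
  sg <- igraph::induced_subgraph(net, present)
  attr(sg, "n_dropped") <- length(genes) - length(present)
  sg
}
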