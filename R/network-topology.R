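#' @title Gene-list network topology and permutation significance
#' @description
#' Builds typed interaction subnetworks for a gene list on a background
#' interactome (co-expression edges excluded), summarises their topology
#' (mean node-degree, mean node-betweenness), and tests the summaries
#' against a null of randomly resampled gene lists of the same size,
#' reporting Z-scores, two-sided normal p-values, empirical p-values and
#' fold enrichments.
#' @name network-topology
NULL

NETWORK_EDGE_TYPES <- c("physical", "genetic", "colocalization",
                        "predicted", "pathway", "shared_domain",
                        "coexpression")

new_gene_network <- function(edges, nodes) {
  structure(list(edges = edges, nodes = nodes), class = "gene_network")
}

empty_nodes <- function(genes = character(0)) {
  data.frame(gene = genes,
             is_list_gene = logical(length(genes)),
             is_connector = logical(length(genes)),
             flagged_isolated = logical(length(genes)),
             stringsAsFactors = FALSE)
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf(
    "gene_network: %d nodes, %d typed edge records (%d simple edges)\n",
    nrow(x$nodes), nrow(x$edges),
    nrow(unique(x$edges[, c("gene_a", "gene_b")]))))
  if (any(x$nodes$is_connector)) {
    cat(sprintf("  connectors: %d\n", sum(x$nodes$is_connector)))
  }
  if (any(x$nodes$flagged_isolated)) {
    cat(sprintf("  listed genes absent from background: %d\n",
                sum(x$nodes$flagged_isolated)))
  }
  invisible(x)
}

# Collapsed simple unweighted igraph (parallel typed records merged,
# isolated nodes kept).
as_igraph_simple <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  ed <- unique(net$edges[, c("gene_a", "gene_b"), drop = FALSE])
  igraph::graph_from_data_frame(ed, directed = FALSE,
                                vertices = net$nodes$gene)
}

#' Build the background interaction network from an edge table
#'
#' Drops co-expression rows (the analysis background uses all but
#' co-expression-derived interactions), normalises each pair to
#' `gene_a < gene_b`, removes self-loops and exact duplicate typed
#' records, and keeps duplicate pairs of different types as typed parallel
#' records (collapsed to simple edges for metric computation). The node
#' universe is every gene incident to at least one retained edge.
#'
#' @param edge_table data.frame with columns `gene_a`, `gene_b`, `type`
#'   and optionally `weight`.
#' @return a `gene_network`.
#' @export
build_background <- function(edge_table) {
  check_cols(edge_table, c("gene_a", "gene_b", "type"), "edge table")
  et <- data.frame(gene_a = as.character(edge_table$gene_a),
                   gene_b = as.character(edge_table$gene_b),
                   type = as.character(edge_table$type),
                   weight = if ("weight" %in% names(edge_table)) {
                     suppressWarnings(as.numeric(edge_table$weight))
                   } else rep(1, nrow(edge_table)),
                   stringsAsFactors = FALSE)
  bad <- which(is.na(et$gene_a) | is.na(et$gene_b) | !nzchar(et$gene_a) |
                 !nzchar(et$gene_b) | is.na(et$type) |
                 !(et$type %in% NETWORK_EDGE_TYPES))
  if (length(bad) > 0L) {
    mn_data_error(sprintf(
      "malformed edge row(s) at line(s): %s (empty gene id or unknown type)",
      paste(utils::head(bad, 10), collapse = ", ")))
  }
  et <- et[et$type != "coexpression", , drop = FALSE]
  loops <- et$gene_a == et$gene_b
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop edge record(s)", sum(loops)))
    et <- et[!loops, , drop = FALSE]
  }
  swap <- et$gene_a > et$gene_b
  tmp <- et$gene_a[swap]
  et$gene_a[swap] <- et$gene_b[swap]
  et$gene_b[swap] <- tmp
  et <- et[!duplicated(et[, c("gene_a", "gene_b", "type")]), , drop = FALSE]
  et <- et[order(et$gene_a, et$gene_b, et$type), , drop = FALSE]
  rownames(et) <- NULL
  genes <- sort(unique(c(et$gene_a, et$gene_b)))
  new_gene_network(et, empty_nodes(genes))
}

#' Induce the subnetwork of a gene list
#'
#' Nodes are the listed genes found in the background plus any listed
#' genes absent from it (kept as isolated nodes, `flagged_isolated`);
#' edges are the background edge records with both ends in the list.
#'
#' @param background a `gene_network` from [build_background()].
#' @param gene_list character vector of gene ids.
#' @return a `gene_network` with `is_list_gene = TRUE` on every node.
#' @export
induce_subnetwork <- function(background, gene_list) {
  stopifnot(inherits(background, "gene_network"))
  gene_list <- unique(as.character(gene_list))
  if (length(gene_list) == 0L) mn_data_error("gene_list is empty")
  keep <- background$edges$gene_a %in% gene_list &
    background$edges$gene_b %in% gene_list
  edges <- background$edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- empty_nodes(sort(gene_list))
  nodes$is_list_gene <- TRUE
  nodes$flagged_isolated <- !(nodes$gene %in% background$nodes$gene)
  new_gene_network(edges, nodes)
}

#' Expand a list subnetwork with connector nodes
#'
#' Adds each background gene outside the list that either interacts with
#' at least two list genes or sits on a length-2 path between `seed_gene`
#' and another list gene, then induces all background edges among the
#' expanded node set. Connectors are flagged `is_connector`; the number of
#' list genes newly connected (degree 0 before, >= 1 after) is reported in
#' the `n_newly_connected` attribute.
#'
#' @param background a `gene_network`.
#' @param gene_list character vector of list genes.
#' @param seed_gene the anchor gene; must be in `gene_list`.
#' @return a `gene_network` over list genes plus connectors.
#' @export
expand_with_connectors <- function(background, gene_list, seed_gene) {
  stopifnot(inherits(background, "gene_network"))
  gene_list <- unique(as.character(gene_list))
  if (!(seed_gene %in% gene_list)) {
    mn_data_error("seed_gene must be a member of gene_list")
  }
  before <- induce_subnetwork(background, gene_list)
  g_before <- as_igraph_simple(before)
  deg_before <- igraph::degree(g_before)

  ed <- unique(background$edges[, c("gene_a", "gene_b")])
  nb <- split(c(ed$gene_b, ed$gene_a), c(ed$gene_a, ed$gene_b))
  outside <- setdiff(background$nodes$gene, gene_list)
  is_conn <- vapply(outside, function(v) {
    hits <- intersect(nb[[v]], gene_list)
    length(hits) >= 2L ||
      (seed_gene %in% hits && length(setdiff(hits, seed_gene)) >= 1L)
  }, logical(1))
  connectors <- outside[is_conn]

  expanded <- c(gene_list, connectors)
  keep <- background$edges$gene_a %in% expanded &
    background$edges$gene_b %in% expanded
  edges <- background$edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- empty_nodes(sort(expanded))
  nodes$is_list_gene <- nodes$gene %in% gene_list
  nodes$is_connector <- nodes$gene %in% connectors
  nodes$flagged_isolated <- nodes$is_list_gene &
    !(nodes$gene %in% background$nodes$gene)
  net <- new_gene_network(edges, nodes)

  deg_after <- igraph::degree(as_igraph_simple(net))
  newly <- sum(deg_before[gene_list] == 0 & deg_after[gene_list] > 0,
               na.rm = TRUE)
  attr(net, "n_connectors") <- length(connectors)
  attr(net, "n_newly_connected") <- newly
  attr(net, "expansion_rule") <-
    ">=2 list neighbors, or length-2 path to seed gene"
  net
}

#' Topology summary of a gene network
#'
#' Degrees and betweenness are computed on the collapsed simple unweighted
#' graph, isolated nodes included in the averages. Betweenness is
#' unnormalised shortest-path betweenness (Brandes), each unordered
#' source-target pair counted once. Averages excluding degree-0 nodes are
#' reported alongside, since a published network figure may drop
#' unconnected genes.
#'
#' @param net a `gene_network`.
#' @return object of class `topology_summary`: `n_nodes`, `n_edges`
#'   (simple), `mean_degree`, `mean_betweenness`,
#'   `mean_degree_connected`, `mean_betweenness_connected`,
#'   `n_connected_list_genes`.
#' @export
topology_summary <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  if (nrow(net$nodes) == 0L) mn_data_error("network has no nodes")
  g <- as_igraph_simple(net)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  conn <- deg > 0
  list_mask <- net$nodes$is_list_gene[match(names(deg), net$nodes$gene)]
  structure(list(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    mean_degree = mean(deg),
    mean_betweenness = mean(btw),
    mean_degree_connected = if (any(conn)) mean(deg[conn]) else 0,
    mean_betweenness_connected = if (any(conn)) mean(btw[conn]) else 0,
    n_connected_list_genes = sum(conn & (list_mask %in% TRUE))),
    class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "topology_summary: %d nodes, %d edges\n",
    "  mean degree      %.4f (connected only: %.4f)\n",
    "  mean betweenness %.4f (connected only: %.4f)\n",
    "  connected list genes: %d\n"),
    x$n_nodes, x$n_edges, x$mean_degree, x$mean_degree_connected,
    x$mean_betweenness, x$mean_betweenness_connected,
    x$n_connected_list_genes))
  invisible(x)
}

# Fast metric pair for the permutation loop: mean degree and mean
# betweenness of the subgraph of `g` induced by vertex ids `vids`,
# denominators including isolated members.
induced_metrics <- function(g, vids) {
  sub <- igraph::induced_subgraph(g, vids)
  c(mean_degree = mean(igraph::degree(sub)),
    mean_betweenness = mean(igraph::betweenness(sub, directed = FALSE,
                                                normalized = FALSE)))
}

#' Permutation test of gene-list network topology
#'
#' Compares the observed mean node-degree and mean node-betweenness of the
#' list-induced subnetwork against `n_perm` subnetworks induced by gene
#' lists of the same size drawn uniformly without replacement from the
#' background node universe. For each metric: `Z = (obs - null mean) /
#' null sd` (sd with n - 1 denominator), two-sided normal p-value
#' `2 * (1 - pnorm(|Z|))`, upper-tail empirical p `(r + 1) / (n_perm + 1)`
#' with `r` the number of null values >= observed, and fold enrichment
#' `obs / null mean`. Listed genes absent from the background stay in the
#' observed denominators as isolated nodes.
#'
#' @param background a `gene_network` from [build_background()].
#' @param gene_list character vector of list genes.
#' @param n_perm number of random lists (>= 2; 1000 in routine use).
#' @param seed integer seed for the resampling stream.
#' @return object of class `permutation_null`: per-metric list with
#'   `observed`, `null_mean`, `null_sd`, `z`, `p_normal`, `p_empirical`,
#'   `fold`, `null_values`; plus `n_perm`, `seed`, `list_size`.
#' @export
permutation_z_test <- function(background, gene_list, n_perm = 1000,
                               seed = 1L) {
  stopifnot(inherits(background, "gene_network"))
  gene_list <- unique(as.character(gene_list))
  n_perm <- check_count(n_perm, "n_perm", min = 2L)
  universe <- background$nodes$gene
  if (length(gene_list) > length(universe)) {
    mn_data_error("gene_list is larger than the background universe")
  }
  obs_net <- induce_subnetwork(background, gene_list)
  obs <- topology_summary(obs_net)
  observed <- c(mean_degree = obs$mean_degree,
                mean_betweenness = obs$mean_betweenness)

  g <- as_igraph_simple(background)
  k <- length(gene_list)
  null_mat <- with_rng(seed, {
    vapply(seq_len(n_perm), function(i) {
      induced_metrics(g, sample(universe, k))
    }, numeric(2))
  })

  metrics <- lapply(rownames(null_mat), function(m) {
    nv <- null_mat[m, ]
    mu <- mean(nv)
    sdev <- stats::sd(nv)
    if (!is.finite(sdev) || sdev == 0) {
      mn_degenerate_error(sprintf(
        "degenerate permutation null for %s: sd = 0 over %d replicates (null mean %.6g)",
        m, n_perm, mu))
    }
    z <- (observed[[m]] - mu) / sdev
    list(observed = observed[[m]], null_mean = mu, null_sd = sdev,
         z = z, p_normal = zscore_to_pvalue(z),
         p_empirical = (sum(nv >= observed[[m]]) + 1) / (n_perm + 1),
         fold = if (mu > 0) observed[[m]] / mu else NA_real_,
         null_values = nv)
  })
  names(metrics) <- rownames(null_mat)
  structure(c(metrics, list(n_perm = n_perm, seed = as.integer(seed),
                            list_size = k)),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("permutation_null: list size %d, %d permutations, seed %d\n",
              x$list_size, x$n_perm, x$seed))
  for (m in c("mean_degree", "mean_betweenness")) {
    s <- x[[m]]
    cat(sprintf(
      "  %-16s obs %.4f null %.4f+-%.4f  %.2fx  Z = %.2f  p = %.3g (empirical %.3g)\n",
      m, s$observed, s$null_mean, s$null_sd, s$fold, s$z, s$p_normal,
      s$p_empirical))
  }
  invisible(x)
}

#' Two-sided normal p-value for a Z-score
#'
#' @param z finite Z-score.
#' @return `2 * (1 - pnorm(|z|))`.
#' @export
zscore_to_pvalue <- function(z) {
  stopifnot(all(is.finite(z)))
  2 * stats::pnorm(abs(z), lower.tail = FALSE)
}

#' Restrict a network to genes annotated to a term set
#'
#' Keeps the nodes whose propagated annotations include any term in
#' `term_set` (connectors are retained only if themselves annotated) and
#' re-induces the edges among them.
#'
#' @param net a `gene_network`.
#' @param annotations an `annotation_set` from [propagate_annotations()].
#' @param term_set non-empty character vector of term ids.
#' @return the restricted `gene_network`.
#' @export
go_filtered_subnetwork <- function(net, annotations, term_set) {
  stopifnot(inherits(net, "gene_network"),
            inherits(annotations, "annotation_set"))
  term_set <- unique(as.character(term_set))
  if (length(term_set) == 0L) mn_data_error("term_set is empty")
  annotated <- unique(unlist(annotations$term_genes[
    intersect(term_set, names(annotations$term_genes))], use.names = FALSE))
  keep_nodes <- net$nodes[net$nodes$gene %in% annotated, , drop = FALSE]
  if (nrow(keep_nodes) == 0L) {
    warning("no network node is annotated to the requested terms")
  }
  keep <- net$edges$gene_a %in% keep_nodes$gene &
    net$edges$gene_b %in% keep_nodes$gene
  edges <- net$edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  rownames(keep_nodes) <- NULL
  new_gene_network(edges, keep_nodes)
}

#' Write a network as SIF
#'
#' @param net a `gene_network`.
#' @param path output file; one `gene_a TAB type TAB gene_b` line per
#'   typed edge record.
#' @return invisibly, the path.
#' @export
write_network_sif <- function(net, path) {
  stopifnot(inherits(net, "gene_network"))
  lines <- sprintf("%s\t%s\t%s", net$edges$gene_a, net$edges$type,
                   net$edges$gene_b)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a network as GraphML with node attributes
#'
#' Cytoscape-compatible GraphML carrying `is_list_gene`, `is_connector`
#' and `flagged_isolated` on nodes and `type`/`weight` on edges (typed
#' parallel records preserved).
#'
#' @param net a `gene_network`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_network_graphml <- function(net, path) {
  stopifnot(inherits(net, "gene_network"))
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write permutation-test results as JSON
#'
#' @param perm a `permutation_null`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_netstat_json <- function(perm, path) {
  stopifnot(inherits(perm, "permutation_null"))
  out <- list(n_perm = perm$n_perm, seed = perm$seed,
              list_size = perm$list_size)
  for (m in c("mean_degree", "mean_betweenness")) {
    s <- perm[[m]]
    out[[m]] <- s[c("observed", "null_mean", "null_sd", "z", "p_normal",
                    "p_empirical", "fold")]
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
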