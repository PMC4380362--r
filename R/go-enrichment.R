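#' @title Term enrichment with elim de-correlation
#' @description
#' Gene-set over-representation analysis on a rooted ontology DAG:
#' true-path annotation propagation, exact hypergeometric upper-tail
#' tests, bottom-up elimination of significant child terms' genes from
#' their ancestors (de-correlating the term graph into conditionally
#' independent tests), and Benjamini-Yekutieli false-discovery-rate
#' control valid under arbitrary dependence.
#' @name go-enrichment
NULL

#' Construct an ontology DAG from child-parent edges
#'
#' @param parent_edges data.frame with columns `child`, `parent` (term
#'   ids); `is_a`-style edges only.
#' @param terms optional character vector of all term ids (defaults to the
#'   ids appearing in `parent_edges`); terms without a parent are roots.
#' @return object of class `go_dag` with fields `terms`, `parent_edges`,
#'   `roots` and `depth` (longest path from a root, used for bottom-up
#'   processing order).
#' @export
go_dag <- function(parent_edges, terms = NULL) {
  check_cols(parent_edges, c("child", "parent"), "ontology edge table")
  parent_edges <- data.frame(child = as.character(parent_edges$child),
                             parent = as.character(parent_edges$parent),
                             stringsAsFactors = FALSE)
  terms <- sort(unique(c(terms, parent_edges$child, parent_edges$parent)))
  if (length(terms) < 1L) mn_data_error("an ontology needs at least 1 term")
  g <- igraph::graph_from_data_frame(
    parent_edges[, c("child", "parent")], directed = TRUE,
    vertices = data.frame(name = terms))
  if (!igraph::is_dag(g)) mn_data_error("ontology edges contain a cycle")
  roots <- terms[!(terms %in% parent_edges$child)]
  if (length(roots) == 0L) mn_data_error("ontology has no root term")
  reach <- igraph::distances(g, mode = "out")  # child -> ancestor hops
  unreachable <- terms[apply(reach[, roots, drop = FALSE], 1,
                             function(d) all(!is.finite(d)))]
  unreachable <- setdiff(unreachable, roots)
  if (length(unreachable) > 0L) {
    mn_data_error(sprintf("term(s) cannot reach a root: %s",
                          paste(unreachable, collapse = ", ")))
  }
  # Longest child->parent path length to any node = depth below the root
  # system; computed on the reversed graph by topological relaxation.
  topo <- names(igraph::topo_sort(g, mode = "out"))  # children first
  depth <- stats::setNames(rep(0L, length(terms)), terms)
  for (t in rev(topo)) {  # parents first
    for (ch in names(igraph::neighbors(g, t, mode = "in"))) {
      depth[ch] <- max(depth[ch], depth[t] + 1L)
    }
  }
  structure(list(terms = terms, parent_edges = parent_edges,
                 roots = roots, depth = depth, graph = g),
            class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("go_dag: %d terms, %d is_a edges, root(s): %s, max depth %d\n",
              length(x$terms), nrow(x$parent_edges),
              paste(x$roots, collapse = ", "), max(x$depth)))
  invisible(x)
}

# term -> all ancestor terms (transitive closure; term itself excluded)
dag_ancestors <- function(dag) {
  anc <- stats::setNames(vector("list", length(dag$terms)), dag$terms)
  topo <- names(igraph::topo_sort(dag$graph, mode = "out"))
  parents <- split(dag$parent_edges$parent, dag$parent_edges$child)
  for (t in rev(topo)) {  # parents before children
    ps <- parents[[t]]
    anc[[t]] <- if (is.null(ps)) character(0) else
      unique(c(ps, unlist(anc[ps], use.names = FALSE)))
  }
  anc
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' A gene annotated to a term is implicitly annotated to every ancestor of
#' that term; in a diamond (two paths to the root) each ancestor is
#' counted once per gene.
#'
#' @param dag a [go_dag()].
#' @param direct data.frame with columns `gene`, `term` (direct
#'   annotations).
#' @return object of class `annotation_set` with `direct`, `propagated`
#'   (both long data.frames), `gene_terms` and `term_genes` (named lists
#'   of character vectors) and `universe` (genes with >= 1 annotation).
#' @export
propagate_annotations <- function(dag, direct) {
  stopifnot(inherits(dag, "go_dag"))
  check_cols(direct, c("gene", "term"), "annotation table")
  direct <- data.frame(gene = as.character(direct$gene),
                       term = as.character(direct$term),
                       stringsAsFactors = FALSE)
  unknown <- sort(unique(setdiff(direct$term, dag$terms)))
  if (length(unknown) > 0L) {
    mn_data_error(sprintf("annotation term(s) not in ontology: %s",
                          paste(unknown, collapse = ", ")))
  }
  anc <- dag_ancestors(dag)
  gene_terms <- lapply(split(direct$term, direct$gene), function(ts) {
    sort(unique(c(ts, unlist(anc[unique(ts)], use.names = FALSE))))
  })
  propagated <- data.frame(
    gene = rep(names(gene_terms), lengths(gene_terms)),
    term = unlist(gene_terms, use.names = FALSE),
    stringsAsFactors = FALSE)
  term_genes <- lapply(split(propagated$gene, propagated$term), unique)
  structure(list(direct = direct, propagated = propagated,
                 gene_terms = gene_terms, term_genes = term_genes,
                 universe = sort(names(gene_terms))),
            class = "annotation_set")
}

#' Exact hypergeometric upper-tail p-value
#'
#' Probability of drawing at least `k` annotated genes when sampling `n`
#' genes from a universe of `N` genes of which `K` are annotated.
#'
#' @param k study genes annotated to the term.
#' @param K universe genes annotated to the term.
#' @param n study-set size.
#' @param N universe size.
#' @return P(X >= k) under hypergeometric(N, K, n).
#' @export
hypergeometric_pvalue <- function(k, K, n, N) {
  for (v in list(k, K, n, N)) check_count(v, "hypergeometric count")
  if (K > N || n > N || k > min(K, n)) {
    mn_data_error("inconsistent hypergeometric counts: need k <= min(K, n), K <= N, n <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Enrichment with elimination-based de-correlation
#'
#' Terms are tested children-before-parents (decreasing depth; ties broken
#' by term id). When a term's raw hypergeometric p-value falls below
#' `elim_cutoff`, its propagated gene set is removed from all of its
#' ancestors' gene sets — on both the universe side (K) and the study side
#' (k) — before those ancestors are tested, so high-level terms are not
#' flagged merely for containing an enriched descendant. Terms without
#' significant descendants keep `p_elim = p_raw`. Benjamini-Yekutieli
#' correction is applied to the eliminated p-values.
#'
#' @param dag a [go_dag()].
#' @param annotations an [propagate_annotations()] result (or a direct
#'   annotation data.frame, which is propagated first).
#' @param study_set character vector of study genes; must be a subset of
#'   the annotated universe.
#' @param elim_cutoff raw-p threshold triggering elimination (default
#'   0.01; 0 disables elimination).
#' @param alpha FDR level for the significance flag.
#' @return data.frame, one row per term with >= 1 annotated gene: `term`,
#'   `k`, `K`, `n`, `N`, `p_raw`, `p_elim`, `p_by`, `neg_log10_by`,
#'   `significant`, ordered by `p_by` then term id.
#' @export
elim_enrichment <- function(dag, annotations, study_set,
                            elim_cutoff = 0.01, alpha = 0.05) {
  stopifnot(inherits(dag, "go_dag"))
  if (!inherits(annotations, "annotation_set")) {
    annotations <- propagate_annotations(dag, annotations)
  }
  study_set <- unique(as.character(study_set))
  outside <- setdiff(study_set, annotations$universe)
  if (length(outside) > 0L) {
    mn_data_error(sprintf(
      "study gene(s) outside the annotated universe: %s",
      paste(sort(outside), collapse = ", ")))
  }
  check_prob(elim_cutoff, "elim_cutoff")

  term_genes <- annotations$term_genes
  tested <- names(term_genes)[lengths(term_genes) > 0L]
  if (length(tested) == 0L) mn_data_error("no term has any annotated gene")
  N <- length(annotations$universe)
  n <- length(study_set)

  # Bottom-up order: deepest level first, ties by term id.
  ord <- tested[order(-dag$depth[tested], tested)]
  anc <- dag_ancestors(dag)
  eliminated <- stats::setNames(
    replicate(length(tested), character(0), simplify = FALSE), tested)

  res <- data.frame(term = ord, k = NA_integer_, K = NA_integer_,
                    n = n, N = N, p_raw = NA_real_, p_elim = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ord)) {
    t <- ord[i]
    genes <- term_genes[[t]]
    K_raw <- length(genes)
    k_raw <- length(intersect(genes, study_set))
    p_raw <- stats::phyper(k_raw - 1, K_raw, N - K_raw, n,
                           lower.tail = FALSE)
    kept <- setdiff(genes, eliminated[[t]])
    K_el <- length(kept)
    k_el <- length(intersect(kept, study_set))
    p_elim <- stats::phyper(k_el - 1, K_el, N - K_el, n,
                            lower.tail = FALSE)
    res$k[i] <- k_raw; res$K[i] <- K_raw
    res$p_raw[i] <- p_raw; res$p_elim[i] <- p_elim
    if (elim_cutoff > 0 && p_raw < elim_cutoff) {
      for (a in intersect(anc[[t]], tested)) {
        eliminated[[a]] <- union(eliminated[[a]], genes)
      }
    }
  }

  by <- benjamini_yekutieli(res$p_elim, alpha = alpha)
  res$p_by <- by$p_adjusted
  res$neg_log10_by <- -log10(pmax(res$p_by, .Machine$double.xmin))
  res$significant <- by$significant
  res <- res[order(res$p_by, res$term), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "elim_cutoff") <- elim_cutoff
  attr(res, "method") <- "elim (hard gene removal at cutoff), hypergeometric upper tail, BY FDR"
  res
}

#' Benjamini-Yekutieli adjustment
#'
#' FDR control valid under arbitrary dependence:
#' `adj_i = min(1, min_{j >= i} p_(j) * m * c(m) / j)` with
#' `c(m) = sum_{j=1..m} 1/j`, mapped back to input order.
#'
#' @param p_list numeric vector of p-values in \[0, 1\].
#' @param alpha FDR level for the significance flags.
#' @return list with `p_adjusted` (same order as input) and `significant`
#'   (`p_adjusted <= alpha`); empty input gives empty vectors.
#' @export
benjamini_yekutieli <- function(p_list, alpha = 0.05) {
  if (length(p_list) == 0L) {
    return(list(p_adjusted = numeric(0), significant = logical(0)))
  }
  check_prob(p_list, "p-values")
  check_prob(alpha, "alpha")
  adj <- stats::p.adjust(p_list, method = "BY")
  list(p_adjusted = adj, significant = adj <= alpha)
}

#' Read GMT gene-set annotations as a long data.frame
#'
#' @param path GMT file: `term TAB description TAB gene...` per line.
#' @return data.frame `gene`, `term`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0L) {
    mn_data_error(sprintf("malformed GMT line(s): %s",
                          paste(bad, collapse = ", ")))
  }
  do.call(rbind, lapply(parts, function(p) {
    data.frame(gene = p[-(1:2)], term = p[1], stringsAsFactors = FALSE)
  }))
}

#' Write a long annotation data.frame as GMT
#'
#' @param annotations data.frame `gene`, `term`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_gmt <- function(annotations, path) {
  check_cols(annotations, c("gene", "term"), "annotation table")
  sets <- split(annotations$gene, annotations$term)
  lines <- vapply(names(sets), function(t) {
    paste(c(t, t, sort(unique(sets[[t]]))), collapse = "\t")
  }, character(1))
  writeLines(lines[order(names(sets))], path, useBytes = TRUE)
  invisible(path)
}
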