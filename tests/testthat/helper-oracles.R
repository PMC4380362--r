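# Independent oracles, implemented without the code paths they check.

# Brute-force betweenness: for every unordered node pair, enumerate all
# shortest paths by level-increasing DFS over BFS distances and credit
# interior nodes with the fraction of paths passing through them.
brute_betweenness <- function(adj) {
  nodes <- names(adj)
  bc <- stats::setNames(numeric(length(nodes)), nodes)
  bfs_dist <- function(s) {
    d <- stats::setNames(rep(Inf, length(nodes)), nodes)
    d[s] <- 0
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (!is.finite(d[w])) { d[w] <- d[v] + 1; queue <- c(queue, w) }
      }
    }
    d
  }
  for (i in seq_along(nodes)) {
    s <- nodes[i]
    d <- bfs_dist(s)
    for (j in seq_along(nodes)) {
      if (j <= i) next
      t <- nodes[j]
      if (!is.finite(d[t])) next
      paths <- list()
      walk <- function(v, path) {
        if (v == t) { paths[[length(paths) + 1]] <<- path; return() }
        for (w in adj[[v]]) {
          if (d[w] == d[v] + 1 && d[w] <= d[t]) walk(w, c(path, w))
        }
      }
      walk(s, s)
      for (p in paths) {
        for (v in setdiff(p, c(s, t))) bc[v] <- bc[v] + 1 / length(paths)
      }
    }
  }
  bc
}

# Random undirected simple graph as an edge table + adjacency list.
random_graph_fixture <- function(n, p) {
  genes <- sprintf("n%02d", seq_len(n))
  pairs <- t(utils::combn(genes, 2))
  keep <- stats::runif(nrow(pairs)) < p
  edges <- data.frame(gene_a = pairs[keep, 1], gene_b = pairs[keep, 2],
                      type = rep("physical", sum(keep)),
                      stringsAsFactors = FALSE)
  adj <- stats::setNames(replicate(n, character(0), simplify = FALSE),
                         genes)
  for (r in seq_len(nrow(edges))) {
    a <- edges$gene_a[r]; b <- edges$gene_b[r]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  list(genes = genes, edges = edges, adj = adj)
}

# Exhaustive hypergeometric upper tail: enumerate every n-subset of an
# N-gene universe whose first K genes are annotated.
enum_hyper_tail <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Mean degree and betweenness of a gene_network via the brute-force path
# enumerator, isolated nodes included.
brute_topology <- function(net) {
  genes <- net$nodes$gene
  adj <- stats::setNames(replicate(length(genes), character(0),
                                   simplify = FALSE), genes)
  ed <- unique(net$edges[, c("gene_a", "gene_b")])
  for (r in seq_len(nrow(ed))) {
    a <- ed$gene_a[r]; b <- ed$gene_b[r]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  list(mean_degree = mean(lengths(adj)),
       betweenness = brute_betweenness(adj),
       mean_betweenness = mean(brute_betweenness(adj)))
}
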