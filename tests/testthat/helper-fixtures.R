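# Small fixtures built in code.

# Two-term toy ontology: root R annotates genes x1..x10, child A annotates
# x1..x5; study set {x1..x4}.
toy_enrichment_fixture <- function() {
  list(dag = go_dag(data.frame(child = "A", parent = "R",
                               stringsAsFactors = FALSE)),
       direct = data.frame(
         gene = c(paste0("x", 1:10), paste0("x", 1:5)),
         term = c(rep("R", 10), rep("A", 5)),
         stringsAsFactors = FALSE),
       study = paste0("x", 1:4))
}

path_network <- function() {
  build_background(data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"),
                              type = "physical", stringsAsFactors = FALSE))
}

star_network <- function() {
  build_background(data.frame(gene_a = "hub",
                              gene_b = c("l1", "l2", "l3"),
                              type = "physical", stringsAsFactors = FALSE))
}

# Erdos-Renyi background over n genes, single edge type.
er_background <- function(n, p, seed) {
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n))
  pairs <- t(utils::combn(genes, 2))
  keep <- stats::runif(nrow(pairs)) < p
  build_background(data.frame(gene_a = pairs[keep, 1],
                              gene_b = pairs[keep, 2],
                              type = "physical", stringsAsFactors = FALSE))
}
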