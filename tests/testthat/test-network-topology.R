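test_that("background construction filters, normalises and collapses", {
  tab <- data.frame(
    gene_a = c("a", "b", "c", "d", "b"),
    gene_b = c("b", "c", "d", "e", "a"),
    type = c("physical", "coexpression", "coexpression", "genetic",
             "genetic"))
  bg <- build_background(tab)
  # 2 co-expression rows dropped; a-b kept as two typed records
  expect_equal(nrow(bg$edges), 3L)
  expect_false("coexpression" %in% bg$edges$type)
  expect_true(all(bg$edges$gene_a < bg$edges$gene_b))
  # typed parallel records collapse to one simple edge for metrics
  dup <- build_background(data.frame(gene_a = c("a", "a"),
                                     gene_b = c("b", "b"),
                                     type = c("physical", "genetic")))
  expect_equal(nrow(dup$edges), 2L)
  expect_equal(topology_summary(dup)$n_edges, 1L)

  empty <- build_background(data.frame(gene_a = character(),
                                       gene_b = character(),
                                       type = character()))
  expect_equal(nrow(empty$nodes), 0L)
  expect_error(topology_summary(empty), "no nodes")

  bad <- data.frame(gene_a = c("a", ""), gene_b = c("b", "c"),
                    type = c("physical", "physical"))
  expect_error(build_background(bad), "malformed")
  expect_warning(build_background(data.frame(gene_a = "a", gene_b = "a",
                                             type = "physical")),
                 "self-loop")
})

test_that("list subnetwork induction keeps absent genes as flagged isolates", {
  bg <- path_network()  # a - b - c
  net <- induce_subnetwork(bg, c("a", "b"))
  expect_equal(nrow(net$edges), 1L)
  expect_true(all(net$nodes$is_list_gene))

  with_missing <- induce_subnetwork(bg, c("a", "b", "zz"))
  zz <- with_missing$nodes[with_missing$nodes$gene == "zz", ]
  expect_true(zz$flagged_isolated)
  expect_equal(topology_summary(with_missing)$n_nodes, 3L)

  ends <- induce_subnetwork(bg, c("a", "c"))
  expect_equal(nrow(ends$edges), 0L)
  expect_equal(nrow(ends$nodes), 2L)
})

test_that("connector expansion links list genes through shared neighbors", {
  # c is adjacent to both listed genes a and b
  bg <- build_background(data.frame(gene_a = c("a", "b"),
                                    gene_b = c("c", "c"),
                                    type = "physical"))
  net <- expand_with_connectors(bg, c("a", "b"), seed_gene = "a")
  expect_true("c" %in% net$nodes$gene)
  expect_true(net$nodes$is_connector[net$nodes$gene == "c"])
  expect_equal(attr(net, "n_newly_connected"), 2L)
  expect_equal(topology_summary(net)$n_edges, 2L)

  # no outside node touches two list genes and the seed has no 2-path
  # to another list gene: expansion reduces to plain induction
  bg2 <- path_network()
  net2 <- expand_with_connectors(bg2, c("a", "b"), seed_gene = "b")
  expect_equal(sum(net2$nodes$is_connector), 0L)
  expect_equal(nrow(net2$edges),
               nrow(induce_subnetwork(bg2, c("a", "b"))$edges))
  expect_error(expand_with_connectors(bg2, c("a", "b"), seed_gene = "zz"),
               "member")
})

test_that("topology summaries match hand-checkable graphs", {
  path <- topology_summary(induce_subnetwork(path_network(),
                                             c("a", "b", "c")))
  expect_equal(path$mean_degree, 4 / 3)
  expect_equal(path$mean_betweenness, 1 / 3)

  star <- topology_summary(induce_subnetwork(star_network(),
                                             c("hub", "l1", "l2", "l3")))
  expect_equal(star$mean_betweenness, 3 / 4)
  expect_equal(star$mean_degree, 6 / 4)

  lonely <- induce_subnetwork(path_network(), c("a", "zz"))
  s <- topology_summary(lonely)
  expect_equal(s$mean_degree, 0)
  expect_equal(s$mean_betweenness, 0)
})

test_that("mean degree equals 2E/N on generated networks", {
  set.seed(31)
  for (i in 1:10) {
    fx <- random_graph_fixture(sample(5:30, 1), runif(1, 0.1, 0.5))
    if (nrow(fx$edges) == 0) next
    net <- induce_subnetwork(build_background(fx$edges), fx$genes)
    s <- topology_summary(net)
    expect_equal(s$mean_degree, 2 * s$n_edges / s$n_nodes)
  }
})

test_that("betweenness agrees with brute-force path enumeration", {
  set.seed(17)
  for (i in 1:30) {
    fx <- random_graph_fixture(sample(4:8, 1), runif(1, 0.2, 0.8))
    if (nrow(fx$edges) == 0) next
    net <- induce_subnetwork(build_background(fx$edges), fx$genes)
    expect_equal(topology_summary(net)$mean_betweenness,
                 brute_topology(net)$mean_betweenness, tolerance = 1e-10)
  }
})

test_that("permutation test is seed-stable and internally consistent", {
  bg <- er_background(80, 0.08, seed = 21)
  gl <- bg$nodes$gene[1:12]
  p1 <- permutation_z_test(bg, gl, n_perm = 50, seed = 9)
  p2 <- permutation_z_test(bg, gl, n_perm = 50, seed = 9)
  expect_identical(p1, p2)
  for (m in c("mean_degree", "mean_betweenness")) {
    s <- p1[[m]]
    expect_equal(s$z, (s$observed - mean(s$null_values)) /
                   sd(s$null_values))
    expect_equal(s$p_normal, zscore_to_pvalue(s$z))
    expect_equal(s$fold, s$observed / mean(s$null_values))
    expect_equal(s$p_empirical,
                 (sum(s$null_values >= s$observed) + 1) / 51)
  }
  expect_error(permutation_z_test(bg, gl, n_perm = 1, seed = 1), "n_perm")
})

test_that("a vertex-transitive background degenerates the null", {
  pairs <- t(utils::combn(sprintf("k%02d", 1:8), 2))
  bg <- build_background(data.frame(gene_a = pairs[, 1],
                                    gene_b = pairs[, 2],
                                    type = "physical"))
  expect_error(permutation_z_test(bg, bg$nodes$gene[1:3], n_perm = 20,
                                  seed = 2),
               class = "modnet_degenerate_error")
})

test_that("Z-scores convert to two-sided normal p-values", {
  expect_equal(round(zscore_to_pvalue(2.75), 3), 0.006)
  expect_equal(zscore_to_pvalue(0), 1)
  expect_lt(abs(zscore_to_pvalue(1.959964) - 0.05), 1e-6)
})

test_that("annotation filtering restricts nodes and crossing edges", {
  bg <- path_network()
  net <- induce_subnetwork(bg, c("a", "b", "c"))
  dag <- go_dag(data.frame(child = "t", parent = "root"))
  ann_all <- propagate_annotations(dag, data.frame(
    gene = c("a", "b", "c"), term = "t"))
  same <- go_filtered_subnetwork(net, ann_all, "t")
  expect_setequal(same$nodes$gene, c("a", "b", "c"))
  expect_equal(nrow(same$edges), nrow(net$edges))

  ann_half <- propagate_annotations(dag, data.frame(gene = c("a", "b"),
                                                    term = "t"))
  half <- go_filtered_subnetwork(net, ann_half, "t")
  expect_setequal(half$nodes$gene, c("a", "b"))
  expect_equal(nrow(half$edges), 1L)  # b-c crosses the boundary

  ann_none <- propagate_annotations(dag, data.frame(gene = "q",
                                                    term = "t"))
  expect_warning(none <- go_filtered_subnetwork(net, ann_none, "t"),
                 "no network node")
  expect_equal(nrow(none$nodes), 0L)
  expect_error(go_filtered_subnetwork(net, ann_all, character()), "empty")
})

test_that("network exports carry attributes and round-trip", {
  bg <- star_network()
  net <- expand_with_connectors(bg, c("l1", "l2"), seed_gene = "l1")
  gml <- withr::local_tempfile(fileext = ".graphml")
  sif <- withr::local_tempfile(fileext = ".sif")
  write_network_graphml(net, gml)
  write_network_sif(net, sif)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::vertex_attr(g, "name"), net$nodes$gene)
  expect_true("is_connector" %in% igraph::vertex_attr_names(g))
  expect_equal(length(readLines(sif)), nrow(net$edges))

  perm <- permutation_z_test(er_background(40, 0.15, seed = 3),
                             sprintf("g%04d", 1:8), n_perm = 30, seed = 4)
  js <- withr::local_tempfile(fileext = ".json")
  write_netstat_json(perm, js)
  back <- jsonlite::read_json(js)
  expect_equal(back$n_perm, 30L)
  expect_equal(back$mean_degree$z, perm$mean_degree$z)
})
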