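test_that("generators are byte-identical under a fixed seed", {
  s <- interactome_spec(n_genes = 60, module_size = 8, seed = 7)
  expect_identical(generate_interactome(s), generate_interactome(s))

  o <- ontology_spec(n_terms = 15, n_genes = 40, seed = 7)
  expect_identical(generate_ontology(o), generate_ontology(o))

  sc <- screen_spec(seed = 7)
  expect_identical(generate_screen_table(sc), generate_screen_table(sc))

  expect_identical(generate_orthology_table(30, seed = 7),
                   generate_orthology_table(30, seed = 7))
})

test_that("interactome spec validation rejects impossible parameters", {
  expect_error(interactome_spec(n_genes = 10, module_size = 11),
               "module_size")
  expect_error(interactome_spec(background_edge_prob = 1.2), "\\[0, 1\\]")
  expect_error(interactome_spec(type_mix = c(physical = 0.5,
                                             genetic = 0.2)),
               "sum to 1")
})

test_that("extreme edge probabilities force the planted module exactly", {
  m <- 6
  net <- generate_interactome(interactome_spec(
    n_genes = 40, background_edge_prob = 0, module_size = m,
    module_edge_prob = 1, seed = 3))
  # every within-module pair carries one edge per non-co-expression type
  expect_equal(nrow(net$edges), choose(m, 2) * 4)
  expect_true(all(net$edges$gene_a %in% net$module_genes))
  expect_true(all(net$edges$gene_b %in% net$module_genes))
  expect_true(all(net$edges$gene_a < net$edges$gene_b))
  expect_false(any(duplicated(net$edges[, c("gene_a", "gene_b", "type")])))
  expect_false("coexpression" %in% net$edges$type)
})

test_that("without a densified module the planted list's Z is calibrated", {
  zs <- vapply(1:300, function(i) {
    net <- generate_interactome(interactome_spec(
      n_genes = 100, background_edge_prob = 0.05, module_size = 10,
      module_edge_prob = 0.05, seed = 20000L + i))
    bg <- build_background(net$edges)
    permutation_z_test(bg, net$module_genes, n_perm = 100,
                       seed = 70000L + i)$mean_degree$z
  }, numeric(1))
  expect_lt(abs(mean(zs)), 0.2)
})

test_that("ontology output is a rooted DAG obeying the true-path rule", {
  ont <- generate_ontology(ontology_spec(n_terms = 20, n_genes = 50,
                                         seed = 11))
  dag <- go_dag(ont$parent_edges, ont$terms)
  expect_identical(dag$roots, "T0001")
  ann <- propagate_annotations(dag, ont$annotations)
  # every gene annotated, and the root annotates all of them
  expect_setequal(ann$universe, ont$genes)
  expect_setequal(ann$term_genes[["T0001"]], ont$genes)
  expect_error(ontology_spec(n_terms = 1), "n_terms")
})

test_that("an unenriched planted term yields calibrated hypergeometric p", {
  ps <- vapply(1:500, function(i) {
    ont <- generate_ontology(ontology_spec(
      n_terms = 20, n_genes = 100, study_size = 20,
      planted_enrichment_odds = 1, seed = i))
    dag <- go_dag(ont$parent_edges, ont$terms)
    ann <- propagate_annotations(dag, ont$annotations)
    tg <- ann$term_genes[[ont$planted_term]]
    if (is.null(tg)) return(1)
    hypergeometric_pvalue(length(intersect(tg, ont$study_genes)),
                          length(tg), length(ont$study_genes),
                          length(ann$universe))
  }, numeric(1))
  # a discrete upper-tail test is conservative: the rejection rate must
  # not exceed nominal plus Monte-Carlo error, and the p distribution
  # must not lean towards small values
  expect_lte(mean(ps < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 500))
  expect_gte(mean(ps), 0.5)
})

test_that("screen tables realise the specified genotype structure", {
  # degenerate noise: zero sd pins every fly at the genotype mean
  scr0 <- generate_screen_table(screen_spec(
    genotype_means = c(control = 100, tester = 30),
    genotype_sds = c(control = 0, tester = 0),
    viability_probs = c(control = 1, tester = 0.8),
    climbing_decline = list(control = rep(0.8, 5), tester = rep(0.4, 5)),
    seed = 2))
  expect_true(all(scr0$eye$area[scr0$eye$genotype == "control"] == 100))
  expect_true(all(scr0$eye$area[scr0$eye$genotype == "tester"] == 30))
  # certain eclosion recovers the expected count exactly
  ctrl <- scr0$viability[scr0$viability$genotype == "control", ]
  expect_equal(ctrl$observed, ctrl$expected)
  # 10 trials x 5 time points, counts bounded by vial size
  expect_equal(nrow(scr0$climbing), 2 * 5 * 10)
  expect_true(all(scr0$climbing$n_above <= scr0$climbing$n_total))

  # sample means recover the planted means within 3 standard errors
  scr <- generate_screen_table(screen_spec(
    genotype_means = c(control = 100, tester = 30),
    genotype_sds = c(control = 5, tester = 5),
    n_flies_per_genotype = 20,
    viability_probs = c(control = 1, tester = 0.8),
    climbing_decline = list(control = rep(0.8, 5), tester = rep(0.4, 5)),
    seed = 3))
  means <- tapply(scr$eye$area, scr$eye$genotype, mean)
  se3 <- 3 * 5 / sqrt(20)
  expect_lt(abs(means[["control"]] - 100), se3)
  expect_lt(abs(means[["tester"]] - 30), se3)
  expect_true(all(scr$eye$area >= 0))
})

test_that("orthology generator respects mapping rate and vote support", {
  # full mapping with unanimous 10-algorithm support survives the filter
  full <- generate_orthology_table(20, mapping_rate = 1,
                                   vote_distribution = c(rep(0, 9), 1),
                                   seed = 5)
  kept <- filter_candidates(full, min_score = 2)
  expect_equal(map_gene_list(sprintf("g%04d", 1:20), kept)$coverage, 1)

  # single-algorithm support is removed entirely
  weak <- generate_orthology_table(20, mapping_rate = 1,
                                   vote_distribution = c(1, rep(0, 9)),
                                   seed = 5)
  expect_equal(nrow(filter_candidates(weak, min_score = 2)), 0)

  # mapped-gene count falls in the binomial 99% interval
  tab <- generate_orthology_table(85, mapping_rate = 0.9, seed = 11)
  n_mapped <- length(unique(tab$source_gene))
  expect_gte(n_mapped, qbinom(0.005, 85, 0.9))
  expect_lte(n_mapped, qbinom(0.995, 85, 0.9))
})
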