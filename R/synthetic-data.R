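#' @title Synthetic inputs for modifier-screen analysis
#' @description
#' Seeded generators that emulate the statistical structure the pipeline
#' assumes: a multi-type interactome with a planted high-connectivity
#' module, a small rooted ontology DAG with a planted enriched term,
#' screen tables with genotype-dependent means, and a cross-species
#' orthology candidate table with per-algorithm vote counts. Identical
#' specifications and seeds produce byte-identical outputs.
#' @name synthetic-data
NULL

INTERACTION_TYPES <- c("physical", "genetic", "colocalization",
                       "predicted", "coexpression")

gene_ids <- function(n, prefix = "g") sprintf("%s%04d", prefix, seq_len(n))

#' Specify a synthetic interactome
#'
#' Per-type Erdos-Renyi random graph over gene pairs with an independently
#' densified planted module. Each unordered gene pair acquires an edge of
#' interaction type `t` with probability `background_edge_prob * type_mix[t]
#' * n_active_types` (capped at 1), where `n_active_types` counts the types
#' with positive mix, so a uniform mix reproduces `background_edge_prob`
#' per pair per type and a skewed mix tilts the composition while keeping
#' the expected edge total fixed. Pairs inside the planted module use
#' `module_edge_prob` instead, for every type except co-expression —
#' co-expression edges are discarded when the analysis background is built,
#' so densifying them would not contribute planted signal.
#'
#' @param n_genes number of genes in the universe.
#' @param background_edge_prob per-pair, per-type edge probability outside
#'   the module.
#' @param type_mix named proportions over
#'   `c("physical","genetic","colocalization","predicted","coexpression")`;
#'   must sum to 1.
#' @param module_size number of genes in the planted module.
#' @param module_edge_prob per-pair, per-type edge probability inside the
#'   module (non-co-expression types).
#' @param seed integer seed.
#' @return an object of class `interactome_spec`.
#' @export
interactome_spec <- function(n_genes = 300,
                             background_edge_prob = 0.02,
                             type_mix = c(physical = 0.2, genetic = 0.2,
                                          colocalization = 0.2,
                                          predicted = 0.2,
                                          coexpression = 0.2),
                             module_size = 15,
                             module_edge_prob = 0.5,
                             seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes", min = 2L)
  module_size <- check_count(module_size, "module_size", min = 0L)
  if (module_size > n_genes) {
    mn_config_error("module_size must not exceed n_genes")
  }
  check_prob(background_edge_prob, "background_edge_prob")
  check_prob(module_edge_prob, "module_edge_prob")
  if (is.null(names(type_mix)) ||
      !all(names(type_mix) %in% INTERACTION_TYPES)) {
    mn_config_error(sprintf("type_mix names must be among: %s",
                            paste(INTERACTION_TYPES, collapse = ", ")))
  }
  check_prob(type_mix, "type_mix proportions")
  if (abs(sum(type_mix) - 1) > 1e-8) {
    mn_config_error("type_mix proportions must sum to 1")
  }
  structure(list(n_genes = n_genes,
                 background_edge_prob = background_edge_prob,
                 type_mix = type_mix,
                 module_size = module_size,
                 module_edge_prob = module_edge_prob,
                 seed = as.integer(seed)),
            class = "interactome_spec")
}

#' Generate a synthetic typed interactome
#'
#' @param spec an [interactome_spec()].
#' @return list with `edges` (data.frame `gene_a`, `gene_b`, `type`,
#'   `weight`; `gene_a < gene_b` lexicographically, one row per pair per
#'   type, deterministic row order), `module_genes` (character vector of
#'   planted-module members) and `genes` (the full universe).
#' @export
generate_interactome <- function(spec) {
  stopifnot(inherits(spec, "interactome_spec"))
  with_rng(spec$seed, {
    genes <- gene_ids(spec$n_genes)
    module_genes <- sort(sample(genes, spec$module_size))

    # All unordered pairs i < j, as index vectors.
    n <- spec$n_genes
    pair_i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
    pair_j <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n),
                     use.names = FALSE)
    in_module <- genes[pair_i] %in% module_genes &
      genes[pair_j] %in% module_genes

    active <- INTERACTION_TYPES[INTERACTION_TYPES %in%
                                  names(spec$type_mix)[spec$type_mix > 0]]
    n_active <- length(active)
    parts <- vector("list", n_active)
    for (t in seq_len(n_active)) {
      type <- active[t]
      scale <- spec$type_mix[[type]] * n_active
      p <- rep.int(min(1, spec$background_edge_prob * scale), length(pair_i))
      if (type != "coexpression") {
        p[in_module] <- min(1, spec$module_edge_prob * scale)
      }
      keep <- stats::runif(length(p)) < p
      if (any(keep)) {
        parts[[t]] <- data.frame(gene_a = genes[pair_i[keep]],
                                 gene_b = genes[pair_j[keep]],
                                 type = type,
                                 weight = round(stats::runif(sum(keep),
                                                             0.1, 1), 4),
                                 stringsAsFactors = FALSE)
      }
    }
    edges <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
    if (is.null(edges)) {
      edges <- data.frame(gene_a = character(), gene_b = character(),
                          type = character(), weight = numeric(),
                          stringsAsFactors = FALSE)
    }
    edges <- edges[order(edges$gene_a, edges$gene_b, edges$type), ,
                   drop = FALSE]
    rownames(edges) <- NULL
    list(edges = edges, module_genes = module_genes, genes = genes)
  })
}

#' Specify a synthetic ontology
#'
#' @param n_terms number of terms including the root (>= 2).
#' @param max_depth maximum depth of any term below the root.
#' @param n_genes number of annotated genes.
#' @param planted_term term id carrying the planted enrichment; defaults to
#'   the deepest-indexed term `sprintf("T%04d", n_terms)`.
#' @param planted_enrichment_odds odds by which the study set over-samples
#'   genes annotated (after propagation) to `planted_term`; 1 = no signal.
#' @param study_size number of genes designated as the study set.
#' @param seed integer seed.
#' @return an object of class `ontology_spec`.
#' @export
ontology_spec <- function(n_terms = 25,
                          max_depth = 4,
                          n_genes = 120,
                          planted_term = NULL,
                          planted_enrichment_odds = 1,
                          study_size = 20,
                          seed = 1L) {
  n_terms <- check_count(n_terms, "n_terms", min = 2L)
  max_depth <- check_count(max_depth, "max_depth", min = 1L)
  n_genes <- check_count(n_genes, "n_genes", min = 2L)
  study_size <- check_count(study_size, "study_size", min = 1L)
  if (study_size > n_genes) mn_config_error("study_size must not exceed n_genes")
  if (!is.finite(planted_enrichment_odds) || planted_enrichment_odds <= 0) {
    mn_config_error("planted_enrichment_odds must be positive")
  }
  planted_term <- planted_term %||% sprintf("T%04d", n_terms)
  structure(list(n_terms = n_terms, max_depth = max_depth,
                 n_genes = n_genes, planted_term = planted_term,
                 planted_enrichment_odds = planted_enrichment_odds,
                 study_size = study_size, seed = as.integer(seed)),
            class = "ontology_spec")
}

#' Generate a synthetic rooted ontology DAG with annotations
#'
#' Terms `T0001 ... T{n_terms}` form a DAG rooted at `T0001`: each later
#' term attaches to one uniformly chosen earlier term whose depth is below
#' `max_depth` (falling back to the root), and with probability 0.3 to a
#' second one, creating diamond motifs. Each gene receives one to three
#' direct annotations to uniformly chosen non-root terms. The study set is
#' drawn without replacement with weight `planted_enrichment_odds` for
#' genes whose propagated annotations include `planted_term`, weight 1
#' otherwise.
#'
#' @param spec an [ontology_spec()].
#' @return list with `parent_edges` (data.frame `child`, `parent`),
#'   `terms`, `annotations` (data.frame `gene`, `term`; direct only),
#'   `study_genes`, `planted_term`, `genes`.
#' @export
generate_ontology <- function(spec) {
  stopifnot(inherits(spec, "ontology_spec"))
  with_rng(spec$seed, {
    terms <- sprintf("T%04d", seq_len(spec$n_terms))
    depth <- integer(spec$n_terms)  # depth[1] = 0 (root)
    child <- character(0); parent <- character(0)
    for (i in 2:spec$n_terms) {
      eligible <- which(depth[seq_len(i - 1L)] < spec$max_depth)
      p1 <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
      depth[i] <- depth[p1] + 1L
      child <- c(child, terms[i]); parent <- c(parent, terms[p1])
      if (length(eligible) > 1L && stats::runif(1) < 0.3) {
        others <- setdiff(eligible, p1)
        p2 <- if (length(others) == 1L) others else sample(others, 1L)
        child <- c(child, terms[i]); parent <- c(parent, terms[p2])
        depth[i] <- max(depth[i], depth[p2] + 1L)
      }
    }
    parent_edges <- data.frame(child = child, parent = parent,
                               stringsAsFactors = FALSE)

    genes <- gene_ids(spec$n_genes)
    non_root <- terms[-1L]
    ann <- lapply(seq_len(spec$n_genes), function(g) {
      k <- sample(1:3, 1L)
      unique(sample(non_root, min(k, length(non_root))))
    })
    annotations <- data.frame(
      gene = rep(genes, lengths(ann)),
      term = unlist(ann, use.names = FALSE),
      stringsAsFactors = FALSE)

    # Propagated membership of the planted term, for study-set weighting.
    anc <- term_ancestors(parent_edges, terms)
    has_planted <- vapply(ann, function(ts) {
      spec$planted_term %in% unique(c(ts, unlist(anc[ts], use.names = FALSE)))
    }, logical(1))
    w <- ifelse(has_planted, spec$planted_enrichment_odds, 1)
    study_genes <- sort(sample(genes, spec$study_size, prob = w))

    list(parent_edges = parent_edges, terms = terms,
         annotations = annotations, study_genes = study_genes,
         planted_term = spec$planted_term, genes = genes)
  })
}

# child -> all ancestors (transitive closure over parent edges), memoised
# by processing terms in index order (parents always precede children).
term_ancestors <- function(parent_edges, terms) {
  parents <- split(parent_edges$parent, parent_edges$child)
  anc <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms) {
    ps <- parents[[t]]
    anc[[t]] <- if (is.null(ps)) character(0) else
      unique(c(ps, unlist(anc[ps], use.names = FALSE)))
  }
  anc
}

#' Specify a synthetic screen
#'
#' Defaults emulate the study conditions of an eye-phenotype modifier
#' screen: the tester genotype's mean eye area is 30% of the control's,
#' tester eclosion probability is 0.8, and climbing performance declines
#' with age for the tester while controls hold at about 0.8. Two modifier
#' genotypes are included by default — a suppressor (`mod_sup`) and an
#' enhancer (`mod_enh`) — so end-to-end runs quantify both directions.
#'
#' @param genotype_means named mean eye areas (arbitrary units).
#' @param genotype_sds named standard deviations, same names.
#' @param n_flies_per_genotype flies measured per genotype (>= 15).
#' @param viability_expected Mendelian-expected count of the tracked class.
#' @param viability_probs named per-genotype eclosion probabilities.
#' @param climbing_decline named list: per-genotype vector of 5 per-time-point
#'   climb probabilities (time points 48 h apart).
#' @param seed integer seed.
#' @return an object of class `screen_spec`.
#' @export
screen_spec <- function(genotype_means = c(control = 100, tester = 30,
                                           mod_sup = 80, mod_enh = 15),
                        genotype_sds = c(control = 10, tester = 5,
                                         mod_sup = 8, mod_enh = 3),
                        n_flies_per_genotype = 20,
                        viability_expected = 100,
                        viability_probs = c(control = 1, tester = 0.8,
                                            mod_sup = 0.8, mod_enh = 0.4),
                        climbing_decline = list(
                          control = c(0.85, 0.83, 0.82, 0.81, 0.80),
                          tester = c(0.70, 0.55, 0.40, 0.25, 0.15),
                          mod_sup = c(0.80, 0.75, 0.72, 0.70, 0.65),
                          mod_enh = c(0.45, 0.25, 0.10, 0.03, 0.01)),
                        seed = 1L) {
  n_flies_per_genotype <- check_count(n_flies_per_genotype,
                                      "n_flies_per_genotype", min = 15L)
  viability_expected <- check_count(viability_expected,
                                    "viability_expected", min = 1L)
  if (!setequal(names(genotype_means), names(genotype_sds))) {
    mn_config_error("genotype_means and genotype_sds must share genotype keys")
  }
  if (any(genotype_sds < 0)) mn_config_error("genotype_sds must be >= 0")
  check_prob(unlist(viability_probs), "viability_probs")
  probs <- unlist(climbing_decline, use.names = FALSE)
  check_prob(probs, "climbing_decline probabilities")
  if (any(lengths(climbing_decline) != 5L)) {
    mn_config_error("climbing_decline requires 5 time points per genotype")
  }
  structure(list(genotype_means = genotype_means,
                 genotype_sds = genotype_sds,
                 n_flies_per_genotype = n_flies_per_genotype,
                 viability_expected = viability_expected,
                 viability_probs = viability_probs,
                 climbing_decline = climbing_decline,
                 seed = as.integer(seed)),
            class = "screen_spec")
}

#' Generate synthetic screen tables
#'
#' Eye areas are drawn per genotype from the stated normal mean/sd,
#' truncated at zero by resampling (areas are physical). Eclosion counts
#' are binomial(`viability_expected`, genotype probability). Climbing
#' counts are binomial(10, p_t) per trial, with 10 trials at each of 5
#' time points spaced 48 h apart.
#'
#' @param spec a [screen_spec()].
#' @return list of data.frames: `eye` (`genotype`, `fly_id`, `area`),
#'   `viability` (`genotype`, `observed`, `expected`), `climbing`
#'   (`genotype`, `time_point`, `trial`, `n_above`, `n_total`).
#' @export
generate_screen_table <- function(spec) {
  stopifnot(inherits(spec, "screen_spec"))
  with_rng(spec$seed, {
    gts <- names(spec$genotype_means)
    n <- spec$n_flies_per_genotype
    eye <- do.call(rbind, lapply(gts, function(g) {
      x <- stats::rnorm(n, spec$genotype_means[[g]], spec$genotype_sds[[g]])
      while (any(bad <- x < 0)) {
        x[bad] <- stats::rnorm(sum(bad), spec$genotype_means[[g]],
                               spec$genotype_sds[[g]])
      }
      data.frame(genotype = g, fly_id = sprintf("%s_f%03d", g, seq_len(n)),
                 area = round(x, 3), stringsAsFactors = FALSE)
    }))

    vgts <- names(spec$viability_probs)
    viability <- data.frame(
      genotype = vgts,
      observed = vapply(vgts, function(g) {
        stats::rbinom(1L, spec$viability_expected, spec$viability_probs[[g]])
      }, integer(1)),
      expected = spec$viability_expected,
      stringsAsFactors = FALSE)
    rownames(viability) <- NULL

    cgts <- names(spec$climbing_decline)
    climbing <- do.call(rbind, lapply(cgts, function(g) {
      p <- spec$climbing_decline[[g]]
      do.call(rbind, lapply(1:5, function(tp) {
        data.frame(genotype = g, time_point = tp, trial = 1:10,
                   n_above = stats::rbinom(10L, 10L, p[tp]), n_total = 10L,
                   stringsAsFactors = FALSE)
      }))
    }))
    rownames(climbing) <- NULL

    list(eye = eye, viability = viability, climbing = climbing)
  })
}

#' Generate a synthetic orthology candidate table
#'
#' Emulates a consensus orthology tool: each source gene maps with
#' probability `mapping_rate`; mapped genes receive one to three candidate
#' targets, each supported by an integer number of algorithm votes drawn
#' from `vote_distribution`.
#'
#' @param n_source_genes number of source-species genes.
#' @param mapping_rate probability a source gene has any candidate.
#' @param vote_distribution probability weights over vote counts
#'   `1:length(vote_distribution)`; default spreads over 1..10 algorithms
#'   with most support in the mid range.
#' @param seed integer seed.
#' @return data.frame `source_gene`, `target_gene`, `score`.
#' @export
generate_orthology_table <- function(n_source_genes,
                                     mapping_rate = 0.9,
                                     vote_distribution =
                                       c(2, 3, 4, 5, 5, 4, 3, 2, 1, 1),
                                     seed = 1L) {
  n_source_genes <- check_count(n_source_genes, "n_source_genes", min = 1L)
  check_prob(mapping_rate, "mapping_rate")
  if (any(vote_distribution < 0) || sum(vote_distribution) <= 0) {
    mn_config_error("vote_distribution must be non-negative weights")
  }
  with_rng(seed, {
    src <- gene_ids(n_source_genes)
    mapped <- src[stats::runif(n_source_genes) < mapping_rate]
    votes <- seq_along(vote_distribution)
    rows <- lapply(mapped, function(g) {
      k <- sample(1:3, 1L, prob = c(0.6, 0.3, 0.1))
      data.frame(source_gene = g,
                 target_gene = sprintf("%s_h%d", sub("^g", "h", g),
                                       seq_len(k)),
                 score = sample(votes, k, replace = TRUE,
                                prob = vote_distribution),
                 stringsAsFactors = FALSE)
    })
    out <- if (length(rows) > 0) do.call(rbind, rows) else
      data.frame(source_gene = character(), target_gene = character(),
                 score = integer(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Write a full set of synthetic pipeline inputs
#'
#' Generates interactome, ontology, screen and orthology tables from a
#' single top-level seed (each generator gets its own stream via a fixed
#' offset) and writes them as UTF-8 TSV/GMT/text files with deterministic
#' row order.
#'
#' @param dir output directory (created if absent).
#' @param seed top-level integer seed.
#' @param interactome,ontology,screen optional specs; defaults emulate the
#'   study conditions (seeds inside these specs are overridden by the
#'   derived streams).
#' @return invisibly, a named list of file paths plus the generated objects.
#' @export
write_synthetic_inputs <- function(dir, seed = 1L,
                                   interactome = interactome_spec(),
                                   ontology = ontology_spec(),
                                   screen = screen_spec()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  interactome$seed <- derive_seed(seed, 101L)
  ontology$seed <- derive_seed(seed, 202L)
  screen$seed <- derive_seed(seed, 303L)

  net <- generate_interactome(interactome)
  ont <- generate_ontology(ontology)
  scr <- generate_screen_table(screen)
  orth <- generate_orthology_table(
    n_source_genes = interactome$n_genes,
    seed = derive_seed(seed, 404L))

  paths <- list(
    edges = file.path(dir, "edges.tsv"),
    module_genes = file.path(dir, "module_genes.txt"),
    ontology = file.path(dir, "ontology.tsv"),
    annotations = file.path(dir, "annotations.gmt"),
    study_genes = file.path(dir, "study_genes.txt"),
    screen_eye = file.path(dir, "screen_eye.tsv"),
    screen_viability = file.path(dir, "screen_viability.tsv"),
    screen_climbing = file.path(dir, "screen_climbing.tsv"),
    orthology = file.path(dir, "orthology.tsv"))

  write_tsv(net$edges, paths$edges)
  writeLines(net$module_genes, paths$module_genes)
  write_tsv(ont$parent_edges, paths$ontology)
  write_gmt(ont$annotations, paths$annotations)
  writeLines(ont$study_genes, paths$study_genes)
  write_tsv(scr$eye, paths$screen_eye)
  write_tsv(scr$viability, paths$screen_viability)
  write_tsv(scr$climbing, paths$screen_climbing)
  write_tsv(orth, paths$orthology)

  invisible(c(paths, list(interactome = net, ontology = ont,
                          screen = scr, orthology = orth)))
}
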