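#' @title End-to-end pipeline
#' @description
#' Orchestrates the analysis stages — optional synthetic-input simulation,
#' screen quantification, term enrichment, network-topology testing and
#' orthology mapping — behind a single validated configuration, writing
#' per-stage tables plus a machine-readable JSON report with provenance
#' (input hashes, seed, package version).
#' @name pipeline
NULL

REPORT_SCHEMA_VERSION <- "1.0"

#' Build and validate a run configuration
#'
#' @param config named list or path to a YAML file. Recognised fields:
#'   `simulate` (logical; generate inputs first), input paths (`edges`,
#'   `gene_list`, `ontology`, `annotations`, `study_genes`, `screen_eye`,
#'   `screen_viability`, `screen_climbing`, `orthology`, `disease`),
#'   parameters (`n_perm`, `elim_cutoff`, `alpha`, `min_score`, `seed`,
#'   `control`, `tester`, `seed_gene`) and `out_dir`.
#' @param ... field overrides applied on top of `config`.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(config = list(), ...) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      mn_config_error(sprintf("config file not found: %s", config))
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) mn_config_error("config must be a list or YAML path")
  dots <- list(...)
  config[names(dots)] <- dots

  defaults <- list(simulate = FALSE, n_perm = 1000, elim_cutoff = 0.01,
                   alpha = 0.05, min_score = 2, seed = 1L,
                   control = "control", tester = "tester",
                   seed_gene = NULL, out_dir = "modnet_out",
                   edges = NULL, gene_list = NULL, ontology = NULL,
                   annotations = NULL, study_genes = NULL,
                   screen_eye = NULL, screen_viability = NULL,
                   screen_climbing = NULL, orthology = NULL,
                   disease = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    mn_config_error(sprintf("unknown config field(s): %s",
                            paste(unknown, collapse = ", ")))
  }
  for (f in names(defaults)) config[[f]] <- config[[f]] %||% defaults[[f]]

  # n_perm >= 2 is enforced by the permutation stage itself, so that the
  # failure carries the stage label; config only rules out non-counts.
  config$n_perm <- check_count(config$n_perm, "n_perm", min = 1L)
  config$seed <- check_count(config$seed, "seed")
  config$min_score <- check_count(config$min_score, "min_score", min = 1L)
  check_prob(config$elim_cutoff, "elim_cutoff")
  check_prob(config$alpha, "alpha")

  path_fields <- c("edges", "gene_list", "ontology", "annotations",
                   "study_genes", "screen_eye", "screen_viability",
                   "screen_climbing", "orthology", "disease")
  if (!isTRUE(config$simulate)) {
    if (is.null(config$edges)) {
      mn_config_error("config requires an 'edges' table (or simulate: true)")
    }
    missing <- Filter(function(f) !is.null(config[[f]]) &&
                        !file.exists(config[[f]]), path_fields)
    if (length(missing) > 0L) {
      mn_config_error(sprintf(
        "input file(s) not found: %s",
        paste(vapply(missing, function(f) {
          sprintf("%s (%s)", f, config[[f]])
        }, character(1)), collapse = "; ")))
    }
  }
  structure(config, class = "run_config")
}

run_stage <- function(stage, created, expr) {
  tryCatch(expr, error = function(e) {
    for (f in created()) if (file.exists(f)) unlink(f)
    mn_stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
            class = if (inherits(e, "modnet_error"))
              class(e)[1] else "modnet_data_error",
            stage = stage, parent = e)
  })
}

#' Run the full analysis pipeline
#'
#' Stages: optional simulate, then screen-quant, enrich, netstat and
#' orthomap; each stage is skipped when its inputs are not configured. A
#' failing stage aborts the run with the stage name and cause and removes
#' the partial outputs of the run. All randomness derives from
#' `config$seed` by fixed per-stage offsets.
#'
#' @param config a [run_config()] (or list / YAML path coerced through it).
#' @return invisibly, the run report (also written to
#'   `out_dir/report.json` and summarised in `out_dir/summary.txt`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  created_files <- character(0)
  note <- function(path) {
    created_files <<- c(created_files, path)
    path
  }
  created <- function() created_files

  if (isTRUE(config$simulate)) {
    run_stage("simulate", created, {
      sim <- write_synthetic_inputs(file.path(out_dir, "inputs"),
                                    seed = config$seed)
      for (f in c("edges", "ontology", "annotations", "study_genes",
                  "screen_eye", "screen_viability", "screen_climbing",
                  "orthology")) {
        config[[f]] <- sim[[f]]
        note(sim[[f]])
      }
      config$gene_list <- note(sim$module_genes)
    })
  }

  stage_outputs <- list(config = unclass(config))

  # ---- screen-quant ----
  if (!is.null(config$screen_eye)) {
    stage_outputs$screen_quant <- run_stage("screen-quant", created, {
      eye <- read_tsv(config$screen_eye)
      viability <- if (!is.null(config$screen_viability))
        read_tsv(config$screen_viability) else NULL
      climbing <- if (!is.null(config$screen_climbing))
        read_tsv(config$screen_climbing) else NULL
      quant <- quantify_modifiers(eye, viability, climbing,
                                  control = config$control,
                                  tester = config$tester)
      write_tsv(quant, note(file.path(out_dir, "modifiers_quant.tsv")))
      class_counts <- table(factor(
        quant$strength_class,
        levels = c("strong", "intermediate", "weak", "enhancer", "none")))
      list(n_modifiers = nrow(quant),
           class_counts = as.list(class_counts),
           suppression_pct = stats::setNames(quant$suppression_pct,
                                             quant$gene),
           lethality_pct = stats::setNames(quant$lethality_pct,
                                           quant$gene))
    })
  }

  # ---- enrich ----
  if (!is.null(config$ontology) && !is.null(config$annotations) &&
      !is.null(config$study_genes)) {
    stage_outputs$enrich <- run_stage("enrich", created, {
      dag <- go_dag(read_tsv(config$ontology))
      direct <- read_gmt(config$annotations)
      ann <- propagate_annotations(dag, direct)
      study <- readLines(config$study_genes)
      study <- intersect(study, ann$universe)
      enr <- elim_enrichment(dag, ann, study,
                             elim_cutoff = config$elim_cutoff,
                             alpha = config$alpha)
      write_tsv(enr, note(file.path(out_dir, "enrichment.tsv")))
      top <- utils::head(enr, 5)
      list(n_terms_tested = nrow(enr),
           n_significant = sum(enr$significant),
           elim_cutoff = config$elim_cutoff, alpha = config$alpha,
           top_terms = top[, c("term", "k", "K", "p_elim", "p_by")])
    })
  }

  # ---- netstat ----
  if (!is.null(config$edges) && !is.null(config$gene_list)) {
    stage_outputs$netstat <- run_stage("netstat", created, {
      background <- build_background(read_tsv(config$edges))
      gene_list <- readLines(config$gene_list)
      perm <- permutation_z_test(background, gene_list,
                                 n_perm = config$n_perm,
                                 seed = derive_seed(config$seed, 505L))
      subnet <- if (!is.null(config$seed_gene)) {
        expand_with_connectors(background, gene_list, config$seed_gene)
      } else {
        induce_subnetwork(background, gene_list)
      }
      write_netstat_json(perm, note(file.path(out_dir, "netstat.json")))
      write_network_graphml(subnet,
                            note(file.path(out_dir, "network.graphml")))
      write_network_sif(subnet, note(file.path(out_dir, "network.sif")))
      summ <- topology_summary(subnet)
      list(list_size = perm$list_size, n_perm = perm$n_perm,
           n_connected_list_genes = summ$n_connected_list_genes,
           metrics = lapply(
             perm[c("mean_degree", "mean_betweenness")],
             function(s) s[c("observed", "null_mean", "null_sd", "z",
                             "p_normal", "p_empirical", "fold")]))
    })
  }

  # ---- orthomap ----
  if (!is.null(config$orthology)) {
    stage_outputs$orthomap <- run_stage("orthomap", created, {
      cand <- read_tsv(config$orthology)
      gene_list <- if (!is.null(config$gene_list))
        readLines(config$gene_list) else unique(cand$source_gene)
      filtered <- filter_candidates(cand, min_score = config$min_score)
      mapping <- map_gene_list(gene_list, filtered)
      writeLines(sort(unique(mapping$mapping$target_gene)),
                 note(file.path(out_dir, "human_list.txt")))
      if (!is.null(config$disease)) {
        joined <- join_disease_annotations(mapping$mapping,
                                           read_tsv(config$disease))
        write_tsv(joined, note(file.path(out_dir, "disease_join.tsv")))
      }
      list(n_source = length(unique(gene_list)),
           n_mapped = mapping$n_mapped, coverage = mapping$coverage,
           min_score = config$min_score)
    })
  }

  report <- write_report(stage_outputs, out_dir)
  invisible(report)
}

#' Write the machine-readable run report and human-readable summary
#'
#' @param stage_outputs named list of per-stage outputs (as assembled by
#'   [run_pipeline()]); must contain at least one stage beside `config`.
#' @param out_dir directory receiving `report.json` and `summary.txt`.
#' @return invisibly, the report list.
#' @export
write_report <- function(stage_outputs, out_dir) {
  stages <- setdiff(names(stage_outputs), "config")
  if (length(stages) == 0L) {
    mn_data_error("write_report needs at least one stage output")
  }
  config <- stage_outputs$config
  input_files <- Filter(function(p) is.character(p) && file.exists(p),
                        config[c("edges", "gene_list", "ontology",
                                 "annotations", "study_genes",
                                 "screen_eye", "screen_viability",
                                 "screen_climbing", "orthology",
                                 "disease")])
  provenance <- list(
    package = "modnet",
    version = as.character(utils::packageVersion("modnet")),
    schema_version = REPORT_SCHEMA_VERSION,
    seed = config$seed,
    connector_rule = ">=2 list neighbors, or length-2 path to seed gene",
    enrichment_method = "elim (hard gene removal at cutoff), hypergeometric upper tail, BY FDR",
    input_md5 = lapply(input_files, function(p)
      unname(tools::md5sum(p))))
  report <- c(list(provenance = provenance), stage_outputs)

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null")

  lines <- c("modnet run summary",
             sprintf("seed: %d", config$seed), "")
  for (stage in c("screen_quant", "enrich", "netstat", "orthomap")) {
    s <- stage_outputs[[stage]]
    if (is.null(s)) {
      lines <- c(lines, sprintf("[%s] not run", stage))
      next
    }
    lines <- c(lines, sprintf("[%s]", stage))
    if (stage == "screen_quant") {
      cc <- unlist(s$class_counts)
      lines <- c(lines,
                 sprintf("  modifiers quantified: %d", s$n_modifiers),
                 sprintf("  classes: %s",
                         paste(sprintf("%s=%d", names(cc), cc),
                               collapse = ", ")))
    } else if (stage == "enrich") {
      lines <- c(lines,
                 sprintf("  terms tested: %d, significant at BY alpha=%g: %d",
                         s$n_terms_tested, s$alpha, s$n_significant),
                 sprintf("  top term: %s (p_by = %.3g)",
                         s$top_terms$term[1], s$top_terms$p_by[1]))
    } else if (stage == "netstat") {
      for (m in names(s$metrics)) {
        x <- s$metrics[[m]]
        lines <- c(lines, sprintf(
          "  %s: obs %.4f, %.2fx, Z = %.2f, p = %.3g (empirical %.3g)",
          m, x$observed, x$fold, x$z, x$p_normal, x$p_empirical))
      }
      lines <- c(lines, sprintf("  connected list genes: %d of %d",
                                s$n_connected_list_genes, s$list_size))
    } else if (stage == "orthomap") {
      lines <- c(lines, sprintf(
        "  orthology coverage: %d of %d (%.1f%%) at min score %d",
        s$n_mapped, s$n_source, 100 * s$coverage, s$min_score))
    }
  }
  writeLines(lines, file.path(out_dir, "summary.txt"))
  invisible(report)
}
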