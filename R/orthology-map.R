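#' @title Consensus orthology mapping and disease joins
#' @description
#' Cross-species gene-list mapping from a candidate table whose integer
#' score counts the orthology-prediction algorithms supporting each pair.
#' Candidates below a minimum vote score are removed (single-algorithm
#' predictions are unreliable), surviving targets are mapped per source
#' gene with best-score flags, and human targets are left-joined to
#' disease annotations.
#' @name orthology-map
NULL

#' Filter orthology candidates by vote score
#'
#' @param candidates data.frame with columns `source_gene`, `target_gene`,
#'   `score` (integer algorithm-vote count >= 1).
#' @param min_score minimum score retained (default 2: at least two
#'   algorithms must support the call).
#' @return the retained candidate rows.
#' @export
filter_candidates <- function(candidates, min_score = 2) {
  check_cols(candidates, c("source_gene", "target_gene", "score"),
             "orthology candidate table")
  min_score <- check_count(min_score, "min_score", min = 1L)
  if (any(!is.finite(candidates$score)) || any(candidates$score < 1)) {
    mn_data_error("candidate scores must be integers >= 1")
  }
  out <- candidates[candidates$score >= min_score, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map a source gene list through orthology candidates
#'
#' Every surviving target of a listed source gene is retained; the
#' maximum-score target(s) per source are flagged `is_best`, and sources
#' whose best score is tied across several targets are flagged
#' `ambiguous` on all tied rows. Duplicate (source, target) rows are
#' collapsed to their maximum score with a warning.
#'
#' @param source_list character vector of source-species gene ids.
#' @param candidates candidate table, typically already passed through
#'   [filter_candidates()].
#' @return list with `mapping` (data.frame `source_gene`, `target_gene`,
#'   `score`, `is_best`, `ambiguous`), `coverage` (mapped sources /
#'   list size), `n_mapped`, `unmapped` (character vector).
#' @export
map_gene_list <- function(source_list, candidates) {
  check_cols(candidates, c("source_gene", "target_gene", "score"),
             "orthology candidate table")
  source_list <- unique(as.character(source_list))
  if (length(source_list) == 0L) mn_data_error("source_list is empty")
  cand <- candidates[candidates$source_gene %in% source_list, ,
                     drop = FALSE]
  key <- paste(cand$source_gene, cand$target_gene, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate (source, target) candidate rows collapsed to max score")
    mx <- tapply(cand$score, key, max)
    cand <- cand[!duplicated(key), , drop = FALSE]
    cand$score <- as.numeric(mx[paste(cand$source_gene, cand$target_gene,
                                      sep = "\r")])
  }
  if (nrow(cand) > 0L) {
    best <- tapply(cand$score, cand$source_gene, max)
    cand$is_best <- cand$score == best[cand$source_gene]
    n_best <- tapply(cand$is_best, cand$source_gene, sum)
    cand$ambiguous <- n_best[cand$source_gene] > 1L
    cand <- cand[order(cand$source_gene, -cand$score, cand$target_gene), ,
                 drop = FALSE]
  } else {
    cand$is_best <- logical(0)
    cand$ambiguous <- logical(0)
  }
  rownames(cand) <- NULL
  mapped <- unique(cand$source_gene)
  list(mapping = cand,
       coverage = length(mapped) / length(source_list),
       n_mapped = length(mapped),
       unmapped = setdiff(source_list, mapped))
}

#' Join disease annotations onto a mapping
#'
#' Left join on the human (target) gene id: a target with several disease
#' records yields several rows; targets with no record keep empty disease
#' fields.
#'
#' @param mapping the `mapping` data.frame from [map_gene_list()] (or any
#'   data.frame with a `target_gene` column).
#' @param disease_table data.frame with columns `human_gene`,
#'   `disease_name`, `source` (`OMIM` or `GWAS`), `identifier`.
#' @return the annotated mapping data.frame.
#' @export
join_disease_annotations <- function(mapping, disease_table) {
  check_cols(mapping, "target_gene", "orthology mapping")
  check_cols(disease_table,
             c("human_gene", "disease_name", "source", "identifier"),
             "disease table")
  if (nrow(disease_table) > 0L &&
      !all(disease_table$source %in% c("OMIM", "GWAS"))) {
    mn_data_error("disease sources must be OMIM or GWAS")
  }
  out <- merge(mapping, disease_table, by.x = "target_gene",
               by.y = "human_gene", all.x = TRUE, sort = FALSE)
  for (col in c("disease_name", "source", "identifier")) {
    out[[col]][is.na(out[[col]])] <- ""
  }
  first <- intersect(c("source_gene", "target_gene"), names(out))
  out <- out[, c(first, setdiff(names(out), first)), drop = FALSE]
  ord <- do.call(order, out[, first, drop = FALSE])
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
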