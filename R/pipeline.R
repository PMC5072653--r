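#' Run the full analysis pipeline
#'
#' Wires the stages end to end — normalize, score, enrich, cluster,
#' segment, double-cluster — and writes every stage result as TSV into
#' `outdir`: `normalized.tsv`, `scores.tsv`, `enrich.tsv`, `clusters.tsv`,
#' `markers.tsv`, plus a `run.log` echoing every parameter. Outputs are
#' deterministic for identical inputs and configuration (the log's
#' timestamp line aside).
#'
#' @param expr Expression tibble, or a path to an expression TSV.
#' @param sets Gene-set tibble, or a path to a GMT file.
#' @param pheno Phenotype tibble, or a path to a 2-column TSV.
#' @param outdir Output directory (created if absent).
#' @param fdr_threshold Enrichment significance threshold (default 0.01).
#' @param min_support See [score_gene_sets()].
#' @param method,theta Similarity configuration, see [smic()] and
#'   [baseline_similarity()].
#' @param loess_span,min_class_size Segmentation controls, see
#'   [segment_trace()].
#' @param direction_filter Which significant sets feed the clustering:
#'   `"SUP"` (default — down-regulated calls are the less reliable
#'   direction), `"SDP"`, or `"both"`.
#' @param allow_negative,log2p1 Input handling, see [read_expression()];
#'   used only when `expr` is a path.
#' @param seed Optional integer echoed to the log (the pipeline itself is
#'   deterministic).
#' @return Invisibly, a list with `enrichment` (tibble), `clustering`
#'   (`igsa_clustering` or `NULL`), `double` (see [double_cluster()], or
#'   `NULL`) and `outdir`.
#' @export
igsa_run <- function(expr, sets, pheno, outdir,
                     fdr_threshold = 0.01, min_support = 1L,
                     method = "smic_mle", theta = NULL,
                     loess_span = 0.5, min_class_size = 3L,
                     direction_filter = c("SUP", "SDP", "both"),
                     allow_negative = FALSE, log2p1 = FALSE, seed = NULL) {
  direction_filter <- match.arg(direction_filter)
  if (is.character(expr)) {
    expr <- read_expression(expr, allow_negative = allow_negative,
                            log2p1 = log2p1)
  }
  if (is.character(sets)) sets <- read_gmt(sets)
  samples <- setdiff(names(expr), "gene")
  if (is.character(pheno)) pheno <- read_phenotypes(pheno, samples)
  pheno <- validate_phenotypes(pheno, samples)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  log_path <- file.path(outdir, "run.log")
  logf <- function(...) {
    cat(paste0(..., "\n"), file = log_path, append = TRUE)
    invisible(NULL)
  }
  cat(sprintf("# igsa run %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      file = log_path)
  logf("genes=", nrow(expr), " samples=", length(samples),
       " sets=", length(unique(sets$set)))
  logf("fdr_threshold=", fdr_threshold, " min_support=", min_support,
       " method=", method, " theta=", theta %||% "NA",
       " loess_span=", loess_span, " min_class_size=", min_class_size,
       " direction_filter=", direction_filter, " seed=", seed %||% "NA")

  norm <- normalize_expression(expr)
  if (length(attr(norm, "dropped_genes")) > 0L) {
    logf("dropped zero-sum genes: ",
         paste(attr(norm, "dropped_genes"), collapse = ","))
  }
  write_table(norm, file.path(outdir, "normalized.tsv"))

  enr <- run_enrichment(expr, sets, pheno, fdr_threshold = fdr_threshold,
                        min_support = min_support)
  scores <- attr(enr, "scores")
  write_table(scores, file.path(outdir, "scores.tsv"))
  write_table(enr, file.path(outdir, "enrich.tsv"))
  logf("significant sets: SUP=", sum(enr$direction == "SUP"),
       " SDP=", sum(enr$direction == "SDP"))

  keep <- if (direction_filter == "both") {
    enr$set[enr$direction != "none"]
  } else {
    enr$set[enr$direction == direction_filter]
  }
  clustering <- NULL
  dbl <- NULL
  if (length(keep) == 0L) {
    warning("no significant set passes direction_filter = '",
            direction_filter, "'; clustering skipped", call. = FALSE)
    logf("clustering skipped: no significant sets after filter")
    write_table(tibble::tibble(rank = integer(), sample_id = character(),
                               avg_similarity = double(),
                               class = integer()),
                file.path(outdir, "clusters.tsv"))
    write_table(tibble::tibble(set = character()),
                file.path(outdir, "markers.tsv"))
  } else {
    clustering <- cluster_samples(scores, pheno, significant = keep,
                                  method = method, theta = theta,
                                  loess_span = loess_span,
                                  min_class_size = min_class_size)
    write_table(tidy(clustering), file.path(outdir, "clusters.tsv"))
    logf("clustered ", length(clustering$ordered_ids), " cases into ",
         max(clustering$classes), " class(es)")
    dbl <- double_cluster(scores, pheno, significant = keep,
                          method = method, theta = theta)
    write_table(values_to_tbl(dbl$markers * 1L, "set"),
                file.path(outdir, "markers.tsv"))
  }
  logf("done")
  invisible(list(enrichment = enr, clustering = clustering, double = dbl,
                 outdir = outdir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate pipeline inputs without computing
#'
#' Checks the three inputs against each other and reports how the gene-set
#' collection overlaps the expression matrix — the per-set intersection
#' sizes that determine which sets can be scored at all. Fully disjoint
#' namespaces (no set gene present in the matrix) are an error, as that
#' almost always means mismatched identifier types.
#'
#' @inheritParams igsa_run
#' @return A tibble with one row per set: `set`, `size`, `n_in_matrix`,
#'   `fraction_in_matrix`.
#' @export
igsa_validate <- function(expr, sets, pheno,
                          allow_negative = FALSE, log2p1 = FALSE) {
  if (is.character(expr)) {
    expr <- read_expression(expr, allow_negative = allow_negative,
                            log2p1 = log2p1)
  }
  if (is.character(sets)) sets <- read_gmt(sets)
  expr <- validate_expression(expr, allow_negative = TRUE)
  samples <- setdiff(names(expr), "gene")
  if (is.character(pheno)) pheno <- read_phenotypes(pheno, samples)
  validate_phenotypes(pheno, samples)
  overlap <- sets |>
    dplyr::group_by(.data$set) |>
    dplyr::summarise(
      size = dplyr::n(),
      n_in_matrix = sum(.data$gene %in% expr$gene),
      .groups = "drop"
    ) |>
    dplyr::mutate(fraction_in_matrix = .data$n_in_matrix / .data$size)
  if (sum(overlap$n_in_matrix) == 0L) {
    stop("no gene of any set is present in the expression matrix; ",
         "gene identifier namespaces do not match", call. = FALSE)
  }
  overlap
}
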