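#' Run the full ranking pipeline
#'
#' Orchestrates the stages in their canonical order — prefilter, graph
#' construction, optional b-matching sparsification, normalisation,
#' evidence propagation — and writes the ranked candidate list plus
#' supporting artifacts to `output_dir`:
#'
#' * `ranking.tsv` — the top `top_n` samples, `id<TAB>rank<TAB>score`;
#' * `filter_report.tsv` — nearest-positive distance and dropped flag per
#'   input sample (always written; trivial when `filter_k = 0`);
#' * `manifest.json` — machine-readable run manifest: every parameter,
#'   the seed, package version, and MD5 checksums of the inputs;
#' * optionally `graph_edges.tsv` and `pattern_edges.tsv` dumps.
#'
#' The kernel bandwidth is estimated on the retained (post-filter) set:
#' the bandwidth heuristic is defined on the dataset actually being
#' ranked.
#'
#' @param features Path to the feature table, or a feature-table tibble.
#' @param queries Path to the label file, or a label tibble.
#' @param output_dir Directory for artifacts (created if needed).
#' @param filter_k Prefilter budget: drop this many unlabeled samples
#'   farthest from the queries (0 = no filtering).
#' @param sparsify_b b-matching degree budget; `NULL` disables
#'   sparsification and `"auto"` uses `max(5, ceiling(log2(n)))`.
#' @param alpha,gamma,mode,solver,tol,max_iter Ranking controls; see
#'   [manifold_rank()].
#' @param top_n How many top-ranked samples to write.
#' @param sigma Optional kernel bandwidth override.
#' @param zscore Standardise features first?
#' @param seed Integer seed recorded in the manifest and used by any
#'   stochastic stage.
#' @param write_graph Also dump graph (and pattern) edge lists?
#' @param delim Feature-file delimiter when `features` is a path.
#' @return The `secrank_ranking`, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(features, queries, output_dir,
                         filter_k = 0L, sparsify_b = NULL,
                         alpha = 0.5, gamma = 0.5,
                         mode = c("positive_only", "universal"),
                         solver = c("closed_form", "iterative"),
                         top_n = Inf, sigma = NULL, zscore = FALSE,
                         seed = 1L, write_graph = FALSE,
                         tol = 1e-9, max_iter = 10000L,
                         delim = c("tab", "comma")) {
  mode <- match.arg(mode)
  solver <- match.arg(solver)
  delim <- match.arg(delim)
  set.seed(as.integer(seed))

  input_files <- character()
  if (is.character(features)) {
    input_files["features"] <- features
    data <- read_feature_table(features, delim = delim)
  } else {
    data <- validate_feature_table(features)
  }
  if (is.character(queries)) {
    input_files["queries"] <- queries
    labels <- read_labels(queries, data)
  } else {
    labels <- queries
    check_labels_match(data, labels)
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  inform(paste0("input: ", nrow(data), " samples, ", ncol(data) - 1L,
                " features, ", sum(labels$status == "positive"), " queries"))

  filtered <- filter_bottom_k(data, labels, k = filter_k)
  write_filter_report(filtered$report, file.path(output_dir, "filter_report.tsv"))
  if (filter_k > 0) {
    inform(paste0("prefilter: dropped ", filter_k, " of ",
                  nrow(filtered$report), " samples; ",
                  nrow(filtered$data), " retained"))
  }
  data <- filtered$data
  labels <- filtered$labels

  if (identical(sparsify_b, "auto")) {
    sparsify_b <- max(5L, as.integer(ceiling(log2(nrow(data)))))
  }
  if (!is.null(sparsify_b) && (nrow(data) * sparsify_b) %% 2L != 0L) {
    stop_validation(paste0(
      "sparsify_b = ", sparsify_b, " is infeasible for n = ", nrow(data),
      " (n*b must be even)"
    ))
  }

  result <- manifold_rank(
    data, labels, alpha = alpha, mode = mode, gamma = gamma,
    solver = solver, sigma = sigma, sparsify_b = sparsify_b,
    zscore = zscore, tol = tol, max_iter = max_iter
  )
  inform(paste0("graph: sigma = ", format(result$sigma, digits = 6),
                if (!is.null(sparsify_b)) paste0(", sparsified to b = ", sparsify_b) else ""))

  n_out <- min(top_n, nrow(data))
  write_ranking(result, file.path(output_dir, "ranking.tsv"), top_n = n_out)
  inform(paste0("ranking: wrote top ", n_out, " of ", nrow(data), " samples"))

  if (write_graph) {
    write_graph_edges(result$graph, file.path(output_dir, "graph_edges.tsv"))
    if (!is.null(result$pattern)) {
      edges <- tidy(result$pattern)
      writeLines(c("from\tto", paste(edges$from, edges$to, sep = "\t")),
                 file.path(output_dir, "pattern_edges.tsv"))
    }
  }

  manifest <- list(
    package = "secrank",
    version = as.character(utils::packageVersion("secrank")),
    parameters = list(
      filter_k = filter_k,
      sparsify_b = if (is.null(sparsify_b)) NA else sparsify_b,
      alpha = alpha, gamma = gamma, mode = mode, solver = solver,
      top_n = if (is.finite(top_n)) top_n else NA,
      sigma_override = if (is.null(sigma)) NA else sigma,
      sigma_used = result$sigma,
      zscore = zscore, tol = tol, max_iter = max_iter
    ),
    seed = as.integer(seed),
    n_input = nrow(filtered$report),
    n_ranked = nrow(data),
    input_checksums = as.list(if (length(input_files) > 0) {
      tools::md5sum(input_files)
    } else {
      setNames(character(0), character(0))
    })
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(result)
}
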