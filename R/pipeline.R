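#' Run the full classification pipeline
#'
#' Extract features, split, train one model per fold, evaluate, and write the
#' artifacts: the feature table, per-fold score tables, ROC / precision-recall
#' curve points, and a summary JSON embedding the configuration, its hash and
#' the seed, so a rerun with the same configuration reproduces identical
#' outputs.
#'
#' @param contigs Contig tibble (`id`, `sequence`, `experiment_id`, `label`);
#'   alternatively pass `fasta` and `labels` paths, or a precomputed
#'   `features` table.
#' @param fasta,labels Paths to a contig FASTA and a label TSV, used when
#'   `contigs` is `NULL`.
#' @param features Optional feature tibble from [extract_features()] or
#'   [read_feature_table()]; skips the extraction stage.
#' @param output_dir Directory for artifacts; created if absent. `NULL` skips
#'   writing.
#' @param model `"random_forest"` or `"neural_net"`.
#' @param config Model configuration ([rf_config()] / [nn_config()]).
#' @param evaluation `"loeo"` or `"kfold:K"` (e.g. `"kfold:10"`).
#' @param threshold Classification threshold for the per-class metrics.
#' @param min_coding_nt,min_orfs Feature-extraction parameters.
#' @param seed Integer seed; per-stage seeds are derived from it so stages
#'   can be rerun in isolation.
#' @param quiet Suppress progress messages.
#' @return The `viroscu_eval` summary, invisibly when artifacts are written.
#' @export
run_pipeline <- function(contigs = NULL, fasta = NULL, labels = NULL,
                         features = NULL,
                         output_dir = NULL,
                         model = c("random_forest", "neural_net"),
                         config = NULL,
                         evaluation = "loeo", threshold = 0.5,
                         min_coding_nt = 120L, min_orfs = 2L,
                         seed = 1L, quiet = FALSE) {
  model <- match.arg(model)
  if (is.null(features)) {
    if (is.null(contigs)) {
      if (is.null(fasta) || is.null(labels)) {
        abort("provide `contigs`, `features`, or both `fasta` and `labels` paths")
      }
      validate_inputs(fasta, labels)
      contigs <- attach_labels(read_contigs(fasta), read_labels(labels))
    }
    features <- extract_features(contigs, min_coding_nt, min_orfs, quiet = quiet)
  }
  if (!quiet) {
    prev <- features |>
      group_by(.data$experiment_id) |>
      summarise(prevalence = mean(.data$label == "virus"), n = n(), .groups = "drop")
    inform(paste0(
      "per-experiment prevalence: ",
      paste(sprintf("%s=%.3f (n=%d)", prev$experiment_id, prev$prevalence, prev$n), collapse = ", ")
    ))
  }
  folds <- if (identical(evaluation, "loeo")) {
    loeo_split(features)
  } else if (grepl("^kfold:[0-9]+$", evaluation)) {
    kfold_split(features, k = as.integer(sub("^kfold:", "", evaluation)), seed = .derive_seed(seed, 2L))
  } else {
    abort(sprintf("unknown evaluation mode '%s' (use 'loeo' or 'kfold:K')", evaluation))
  }
  cv <- crossvalidate(features, model = model, folds = folds, config = config,
                      seed = .derive_seed(seed, 3L), quiet = quiet)
  summary <- summarize_evaluation(cv, threshold = threshold)

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    run_config <- list(
      tool = "viroscu",
      version = as.character(utils::packageVersion("viroscu")),
      model = model,
      config = unclass(attr(cv, "config")),
      evaluation = evaluation,
      threshold = threshold,
      min_coding_nt = min_coding_nt,
      min_orfs = min_orfs,
      seed = as.integer(seed)
    )
    run_config$config_hash <- rlang::hash(run_config)
    write_feature_table(features, file.path(output_dir, "features.tsv"))
    fold_scores <- list_rbind(map(seq_len(nrow(cv)), function(i) {
      tibble(
        fold = cv$fold[i],
        score = cv$scores[[i]],
        label = cv$labels[[i]]
      )
    }))
    readr::write_tsv(fold_scores, file.path(output_dir, "fold_scores.tsv"))
    readr::write_csv(summary$micro$curve, file.path(output_dir, "roc_micro.csv"))
    readr::write_csv(summary$macro$curve, file.path(output_dir, "roc_macro.csv"))
    readr::write_csv(summary$pr_tradeoff, file.path(output_dir, "precision_recall.csv"))
    jsonlite::write_json(
      c(run_config, list(
        micro_auroc = summary$micro$auroc,
        macro_auroc = summary$macro$auroc,
        per_fold_auroc = setNames(
          as.list(summary$per_fold_auroc$auroc),
          summary$per_fold_auroc$fold
        ),
        micro_metrics = summary$micro_metrics,
        macro_metrics = summary$macro_metrics
      )),
      file.path(output_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    return(invisible(summary))
  }
  summary
}

#' Write a simulated dataset to disk
#'
#' FASTA + label TSV + a JSON provenance record of the generator
#' configuration and seed.
#'
#' @param contigs Tibble from [generate_dataset()].
#' @param output_dir Output directory (created if absent).
#' @return Named list of the written paths, invisibly.
#' @export
write_dataset <- function(contigs, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    fasta = file.path(output_dir, "contigs.fasta"),
    labels = file.path(output_dir, "labels.tsv"),
    provenance = file.path(output_dir, "provenance.json")
  )
  write_contigs(contigs, paths$fasta)
  write_labels(contigs, paths$labels)
  config <- attr(contigs, "config")
  jsonlite::write_json(
    list(
      tool = "viroscu",
      version = as.character(utils::packageVersion("viroscu")),
      config = config,
      config_hash = rlang::hash(config)
    ),
    paths$provenance,
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(paths)
}
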