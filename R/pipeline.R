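# End-to-end driver: simulate (or read) a study, extract features, select a
# signature and classify per scope, evaluate, and record every artifact with
# a content hash so identical configs provably yield identical outputs.

#' Pipeline configuration
#'
#' Exactly one input mode: either `generator` (a [generator_config()], the
#' study is simulated) or `paths` (a named list with `manifest`,
#' `annotation`, `positives` and optionally `expression` file paths).
#'
#' @param out_dir output directory.
#' @param generator optional [generator_config()].
#' @param paths optional named list of input file paths.
#' @param scopes feature scopes to run (see [scope_columns()]).
#' @param n_resamples balanced resamples per scope (reference analysis: 500;
#'   default here 100 for desk-scale runs).
#' @param n_folds stratified CV folds in step 3.
#' @param frequency_threshold,prob_threshold,call_threshold signature,
#'   per-model probability and candidate-call thresholds.
#' @param master_seed integer seed driving every stage.
#' @param use_expression append the expression column to the matrix.
#' @return validated `plurisig_pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            generator = NULL,
                            paths = NULL,
                            scopes = "combined",
                            n_resamples = 100,
                            n_folds = 10,
                            frequency_threshold = 0.5,
                            prob_threshold = 0.5,
                            call_threshold = 0.9,
                            master_seed = 1,
                            use_expression = FALSE) {
  if (is.null(generator) == is.null(paths)) {
    abort("exactly one of `generator` or `paths` must be given")
  }
  bad <- setdiff(scopes, c("epigenetic", "protein_binding", "combined", "combined_expression"))
  if (length(bad) > 0) abort(paste0("unknown scope: ", bad[1]))
  for (th in c(frequency_threshold, prob_threshold, call_threshold)) {
    if (th < 0 || th > 1) abort("thresholds must be in [0, 1]")
  }
  if (!is.null(paths)) {
    need <- c("manifest", "annotation", "positives")
    if (!all(need %in% names(paths))) {
      abort("paths must name manifest, annotation and positives files")
    }
  }
  structure(
    list(
      out_dir = out_dir, generator = generator, paths = paths,
      scopes = scopes, n_resamples = as.integer(n_resamples),
      n_folds = as.integer(n_folds),
      frequency_threshold = frequency_threshold,
      prob_threshold = prob_threshold, call_threshold = call_threshold,
      master_seed = as.integer(master_seed),
      use_expression = isTRUE(use_expression)
    ),
    class = "plurisig_pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; a `generator`
#' block mirrors [generator_config()] fields, with `signature_datasets` as a
#' mapping from dataset id to `{count, breadth, distance}` effect sizes.
#'
#' @param path YAML file.
#' @return a `plurisig_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen <- NULL
  if (!is.null(y$generator)) {
    g <- y$generator
    if (!is.null(g$signature_datasets)) {
      g$signature_datasets <- lapply(g$signature_datasets, function(e) {
        list(count = e$count %||% 0, breadth = e$breadth %||% 0, distance = e$distance %||% 0)
      })
    }
    gen <- do.call(generator_config, g)
  }
  args <- y[setdiff(names(y), "generator")]
  args$generator <- gen
  do.call(pipeline_config, args)
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$generator)) {
    return(generate_study(config$generator, dir = file.path(config$out_dir, "study")))
  }
  p <- config$paths
  manifest <- read_dataset_manifest(p$manifest)
  manifest$path <- resolve_paths(manifest$path, dirname(p$manifest))
  peaks <- lapply(seq_len(nrow(manifest)), function(i) {
    read_peak_file(manifest$path[i], manifest$dialect[i])
  })
  names(peaks) <- manifest$dataset_id
  structure(
    list(
      annotation = read_gene_annotation(p$annotation),
      manifest = manifest, peaks = peaks,
      expression = if (!is.null(p$expression)) read_expression_table(p$expression) else NULL,
      positives = read_gene_list(p$positives),
      config = NULL
    ),
    class = "plurisig_study"
  )
}

#' Extract and normalize the feature matrix of a study
#'
#' Convenience wrapper running [assign_peaks_to_genes()],
#' [extract_features()] and [build_feature_matrix()] over every dataset of a
#' study.
#'
#' @param study a `plurisig_study`.
#' @param use_expression append the expression column.
#' @param normalize Z-score the matrix before returning it.
#' @return a `plurisig_features` object.
#' @export
study_features <- function(study, use_expression = FALSE, normalize = FALSE) {
  per_ds <- lapply(study$peaks, function(pk) {
    extract_features(assign_peaks_to_genes(pk, study$annotation), study$annotation)
  })
  features <- build_feature_matrix(
    per_ds, study$manifest,
    expression = if (use_expression) study$expression else NULL
  )
  if (normalize) zscore_normalize(features) else features
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages: obtain the study (simulate or read), extract and normalize
#' features, then per scope: signature selection over the resampling plan,
#' ensemble classification on the selected columns (falling back to all
#' scope columns, with a log note, when nothing reaches the selection
#' threshold — the situation expected under a null study), and evaluation
#' (count-breadth correlations, distance summaries, expression comparison of
#' candidates when expression is available). Every produced file is recorded
#' in the returned manifest with its md5 hash; a run log with seeds and
#' per-stage timing is written alongside (the log itself is not hashed, as
#' it contains wall-clock times).
#'
#' @param config a `plurisig_pipeline_config`.
#' @return tibble manifest of produced files (`file`, `md5`) with the
#'   per-scope results in the `results` attribute.
#' @export
run_pipeline <- function(config) {
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- c(
    sprintf("plurisig %s", as.character(utils::packageVersion("plurisig"))),
    sprintf("master_seed: %d", config$master_seed)
  )
  tick <- function(msg, t0) {
    log_lines <<- c(log_lines, sprintf("%s (%.1f s)", msg, as.numeric(Sys.time()) - t0))
  }
  files <- character()

  t0 <- as.numeric(Sys.time())
  study <- load_pipeline_inputs(config)
  if (!is.null(config$generator)) {
    files <- c(files, list.files(file.path(config$out_dir, "study"), full.names = TRUE))
  }
  tick("stage study", t0)

  t0 <- as.numeric(Sys.time())
  features_raw <- study_features(study, use_expression = config$use_expression)
  features <- zscore_normalize(features_raw)
  f_path <- file.path(config$out_dir, "features.tsv")
  write_feature_matrix(features_raw, f_path)
  files <- c(files, f_path)
  tick("stage features", t0)

  plan <- make_resample_plan(
    intersect(study$positives, features$gene_id), features$gene_id,
    n_resamples = config$n_resamples,
    master_seed = derive_seed(config$master_seed, "plan")
  )

  results <- list()
  for (scope in config$scopes) {
    t0 <- as.numeric(Sys.time())
    signature <- select_signature(features, plan, scope,
      frequency_threshold = config$frequency_threshold,
      inner_folds = config$n_folds
    )
    sig_path <- file.path(config$out_dir, paste0("signature_", scope, ".tsv"))
    write_tsv_plain(as.data.frame(signature), sig_path)
    files <- c(files, sig_path)
    tick(paste("stage select", scope), t0)

    t0 <- as.numeric(Sys.time())
    cols <- signature_columns(signature)
    if (length(cols) == 0) {
      log_lines <- c(log_lines, sprintf(
        "scope %s: empty signature; classifying on all %d scope columns",
        scope, length(scope_columns(features, scope))
      ))
      cols <- scope_columns(features, scope)
    }
    ensemble <- run_ensemble(features, plan, cols,
      n_folds = config$n_folds,
      prob_threshold = config$prob_threshold,
      call_threshold = config$call_threshold
    )
    ensemble$scope <- scope
    auc_path <- file.path(config$out_dir, paste0("auc_", scope, ".tsv"))
    write_tsv_plain(
      data.frame(resample = seq_along(ensemble$per_resample_auc), auc = ensemble$per_resample_auc),
      auc_path
    )
    pred_path <- file.path(config$out_dir, paste0("predictions_", scope, ".tsv"))
    write_tsv_plain(as.data.frame(ensemble$predictions), pred_path)
    files <- c(files, auc_path, pred_path)
    tick(paste("stage classify", scope), t0)

    t0 <- as.numeric(Sys.time())
    corr <- feature_correlations(features_raw)
    corr_path <- file.path(config$out_dir, paste0("correlations_", scope, ".tsv"))
    write_tsv_plain(as.data.frame(corr), corr_path)
    files <- c(files, corr_path)
    dist_ds <- if (nrow(signature) > 0) signature else unique(feature_info(features_raw)$dataset_id)
    dist <- distance_distribution_summary(features_raw, dist_ds)
    dist_path <- file.path(config$out_dir, paste0("distances_", scope, ".tsv"))
    write_tsv_plain(as.data.frame(dist), dist_path)
    files <- c(files, dist_path)
    expr_cmp <- NULL
    if (!is.null(study$expression) && length(ensemble$candidates) >= 2) {
      expr_cmp <- compare_expression(ensemble$candidates, study$expression)
      e_path <- file.path(config$out_dir, paste0("expression_", scope, ".tsv"))
      write_tsv_plain(as.data.frame(expr_cmp), e_path)
      files <- c(files, e_path)
    }
    tick(paste("stage evaluate", scope), t0)

    results[[scope]] <- list(
      signature = signature, ensemble = ensemble,
      correlations = corr, distances = dist, expression = expr_cmp
    )
  }

  manifest <- tibble(
    file = sort(unique(files)),
    md5 = unname(tools::md5sum(sort(unique(files))))
  )
  write_tsv_plain(as.data.frame(manifest), file.path(config$out_dir, "manifest.files.tsv"))
  writeLines(log_lines, log_path)
  structure(manifest, results = results, class = c("plurisig_run", class(manifest)))
}
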