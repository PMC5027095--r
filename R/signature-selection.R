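# Step 2 of the framework: L1-penalized logistic regression refit over many
# balanced resamples of the gold-standard positives against random negative
# gene sets, then aggregation of per-resample selections into a signature.

#' Build a balanced resampling plan
#'
#' Each resample pairs the full positive set with an equally sized negative
#' set drawn without replacement from the universe minus the positives.
#' Resample r's draw is seeded deterministically from `(master_seed, r)`, so
#' any single resample can be reproduced in isolation.
#'
#' @param positives character vector of positive gene ids.
#' @param universe character vector of all gene ids under study.
#' @param n_resamples number of balanced resamples (the reference analysis
#'   uses 500).
#' @param master_seed integer seed for the whole plan.
#' @return a `plurisig_resample_plan` list: `positives`, `universe`,
#'   `n_resamples`, `master_seed`, `negative_sets`.
#' @export
make_resample_plan <- function(positives, universe, n_resamples = 500, master_seed = 1) {
  positives <- unique(positives)
  if (!all(positives %in% universe)) abort("positives must be a subset of the universe")
  pool <- setdiff(universe, positives)
  if (length(pool) < length(positives)) {
    abort(sprintf(
      "cannot draw %d negatives from %d non-positive genes",
      length(positives), length(pool)
    ))
  }
  negative_sets <- lapply(seq_len(n_resamples), function(r) {
    set.seed(derive_seed(master_seed, paste0("resample_", r)))
    sample(pool, length(positives))
  })
  structure(
    list(
      positives = positives, universe = universe,
      n_resamples = as.integer(n_resamples), master_seed = as.integer(master_seed),
      negative_sets = negative_sets
    ),
    class = "plurisig_resample_plan"
  )
}

resample_labels <- function(plan, r) {
  genes <- c(plan$positives, plan$negative_sets[[r]])
  stats::setNames(c(rep(1L, length(plan$positives)), rep(0L, length(plan$negative_sets[[r]]))), genes)
}

#' Fit an L1-penalized logistic regression with inner cross-validation
#'
#' Fits the penalized binomial likelihood over a descending lambda path
#' (glmnet coordinate descent; features enter as-is, since the matrix is
#' already Z-scored) and picks the lambda minimizing the mean held-out
#' binomial deviance over stratified inner folds.
#'
#' @param features a normalized `plurisig_features` object, already
#'   restricted to the scope of interest via `columns`.
#' @param labels named 0/1 vector over one resample's genes (names are gene
#'   ids present in `features`).
#' @param columns value columns to use; defaults to all.
#' @param lambda_grid optional descending lambda path; by default glmnet's
#'   100-point log-spaced path.
#' @param inner_folds number of stratified CV folds (default 10).
#' @param fold_seed seed for the fold split.
#' @param ... further arguments passed to [glmnet::cv.glmnet()] (e.g.
#'   `thresh` to tighten the coordinate-descent tolerance).
#' @return a `plurisig_lasso` list: `lambda` (chosen), `intercept`,
#'   `coefficients` (named, at the chosen lambda), `selected` (columns with
#'   nonzero coefficient), `cv_deviance_path` tibble and the underlying
#'   `glmnet` path fit.
#' @export
fit_lasso_logistic <- function(features, labels, columns = NULL,
                               lambda_grid = NULL, inner_folds = 10, fold_seed = 1, ...) {
  if (!is_normalized(features)) abort("features must be Z-score normalized before model fitting")
  columns <- columns %||% feature_info(features)$column
  idx <- match(names(labels), features$gene_id)
  if (anyNA(idx)) abort("labels contain genes absent from the feature matrix")
  x <- as.matrix(features[idx, columns, drop = FALSE])
  y <- as.integer(labels)
  if (length(unique(y)) != 2) abort("labels must contain both classes")
  foldid <- make_stratified_folds(y, inner_folds, seed = fold_seed)
  cv <- glmnet::cv.glmnet(
    x, y,
    family = "binomial", foldid = foldid, type.measure = "deviance",
    lambda = lambda_grid, nlambda = 100, standardize = FALSE, ...
  )
  lam <- cv$lambda.min
  beta <- as.numeric(stats::coef(cv$glmnet.fit, s = lam))
  names(beta) <- c("(intercept)", columns)
  coefs <- beta[-1]
  structure(
    list(
      lambda = lam,
      intercept = beta[[1]],
      coefficients = coefs,
      selected = names(coefs)[coefs != 0],
      cv_deviance_path = tibble(lambda = cv$lambda, mean_deviance = cv$cvm),
      glmnet_fit = cv$glmnet.fit
    ),
    class = "plurisig_lasso"
  )
}

#' Coefficients of a penalized path fit at an arbitrary lambda
#'
#' @param fit a `plurisig_lasso` object.
#' @param lambda penalty value (interpolated on the path if needed).
#' @return named vector: `(intercept)` followed by the feature coefficients.
#' @export
coef_at_lambda <- function(fit, lambda) {
  beta <- as.numeric(stats::coef(fit$glmnet_fit, s = lambda, exact = FALSE))
  stats::setNames(beta, c("(intercept)", names(fit$coefficients)))
}

#' Select a feature signature over a resampling plan
#'
#' Runs [fit_lasso_logistic()] once per resample of `plan` on the scope's
#' columns and aggregates: a column's selection frequency is the fraction of
#' resamples in which its coefficient was nonzero, its sign the sign of the
#' median nonzero coefficient. The signature keeps columns at or above
#' `frequency_threshold`, sorted by descending frequency then column order.
#'
#' @param features a normalized `plurisig_features` object covering the full
#'   gene universe.
#' @param plan a `plurisig_resample_plan`.
#' @param scope feature scope (see [scope_columns()]).
#' @param frequency_threshold minimum selection frequency (default 0.5).
#' @param inner_folds stratified inner CV folds per fit.
#' @return a `plurisig_signature` tibble: `dataset_id`, `feature_type`,
#'   `selection_frequency`, `sign`, `median_coefficient`; per-column
#'   frequencies for all scope columns are kept in the
#'   `all_frequencies` attribute.
#' @export
select_signature <- function(features, plan,
                             scope = c("combined", "epigenetic", "protein_binding", "combined_expression"),
                             frequency_threshold = 0.5, inner_folds = 10) {
  scope <- match.arg(scope)
  cols <- scope_columns(features, scope)
  if (length(cols) == 0) abort(paste0("no feature columns in scope ", scope))
  info <- feature_info(features)
  n_sel <- stats::setNames(integer(length(cols)), cols)
  coef_draws <- lapply(stats::setNames(nm = cols), function(...) numeric())
  for (r in seq_len(plan$n_resamples)) {
    labels <- resample_labels(plan, r)
    fit <- fit_lasso_logistic(
      features, labels,
      columns = cols, inner_folds = inner_folds,
      fold_seed = resample_fold_seed(plan$master_seed, "folds", names(labels))
    )
    nz <- fit$selected
    n_sel[nz] <- n_sel[nz] + 1L
    for (cl in nz) coef_draws[[cl]] <- c(coef_draws[[cl]], fit$coefficients[[cl]])
  }
  med <- vapply(coef_draws, function(v) if (length(v)) stats::median(v) else 0, 0)
  freq_tbl <- tibble(
    column = cols,
    dataset_id = info$dataset_id[match(cols, info$column)],
    feature_type = info$feature_type[match(cols, info$column)],
    selection_frequency = as.numeric(n_sel) / plan$n_resamples,
    median_coefficient = unname(med)
  )
  keep <- freq_tbl$selection_frequency >= frequency_threshold & freq_tbl$median_coefficient != 0
  sig <- freq_tbl[keep, , drop = FALSE]
  sig <- sig[order(-sig$selection_frequency, match(sig$column, cols)), ]
  out <- tibble(
    dataset_id = sig$dataset_id,
    feature_type = sig$feature_type,
    selection_frequency = sig$selection_frequency,
    sign = ifelse(sig$median_coefficient > 0, "+", "-"),
    median_coefficient = sig$median_coefficient
  )
  structure(
    out,
    scope = scope,
    n_resamples = plan$n_resamples,
    frequency_threshold = frequency_threshold,
    columns = sig$column,
    all_frequencies = freq_tbl,
    class = c("plurisig_signature", class(out))
  )
}

signature_columns <- function(signature) attr(signature, "columns", exact = TRUE)

#' @export
print.plurisig_signature <- function(x, ...) {
  cat(sprintf(
    "<plurisig signature: scope %s, %d feature(s) at frequency >= %.2f over %d resamples>\n",
    attr(x, "scope"), nrow(x), attr(x, "frequency_threshold"), attr(x, "n_resamples")
  ))
  NextMethod()
}
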