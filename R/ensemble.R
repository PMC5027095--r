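# Step 3 of the framework: per-resample 10-fold cross-validated logistic
# models on the selected features, AUC per resample, and per-gene prediction
# rates aggregated over the ensemble with the >= 90% candidate call.

# The >= 90% rule: a non-positive gene is a candidate when its prediction
# rate reaches the call threshold (450 of 500 models is a call; 449 is not).
candidate_calls <- function(prediction_rate, is_positive, call_threshold) {
  !is_positive & prediction_rate >= call_threshold
}

logistic_prob <- function(x_train, y, x_score) {
  fit <- suppressWarnings(stats::glm.fit(
    cbind(1, x_train), y,
    family = stats::binomial(), control = list(maxit = 50)
  ))
  eta <- drop(cbind(1, x_score) %*% ifelse(is.na(fit$coefficients), 0, fit$coefficients))
  stats::plogis(eta)
}

#' Run the resampled classification ensemble
#'
#' For each resample of `plan`: its balanced positive/negative genes are
#' split into stratified folds; an unpenalized logistic model on the
#' signature columns scores each held-out fold (out-of-fold probabilities),
#' giving the resample AUC; the model refit on the whole resample scores
#' every other gene. A gene counts as predicted pluripotent in a resample
#' when its applicable probability (out-of-fold for that resample's training
#' genes, full-model otherwise) exceeds `prob_threshold`. The prediction
#' rate is the fraction of resamples in which that happened, and candidates
#' are non-positive genes with rate at or above `call_threshold` (the
#' reference analysis calls genes predicted in >= 90% of 500 models).
#'
#' @param features a normalized `plurisig_features` object over the full
#'   gene universe.
#' @param plan a `plurisig_resample_plan`.
#' @param signature a `plurisig_signature`, or a character vector of feature
#'   columns to model on.
#' @param n_folds stratified CV folds per resample (default 10).
#' @param prob_threshold probability cut for "predicted pluripotent"
#'   (default 0.5, natural for balanced training sets).
#' @param call_threshold minimum prediction rate for a candidate call
#'   (default 0.9).
#' @return a `plurisig_ensemble` list: `scope`, `per_resample_auc`,
#'   `mean_auc`, `sd_auc`, `predictions` tibble (`gene_id`, `n_called`,
#'   `prediction_rate`, `is_positive`, `is_candidate`), `candidates`,
#'   `n_resamples`, thresholds.
#' @export
run_ensemble <- function(features, plan, signature, n_folds = 10,
                         prob_threshold = 0.5, call_threshold = 0.9) {
  if (!is_normalized(features)) abort("features must be Z-score normalized before model fitting")
  cols <- if (inherits(signature, "plurisig_signature")) {
    signature_columns(signature)
  } else {
    as.character(signature)
  }
  if (length(cols) == 0) abort("no features selected: the signature is empty")
  missing_cols <- setdiff(cols, feature_info(features)$column)
  if (length(missing_cols) > 0) {
    abort(paste0("signature column absent from features: ", missing_cols[1]))
  }
  genes <- features$gene_id
  x_all <- as.matrix(features[, cols, drop = FALSE])
  rownames(x_all) <- genes
  n_res <- plan$n_resamples
  called <- stats::setNames(integer(length(genes)), genes)
  aucs <- numeric(n_res)
  for (r in seq_len(n_res)) {
    labels <- resample_labels(plan, r)
    tr_genes <- names(labels)
    tr_idx <- match(tr_genes, genes)
    if (anyNA(tr_idx)) abort("resample plan contains genes absent from the feature matrix")
    x_tr <- x_all[tr_idx, , drop = FALSE]
    y <- as.integer(labels)
    folds <- make_stratified_folds(y, n_folds,
      seed = resample_fold_seed(plan$master_seed, "cvfolds", tr_genes)
    )
    oof <- numeric(length(y))
    for (f in seq_len(n_folds)) {
      hold <- folds == f
      oof[hold] <- logistic_prob(
        x_tr[!hold, , drop = FALSE], y[!hold],
        x_tr[hold, , drop = FALSE]
      )
    }
    aucs[r] <- auc_mann_whitney(y, oof)
    other_idx <- setdiff(seq_along(genes), tr_idx)
    prob <- numeric(length(genes))
    prob[tr_idx] <- oof
    if (length(other_idx) > 0) {
      prob[other_idx] <- logistic_prob(x_tr, y, x_all[other_idx, , drop = FALSE])
    }
    called <- called + (prob > prob_threshold)
  }
  predictions <- tibble(
    gene_id = genes,
    n_called = as.integer(called),
    prediction_rate = as.numeric(called) / n_res,
    is_positive = genes %in% plan$positives
  )
  predictions$is_candidate <- candidate_calls(
    predictions$prediction_rate, predictions$is_positive, call_threshold
  )
  structure(
    list(
      scope = if (inherits(signature, "plurisig_signature")) attr(signature, "scope") else NA_character_,
      per_resample_auc = aucs,
      mean_auc = mean(aucs),
      sd_auc = stats::sd(aucs),
      predictions = predictions,
      candidates = predictions$gene_id[predictions$is_candidate],
      n_resamples = n_res,
      n_folds = n_folds,
      prob_threshold = prob_threshold,
      call_threshold = call_threshold
    ),
    class = "plurisig_ensemble"
  )
}

#' ROC curve and AUC
#'
#' The AUC is the Mann-Whitney probability that a random positive outranks a
#' random negative (ties counted one half); the curve enumerates every
#' distinct score as a threshold, from the most to the least stringent.
#'
#' @param labels binary labels (both classes required).
#' @param scores numeric scores, higher meaning more positive.
#' @return list with `roc` (tibble `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
compute_roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  auc <- auc_mann_whitney(labels, scores) # errors on single-class input
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n_neg, 0)
  list(
    roc = tibble(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr)),
    auc = auc
  )
}

#' Rank feature scopes by ensemble AUC
#'
#' @param results named list (by scope) of `plurisig_ensemble` objects; at
#'   least two scopes.
#' @return tibble (`scope`, `mean_auc`, `sd_auc`, `n_resamples`) sorted by
#'   descending mean AUC, ties broken by scope name.
#' @export
compare_scopes <- function(results) {
  if (length(results) < 2) abort("compare_scopes needs at least two scopes")
  out <- dplyr::bind_rows(lapply(names(results), function(sc) {
    e <- results[[sc]]
    tibble(
      scope = sc, mean_auc = e$mean_auc, sd_auc = e$sd_auc,
      n_resamples = e$n_resamples
    )
  }))
  out[order(-out$mean_auc, out$scope), ]
}

#' @export
print.plurisig_ensemble <- function(x, ...) {
  cat(sprintf(
    "<plurisig ensemble: scope %s, %d resamples, mean AUC %.3f (sd %.3f), %d candidate(s)>\n",
    x$scope, x$n_resamples, x$mean_auc, x$sd_auc, length(x$candidates)
  ))
  invisible(x)
}
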