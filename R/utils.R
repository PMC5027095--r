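#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble is_tibble
NULL

# Deterministic 31-bit seed derived from a master seed and a stage tag, so a
# stage re-run in isolation sees the same stream as inside the pipeline.
derive_seed <- function(master_seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  s <- (as.numeric(master_seed) %% 2147483647) * 48271 + h * 8191 + 1
  as.integer(s %% 2147483647L)
}

# Stratified fold ids: within each class, fold labels are shuffled so every
# fold keeps the class balance as even as integer counts allow.
make_stratified_folds <- function(y, k, seed = NULL) {
  stopifnot(k >= 2)
  if (!is.null(seed)) set.seed(seed)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

# Laplace (double-exponential) sampler; scale b, location mu.
rlaplace <- function(n, mu = 0, b = 1) {
  u <- stats::runif(n) - 0.5
  mu - b * sign(u) * log1p(-2 * abs(u))
}

#' Area under the ROC curve by the rank (Mann-Whitney) formula
#'
#' AUC is computed as U / (n_pos * n_neg) where U is the Mann-Whitney
#' statistic with ties counted one half, i.e. the probability that a random
#' positive outranks a random negative.
#'
#' @param labels binary vector (0/1 or logical); both classes must be present.
#' @param scores numeric scores, higher meaning more positive.
#' @return AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) {
    abort("`labels` and `scores` must have equal length")
  }
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    abort("both classes must be present to compute an AUC")
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

`%empty%` <- function(x, y) if (length(x) == 0) y else x

# Manifest paths may be relative to the manifest's own directory.
resolve_paths <- function(paths, base) {
  ifelse(grepl("^(/|[A-Za-z]:)", paths), paths, file.path(base, paths))
}

# Fold seed derived from the resample's *content* (its gene set), not its
# index, so per-gene prediction rates are invariant to resample order.
resample_fold_seed <- function(master_seed, stage, genes) {
  derive_seed(master_seed, paste(c(stage, sort(genes)), collapse = "|"))
}
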