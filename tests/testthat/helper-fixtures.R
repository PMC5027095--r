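# Shared fixtures: tiny in-code studies, hand-built feature matrices and the
# independent oracles used across the suite.

tiny_annotation <- function(tss = c(1000, 3000, 6000),
                            strand = rep_len(c("+", "-"), length(tss)),
                            chrom = "chr1") {
  tibble::tibble(
    gene_id = sprintf("g%02d", seq_along(tss)),
    chrom = chrom, tss = as.integer(tss), strand = strand
  )
}

peak_tbl <- function(chrom, start, end, name = NA_character_,
                     signal_value = NA_real_, summit_offset = NA_integer_) {
  tibble::tibble(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    name = rep_len(name, length(start)),
    signal_value = rep_len(signal_value, length(start)),
    summit_offset = rep_len(as.integer(summit_offset), length(start))
  )
}

# Build a plurisig_features object directly from a named list of numeric
# columns plus per-column (dataset_id, feature_type, assay_class) metadata.
manual_features <- function(gene_ids, cols, info, normalized = FALSE) {
  tbl <- tibble::tibble(gene_id = gene_ids, !!!cols)
  plurisig:::new_plurisig_features(tbl, info, normalized = normalized)
}

# A normalized random feature matrix: `planted` columns carry a class signal
# of the given strength for the first n_pos genes, the rest are pure noise.
random_features <- function(n_genes, n_noise, planted = 0, effect = 2,
                            n_pos = n_genes / 2, seed = 1) {
  set.seed(seed)
  y <- c(rep(1, n_pos), rep(0, n_genes - n_pos))
  cols <- list()
  info <- list()
  ids <- character()
  total <- n_noise + planted
  for (j in seq_len(total)) {
    ds <- sprintf("ds%02d", j)
    id <- paste0(ds, ".count")
    x <- rnorm(n_genes)
    if (j <= planted) x <- x + effect * y
    cols[[id]] <- x
    info[[id]] <- tibble::tibble(
      column = id, dataset_id = ds, feature_type = "count",
      assay_class = if (j %% 2 == 0) "protein_binding" else "epigenetic"
    )
    ids <- c(ids, id)
  }
  f <- manual_features(sprintf("g%04d", seq_len(n_genes)), cols, dplyr::bind_rows(info))
  list(
    features = zscore_normalize(f),
    labels = stats::setNames(y, sprintf("g%04d", seq_len(n_genes))),
    planted_columns = ids[seq_len(planted)]
  )
}

# Brute-force nearest-TSS oracle over all (peak, gene) pairs.
brute_force_assignment <- function(peaks, annotation) {
  anchor <- ifelse(!is.na(peaks$summit_offset),
    peaks$start + peaks$summit_offset,
    floor((peaks$start + peaks$end) / 2)
  )
  vapply(seq_len(nrow(peaks)), function(i) {
    cand <- annotation[annotation$chrom == peaks$chrom[i], ]
    if (nrow(cand) == 0) {
      return(NA_character_)
    }
    d <- abs(anchor[i] - cand$tss)
    best <- which(d == min(d))
    sort(cand$gene_id[best])[1]
  }, "")
}

# Pairwise Mann-Whitney AUC oracle: wins + half-ties over all pos-neg pairs.
brute_force_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Exact hypergeometric upper-tail oracle by direct summation.
brute_force_overlap_p <- function(both, n_a, n_b, universe) {
  ks <- both:min(n_a, n_b)
  sum(choose(n_a, ks) * choose(universe - n_a, n_b - ks)) / choose(universe, n_b)
}

# Penalized logistic objective: mean negative log-likelihood + lambda * |beta|_1
# (the intercept is unpenalized).
lasso_objective <- function(par, x, y, lambda) {
  eta <- par[1] + drop(x %*% par[-1])
  mean(log1p(exp(-(2 * y - 1) * eta))) + lambda * sum(abs(par[-1]))
}

# Independent minimizer of the penalized objective: coarse grid over the
# coefficients followed by Nelder-Mead refinement from the best grid points.
brute_force_lasso <- function(x, y, lambda, span = 3, step = 0.25) {
  grid <- seq(-span, span, by = step)
  best <- NULL
  for (b1 in grid) {
    for (b2 in grid) {
      o <- stats::optimize(
        function(b0) lasso_objective(c(b0, b1, b2), x, y, lambda),
        c(-5, 5)
      )
      if (is.null(best) || o$objective < best$value) {
        best <- list(par = c(o$minimum, b1, b2), value = o$objective)
      }
    }
  }
  refined <- stats::optim(best$par, lasso_objective,
    x = x, y = y, lambda = lambda,
    method = "Nelder-Mead", control = list(maxit = 5000, reltol = 1e-12)
  )
  # polish exact zeros: L1 solutions sit on axes Nelder-Mead cannot reach
  par <- refined$par
  for (j in 2:3) {
    zeroed <- par
    zeroed[j] <- 0
    z <- stats::optim(zeroed, function(p) {
      p[j] <- 0
      lasso_objective(p, x, y, lambda)
    }, method = "Nelder-Mead", control = list(maxit = 2000, reltol = 1e-12))
    if (z$value < refined$value) {
      refined <- z
      refined$par[j] <- 0
      par <- refined$par
    }
  }
  list(par = refined$par, value = refined$value)
}

# Spearman rho by the explicit rank formula (average ranks for ties).
brute_force_spearman <- function(a, b) {
  ra <- rank(a)
  rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

small_study_config <- function(seed = 1, ...) {
  args <- list(
    n_genes = 240, n_positive = 40,
    n_datasets_epigenetic = 3, n_datasets_protein = 3,
    signature_datasets = signature_effects(c("ep01", "pb01"),
      count = 1.5, breadth = 1.5, distance = -0.5
    ),
    seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(generator_config, args)
}
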