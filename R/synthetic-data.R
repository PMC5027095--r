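# Synthetic studies with the statistical structure the analysis assumes:
# peaks placed around TSSs, peak count and breadth positively coupled
# through a shared latent intensity, a subset of "signature" datasets whose
# features shift at positive genes, and balanced gold-standard labels.

#' Per-dataset signature effect sizes
#'
#' Convenience constructor for the `signature_datasets` field of
#' [generator_config()]: the same latent-scale effect triple for each listed
#' dataset. Count and breadth effects act on the latent intensity / log
#' breadth; the distance effect shifts the Laplace location in units of
#' `distance_scale`.
#'
#' @param dataset_ids character vector of dataset ids.
#' @param count,breadth,distance effect sizes on the latent scale.
#' @return named list of effect triples.
#' @export
signature_effects <- function(dataset_ids, count = 1, breadth = 1, distance = -0.5) {
  stats::setNames(
    lapply(dataset_ids, function(d) list(count = count, breadth = breadth, distance = distance)),
    dataset_ids
  )
}

#' Configuration of the synthetic-study generator
#'
#' Defaults define the reference simulated study: 2000 genes of which 200
#' are positives, 10 histone-mark and 10 protein-binding datasets, 6 of them
#' (3 + 3) signature datasets with count/breadth effects 1.0 and distance
#' effect -0.5, and `breadth_coupling = 0.46`, the value at which a
#' calibration sweep puts the pooled count-breadth Spearman correlation at
#' about 0.22.
#'
#' @param n_genes number of genes (>= 2).
#' @param n_positive number of gold-standard positive genes (< `n_genes`).
#' @param n_datasets_epigenetic,n_datasets_protein dataset counts per assay
#'   class; ids are `ep01..`, `pb01..`.
#' @param signature_datasets named list mapping dataset ids to effect triples
#'   (see [signature_effects()]); keys must be declared dataset ids.
#' @param baseline_peak_rate expected extra peaks per gene per dataset
#'   (counts are `1 + Poisson`).
#' @param breadth_coupling coupling in \[0, 1\] between the latent intensity
#'   and both peak count and log breadth; the single knob behind the
#'   count-breadth rank correlation.
#' @param distance_scale Laplace scale (bp) of peak-anchor offsets from the
#'   TSS.
#' @param expression_shift log-scale expression shift for positive genes.
#' @param missing_rate probability a gene has no peaks in a dataset (reduced
#'   for positives in signature datasets with a positive count effect).
#' @param seed integer master seed; every stage stream is derived from it.
#' @param breadth_scale median breadth (bp) of a baseline broadest peak.
#' @param breadth_sdlog gene-level lognormal sd of the broadest-peak breadth.
#' @param dataset_mu_sd sd of per-dataset baseline intensity offsets.
#' @return validated config (class `plurisig_generator_config`).
#' @export
generator_config <- function(n_genes = 2000,
                             n_positive = 200,
                             n_datasets_epigenetic = 10,
                             n_datasets_protein = 10,
                             signature_datasets = NULL,
                             baseline_peak_rate = 0.5,
                             breadth_coupling = 0.46,
                             distance_scale = 5000,
                             expression_shift = 1,
                             missing_rate = 0.1,
                             seed = 1,
                             breadth_scale = 1000,
                             breadth_sdlog = 0.45,
                             dataset_mu_sd = 0.5) {
  ep_ids <- sprintf("ep%02d", seq_len(n_datasets_epigenetic)) %empty% character()
  pb_ids <- sprintf("pb%02d", seq_len(n_datasets_protein)) %empty% character()
  if (is.null(signature_datasets)) {
    signature_datasets <- signature_effects(c(
      utils::head(ep_ids, 3), utils::head(pb_ids, 3)
    ))
  }
  cfg <- structure(
    list(
      n_genes = as.integer(n_genes), n_positive = as.integer(n_positive),
      n_datasets_epigenetic = as.integer(n_datasets_epigenetic),
      n_datasets_protein = as.integer(n_datasets_protein),
      signature_datasets = signature_datasets,
      baseline_peak_rate = baseline_peak_rate,
      breadth_coupling = breadth_coupling,
      distance_scale = distance_scale,
      expression_shift = expression_shift,
      missing_rate = missing_rate,
      seed = as.integer(seed),
      breadth_scale = breadth_scale,
      breadth_sdlog = breadth_sdlog,
      dataset_mu_sd = dataset_mu_sd
    ),
    class = "plurisig_generator_config"
  )
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  if (cfg$n_genes < 2) abort("n_genes must be at least 2")
  if (cfg$n_positive < 1 || cfg$n_positive >= cfg$n_genes) {
    abort("n_positive must satisfy 1 <= n_positive < n_genes")
  }
  if (cfg$n_datasets_epigenetic < 0 || cfg$n_datasets_protein < 0) {
    abort("dataset counts must be non-negative")
  }
  ids <- dataset_ids(cfg)
  extra <- setdiff(names(cfg$signature_datasets), ids)
  if (length(extra) > 0) {
    abort(paste0("signature_datasets names not in declared datasets: ", extra[1]))
  }
  for (p in c("missing_rate", "breadth_coupling")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) abort(paste0(p, " must be in [0, 1]"))
  }
  if (cfg$baseline_peak_rate <= 0) abort("baseline_peak_rate must be positive")
  if (cfg$distance_scale <= 0) abort("distance_scale must be positive")
  cfg
}

dataset_ids <- function(cfg) {
  c(
    sprintf("ep%02d", seq_len(cfg$n_datasets_epigenetic)) %empty% character(),
    sprintf("pb%02d", seq_len(cfg$n_datasets_protein)) %empty% character()
  )
}

generator_manifest <- function(cfg, dir = NA_character_) {
  ids <- dataset_ids(cfg)
  classes <- c(
    rep("epigenetic", cfg$n_datasets_epigenetic),
    rep("protein_binding", cfg$n_datasets_protein)
  )
  tibble(
    dataset_id = ids,
    assay_class = classes,
    label = paste0(ifelse(classes == "epigenetic", "mark_", "factor_"), ids),
    path = if (is.na(dir)) NA_character_ else file.path(dir, paste0(ids, ".broadPeak")),
    dialect = "broadPeak"
  )
}

#' Simulate a gene annotation
#'
#' Genes sit on one synthetic chromosome with TSSs 250 kb apart (well beyond
#' any realistic peak offset at the default `distance_scale`), so the true
#' closest-TSS assignment of every simulated peak is unambiguous by
#' construction. Strands alternate + / -.
#'
#' @param config a [generator_config()].
#' @return annotation tibble (`gene_id`, `chrom`, `tss`, `strand`).
#' @export
simulate_annotation <- function(config) {
  validate_generator_config(config)
  n <- config$n_genes
  tibble(
    gene_id = sprintf("g%05d", seq_len(n)),
    chrom = "chrS",
    tss = as.integer(1e6 + (seq_len(n) - 1) * 250000),
    strand = rep_len(c("+", "-"), n)
  )
}

dataset_effects <- function(cfg, ds) {
  eff <- cfg$signature_datasets[[ds]]
  list(
    count = eff$count %||% 0,
    breadth = eff$breadth %||% 0,
    distance = eff$distance %||% 0
  )
}

#' Simulate peak files for every dataset
#'
#' For gene g in dataset d a latent intensity `z ~ Normal(mu_d + s_count *
#' pos, 1)` drives both the peak count, `1 + Poisson(rate * exp(coupling *
#' z))`, and the log breadth of the gene's broadest peak, so the two
#' features are rank-correlated exactly as strongly as `breadth_coupling`
#' dictates. The broadest peak's breadth is drawn once at the gene level and
#' secondary peaks are scaled-down copies, which makes count and breadth
#' exactly independent when the coupling is 0. Peak anchors are offset from
#' the TSS by a Laplace draw on the strand-aware axis, shifted by the
#' distance effect for positives in signature datasets. With probability
#' `missing_rate` (reduced by `exp(-count effect)` for positives in
#' signature datasets) a gene has no peaks at all.
#'
#' @param config a [generator_config()].
#' @param annotation output of [simulate_annotation()].
#' @param positives character vector of positive gene ids.
#' @return named list (by dataset id) of peak tibbles.
#' @export
simulate_peaks <- function(config, annotation, positives) {
  validate_generator_config(config)
  if (nrow(annotation) == 0) abort("annotation must be nonempty")
  n <- nrow(annotation)
  pos <- annotation$gene_id %in% positives
  strand_sign <- ifelse(annotation$strand == "+", 1L, -1L)
  out <- list()
  for (ds in dataset_ids(config)) {
    set.seed(derive_seed(config$seed, paste0("peaks_", ds)))
    eff <- dataset_effects(config, ds)
    mu_d <- stats::rnorm(1, 0, config$dataset_mu_sd)
    miss_p <- config$missing_rate *
      ifelse(pos & eff$count > 0, exp(-eff$count), 1)
    present <- stats::runif(n) >= miss_p
    z <- stats::rnorm(n, mu_d + eff$count * pos, 1)
    count <- 1L + stats::rpois(n, config$baseline_peak_rate * exp(config$breadth_coupling * z))
    top_breadth <- pmax(2L, as.integer(round(exp(
      log(config$breadth_scale) + config$breadth_coupling * z +
        eff$breadth * pos + stats::rnorm(n, 0, config$breadth_sdlog)
    ))))
    idx <- which(present)
    k <- count[idx]
    g_rep <- rep(idx, k)
    peak_no <- sequence(k)
    loc <- eff$distance * config$distance_scale * pos[g_rep]
    offs <- round(rlaplace(length(g_rep), loc, config$distance_scale))
    # peak 1 carries the gene-level broadest breadth; later peaks are
    # scaled-down copies, so the per-gene breadth feature equals the
    # gene-level draw regardless of the count
    breadths <- ifelse(
      peak_no == 1L, top_breadth[g_rep],
      pmax(1L, as.integer(round(top_breadth[g_rep] * stats::runif(length(g_rep), 0.2, 0.9))))
    )
    mid <- annotation$tss[g_rep] + strand_sign[g_rep] * offs
    start <- pmax(0L, as.integer(mid - floor(breadths / 2)))
    out[[ds]] <- tibble(
      chrom = annotation$chrom[g_rep] %empty% character(),
      start = start %empty% integer(),
      end = (start + as.integer(breadths)) %empty% integer(),
      name = sprintf("%s_%s_%d", ds, annotation$gene_id[g_rep], peak_no) %empty% character(),
      signal_value = round(exp(stats::rnorm(length(g_rep), 1.5, 0.4)), 4) %empty% double(),
      summit_offset = rep(NA_integer_, length(g_rep))
    )
  }
  out
}

#' Simulate an expression table
#'
#' Log expression is `Normal(2, 1)` plus `expression_shift` for positives;
#' the reported value is its exponential, so every gene is "expressed".
#'
#' @inheritParams simulate_peaks
#' @return expression tibble (`gene_id`, `expression`).
#' @export
simulate_expression <- function(config, positives, annotation) {
  validate_generator_config(config)
  set.seed(derive_seed(config$seed, "expression"))
  pos <- annotation$gene_id %in% positives
  tibble(
    gene_id = annotation$gene_id,
    expression = exp(stats::rnorm(nrow(annotation), 2, 1) + config$expression_shift * pos)
  )
}

#' Generate a complete synthetic study
#'
#' Composes [simulate_annotation()], a seeded draw of the positive gene set,
#' [simulate_peaks()] and [simulate_expression()]. When `dir` is given the
#' study is also written to disk (annotation.tsv, manifest.tsv,
#' expression.tsv, positives.txt and one broadPeak file per dataset) through
#' the package's own writers, so re-reading reproduces the in-memory study.
#'
#' @param config a [generator_config()].
#' @param dir optional output directory (created if missing).
#' @return a `plurisig_study` list: `annotation`, `manifest`, `peaks`,
#'   `expression`, `positives`, `config`.
#' @export
generate_study <- function(config, dir = NULL) {
  validate_generator_config(config)
  annotation <- simulate_annotation(config)
  set.seed(derive_seed(config$seed, "positives"))
  positives <- sort(sample(annotation$gene_id, config$n_positive))
  peaks <- simulate_peaks(config, annotation, positives)
  expression <- simulate_expression(config, positives, annotation)
  manifest <- generator_manifest(config, dir %||% NA_character_)
  study <- structure(
    list(
      annotation = annotation, manifest = manifest, peaks = peaks,
      expression = expression, positives = positives, config = config
    ),
    class = "plurisig_study"
  )
  if (!is.null(dir)) write_study(study, dir)
  study
}

#' @export
#' @rdname generate_study
#' @param study a `plurisig_study`.
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  # paths are written relative to the study directory so a study written to
  # two different directories is byte-identical
  study$manifest$path <- paste0(study$manifest$dataset_id, ".broadPeak")
  write_gene_annotation(study$annotation, file.path(dir, "annotation.tsv"))
  write_dataset_manifest(study$manifest, file.path(dir, "manifest.tsv"))
  write_expression_table(study$expression, file.path(dir, "expression.tsv"))
  write_gene_list(study$positives, file.path(dir, "positives.txt"))
  for (ds in study$manifest$dataset_id) {
    write_peak_file(study$peaks[[ds]], file.path(dir, paste0(ds, ".broadPeak")))
  }
  invisible(dir)
}

#' @export
#' @rdname generate_study
read_study <- function(dir) {
  manifest <- read_dataset_manifest(file.path(dir, "manifest.tsv"))
  manifest$path <- resolve_paths(manifest$path, dir)
  peaks <- lapply(seq_len(nrow(manifest)), function(i) {
    read_peak_file(manifest$path[i], manifest$dialect[i])
  })
  names(peaks) <- manifest$dataset_id
  structure(
    list(
      annotation = read_gene_annotation(file.path(dir, "annotation.tsv")),
      manifest = manifest,
      peaks = peaks,
      expression = read_expression_table(file.path(dir, "expression.tsv")),
      positives = read_gene_list(file.path(dir, "positives.txt")),
      config = NULL
    ),
    class = "plurisig_study"
  )
}

#' @export
print.plurisig_study <- function(x, ...) {
  cat(sprintf(
    "<plurisig synthetic study: %d genes (%d positive), %d datasets>\n",
    nrow(x$annotation), length(x$positives), nrow(x$manifest)
  ))
  invisible(x)
}
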